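# Branch-specific METs prediction and calibration fitting. Each branch
# (nonlocomotive / locomotive) is a linear equation in the epoch synthetic
# acceleration (the gravity-removed FSA, in mg), optionally with weight, age
# and sex covariates. Three child calibrations are packaged; new models are
# fitted by OLS from labeled epoch + calorimetry data.

MIN_METS <- 0.1

#' Construct a branch regression model
#'
#' @param branch `"nonlocomotive"` or `"locomotive"`.
#' @param intercept Intercept in METs.
#' @param coef_sa Slope in METs per mg of synthetic acceleration.
#' @param coef_weight,coef_age,coef_sex Optional covariate coefficients
#'   (METs per kg, METs per year, METs for girls vs boys; sex coded
#'   0 = boy, 1 = girl). `NULL` when absent from the model form.
#' @param r2 Coefficient of determination (adjusted when covariates are
#'   present), or `NA`.
#' @param rmse Root mean square error in METs, or `NA`.
#' @return An object of class `regression_model`.
#' @export
regression_model <- function(branch, intercept, coef_sa,
                             coef_weight = NULL, coef_age = NULL,
                             coef_sex = NULL, r2 = NA_real_,
                             rmse = NA_real_) {
  branch <- match.arg(branch, c("nonlocomotive", "locomotive"))
  if (!is.na(rmse) && rmse < 0) stop("rmse must be non-negative")
  structure(list(branch = branch, intercept = intercept, coef_sa = coef_sa,
                 coef_weight = coef_weight, coef_age = coef_age,
                 coef_sex = coef_sex, r2 = r2, rmse = rmse),
            class = "regression_model")
}

.has_covariates <- function(m) {
  !is.null(m$coef_weight) || !is.null(m$coef_age) || !is.null(m$coef_sex)
}

#' @export
print.regression_model <- function(x, ...) {
  terms <- sprintf("%.3f x SA + %.3f", x$coef_sa, x$intercept)
  if (!is.null(x$coef_weight)) terms <- paste0(terms, sprintf(" + %.3f x weight", x$coef_weight))
  if (!is.null(x$coef_age)) terms <- paste0(terms, sprintf(" + %.3f x age", x$coef_age))
  if (!is.null(x$coef_sex)) terms <- paste0(terms, sprintf(" + %.3f x sex", x$coef_sex))
  cat(sprintf("<%s branch: METs = %s>", x$branch, terms),
      if (!is.na(x$r2)) sprintf(" R2 = %.3f", x$r2) else "",
      if (!is.na(x$rmse)) sprintf(" RMSE = %.3f", x$rmse) else "", "\n", sep = "")
  invisible(x)
}

#' Construct a two-branch model set
#'
#' @param nonlocomotive,locomotive [regression_model()] objects for the two
#'   branches.
#' @param classifier The [classifier_config()] bundled with the equations.
#' @param provenance One of `"child_standard_total"`, `"child_standard_dev"`,
#'   `"child_multivariable"`, `"user_fit"`.
#' @return An object of class `model_set`.
#' @export
model_set <- function(nonlocomotive, locomotive,
                      classifier = classifier_config(),
                      provenance = "user_fit") {
  stopifnot(inherits(nonlocomotive, "regression_model"),
            inherits(locomotive, "regression_model"))
  if (nonlocomotive$branch != "nonlocomotive" ||
      locomotive$branch != "locomotive")
    stop("branch models supplied in the wrong slots")
  structure(list(nonlocomotive = nonlocomotive, locomotive = locomotive,
                 classifier = classifier, provenance = provenance),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set '%s', threshold %.2f>\n", x$provenance,
              x$classifier$threshold))
  print(x$nonlocomotive); print(x$locomotive)
  invisible(x)
}

.model_to_list <- function(m) {
  keep <- c("intercept", "coef_sa", "coef_weight", "coef_age", "coef_sex",
            "r2", "rmse")
  out <- m[keep]
  out[!vapply(out, function(v) is.null(v) || (length(v) == 1 && is.na(v)),
              logical(1))]
}

#' Serialize a model set to JSON
#' @param model A [model_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(model, path) {
  obj <- list(nonlocomotive = .model_to_list(model$nonlocomotive),
              locomotive = .model_to_list(model$locomotive),
              classifier = list(threshold = model$classifier$threshold,
                                movement_floor_mg = model$classifier$movement_floor_mg,
                                bout_rule = model$classifier$bout_rule),
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model set from JSON or a packaged name
#'
#' Packaged calibrations: `"child_standard_total"` (all 68 children),
#' `"child_standard_dev"` (48-child development group) and
#' `"child_multivariable"` (covariate-adjusted equations). Any other value is
#' treated as a file path.
#'
#' @param name_or_path Packaged model name or path to a model JSON.
#' @return A [model_set()].
#' @export
load_model_set <- function(name_or_path) {
  packaged <- c("child_standard_total", "child_standard_dev",
                "child_multivariable")
  path <- if (name_or_path %in% packaged) {
    system.file("extdata", "models", paste0(name_or_path, ".json"),
                package = "grpaca", mustWork = TRUE)
  } else name_or_path
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(branch, l) {
    regression_model(branch, intercept = l$intercept, coef_sa = l$coef_sa,
                     coef_weight = l$coef_weight, coef_age = l$coef_age,
                     coef_sex = l$coef_sex,
                     r2 = if (is.null(l$r2)) NA_real_ else l$r2,
                     rmse = if (is.null(l$rmse)) NA_real_ else l$rmse)
  }
  cl <- classifier_config(threshold = obj$classifier$threshold,
                          movement_floor_mg = obj$classifier$movement_floor_mg)
  model_set(mk("nonlocomotive", obj$nonlocomotive),
            mk("locomotive", obj$locomotive),
            classifier = cl, provenance = obj$provenance)
}

#' Predict METs from synthetic acceleration
#'
#' Evaluates the branch equation METs = intercept + coef_sa x SA (+ covariate
#' terms). Predictions are floored at 0.1 METs; floored values are flagged in
#' the `"floored"` attribute.
#'
#' @param sa_mg Synthetic acceleration in mg (the gravity-removed FSA;
#'   vectorized, non-negative).
#' @param branch `"nonlocomotive"` or `"locomotive"`.
#' @param model A [model_set()].
#' @param subject A one-row subject data.frame (with `weight_kg`, `age_yr`,
#'   `sex_code`); required iff the branch model has covariate terms.
#' @return METs, with a logical `"floored"` attribute.
#' @export
predict_mets <- function(sa_mg, branch, model, subject = NULL) {
  branch <- match.arg(branch, c("nonlocomotive", "locomotive"))
  if (any(sa_mg < 0)) stop("sa_mg must be non-negative")
  m <- model[[branch]]
  mets <- m$intercept + m$coef_sa * sa_mg
  if (.has_covariates(m)) {
    if (is.null(subject))
      stop("covariate model requires a subject record")
    if (!is.null(m$coef_weight)) mets <- mets + m$coef_weight * subject$weight_kg
    if (!is.null(m$coef_age)) mets <- mets + m$coef_age * subject$age_yr
    if (!is.null(m$coef_sex)) mets <- mets + m$coef_sex * subject$sex_code
  }
  floored <- mets < MIN_METS
  mets[floored] <- MIN_METS
  attr(mets, "floored") <- floored
  mets
}

#' Classify and predict METs for an epoch series
#'
#' Each epoch is classified with the model's bundled classifier and routed to
#' the matching branch equation; the SA fed to the equation is the epoch FSA
#' (the gravity-removed feature — the published intercepts near 1.2 METs
#' correspond to movement-free epochs with SA near 0).
#'
#' @param features An [epoch_features()] table from one recording.
#' @param model A [model_set()].
#' @param subject Subject record, required for covariate models.
#' @return A data.frame `epoch_index, class, mets` (zero rows for empty
#'   input).
#' @export
predict_series <- function(features, model, subject = NULL) {
  if (nrow(features) == 0L)
    return(data.frame(epoch_index = integer(), class = character(),
                      mets = numeric()))
  cls <- classify_epoch(features, model$classifier)
  mets <- numeric(nrow(features))
  for (br in c("nonlocomotive", "locomotive")) {
    idx <- which(cls == br)
    if (length(idx))
      mets[idx] <- as.numeric(predict_mets(features$fsa_mg[idx], br, model,
                                           subject))
  }
  data.frame(epoch_index = features$epoch_index, class = cls, mets = mets,
             stringsAsFactors = FALSE)
}

#' Fit a branch METs equation by ordinary least squares
#'
#' Regresses measured METs on synthetic acceleration (and an explicit
#' covariate set; stepwise selection is deliberately not provided). Reports
#' R^2 (adjusted when covariates are present) and RMSE (residual standard
#' error, denominator n - p - 1).
#'
#' @param rows A data.frame with columns `sa_mg`, `mets`, and (when used as
#'   covariates) `weight_kg`, `age_yr`, `sex_code`.
#' @param branch `"nonlocomotive"` or `"locomotive"`.
#' @param covariates Character subset of `c("weight", "age", "sex")`.
#' @return A [regression_model()] with an `"fit"` attribute holding the `lm`
#'   object.
#' @export
fit_branch_model <- function(rows, branch, covariates = character()) {
  branch <- match.arg(branch, c("nonlocomotive", "locomotive"))
  if (length(covariates))
    covariates <- match.arg(covariates, c("weight", "age", "sex"),
                            several.ok = TRUE)
  cov_cols <- c(weight = "weight_kg", age = "age_yr", sex = "sex_code")
  cols <- c("sa_mg", unname(cov_cols[covariates]))
  miss <- setdiff(c(cols, "mets"), names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  p <- length(cols)
  if (nrow(rows) < p + 2L)
    stop(sprintf("need at least %d rows to fit %d predictors", p + 2L, p))
  X <- as.matrix(cbind(1, rows[cols]))
  colnames(X) <- c("(Intercept)", cols)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fml <- stats::reformulate(cols, response = "mets")
  fit <- stats::lm(fml, data = rows)
  s <- summary(fit)
  cf <- stats::coef(fit)
  m <- regression_model(
    branch,
    intercept = unname(cf["(Intercept)"]),
    coef_sa = unname(cf["sa_mg"]),
    coef_weight = if ("weight" %in% covariates) unname(cf["weight_kg"]),
    coef_age = if ("age" %in% covariates) unname(cf["age_yr"]),
    coef_sex = if ("sex" %in% covariates) unname(cf["sex_code"]),
    r2 = if (length(covariates)) s$adj.r.squared else s$r.squared,
    rmse = s$sigma
  )
  attr(m, "fit") <- fit
  m
}

#' Stratified development / cross-validation split
#'
#' Splits subjects into a development and a cross-validation group within
#' each sex x age-band stratum (bands 6-9 and 10-12 years by default), with
#' per-stratum rounded allocation, deterministically for a given seed.
#'
#' @param subjects Subject data.frame (`subject_id`, `sex_code`, `age_yr`).
#' @param dev_fraction Fraction allocated to the development group
#'   (default 48/68).
#' @param seed Integer seed; the split is a pure function of
#'   (subjects, dev_fraction, seed).
#' @param age_break Age separating the two bands (default 10: 6-9 vs 10-12).
#' @return A list with character vectors `dev` and `cv` of subject ids.
#' @export
split_development_crossvalidation <- function(subjects, dev_fraction = 48 / 68,
                                              seed = 1L, age_break = 10) {
  if (dev_fraction <= 0 || dev_fraction >= 1)
    stop("dev_fraction must lie in (0, 1)")
  band <- factor(ifelse(subjects$age_yr < age_break, "younger", "older"),
                 levels = c("younger", "older"))
  sex <- factor(subjects$sex_code, levels = c(0L, 1L))
  strata <- split(subjects$subject_id, interaction(sex, band, drop = FALSE))
  empty <- names(strata)[lengths(strata) == 0L]
  if (length(empty))
    warning("empty strata: ", paste(empty, collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  dev <- character()
  for (ids in strata) {
    if (length(ids) == 0L) next
    n_dev <- round(dev_fraction * length(ids))
    dev <- c(dev, sample(ids, n_dev))
  }
  list(dev = sort(dev), cv = sort(setdiff(subjects$subject_id, dev)))
}
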