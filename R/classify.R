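# GRPACA classification: an epoch whose USA/FSA ratio is at or above the
# cut-off is nonlocomotive (posture change inflates USA but not FSA); below
# the cut-off it is locomotive. Movement-free epochs (FSA under the floor)
# are sedentary, hence nonlocomotive.

#' Classifier configuration
#'
#' @param threshold USA/FSA cut-off; 1.12 is the child calibration default,
#'   1.16 the adult preset (`preset = "adult"`).
#' @param movement_floor_mg FSA below this marks a movement-free epoch whose
#'   ratio is undefined; classified nonlocomotive (default 3 mg, the device
#'   resolution).
#' @param bout_rule Bout decision rule; only `"majority_vote"` is defined.
#' @param preset Convenience: `"child"` (1.12) or `"adult"` (1.16); an
#'   explicit `threshold` wins.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(threshold = NULL, movement_floor_mg = 3,
                              bout_rule = "majority_vote",
                              preset = c("child", "adult")) {
  preset <- match.arg(preset)
  if (is.null(threshold))
    threshold <- if (preset == "adult") 1.16 else 1.12
  if (threshold < 1) stop("threshold must be at least 1")
  if (movement_floor_mg < 0) stop("movement_floor_mg must be >= 0")
  bout_rule <- match.arg(bout_rule, "majority_vote")
  structure(list(threshold = threshold,
                 movement_floor_mg = movement_floor_mg,
                 bout_rule = bout_rule),
            class = "classifier_config")
}

#' Classify epochs by USA/FSA ratio
#'
#' Vectorized over the rows of an epoch feature table. An epoch is
#' nonlocomotive when FSA is below the movement floor (sedentary) or when the
#' ratio is at or above the threshold (ties go to nonlocomotive, reserving
#' the locomotive branch for unambiguous gait); otherwise locomotive.
#'
#' @param features An [epoch_features()] table (or any data.frame with
#'   `usa_mg`, `fsa_mg`, `ratio`).
#' @param config A [classifier_config()].
#' @return Character vector of `"nonlocomotive"` / `"locomotive"`.
#' @export
classify_epoch <- function(features, config = classifier_config()) {
  ratio <- ifelse(features$fsa_mg < config$movement_floor_mg,
                  NA_real_, features$ratio)
  ifelse(is.na(ratio) | ratio >= config$threshold,
         "nonlocomotive", "locomotive")
}

#' Classify a bout by majority vote over its epochs
#'
#' An exact tie goes to nonlocomotive.
#'
#' @param bout An [activity_bout()].
#' @param config A [classifier_config()].
#' @return `"nonlocomotive"` or `"locomotive"`.
#' @export
classify_bout <- function(bout, config = classifier_config()) {
  stopifnot(inherits(bout, "activity_bout"))
  labels <- classify_epoch(bout$epochs, config)
  n_loc <- sum(labels == "locomotive")
  if (n_loc > length(labels) / 2) "locomotive" else "nonlocomotive"
}

#' Per-activity discrimination table
#'
#' For each activity, the percentage of bouts (default) or epochs whose
#' predicted class matches the true class; the total is the unweighted mean
#' across activities, matching the semantics of a "total discrimination" row.
#'
#' @param bouts A list of [activity_bout()] objects covering every activity
#'   at least once.
#' @param config A [classifier_config()].
#' @param unit `"bout"` (default) or `"epoch"` scoring.
#' @return A data.frame `activity, n, correct_rate_pct` of class
#'   `discrimination_table`, with the unweighted mean in attribute
#'   `total_rate` (also exposed by [total_rate()]).
#' @export
discrimination_table <- function(bouts, config = classifier_config(),
                                 unit = c("bout", "epoch")) {
  unit <- match.arg(unit)
  if (length(bouts) == 0L) stop("no bouts supplied")
  acts <- vapply(bouts, function(b) b$activity, character(1))
  if (any(is.na(acts) | !nzchar(acts)))
    stop("unknown (missing or empty) activity label")
  res <- lapply(split(seq_along(bouts), acts), function(idx) {
    if (unit == "bout") {
      pred <- vapply(bouts[idx], classify_bout, character(1), config = config)
      truth <- vapply(bouts[idx], function(b) b$true_class, character(1))
    } else {
      pred <- unlist(lapply(bouts[idx], function(b)
        classify_epoch(b$epochs, config)))
      truth <- unlist(lapply(bouts[idx], function(b)
        rep(b$true_class, nrow(b$epochs))))
    }
    c(n = length(pred), rate = 100 * mean(pred == truth))
  })
  out <- data.frame(activity = names(res),
                    n = vapply(res, `[[`, numeric(1), "n"),
                    correct_rate_pct = vapply(res, `[[`, numeric(1), "rate"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total_rate") <- mean(out$correct_rate_pct)
  class(out) <- c("discrimination_table", "data.frame")
  out
}

#' Total discrimination rate of a table
#' @param table A [discrimination_table()].
#' @return The unweighted mean of the per-activity correct rates, in percent.
#' @export
total_rate <- function(table) attr(table, "total_rate")

#' Write a discrimination table (with TOTAL row) to CSV
#' @param table A [discrimination_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discrimination_table <- function(table, path) {
  df <- rbind(data.frame(activity = table$activity, n_bouts = table$n,
                         correct_rate_pct = sprintf("%.1f", table$correct_rate_pct)),
              data.frame(activity = "TOTAL", n_bouts = sum(table$n),
                         correct_rate_pct = sprintf("%.1f", total_rate(table))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the discrimination threshold by grid sweep
#'
#' ROC-style search: evaluates the discrimination table at every grid
#' threshold and returns the one maximizing the total (unweighted mean
#' per-activity) rate; ties are broken toward the smallest threshold. The
#' full sweep is retained for reporting.
#'
#' @param bouts Labeled [activity_bout()] list containing both classes.
#' @param grid Candidate thresholds (default 1.00-1.50 by 0.01, covering the
#'   span between the child and adult cut-offs).
#' @param config Base [classifier_config()]; its threshold is overridden.
#' @param unit Scoring unit, see [discrimination_table()].
#' @return A list with `best_threshold`, `table` (the discrimination table at
#'   the best threshold), and `sweep` (data.frame `threshold,
#'   total_rate_pct`).
#' @export
optimize_threshold <- function(bouts, grid = seq(1.00, 1.50, by = 0.01),
                               config = classifier_config(),
                               unit = c("bout", "epoch")) {
  unit <- match.arg(unit)
  if (length(grid) == 0L) stop("threshold grid must be non-empty")
  truths <- vapply(bouts, function(b) b$true_class, character(1))
  if (length(unique(truths)) < 2L)
    stop("threshold optimization requires both classes to be present")
  rates <- vapply(grid, function(th) {
    cfg <- config; cfg$threshold <- th
    total_rate(discrimination_table(bouts, cfg, unit = unit))
  }, numeric(1))
  best_i <- which(rates == max(rates))[1]  # smallest maximizer
  cfg <- config; cfg$threshold <- grid[best_i]
  list(best_threshold = grid[best_i],
       table = discrimination_table(bouts, cfg, unit = unit),
       sweep = data.frame(threshold = grid, total_rate_pct = rates))
}
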