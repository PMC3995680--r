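test_that("packaged child equations evaluate to their published constants", {
  total <- load_model_set("child_standard_total")
  expect_equal(as.numeric(predict_mets(0, "nonlocomotive", total)), 1.220)
  expect_equal(as.numeric(predict_mets(0, "locomotive", total)), 0.944)
  expect_equal(as.numeric(predict_mets(100, "nonlocomotive", total)),
               0.013 * 100 + 1.220)
  expect_equal(total$classifier$threshold, 1.12)

  dev <- load_model_set("child_standard_dev")
  expect_equal(as.numeric(predict_mets(0, "nonlocomotive", dev)), 1.235)
  expect_equal(as.numeric(predict_mets(0, "locomotive", dev)), 0.878)

  multi <- load_model_set("child_multivariable")
  boy10 <- data.frame(subject_id = "S1", sex_code = 0L, age_yr = 10,
                      weight_kg = 34)
  expect_equal(as.numeric(predict_mets(100, "nonlocomotive", multi, boy10)),
               -0.537 + 0.013 * 100 + 0.170 * 10 + 0.076 * 0)
  # locomotive branch carries a weight term
  expect_equal(as.numeric(predict_mets(200, "locomotive", multi, boy10)),
               -0.925 + 0.005 * 200 + 0.032 * 34 + 0.085 * 10 + 0.092 * 0)
  expect_error(predict_mets(100, "nonlocomotive", multi), "subject")
})

test_that("predictions are affine in SA and floored at 0.1 METs", {
  total <- load_model_set("child_standard_total")
  h <- 64
  slope <- (as.numeric(predict_mets(100 + h, "locomotive", total)) -
              as.numeric(predict_mets(100, "locomotive", total))) / h
  expect_equal(slope, 0.005, tolerance = 1e-12)

  low <- model_set(regression_model("nonlocomotive", -2, 0.001),
                   regression_model("locomotive", 0.9, 0.005))
  p <- predict_mets(c(0, 5000), "nonlocomotive", low)
  expect_equal(as.numeric(p), c(0.1, 3))
  expect_equal(attr(p, "floored"), c(TRUE, FALSE))
  expect_error(predict_mets(-1, "locomotive", total), "non-negative")
})

test_that("series prediction routes epochs through the classifier", {
  total <- load_model_set("child_standard_total")
  z <- rep(0, 640)
  feats <- compute_epoch_features(triaxial_recording(z, z, z))
  pred <- predict_series(feats, total)
  expect_true(all(pred$class == "nonlocomotive"))
  expect_equal(pred$mets, rep(1.220, 2))

  walk <- epoch_features(0L, 320L, 330 * 1.02, 330, 1.02)
  pw <- predict_series(walk, total)
  expect_equal(pw$class, "locomotive")
  expect_equal(pw$mets, 0.005 * 330 + 0.944)

  empty <- predict_series(feats[0, ], total)
  expect_equal(nrow(empty), 0L)
})

test_that("noiseless calibration data are interpolated exactly", {
  rows <- data.frame(sa_mg = c(100, 300, 500, 900, 1100),
                     mets = 0.005 * c(100, 300, 500, 900, 1100) + 0.944)
  m <- suppressWarnings(fit_branch_model(rows, "locomotive"))  # perfect fit
  expect_equal(m$coef_sa, 0.005, tolerance = 1e-12)
  expect_equal(m$intercept, 0.944, tolerance = 1e-12)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0, tolerance = 1e-9)
})

test_that("OLS fits equal the explicit normal-equations solution", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    rows <- data.frame(sa_mg = runif(n, 0, 1200),
                       weight_kg = runif(n, 18, 60),
                       age_yr = runif(n, 6, 13),
                       sex_code = sample(0:1, n, replace = TRUE))
    rows$mets <- 1 + 0.004 * rows$sa_mg + rnorm(n, 0, 0.6)
    covs <- list(character(), c("weight", "age", "sex"))[[1 + rep %% 2]]
    m <- fit_branch_model(rows, "locomotive", covs)
    cols <- c("sa_mg", c(weight = "weight_kg", age = "age_yr",
                         sex = "sex_code")[covs])
    X <- as.matrix(cbind(1, rows[, cols, drop = FALSE]))
    beta <- solve(t(X) %*% X) %*% t(X) %*% rows$mets  # brute-force oracle
    got <- c(m$intercept, m$coef_sa, m$coef_weight, m$coef_age, m$coef_sex)
    expect_equal(got, as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("fitted models have zero-mean training residuals", {
  set.seed(42)
  rows <- data.frame(sa_mg = runif(200, 0, 400))
  rows$mets <- 1.2 + 0.013 * rows$sa_mg + rnorm(200, 0, 0.65)
  m <- fit_branch_model(rows, "nonlocomotive")
  res <- rows$mets - (m$intercept + m$coef_sa * rows$sa_mg)
  expect_lt(abs(mean(res)), 1e-9)
})

test_that("degenerate designs are rejected with informative errors", {
  rows <- data.frame(sa_mg = rep(100, 10), mets = rnorm(10, 2))
  expect_error(fit_branch_model(rows, "locomotive"), "collinear")
  rows2 <- data.frame(sa_mg = c(1, 2), mets = c(1, 2))
  expect_error(fit_branch_model(rows2, "locomotive"), "at least")
  rows3 <- data.frame(sa_mg = runif(20, 0, 100),
                      mets = rnorm(20, 2),
                      weight_kg = 30, age_yr = 10,
                      sex_code = 0L)
  expect_error(fit_branch_model(rows3, "locomotive", c("weight", "age")),
               "collinear")
})

test_that("a simulated cohort recovers the planted slope within 10%", {
  set.seed(43)
  n <- 300
  sa <- runif(n, 0, 400)
  rows <- data.frame(sa_mg = sa, mets = 1.220 + 0.013 * sa + rnorm(n, 0, 0.65))
  m <- fit_branch_model(rows, "nonlocomotive")
  expect_equal(m$coef_sa, 0.013, tolerance = 0.10)
})

test_that("model sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- model_set(regression_model("nonlocomotive", 1.3, 0.0121, r2 = 0.8,
                                  rmse = 0.61),
                 regression_model("locomotive", 0.91, 0.0049,
                                  coef_weight = 0.03, coef_age = 0.08,
                                  coef_sex = 0.09),
                 classifier = classifier_config(threshold = 1.14))
  write_model_set(m, path)
  back <- load_model_set(path)
  expect_equal(back$nonlocomotive$intercept, 1.3)
  expect_equal(back$locomotive$coef_weight, 0.03)
  expect_equal(back$classifier$threshold, 1.14)
  expect_error(load_model_set("no_such_model.json"), "not found")
})

test_that("stratified split reproduces the study's 48/20 allocation", {
  set.seed(44)
  ages <- c(runif(15, 6, 9.9), runif(27, 10, 12.9),
            runif(14, 6, 9.9), runif(12, 10, 12.9))
  subjects <- data.frame(subject_id = sprintf("S%02d", 1:68),
                         sex_code = rep(c(0L, 1L), c(42, 26)),
                         age_yr = ages)
  sp <- split_development_crossvalidation(subjects, 48 / 68, seed = 5)
  expect_length(sp$dev, 48L)
  expect_length(sp$cv, 20L)
  expect_setequal(c(sp$dev, sp$cv), subjects$subject_id)
  sp2 <- split_development_crossvalidation(subjects, 48 / 68, seed = 5)
  expect_identical(sp, sp2)

  four <- data.frame(subject_id = c("a", "b", "c", "d"), sex_code = 0L,
                     age_yr = c(7, 7, 8, 8))
  expect_warning(
    sp3 <- split_development_crossvalidation(four, 0.5, seed = 1),
    "empty strata")
  expect_length(sp3$dev, 2L)
  expect_length(sp3$cv, 2L)
})
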