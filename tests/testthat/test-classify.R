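test_that("epoch classification follows the cut-off with ties nonlocomotive", {
  cfg <- classifier_config(threshold = 1.12)
  mk <- function(ratio, fsa = 100)
    epoch_features(0L, 320L, fsa * ratio, fsa, ratio)
  expect_equal(classify_epoch(mk(1.00), cfg), "locomotive")
  expect_equal(classify_epoch(mk(1.50), cfg), "nonlocomotive")
  expect_equal(classify_epoch(mk(1.12), cfg), "nonlocomotive")  # tie rule
  # movement-free epoch (FSA under the floor) is sedentary, nonlocomotive
  still <- epoch_features(0L, 320L, 1, 1, NA_real_)
  expect_equal(classify_epoch(still, cfg), "nonlocomotive")
})

test_that("adult preset and config invariants hold", {
  expect_equal(classifier_config(preset = "adult")$threshold, 1.16)
  expect_equal(classifier_config()$threshold, 1.12)
  expect_error(classifier_config(threshold = 0.9), "at least 1")
})

test_that("bout classification is a majority vote with ties nonlocomotive", {
  cfg <- classifier_config()
  expect_equal(classify_bout(planted_bout(c(1.0, 1.0, 1.3), "locomotive"),
                             cfg), "locomotive")
  expect_equal(classify_bout(planted_bout(c(1.0, 1.3), "locomotive"), cfg),
               "nonlocomotive")  # exact tie
  set.seed(21)
  walking <- lapply(1:48, function(i)
    planted_bout(rnorm(6, 1.03, 0.01), "locomotive", sprintf("S%02d", i),
                 "normal walking"))
  calls <- vapply(walking, classify_bout, character(1), config = cfg)
  expect_true(all(calls == "locomotive"))
})

test_that("discrimination table averages per-activity rates unweighted", {
  cfg <- classifier_config()
  # activity A: all correct; activity B: 9 of 10 correct -> total 95.0
  a <- lapply(1:5, function(i) planted_bout(rep(1.0, 3), "locomotive",
                                            sprintf("a%d", i), "A"))
  b <- c(lapply(1:9, function(i) planted_bout(rep(1.3, 3), "nonlocomotive",
                                              sprintf("b%d", i), "B")),
         list(planted_bout(rep(1.0, 3), "nonlocomotive", "b10", "B")))
  tab <- discrimination_table(c(a, b), cfg)
  expect_equal(sort(tab$correct_rate_pct), c(90, 100))
  expect_equal(total_rate(tab), 95.0)

  # 47 of 48 correct -> 97.9 at the printed granularity
  d <- c(lapply(1:47, function(i) planted_bout(rep(1.0, 3), "locomotive",
                                               sprintf("c%d", i), "C")),
         list(planted_bout(rep(1.3, 3), "locomotive", "c48", "C")))
  expect_equal(total_rate(discrimination_table(d, cfg)), 100 * 47 / 48)

  all_ok <- discrimination_table(a, cfg)
  expect_true(all(all_ok$correct_rate_pct == 100))
  expect_equal(total_rate(all_ok), 100)

  bad <- planted_bout(1.0, "locomotive", "s", "A")
  bad$activity <- ""
  expect_error(discrimination_table(list(bad), cfg), "activity")
})

test_that("threshold optimization separates planted ratio distributions", {
  set.seed(22)
  loc <- lapply(1:50, function(i)
    planted_bout(rnorm(5, 1.05, 0.01), "locomotive", sprintf("l%d", i), "walk"))
  non <- lapply(1:50, function(i)
    planted_bout(rnorm(5, 1.25, 0.02), "nonlocomotive", sprintf("n%d", i),
                 "sweep"))
  opt <- optimize_threshold(c(loc, non))
  # ties break toward the smallest maximizer, which sits just above the
  # upper edge of the locomotive ratio distribution
  expect_gt(opt$best_threshold, 1.05)
  expect_lt(opt$best_threshold, 1.20)
  expect_equal(total_rate(opt$table), 100)

  expect_equal(optimize_threshold(c(loc, non), grid = 1.3)$best_threshold, 1.3)
  expect_error(optimize_threshold(loc), "both classes")
})

test_that("no separation yields chance accuracy at the smallest maximizer", {
  ratios <- seq(1.01, 1.40, length.out = 40)
  bouts <- lapply(seq_along(ratios), function(i)
    planted_bout(ratios[i], if (i %% 2) "locomotive" else "nonlocomotive",
                 sprintf("s%d", i), "mixed"))
  grid <- seq(1.00, 1.50, by = 0.01)
  opt <- optimize_threshold(bouts, grid)
  brute <- vapply(grid, function(th)
    total_rate(discrimination_table(bouts, classifier_config(threshold = th))),
    numeric(1))
  expect_equal(opt$sweep$total_rate_pct, brute)
  expect_equal(opt$best_threshold, grid[which.max(brute)])
  expect_lt(abs(total_rate(opt$table) - 50), 6)
})

test_that("optimizer equals brute-force grid evaluation on random bouts", {
  set.seed(23)
  grid <- seq(1.00, 1.50, by = 0.01)
  for (rep in 1:5) {
    bouts <- lapply(1:30, function(i) {
      cls <- sample(c("locomotive", "nonlocomotive"), 1)
      mu <- if (cls == "locomotive") runif(1, 1.00, 1.20) else runif(1, 1.05, 1.40)
      planted_bout(rnorm(4, mu, 0.05), cls, sprintf("s%d", i),
                   sample(c("A", "B"), 1))
    })
    opt <- optimize_threshold(bouts, grid)
    brute <- vapply(grid, function(th)
      total_rate(discrimination_table(bouts, classifier_config(threshold = th))),
      numeric(1))
    expect_equal(total_rate(opt$table), max(brute))
    expect_equal(opt$best_threshold, grid[which(brute == max(brute))[1]])
  }
})

test_that("the locomotive call set grows monotonically in the threshold", {
  # ratio >= threshold means nonlocomotive, so raising the threshold can only
  # convert nonlocomotive calls into locomotive, never the reverse
  set.seed(24)
  feats <- epoch_features(0:99, 320L, usa_mg = runif(100, 50, 200),
                          fsa_mg = runif(100, 50, 200),
                          ratio = NA)
  feats$ratio <- feats$usa_mg / feats$fsa_mg
  prev <- rep(FALSE, 100)
  for (th in seq(1.01, 1.5, by = 0.05)) {
    loc <- classify_epoch(feats, classifier_config(threshold = th)) ==
      "locomotive"
    expect_true(all(loc | !prev))  # once locomotive, stays so as th rises
    prev <- loc
  }
})

test_that("classification is invariant to common rescaling of USA and FSA", {
  feats <- epoch_features(0:4, 320L, usa_mg = c(100, 120, 90, 115, 200),
                          fsa_mg = rep(100, 5),
                          ratio = c(1.0, 1.2, 0.9, 1.15, 2.0))
  cfg <- classifier_config()
  base <- classify_epoch(feats, cfg)
  for (c_scale in c(0.5, 3, 10)) {
    scaled <- epoch_features(feats$epoch_index, feats$n_samples,
                             feats$usa_mg * c_scale, feats$fsa_mg * c_scale,
                             feats$ratio)
    expect_equal(classify_epoch(scaled, cfg), base)
  }
})
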