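# Agreement between predicted and measured METs: per-activity difference
# tables and Bland-Altman limits of agreement. The difference sign convention
# is predicted - measured throughout (so an underestimated activity shows a
# negative mean difference).

#' Per-activity agreement table
#'
#' For each activity: means and SDs of predicted and measured METs, of their
#' per-subject differences (predicted - measured) and of the percentage
#' differences 100 x (predicted - measured) / measured. Rows with measured
#' METs <= 0 are flagged and excluded from the percentage statistics only.
#'
#' @param pairs A data.frame with columns `activity`, `predicted`,
#'   `measured` (one row per subject x activity).
#' @return A data.frame of class `agreement_table`, one row per activity,
#'   columns `activity, n, predicted_mean, predicted_sd, measured_mean,
#'   measured_sd, absdiff_mean, absdiff_sd, pctdiff_mean, pctdiff_sd,
#'   n_flagged`.
#' @export
agreement_table <- function(pairs) {
  need <- c("activity", "predicted", "measured")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(pairs) == 0L) stop("no pairs supplied")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  rows <- lapply(split(pairs, pairs$activity), function(g) {
    d <- g$predicted - g$measured
    ok <- g$measured > 0
    pct <- 100 * d[ok] / g$measured[ok]
    data.frame(activity = g$activity[1], n = nrow(g),
               predicted_mean = mean(g$predicted), predicted_sd = sd0(g$predicted),
               measured_mean = mean(g$measured), measured_sd = sd0(g$measured),
               absdiff_mean = mean(d), absdiff_sd = sd0(d),
               pctdiff_mean = if (any(ok)) mean(pct) else NA_real_,
               pctdiff_sd = if (any(ok)) sd0(pct) else NA_real_,
               n_flagged = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are predicted - measured; `sd_diff` is the sample SD (n - 1
#' denominator) and the limits of agreement are placed at mean +/- 2 SD
#' (exactly 2, not 1.96).
#'
#' @param predicted,measured Paired METs vectors of equal length >= 2.
#' @return An object of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_upper`, `loa_lower`, `n`, and the per-pair `means`/`diffs` kept
#'   for plotting.
#' @export
bland_altman <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length")
  if (length(predicted) < 2L)
    stop("Bland-Altman analysis requires at least 2 pairs")
  d <- predicted - measured
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_upper = m + 2 * s, loa_lower = m - 2 * s,
                 n = length(d),
                 means = (predicted + measured) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: n = %d, mean diff %.2f METs, limits of agreement (+/-2 SD) %.2f to %.2f>\n",
    x$n, x$mean_diff, x$loa_upper, x$loa_lower))
  invisible(x)
}

#' Mean-vs-difference agreement plot
#'
#' Scatter of pair means against differences with horizontal lines at the
#' mean difference (solid) and the +/-2 SD limits of agreement (dashed).
#'
#' @param x A [bland_altman()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = "Mean of predicted and measured (METs)",
                 ylab = "Predicted - measured (METs)", ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Write an agreement table to CSV
#' @param table An [agreement_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a Bland-Altman summary to CSV
#' @param ba A [bland_altman()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bland_altman <- function(ba, path) {
  df <- data.frame(n = ba$n, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                   loa_upper = ba$loa_upper, loa_lower = ba$loa_lower)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
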