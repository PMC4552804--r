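#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between paired measurements (e.g. the same exam
#' scored by two operators, or two replicate acquisitions by one operator):
#' the bias is the mean of the differences `a - b` and the 95% limits of
#' agreement are `bias +/- 1.96 * SD(differences)` (large-sample factor,
#' per the classical method).
#'
#' @param values_a,values_b Paired measurements (kPa), equal length >= 2.
#' @param labels Optional exam identifiers carried into the plot table.
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `coverage` (fraction of differences inside the
#'   limits) and `table` (data.frame `label, mean, diff` ready for
#'   plotting).
#' @examples
#' ba <- bland_altman(c(10, 9.5, 8), c(10.2, 9.4, 8.3))
#' @export
bland_altman <- function(values_a, values_b, labels = NULL) {
  stop_if(length(values_a) != length(values_b),
          "paired series must have equal length")
  ok <- !is.na(values_a) & !is.na(values_b)
  values_a <- values_a[ok]; values_b <- values_b[ok]
  stop_if(length(values_a) < 2, "need at least 2 complete pairs")
  labels <- if (is.null(labels)) seq_along(values_a) else labels[ok]
  d <- values_a - values_b
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  structure(list(
    mean_diff = bias, sd_diff = s, loa_low = lo, loa_high = hi,
    coverage = mean(d >= lo & d <= hi),
    n = length(d),
    table = data.frame(label = labels, mean = (values_a + values_b) / 2,
                       diff = d, stringsAsFactors = FALSE)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% LoA [%.3f, %.3f], coverage %.2f\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high, x$coverage))
  invisible(x)
}
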