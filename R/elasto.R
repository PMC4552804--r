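#' Convert shear-wave speed to Young's modulus
#'
#' In a locally homogeneous, isotropic, purely elastic tissue the Young's
#' modulus relates to the shear-wave speed `c` as `E = 3 rho c^2`. With
#' `rho` in kg/m^3 and `c` in m/s the product is in Pa; the result is
#' returned in kPa, the scale elastography scanners display.
#'
#' @param c Shear-wave speed(s) in m/s (>= 0).
#' @param rho Tissue density in kg/m^3 (default 1000, soft tissue).
#' @return Young's modulus in kPa; strictly increasing in `c`.
#' @examples
#' sws_to_modulus(1.291) # ~5.00 kPa
#' sws_to_modulus(1.826) # ~10.00 kPa
#' @export
sws_to_modulus <- function(c, rho = 1000) {
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  stop_if(any(c < 0, na.rm = TRUE), "shear-wave speed must be >= 0")
  3 * rho * c^2 / 1000
}

#' Convert Young's modulus back to shear-wave speed
#'
#' Algebraic inverse of [sws_to_modulus()]: `c = sqrt(E / (3 rho))` with
#' `E` in Pa.
#'
#' @param E Young's modulus in kPa (>= 0).
#' @inheritParams sws_to_modulus
#' @return Shear-wave speed in m/s.
#' @export
modulus_to_sws <- function(E, rho = 1000) {
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  stop_if(any(E < 0, na.rm = TRUE), "modulus must be >= 0")
  sqrt(E * 1000 / (3 * rho))
}

#' Summarise one ROI acquisition into a stiffness estimate
#'
#' Per-pixel shear-wave speeds are converted to moduli; the ROI stiffness is
#' their median and the dispersion their sample SD, both on the kPa scale.
#' The quality-control rule rejects the acquisition when the SD exceeds
#' `qc_threshold` (default 30%) of the median: strong within-ROI
#' heterogeneity indicates an acquisition artefact. Equality with the
#' threshold passes. The summary shear-wave speed is the back-conversion of
#' the median modulus (median and the monotone conversion commute).
#'
#' @param sws Numeric vector of per-pixel shear-wave speeds (m/s) inside
#'   the ROI; must be non-empty and positive.
#' @inheritParams sws_to_modulus
#' @param qc_threshold Rejection threshold on SD/median (default 0.30).
#' @return An object of class `stiffness_estimate`: a list with
#'   `median_sws` (m/s), `median_modulus`, `modulus_sd` (kPa),
#'   `sd_fraction`, `qc_pass`, `n_samples`. With a single sample the SD is
#'   undefined (`NA`) and the QC check passes vacuously.
#' @export
summarize_roi <- function(sws, rho = 1000, qc_threshold = 0.30) {
  sws <- as.numeric(sws)
  stop_if(length(sws) == 0 || all(is.na(sws)),
          "ROI has no shear-wave-speed samples")
  sws <- sws[!is.na(sws)]
  stop_if(any(sws <= 0), "shear-wave-speed samples must be positive")
  e <- sws_to_modulus(sws, rho = rho)
  med <- stats::median(e)
  s <- if (length(e) > 1L) stats::sd(e) else NA_real_
  frac <- if (is.na(s)) NA_real_ else s / med
  structure(list(
    median_sws = modulus_to_sws(med, rho = rho),
    median_modulus = med,
    modulus_sd = s,
    sd_fraction = frac,
    qc_pass = is.na(frac) || frac <= qc_threshold,
    n_samples = length(e)
  ), class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("ROI stiffness: %.2f kPa (SWS %.3f m/s), SD %.2f kPa (%.1f%% of median), QC %s, n = %d\n",
              x$median_modulus, x$median_sws,
              if (is.na(x$modulus_sd)) NA else x$modulus_sd,
              100 * if (is.na(x$sd_fraction)) NA else x$sd_fraction,
              if (x$qc_pass) "pass" else "REJECT", x$n_samples))
  invisible(x)
}

#' Summarise every record of an exam table
#'
#' Applies [summarize_roi()] row-wise. Records without samples (lost
#' acquisitions) are kept with `missing = TRUE` and `NA` estimates so the
#' dataset accounting can report them.
#'
#' @param exams A `swe_exams` data.frame (see [simulate_swe_dataset()] /
#'   [read_swe_csv()]).
#' @inheritParams summarize_roi
#' @return A data.frame, one row per record, with the design columns plus
#'   `median_sws, median_kpa, sd_kpa, sd_fraction, qc_pass, missing`.
#' @export
summarize_exams <- function(exams, rho = 1000, qc_threshold = 0.30) {
  m <- sws_samples(exams)
  n <- nrow(m)
  out <- exams[, intersect(c("record", "animal", "group", "hour", "operator",
                             "replicate"), names(exams)), drop = FALSE]
  out$median_sws <- out$median_kpa <- out$sd_kpa <- out$sd_fraction <-
    rep(NA_real_, n)
  out$qc_pass <- rep(NA, n)
  out$missing <- apply(m, 1L, function(r) all(is.na(r)))
  for (i in seq_len(n)) {
    if (out$missing[i]) next
    est <- summarize_roi(m[i, ], rho = rho, qc_threshold = qc_threshold)
    out$median_sws[i] <- est$median_sws
    out$median_kpa[i] <- est$median_modulus
    out$sd_kpa[i] <- est$modulus_sd
    out$sd_fraction[i] <- est$sd_fraction
    out$qc_pass[i] <- est$qc_pass
  }
  rownames(out) <- NULL
  out
}

#' Aggregate replicate estimates into one exam value
#'
#' Each operator acquires up to three replicate images per exam; the exam
#' stiffness is the median of the QC-passing replicate medians and its
#' error bar their sample SD. A single surviving replicate yields an
#' undefined SD (`NA`, not zero); zero survivors mark the exam as missing.
#'
#' @param medians_kpa Replicate ROI medians (kPa) that passed QC; `NA`s and
#'   rejected replicates should already be dropped by the caller.
#' @return List with `median_kpa`, `sd_kpa`, `n_used`, `missing`.
#' @export
aggregate_exam <- function(medians_kpa) {
  medians_kpa <- medians_kpa[!is.na(medians_kpa)]
  if (length(medians_kpa) == 0L) {
    return(list(median_kpa = NA_real_, sd_kpa = NA_real_, n_used = 0L,
                missing = TRUE))
  }
  list(median_kpa = stats::median(medians_kpa),
       sd_kpa = if (length(medians_kpa) > 1L) stats::sd(medians_kpa)
                else NA_real_,
       n_used = length(medians_kpa),
       missing = FALSE)
}

#' Aggregate a per-record summary table to exam level
#'
#' Groups records by animal x hour x operator, drops QC-rejected and
#' missing replicates, and applies [aggregate_exam()].
#'
#' @param summaries Output of [summarize_exams()].
#' @return A data.frame with one row per exam:
#'   `animal, group, hour, operator, median_kpa, sd_kpa, n_used,`
#'   `qc_n_rejected, missing`.
#' @export
aggregate_exams <- function(summaries) {
  key <- interaction(summaries$animal, summaries$hour, summaries$operator,
                     drop = TRUE, lex.order = TRUE)
  parts <- split(summaries, key)
  rows <- lapply(parts, function(d) {
    ok <- !d$missing & d$qc_pass %in% TRUE
    agg <- aggregate_exam(d$median_kpa[ok])
    data.frame(animal = d$animal[1], group = d$group[1], hour = d$hour[1],
               operator = d$operator[1],
               median_kpa = agg$median_kpa, sd_kpa = agg$sd_kpa,
               n_used = agg$n_used,
               qc_n_rejected = sum(!d$missing & d$qc_pass %in% FALSE),
               missing = agg$missing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal, out$hour, out$operator), ]
  rownames(out) <- NULL
  out
}

#' Dataset accounting: totals and rejection percentages
#'
#' Counts missing acquisitions and QC rejections and expresses each as a
#' percentage of the total, rounded to 2 significant figures (the study's
#' reporting convention: 6/378 = 1.6%, 2/378 = 0.53%).
#'
#' @param summaries Output of [summarize_exams()].
#' @return An object of class `dataset_accounting` with fields `n_total`,
#'   `n_rejected_missing`, `n_rejected_qc`, `pct_rejected_missing`,
#'   `pct_rejected_qc`.
#' @export
account_dataset <- function(summaries) {
  n <- nrow(summaries)
  n_miss <- sum(summaries$missing)
  n_qc <- sum(!summaries$missing & summaries$qc_pass %in% FALSE)
  pct <- function(k) if (n == 0) 0 else signif(100 * k / n, 2)
  structure(list(n_total = n,
                 n_rejected_missing = n_miss,
                 n_rejected_qc = n_qc,
                 pct_rejected_missing = pct(n_miss),
                 pct_rejected_qc = pct(n_qc)),
            class = "dataset_accounting")
}

#' @export
print.dataset_accounting <- function(x, ...) {
  cat(sprintf("ROIs analysed: %d\n", x$n_total))
  cat(sprintf("  missing acquisitions: %d (%g%%)\n",
              x$n_rejected_missing, x$pct_rejected_missing))
  cat(sprintf("  QC rejections (SD > 30%% of median): %d (%g%%)\n",
              x$n_rejected_qc, x$pct_rejected_qc))
  invisible(x)
}
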