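#' Quadratic stiffness-trajectory fit
#'
#' Ordinary least squares of stiffness on `{1, t, t^2}`, the model used to
#' summarise stiffness versus cervical maturation time. `R^2` is
#' `1 - SS_res / SS_tot`; when the response is constant (`SS_tot = 0`) it
#' is defined as 0 with a warning.
#'
#' @param hours Times in hours; at least 3 distinct values.
#' @param stiffness Stiffness (kPa), same length.
#' @return Object of class `trajectory_fit`: coefficients `a` (kPa/h^2),
#'   `b` (kPa/h), `c` (kPa), `r_squared`, `residuals`, `fitted`.
#' @examples
#' t <- c(0, 4, 8, 12, 16, 20, 24)
#' fit_quadratic(t, 0.0103 * t^2 - 0.3844 * t + 9.2147)
#' @export
fit_quadratic <- function(hours, stiffness) {
  ok <- !is.na(hours) & !is.na(stiffness)
  hours <- hours[ok]; stiffness <- stiffness[ok]
  stop_if(length(unique(hours)) < 3,
          "need at least 3 distinct hours to fit a quadratic")
  fit <- stats::lm(stiffness ~ hours + I(hours^2))
  ss_tot <- sum((stiffness - mean(stiffness))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  if (ss_tot == 0) {
    warning("constant response: R^2 defined as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  co <- stats::coef(fit)
  structure(list(a = unname(co[3]), b = unname(co[2]), c = unname(co[1]),
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 n = length(hours)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("E(t) = %.4g t^2 %+.4g t %+.4g kPa  (R^2 = %.1f%%, n = %d)\n",
              x$a, x$b, x$c, 100 * x$r_squared, x$n))
  invisible(x)
}

#' Fit per-group quadratic trajectories from exam-level data
#'
#' By default each group's trajectory is fitted on its per-hour medians
#' across animals and operators (7 points for a 7-examination study, the
#' aggregation behind a single printed trajectory per group); set
#' `use_medians = FALSE` to fit on all individual exam values.
#'
#' @param exams data.frame with columns `group`, `hour`, `median_kpa`
#'   (e.g. from [aggregate_exams()]).
#' @param use_medians Fit per-hour medians (default) or all raw points.
#' @return Named list of `trajectory_fit`, one per group.
#' @export
fit_group_trajectories <- function(exams, use_medians = TRUE) {
  stop_if(!all(c("group", "hour", "median_kpa") %in% names(exams)),
          "exams must have columns group, hour, median_kpa")
  out <- lapply(split(exams, exams$group), function(d) {
    if (use_medians) {
      med <- tapply(d$median_kpa, d$hour, stats::median, na.rm = TRUE)
      fit_quadratic(as.numeric(names(med)), as.numeric(med))
    } else {
      fit_quadratic(d$hour, d$median_kpa)
    }
  })
  out
}
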