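#' Per-time rank-sum comparison of two groups with step-up correction
#'
#' At each hour the two groups are compared by a two-sided Wilcoxon
#' rank-sum test (exact enumeration when the combined sample is <= 12 and
#' tie-free, tie-corrected normal approximation otherwise); the per-hour
#' p-values are then adjusted across hours by the Benjamini-Hochberg
#' step-up procedure (plain Bonferroni available via `method`).
#'
#' @param data data.frame with columns `hour`, `group` (two levels) and
#'   `value`; `NA` values are dropped.
#' @param method Multiplicity correction: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param exact_max Combined sample size at or below which the exact
#'   distribution is used (default 12).
#' @return data.frame `hour, n_a, n_b, statistic, p, p_adj`, one row per
#'   hour where both groups are present; hours with an empty group are
#'   skipped with a message.
#' @export
ranksum_by_time <- function(data, method = c("BH", "bonferroni"),
                            exact_max = 12) {
  method <- match.arg(method)
  stop_if(!all(c("hour", "group", "value") %in% names(data)),
          "data must have columns hour, group, value")
  data <- data[!is.na(data$value), , drop = FALSE]
  lv <- sort(unique(as.character(data$group)))
  stop_if(length(lv) != 2, "exactly two groups are required")
  rows <- list()
  for (h in sort(unique(data$hour))) {
    xa <- data$value[data$hour == h & data$group == lv[1]]
    xb <- data$value[data$hour == h & data$group == lv[2]]
    if (length(xa) == 0 || length(xb) == 0) {
      message(sprintf("hour %g skipped: a group has no observations", h))
      next
    }
    use_exact <- (length(xa) + length(xb)) <= exact_max &&
      !anyDuplicated(c(xa, xb))
    if (length(unique(c(xa, xb))) == 1L) {
      ## fully tied: no evidence against exchangeability
      w_stat <- length(xa) * length(xb) / 2
      p_val <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(xa, xb, exact = use_exact, correct = !use_exact)
      )
      w_stat <- unname(wt$statistic)
      p_val <- min(wt$p.value, 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      hour = h, n_a = length(xa), n_b = length(xb),
      statistic = w_stat, p = p_val)
  }
  stop_if(length(rows) == 0, "no hour had both groups present")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k - 1
#' degrees of freedom, used for the prostaglandin group comparison. When
#' every observation is identical the statistic is 0 and p = 1.
#'
#' @param values Numeric observations, or a list of per-group vectors (in
#'   which case `groups` is ignored).
#' @param groups Group labels matching `values`.
#' @return List `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  stop_if(length(values) != length(groups),
          "'values' and 'groups' lengths differ")
  groups <- as.factor(groups)
  stop_if(nlevels(droplevels(groups)) < 2, "need at least two groups")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Rank-based ANOVA-type statistics for a two-factor longitudinal design
#'
#' Nonparametric analysis of a design with one whole-plot factor (group:
#' each animal belongs to one group) and one repeated sub-plot factor
#' (time): the "F1-LD-F1" layout. All observations are mid-ranked jointly;
#' relative treatment effects per group x time cell are
#' `p_hat = (mean rank - 1/2) / N`; the ANOVA-type statistic (ATS) for each
#' hypothesis (group, time, group:time) is a quadratic form in `p_hat`
#' scaled by the trace of the projected empirical covariance of the
#' subjects' ranked profiles, with Box-type numerator degrees of freedom.
#' Within-subject effects are referred to F(df1, Inf); the whole-plot group
#' effect uses a Satterthwaite-type denominator df. Missing cells are
#' handled by available-case means and pairwise covariance estimates.
#'
#' @param data data.frame with columns `animal`, `group`, `hour`, `value`;
#'   one observation per animal x hour (aggregate replicates first).
#' @return data.frame with rows `group`, `time`, `group:time` and columns
#'   `statistic, df1, df2, p`.
#' @references Brunner, Domhof & Langer (2002), Nonparametric Analysis of
#'   Longitudinal Data in Factorial Experiments.
#' @export
anova_type_statistic <- function(data) {
  stop_if(!all(c("animal", "group", "hour", "value") %in% names(data)),
          "data must have columns animal, group, hour, value")
  data <- data[!is.na(data$value), , drop = FALSE]
  grp_of <- tapply(as.character(data$group), data$animal,
                   function(g) unique(g))
  stop_if(any(lengths(grp_of) != 1), "each animal must belong to one group")
  groups <- sort(unique(as.character(data$group)))
  a <- length(groups)
  stop_if(a < 2, "need at least two groups")
  hours <- sort(unique(data$hour))
  t_n <- length(hours)
  stop_if(t_n < 2, "need at least two time points")

  N <- nrow(data)
  data$r <- rank(data$value) / N   # mid-ranks, scaled

  ## subject profile matrices per group
  prof <- list(); n_i <- integer(a)
  for (gi in seq_len(a)) {
    anims <- names(grp_of)[grp_of == groups[gi]]
    stop_if(length(anims) < 2,
            sprintf("group '%s' has fewer than 2 animals; covariance inestimable",
                    groups[gi]))
    P <- matrix(NA_real_, length(anims), t_n,
                dimnames = list(anims, hours))
    for (k in seq_along(anims)) {
      d <- data[data$animal == anims[k], ]
      P[k, match(d$hour, hours)] <- d$r
    }
    prof[[gi]] <- P
    n_i[gi] <- length(anims)
  }

  p_hat <- unlist(lapply(prof, function(P) colMeans(P, na.rm = TRUE)))
  p_hat <- p_hat - 1 / (2 * N)
  ## N * blockdiag(S_i / n_i), pairwise-complete covariance of profiles
  V <- matrix(0, a * t_n, a * t_n)
  for (gi in seq_len(a)) {
    S <- stats::cov(prof[[gi]], use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    idx <- (gi - 1L) * t_n + seq_len(t_n)
    V[idx, idx] <- N * S / n_i[gi]
  }

  P_a <- diag(a) - 1 / a
  P_t <- diag(t_n) - 1 / t_n
  J_t <- matrix(1 / t_n, t_n, t_n)
  J_a <- matrix(1 / a, a, a)
  Ts <- list(group = kronecker(P_a, J_t),
             time = kronecker(J_a, P_t),
             `group:time` = kronecker(P_a, P_t))

  rows <- lapply(names(Ts), function(eff) {
    T <- Ts[[eff]]
    TV <- T %*% V
    tr <- sum(diag(TV))
    if (tr <= .Machine$double.eps) {  # degenerate: no variability
      return(data.frame(effect = eff, statistic = 0, df1 = NA_real_,
                        df2 = NA_real_, p = 1))
    }
    stat <- N * drop(p_hat %*% T %*% p_hat) / tr
    df1 <- tr^2 / sum(diag(TV %*% TV))
    if (eff == "group") {
      tv_i <- vapply(seq_len(a), function(gi) {
        idx <- (gi - 1L) * t_n + seq_len(t_n)
        sum(diag(TV[idx, idx, drop = FALSE])) # group-i contribution
      }, 0)
      df2 <- tr^2 / sum(tv_i^2 / (n_i - 1))
      p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
    } else {
      df2 <- Inf
      p <- stats::pf(stat, df1, Inf, lower.tail = FALSE)
    }
    data.frame(effect = eff, statistic = stat, df1 = df1, df2 = df2, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
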