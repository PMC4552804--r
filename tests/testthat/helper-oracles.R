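## Independent oracles used across the suite.

## Brute-force 2D DFT magnitude (double sum), centred like compute_ft().
dft2_magnitude_centred <- function(m) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0 + 0i, n, p)
  for (u in 0:(n - 1)) {
    for (v in 0:(p - 1)) {
      ph <- outer(0:(n - 1) * u / n, 0:(p - 1) * v / p, "+")
      out[u + 1, v + 1] <- sum(m * exp(-2i * pi * ph))
    }
  }
  sp <- Mod(out)
  ri <- c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2)))
  ci <- c((p - floor(p / 2) + 1):p, 1:(p - floor(p / 2)))
  sp[ri, ci]
}

## Exact two-sided rank-sum p-value by enumeration of all group assignments.
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  obs <- sum(rank(pooled)[seq_len(n)])
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

## SWS sample vector whose modulus-scale summary has an exact SD/median
## ratio: moduli {m - d, m, m + d} have median m and sample SD d.
sws_with_sd_fraction <- function(frac, m = 10, rho = 1000) {
  moduli <- c(m - frac * m, m, m + frac * m)
  modulus_to_sws(moduli, rho = rho)
}

## Per-hour animal-level table from an exam-level aggregate, as the
## pipeline builds it (mean of the operators' exam medians).
animal_level <- function(exam_level) {
  agg <- stats::aggregate(median_kpa ~ animal + group + hour,
                          data = exam_level, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "median_kpa"] <- "value"
  agg[!is.nan(agg$value), ]
}
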