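#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible child seed from a master seed and a stream label.
## Keeps every derived seed inside the 32-bit signed range.
#' @noRd
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483629L)
}

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x),
          sprintf("'%s' must be a single finite number", name))
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  stop_if(lo_bad || hi_bad,
          sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(x)
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
            x < min,
          sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}
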