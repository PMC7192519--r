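# internal numerics shared across modules

# log(sum(exp(x))), stable for large-magnitude and -Inf entries
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# two-sided p-value -> |z|, computed through log-space quantiles so that
# p-values near the double floor do not collapse to Inf prematurely
p_to_z <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad))
    stopf("p-values must lie in (0, 1]; offending value(s): %s",
          paste(utils::head(p[bad], 3), collapse = ", "))
  floor_p <- 1e-300
  if (any(p < floor_p, na.rm = TRUE)) {
    warnf("%d p-value(s) below %g floored before conversion to z-scores",
          sum(p < floor_p, na.rm = TRUE), floor_p)
    p <- pmax(p, floor_p)
  }
  stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

# |z| -> two-sided p-value, floored away from 0 so round trips stay valid
z_to_p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

is_scalar_prob <- function(x, open0 = TRUE, open1 = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open0) x > 0 else x >= 0) && (if (open1) x < 1 else x <= 1)
}
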