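`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_cfg <- function(...) stop(..., call. = FALSE)

# Moving average with window `k` (odd); edges use the available samples only.
moving_average <- function(x, k = 3L) {
  if (k <= 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- mean(x[j])
  }
  out
}

# Clopper-Pearson interval for a binomial proportion.
binom_ci <- function(x, n, conf = 0.66) {
  a <- (1 - conf) / 2
  lo <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  cbind(lower = lo, upper = hi)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
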