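# Small internal numerics shared across modules.

# Population variance (divide by N).  The heart-rate variance feature uses
# this convention so that fixed fixtures have exact expected values.
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

# Causal moving average over `width` samples; partial windows at the head
# are averaged over the samples available so the output has no NA ramp-in.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (n == 0) return(numeric(0))
  cs <- cumsum(x)
  out <- numeric(n)
  idx <- seq_len(n)
  lead <- idx - width
  out <- (cs - ifelse(lead >= 1, cs[pmax(lead, 1L)], 0)) / pmin(idx, width)
  out
}

# Derive `k` reproducible child seeds (< 2^31) from one root seed without
# disturbing the caller's RNG state.
derive_seeds <- function(root, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(root) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

# Truncated normal by resampling (vectorized; fine for mild truncation).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
  }
  pmin(pmax(x, lower), upper)
}
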