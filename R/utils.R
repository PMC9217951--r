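# Shared numeric helpers. Rayleigh variates use inverse-transform sampling so
# reproducibility depends only on the base RNG state.

rrayleigh <- function(n, sigma) sigma * sqrt(-2 * log(runif(n)))

prayleigh <- function(q, sigma) 1 - exp(-(q^2) / (2 * sigma^2))

# Rayleigh draw conditioned >= minValue; re-samples at most maxRetries times.
drawRayleighMin <- function(sigma, minValue, maxRetries = 100L) {
  for (i in seq_len(maxRetries)) {
    x <- rrayleigh(1L, sigma)
    if (x >= minValue) return(x)
  }
  stop("failed to draw a lifetime >= ", minValue, " s within ",
       maxRetries, " attempts (sigma = ", sigma, ")")
}

# Centered 3-frame moving average; endpoints average the two available frames.
movingAverage3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out[1L] <- (x[1L] + x[2L]) / 2
  out[n] <- (x[n - 1L] + x[n]) / 2
  out
}

# Robust per-frame noise SD of a trace, from residuals against the 3-frame
# moving average. Interior residuals of white noise passed through the 3-point
# mean have sd = sigma * sqrt(2/3); the MAD-style constant rescales to sigma.
robustNoiseSd <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  resid <- x - movingAverage3(x)
  1.4826 * median(abs(resid[2:(n - 1L)])) / sqrt(2 / 3)
}

# Deterministic fan-out of one user seed into per-stage seeds (< 2^31).
stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(stage)
}

# Evaluate expr under a seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Sample skewness / excess kurtosis with degenerate traces mapped to 0.
sampleSkewness <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

sampleKurtosis <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}
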