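# Independent oracles used across tests. These re-derive expected values by
# direct enumeration / closed form, independently of the package internals.

# Closed-form mean of a Rice distribution (2-D Gaussian-perturbed offset):
# E|v + e| with |v| = nu and e ~ N(0, sigma^2 I2), via the Laguerre
# polynomial L_{1/2}; scaled Bessel functions keep it stable at large SNR.
riceMean <- function(nu, sigma) {
  if (nu == 0) return(sigma * sqrt(pi / 2))
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# Brute-force peak-count oracle: direct enumeration of qualifying local
# maxima under the documented contract (3-frame moving-average smoothing,
# height above baseline, full width at half prominence, greedy distance
# enforcement favouring higher then earlier peaks).
bruteForcePeakCount <- function(trace, dt, minHeight, minWidth, minDistance,
                                heightUnits = "noise_sd") {
  n <- length(trace)
  if (n < 3L) return(0L)
  sm <- vapply(seq_len(n), function(i)
    mean(trace[max(1L, i - 1L):min(n, i + 1L)]), numeric(1L))
  if (max(sm) == min(sm)) return(0L)
  # interior local maxima; a flat top counts once, at its first index
  idx <- integer(0)
  for (i in 2:(n - 1L)) {
    if (sm[i] <= sm[i - 1L]) next
    j <- i
    while (j < n && sm[j + 1L] == sm[i]) j <- j + 1L
    if (j < n && sm[j + 1L] < sm[i]) idx <- c(idx, i)
  }
  if (!length(idx)) return(0L)
  # prominence: drop to the lowest point before ground higher than the peak
  prom <- numeric(length(idx))
  wid <- numeric(length(idx))
  for (k in seq_along(idx)) {
    p <- idx[k]; h <- sm[p]
    lmin <- h
    for (i in rev(seq_len(p - 1L))) {
      lmin <- min(lmin, sm[i])
      if (sm[i] > h) break
    }
    rmin <- h
    for (i in seq(p + 1L, n)) {
      rmin <- min(rmin, sm[i])
      if (sm[i] > h) break
    }
    prom[k] <- h - max(lmin, rmin)
    half <- h - prom[k] / 2
    li <- p
    while (li > 1L && sm[li - 1L] >= half && sm[li - 1L] <= h) li <- li - 1L
    xl <- if (li == 1L || sm[li - 1L] > h) li
          else li - (sm[li] - half) / (sm[li] - sm[li - 1L])
    ri <- p
    while (ri < n && sm[ri + 1L] >= half && sm[ri + 1L] <= h) ri <- ri + 1L
    xr <- if (ri == n || sm[ri + 1L] > h) ri
          else ri + (sm[ri] - half) / (sm[ri] - sm[ri + 1L])
    wid[k] <- (xr - xl) * dt
  }
  thr <- median(trace) + if (heightUnits == "noise_sd") {
    resid <- trace - sm
    minHeight * 1.4826 * median(abs(resid[2:(n - 1L)])) / sqrt(2 / 3)
  } else minHeight
  ok <- sm[idx] > thr & wid >= minWidth
  idx <- idx[ok]
  if (length(idx) <= 1L) return(length(idx))
  hts <- sm[idx]
  accepted <- integer(0)
  remaining <- seq_along(idx)
  while (length(remaining)) {
    # highest remaining peak, earliest on ties
    best <- remaining[order(-hts[remaining], idx[remaining])][1L]
    if (!length(accepted) ||
        all(abs(idx[best] - idx[accepted]) * dt >= minDistance))
      accepted <- c(accepted, best)
    remaining <- setdiff(remaining, best)
  }
  length(accepted)
}

# A random smooth-ish trace: baseline + a few Gaussian bumps + noise.
randomTrace <- function(n = 40L) {
  t <- seq_len(n)
  tr <- runif(1, 0, 5) + rnorm(n, 0, runif(1, 0.1, 2))
  for (b in seq_len(rpois(1, 2))) {
    c0 <- runif(1, 2, n - 2)
    tr <- tr + runif(1, 2, 30) * exp(-(t - c0)^2 / (2 * runif(1, 0.5, 4)^2))
  }
  tr
}

# Small noise-free generator settings for exact-geometry tests.
noiselessParams <- function(...) {
  eventParams(positionNoiseSd = 0, ampNoiseScale = 0, ...)
}
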