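# Dynamic-feature abstraction: each event's AP2/DNM2 tracks become one
# fixed-length vector of interpretable coordinates spanning brightness and
# positional dynamics. Feature names and order are versioned so that runs are
# reproducible and held-out events can be scored with a stored scaler.

.featureVersion <- "cmetracks-features-1"

.featureNames <- c(
  "lifetime", "dnm2_peak_frac",
  paste0("ap2_", c("max_amp", "mean_amp", "tmax_frac", "rise_slope",
                   "decay_slope", "skewness", "kurtosis", "sig_frac",
                   "n_local_max", "plateau_frac", "amp_cv")),
  paste0("dnm2_", c("max_amp", "mean_amp", "tmax_frac", "rise_slope",
                    "decay_slope", "skewness", "kurtosis", "sig_frac",
                    "n_local_max", "plateau_frac", "amp_cv")),
  "path_length", "end_to_end", "straightness", "mean_step", "msd_slope",
  "radius_gyration", "ap2_dnm2_corr", "step_ratio_post_pre")

.channelFeatures <- function(amp, pres, t) {
  imax <- which.max(amp)
  span <- t[length(t)] - t[1L]
  tmaxFrac <- if (span > 0) (t[imax] - t[1L]) / span else 0.5
  rise <- if (t[imax] > t[1L]) (amp[imax] - amp[1L]) / (t[imax] - t[1L]) else 0
  decay <- if (t[length(t)] > t[imax])
    (amp[length(amp)] - amp[imax]) / (t[length(t)] - t[imax]) else 0
  sm <- movingAverage3(amp)
  n <- length(sm)
  nloc <- if (n >= 3L)
    sum(sm[2:(n - 1L)] > sm[1:(n - 2L)] & sm[2:(n - 1L)] > sm[3:n]) else 0L
  mx <- max(amp)
  m <- mean(amp)
  c(max_amp = mx, mean_amp = m, tmax_frac = tmaxFrac, rise_slope = rise,
    decay_slope = decay, skewness = sampleSkewness(amp),
    kurtosis = sampleKurtosis(amp), sig_frac = mean(pres),
    n_local_max = as.numeric(nloc),
    plateau_frac = if (mx > 0) mean(amp >= 0.9 * mx) else 0,
    amp_cv = if (m > 0) sd(amp) / m else 0)
}

.positionFeatures <- function(xy) {
  n <- nrow(xy)
  steps <- sqrt(rowSums(diff(xy)^2))
  pathLen <- sum(steps)
  e2e <- sqrt(sum((xy[n, ] - xy[1L, ])^2))
  straight <- if (pathLen > 0) e2e / pathLen else 1  # stationary: imputed 1
  ctr <- colMeans(xy)
  rg <- sqrt(mean(rowSums(sweep(xy, 2L, ctr)^2)))
  # MSD log-log slope over lags 1..min(8, n/3); imputed 0 when degenerate
  maxLag <- min(8L, floor(n / 3))
  msdSlope <- 0
  if (maxLag >= 2L) {
    lags <- seq_len(maxLag)
    msd <- vapply(lags, function(l)
      mean(rowSums((xy[(1L + l):n, , drop = FALSE] -
                    xy[1:(n - l), , drop = FALSE])^2)), numeric(1L))
    ok <- msd > 0
    if (sum(ok) >= 2L)
      msdSlope <- unname(coef(lm(log(msd[ok]) ~ log(lags[ok])))[2L])
  }
  c(path_length = pathLen, end_to_end = e2e, straightness = straight,
    mean_step = if (length(steps)) mean(steps) else 0, msd_slope = msdSlope,
    radius_gyration = rg)
}

.eventFeatures <- function(ev, dt) {
  ap2 <- ev[ev$channel == "AP2", , drop = FALSE]
  dnm2 <- ev[ev$channel == "DNM2", , drop = FALSE]
  if (nrow(ap2) < 3L || nrow(dnm2) < 3L)
    stop("event '", ev$event_id[1L],
         "': AP2 and DNM2 channels need at least 3 frames")
  if (all(ap2$amplitude == 0) && all(dnm2$amplitude == 0))
    stop("event '", ev$event_id[1L], "': all-zero amplitudes")
  presA <- which(ap2$amplitude_present)
  if (!length(presA)) presA <- seq_len(nrow(ap2))
  t0 <- ap2$t[presA[1L]]
  t1 <- ap2$t[presA[length(presA)]]
  lifetime <- t1 - t0
  dAmp <- ifelse(dnm2$amplitude_present, dnm2$amplitude, 0)
  imaxD <- which.max(dAmp)
  peakFrac <- if (lifetime > 0)
    min(1, max(0, (dnm2$t[imaxD] - t0) / lifetime)) else 0.5
  xy <- as.matrix(ap2[presA, c("x", "y"), drop = FALSE])
  pre <- presA[presA <= imaxD]
  post <- presA[presA >= imaxD]
  meanStepOf <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    mean(sqrt(rowSums(diff(as.matrix(ap2[idx, c("x", "y")]))^2)))
  }
  spre <- meanStepOf(pre)
  spost <- meanStepOf(post)
  stepRatio <- if (is.finite(spre) && is.finite(spost) && spre > 0)
    spost / spre else 1
  corAD <- if (sd(ap2$amplitude) > 0 && sd(dnm2$amplitude) > 0)
    cor(ap2$amplitude, dnm2$amplitude) else 0
  chA <- .channelFeatures(ap2$amplitude, ap2$amplitude_present, ap2$t)
  chD <- .channelFeatures(dAmp, dnm2$amplitude_present, dnm2$t)
  v <- c(lifetime = lifetime, dnm2_peak_frac = peakFrac,
         setNames(chA, paste0("ap2_", names(chA))),
         setNames(chD, paste0("dnm2_", names(chD))),
         .positionFeatures(xy),
         ap2_dnm2_corr = corAD, step_ratio_post_pre = stepRatio)
  v[.featureNames]
}

#' Decompose events into fixed-length dynamic feature vectors
#'
#' Each event's AP2 and DNM2 traces are summarised by 32 named features
#' spanning brightness dynamics (per-channel max/mean amplitude, time
#' fraction of the maximum, rise and decay slopes, skewness, kurtosis,
#' significant-frame fraction, local-maximum count, plateau fraction,
#' coefficient of variation), event timing (AP2 lifetime; DNM2-peak fraction,
#' the position of the DNM2 maximum within the AP2 event, in \[0,1\]) and
#' AP2 positional dynamics (path length, end-to-end distance, straightness,
#' mean frame-to-frame step, MSD log-log slope, radius of gyration), plus the
#' AP2-DNM2 amplitude correlation and the post/pre DNM2-maximum step ratio.
#' Degenerate cases are imputed (stationary tracks: straightness 1, MSD slope
#' 0) and recorded in the `"imputations"` attribute.
#'
#' @param x a [TrackSet-class] with AP2 and DNM2 channels.
#' @return data.frame with `event_id` plus one column per feature; the
#'   feature-set version string is attached as attribute `"featureVersion"`.
#' @export
extractFeatures <- function(x) {
  stopifnot(is(x, "TrackSet"))
  df <- trackData(x)
  ids <- unique(df$event_id)
  rows <- matrix(NA_real_, length(ids), length(.featureNames),
                 dimnames = list(NULL, .featureNames))
  imputed <- character(0)
  split_ev <- split(df, df$event_id)
  for (k in seq_along(ids)) {
    ev <- split_ev[[ids[k]]]
    v <- .eventFeatures(ev, x@frameInterval)
    if (v["path_length"] == 0) imputed <- c(imputed, ids[k])
    rows[k, ] <- v
  }
  out <- data.frame(event_id = ids, rows, stringsAsFactors = FALSE)
  attr(out, "featureVersion") <- .featureVersion
  attr(out, "imputations") <- imputed
  out
}

#' Scale features to standard-normal marginals
#'
#' Each feature column is mapped through a rank-based quantile transform to a
#' standard normal: value of rank r (ties averaged) among n maps to
#' `qnorm((r - 0.5) / n)`. The transform is monotone in the input, bounds the
#' influence of outliers by the extreme-rank quantile, and is stored so that
#' held-out events can be mapped through the same transform (by monotone
#' interpolation between training values, clamped at the extremes). Constant
#' columns are passed through as zeros with a warning.
#'
#' @param x numeric matrix or feature data.frame from [extractFeatures()]
#'   (an `event_id` column, if present, is carried through untouched).
#' @return list with `scaled` (numeric matrix) and `scaler` (an object of
#'   class `"FeatureScaler"` for [applyFeatureScaler()]).
#' @export
scaleFeatures <- function(x) {
  ids <- NULL
  if (is.data.frame(x) && "event_id" %in% names(x)) {
    ids <- x$event_id
    x <- x[setdiff(names(x), "event_id")]
  }
  m <- as.matrix(x)
  if (nrow(m) < 20L)
    stop("at least 20 events are required to scale features for clustering")
  n <- nrow(m)
  scaled <- matrix(0, n, ncol(m), dimnames = dimnames(m))
  maps <- vector("list", ncol(m))
  names(maps) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (max(v) == min(v)) {
      warning("feature '", colnames(m)[j],
              "' is constant; passed through as zeros")
      maps[[j]] <- list(constant = TRUE, value = v[1L])
      next
    }
    r <- rank(v, ties.method = "average")
    scaled[, j] <- qnorm((r - 0.5) / n)
    ord <- order(v)
    maps[[j]] <- list(constant = FALSE, xs = v[ord],
                      zs = scaled[ord, j])
  }
  scaler <- structure(list(maps = maps, n = n,
                           featureVersion = attr(x, "featureVersion")),
                      class = "FeatureScaler")
  if (!is.null(ids)) rownames(scaled) <- ids
  list(scaled = scaled, scaler = scaler)
}

#' @rdname scaleFeatures
#' @param scaler a `"FeatureScaler"` from [scaleFeatures()].
#' @param newdata matrix or data.frame of held-out feature vectors with the
#'   training columns.
#' @export
applyFeatureScaler <- function(scaler, newdata) {
  stopifnot(inherits(scaler, "FeatureScaler"))
  if (is.data.frame(newdata) && "event_id" %in% names(newdata))
    newdata <- newdata[setdiff(names(newdata), "event_id")]
  m <- as.matrix(newdata)[, names(scaler$maps), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    mp <- scaler$maps[[j]]
    if (mp$constant) next
    ux <- !duplicated(mp$xs)
    out[, j] <- approx(mp$xs[ux], mp$zs[ux], xout = m[, j],
                       rule = 2, ties = "ordered")$y
  }
  out
}
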