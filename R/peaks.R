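# DNM2 burst counting and Rayleigh-fit selection of peak-defining
# parameters. Traces are pre-smoothed by a 3-frame centered moving average
# (stabilises width estimates at 1 s sampling); a peak is an interior local
# maximum of the smoothed trace exceeding the height threshold whose full
# width at half prominence reaches the minimum width; the minimum
# peak-to-peak distance is enforced by discarding the lower of two close
# peaks (equal heights: the earlier peak is kept).

# Candidate local maxima of a trace with prominences and half-prominence
# widths. Plateau-topped maxima are represented by their first index.
peakCandidates <- function(trace, dt) {
  s <- movingAverage3(trace)
  n <- length(s)
  if (n < 3L || max(s) == min(s))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L  # flat top
      if (j < n && s[j + 1L] < s[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks))
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  prom <- numeric(length(peaks))
  width <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- s[p]
    # reference minima between this peak and the nearest higher ground
    lmin <- h; i2 <- p
    while (i2 > 1L) {
      i2 <- i2 - 1L
      lmin <- min(lmin, s[i2])
      if (s[i2] > h) break
    }
    rmin <- h; i2 <- p
    while (i2 < n) {
      i2 <- i2 + 1L
      rmin <- min(rmin, s[i2])
      if (s[i2] > h) break
    }
    prom[k] <- h - max(lmin, rmin)
    half <- h - prom[k] / 2
    # left crossing
    li <- p
    while (li > 1L && s[li - 1L] >= half && s[li - 1L] <= h) li <- li - 1L
    xl <- if (li == 1L || s[li - 1L] > h) li else
      li - (s[li] - half) / (s[li] - s[li - 1L])
    ri <- p
    while (ri < n && s[ri + 1L] >= half && s[ri + 1L] <= h) ri <- ri + 1L
    xr <- if (ri == n || s[ri + 1L] > h) ri else
      ri + (s[ri] - half) / (s[ri] - s[ri + 1L])
    width[k] <- (xr - xl) * dt
  }
  data.frame(index = peaks, height = s[peaks], prominence = prom,
             width = width)
}

.filterCandidates <- function(cand, trace, dt, minHeight, minWidth,
                              minDistance, heightUnits) {
  if (!nrow(cand)) return(cand)
  thr <- median(trace) +
    if (heightUnits == "noise_sd") minHeight * robustNoiseSd(trace)
    else minHeight
  keep <- cand$height > thr & cand$width >= minWidth
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) <= 1L) return(cand)
  # greedy distance enforcement: accept by decreasing height, earlier index
  # winning ties, drop peaks within minDistance of an accepted one
  ord <- order(-cand$height, cand$index)
  acc <- integer(0)
  for (k in ord) {
    if (!length(acc) ||
        all(abs(cand$index[k] - cand$index[acc]) * dt >= minDistance))
      acc <- c(acc, k)
  }
  cand[sort(acc), , drop = FALSE]
}

#' Count qualifying peaks in an amplitude trace
#'
#' @param trace numeric amplitude series, uniformly sampled.
#' @param dt frame interval, seconds.
#' @param minHeight required height above the trace baseline (median), in
#'   robust-noise-SD units (`heightUnits = "noise_sd"`, default, so grids
#'   transfer across intensity scales) or raw amplitude units
#'   (`"absolute"`).
#' @param minWidth minimum full width at half prominence, seconds.
#' @param minDistance minimum peak-to-peak separation, seconds.
#' @param heightUnits interpretation of `minHeight`.
#' @param details if `TRUE`, return the qualifying peak table instead of the
#'   count.
#' @return integer peak count (0 for empty or flat traces), or a data.frame
#'   of qualifying peaks when `details = TRUE`.
#' @export
countPeaks <- function(trace, dt, minHeight, minWidth, minDistance,
                       heightUnits = c("noise_sd", "absolute"),
                       details = FALSE) {
  heightUnits <- match.arg(heightUnits)
  if (length(trace) < 3L) return(if (details) peakCandidates(numeric(0), dt) else 0L)
  cand <- peakCandidates(trace, dt)
  out <- .filterCandidates(cand, trace, dt, minHeight, minWidth, minDistance,
                           heightUnits)
  if (details) out else nrow(out)
}

#' Fit a Rayleigh distribution to single-peak lifetimes
#'
#' The Rayleigh scale is the closed-form maximum-likelihood estimate
#' `sigma = sqrt(sum(x^2) / (2 n))`; the goodness of fit is the one-sample
#' Kolmogorov-Smirnov statistic against Rayleigh(sigma).
#'
#' @param lifetimes positive lifetimes in seconds (at least 20).
#' @return list with `sigmaHat` (seconds) and `gof` (KS statistic).
#' @export
fitRayleigh <- function(lifetimes) {
  x <- as.numeric(lifetimes)
  if (length(x) < 20L) stop("at least 20 lifetimes are required")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("lifetimes must all be positive and finite")
  sigma <- sqrt(sum(x^2) / (2 * length(x)))
  gof <- suppressWarnings(as.numeric(
    ks.test(x, function(q) prayleigh(q, sigma))$statistic))
  list(sigmaHat = sigma, gof = gof)
}

.dnm2Trace <- function(ev) {
  d <- ev[ev$channel == "DNM2", , drop = FALSE]
  ifelse(d$amplitude_present, d$amplitude, 0)
}

.eventTiming <- function(ev) {
  ap2 <- ev[ev$channel == "AP2", , drop = FALSE]
  d <- ev[ev$channel == "DNM2", , drop = FALSE]
  presA <- which(ap2$amplitude_present)
  onsetIdx <- if (length(presA)) presA[1L] else 1L
  dAmp <- ifelse(d$amplitude_present, d$amplitude, 0)
  sIdx <- which.max(dAmp)
  list(tOnset = ap2$t[onsetIdx], onsetFrame = ap2$frame[onsetIdx],
       tScission = d$t[sIdx], scissionFrame = d$frame[sIdx])
}

#' Survey peak-defining parameters and select by Rayleigh fit
#'
#' For every combination of the height, width and distance grids, all events
#' are categorised as having zero, one, or two or more DNM2 peaks; the
#' lifetime distribution of single-peak events (first significant AP2 frame
#' to DNM2 maximum) is fit to a Rayleigh distribution; and the combination
#' minimising the KS goodness-of-fit statistic is selected (ties broken by
#' the lexicographically smallest parameter tuple). Combinations yielding
#' fewer than 20 single-peak events are skipped and flagged in the survey.
#'
#' @param events a [TrackSet-class] of DNM2-positive events (>= 50).
#' @param heightGrid,widthGrid,distanceGrid non-empty numeric grids (height
#'   in robust-noise-SD units; width and distance in seconds).
#' @param heightUnits see [countPeaks()].
#' @return list with `params` (the selected [PeakParams-class], carrying the
#'   fitted sigma and gof) and `survey` (data.frame: height, width, distance,
#'   n0, n1, n2plus, sigma_hat, gof, skipped).
#' @export
selectPeakParameters <- function(events, heightGrid = c(2, 3, 4),
                                 widthGrid = c(1, 2, 3),
                                 distanceGrid = c(3, 5, 8),
                                 heightUnits = c("noise_sd", "absolute")) {
  heightUnits <- match.arg(heightUnits)
  stopifnot(is(events, "TrackSet"))
  if (!length(heightGrid) || !length(widthGrid) || !length(distanceGrid))
    stop("all three parameter grids must be non-empty")
  dt <- frameInterval(events)
  df <- trackData(events)
  evs <- split(df, df$event_id)
  if (length(evs) < 50L)
    stop("at least 50 events are required for the parameter survey")
  cands <- lapply(evs, function(ev) {
    tr <- .dnm2Trace(ev)
    list(cand = peakCandidates(tr, dt), trace = tr,
         timing = .eventTiming(ev))
  })
  lifetimes <- vapply(cands, function(e)
    e$timing$tScission - e$timing$tOnset, numeric(1L))

  grid <- expand.grid(height = sort(heightGrid), width = sort(widthGrid),
                      distance = sort(distanceGrid),
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic order (height, width, distance) for deterministic ties
  grid <- grid[order(grid$height, grid$width, grid$distance), , drop = FALSE]
  survey <- grid
  survey$n0 <- survey$n1 <- survey$n2plus <- 0L
  survey$sigma_hat <- NA_real_
  survey$gof <- NA_real_
  survey$skipped <- FALSE
  for (g in seq_len(nrow(grid))) {
    counts <- vapply(cands, function(e)
      nrow(.filterCandidates(e$cand, e$trace, dt, grid$height[g],
                             grid$width[g], grid$distance[g], heightUnits)),
      integer(1L))
    survey$n0[g] <- sum(counts == 0L)
    survey$n1[g] <- sum(counts == 1L)
    survey$n2plus[g] <- sum(counts >= 2L)
    lt <- lifetimes[counts == 1L]
    lt <- lt[lt > 0]
    if (length(lt) < 20L) {
      survey$skipped[g] <- TRUE
      next
    }
    fit <- fitRayleigh(lt)
    survey$sigma_hat[g] <- fit$sigmaHat
    survey$gof[g] <- fit$gof
  }
  ok <- which(!survey$skipped)
  if (!length(ok))
    stop("every grid combination yielded fewer than 20 single-peak events")
  best <- ok[which.min(survey$gof[ok])]   # first minimum = lexicographic tie
  params <- peakParams(survey$height[best], survey$width[best],
                       survey$distance[best],
                       sigmaHat = survey$sigma_hat[best],
                       gof = survey$gof[best], heightUnits = heightUnits)
  rownames(survey) <- NULL
  list(params = params, survey = survey)
}

#' Keep single-DNM2-peak events and annotate scission
#'
#' Events whose DNM2 trace has exactly one qualifying peak under `params` are
#' retained as CME sites; the scission frame is the frame of maximum DNM2
#' intensity and the event lifetime runs from the first significant AP2
#' frame to scission.
#'
#' @param events a [TrackSet-class].
#' @param params a [PeakParams-class] (typically from
#'   [selectPeakParameters()]).
#' @return list with `events` (the retained subset) and `annotations`
#'   (data.frame: event_id, n_dnm2_peaks, scission_frame, t_scission,
#'   ap2_onset_frame, t_ap2_onset, lifetime).
#' @export
filterSinglePeak <- function(events, params) {
  stopifnot(is(events, "TrackSet"), is(params, "PeakParams"))
  dt <- frameInterval(events)
  df <- trackData(events)
  evs <- split(df, df$event_id)
  rows <- lapply(evs, function(ev) {
    tr <- .dnm2Trace(ev)
    n <- countPeaks(tr, dt, params@minHeight, params@minWidth,
                    params@minDistance, heightUnits = params@heightUnits)
    tm <- .eventTiming(ev)
    data.frame(event_id = ev$event_id[1L], n_dnm2_peaks = n,
               scission_frame = tm$scissionFrame, t_scission = tm$tScission,
               ap2_onset_frame = tm$onsetFrame, t_ap2_onset = tm$tOnset,
               lifetime = tm$tScission - tm$tOnset,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  keep <- ann$event_id[ann$n_dnm2_peaks == 1L]
  ann <- ann[ann$n_dnm2_peaks == 1L, , drop = FALSE]
  if (any(ann$lifetime < 0))
    stop("scission precedes AP2 onset for event(s): ",
         paste(head(ann$event_id[ann$lifetime < 0], 5L), collapse = ", "))
  list(events = subsetEvents(events, keep), annotations = ann)
}
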