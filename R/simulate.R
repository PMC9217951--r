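#' Generator settings for synthetic CME track data
#'
#' Bundles the knobs of the synthetic-data module. Defaults encode the study
#' conditions the analysis assumes: Rayleigh-distributed CME lifetimes
#' (`lifetimeSigma` 20 s), 1 s frame interval, DNM2 recruited in two phases
#' (a low early level of `dnm2EarlyFrac` times the burst peak plus a terminal
#' burst whose maximum marks scission), an ARPC3 burst laterally displaced
#' `arpc3Offset` = 150 nm from the coat in a per-event random direction that
#' starts `arpc3OnsetLead` s before scission, a ~10 s AP2 plateau
#' (`stallPlateau`) for actin-positive (stalled) events, and diffusing
#' short-lived "visitor" contaminant tracks.
#'
#' @param lifetimeSigma Rayleigh scale of base CME lifetimes, seconds.
#' @param frameInterval frame spacing, seconds.
#' @param ap2PeakAmp AP2 peak amplitude, arbitrary fluorescence units.
#' @param dnm2EarlyFrac early-phase DNM2 level as a fraction of the burst peak.
#' @param dnm2BurstWidth full width at half maximum of the terminal DNM2
#'   burst, seconds.
#' @param arpc3Offset true lateral ARPC3 displacement from AP2, nm.
#' @param arpc3OnsetLead ARPC3 onset lead before scission, seconds.
#' @param stallPlateau extra AP2 plateau inserted before scission for
#'   ARPC3-positive events, seconds (added to the base lifetime).
#' @param fracArpc3Positive fraction of non-visitor events with a true late
#'   ARPC3 burst.
#' @param fracVisitors fraction of generated tracks that are visitors.
#' @param fracDoubleBurst fraction of CME events given a second, earlier DNM2
#'   burst (for peak-detection testing).
#' @param strayArpc3PerEvent stray diffusing ARPC3 tracks generated per event
#'   by [simulateDataset()]; these drive random early overlaps.
#' @param positionNoiseSd per-frame isotropic positional jitter, nm.
#' @param ampNoiseScale amplitude noise variance per unit mean amplitude
#'   (Gaussian shot-noise proxy); 0 disables amplitude noise.
#' @param pixelSize camera pixel size, nm (used by track I/O unit handling).
#' @param fieldSize side length of the imaged field, nm.
#' @param movieLength movie duration, seconds.
#' @param visitorLifetimeSigma Rayleigh scale of visitor track lifetimes, s.
#' @param visitorStepSd per-frame random-walk step SD of visitors, nm.
#' @param strayStepSd per-frame random-walk step SD of stray ARPC3 tracks, nm.
#' @param postScissionStepScale multiplier on the random-walk step after
#'   scission (vesicles move fast once released).
#' @param maxLifetimeRetries re-sampling cap for conditioned lifetime draws.
#' @return a validated list of class `"EventParams"`.
#' @export
eventParams <- function(lifetimeSigma = 20, frameInterval = 1,
                        ap2PeakAmp = 100, dnm2EarlyFrac = 0.1,
                        dnm2BurstWidth = 5, arpc3Offset = 150,
                        arpc3OnsetLead = 15, stallPlateau = 10,
                        fracArpc3Positive = 0.7, fracVisitors = 0.15,
                        fracDoubleBurst = 0, strayArpc3PerEvent = 0.5,
                        positionNoiseSd = 20, ampNoiseScale = 1,
                        pixelSize = 108, fieldSize = 20000,
                        movieLength = 240, visitorLifetimeSigma = 5,
                        visitorStepSd = 100, strayStepSd = 50,
                        postScissionStepScale = 2, maxLifetimeRetries = 100L) {
  p <- list(lifetimeSigma = lifetimeSigma, frameInterval = frameInterval,
            ap2PeakAmp = ap2PeakAmp, dnm2EarlyFrac = dnm2EarlyFrac,
            dnm2BurstWidth = dnm2BurstWidth, arpc3Offset = arpc3Offset,
            arpc3OnsetLead = arpc3OnsetLead, stallPlateau = stallPlateau,
            fracArpc3Positive = fracArpc3Positive,
            fracVisitors = fracVisitors, fracDoubleBurst = fracDoubleBurst,
            strayArpc3PerEvent = strayArpc3PerEvent,
            positionNoiseSd = positionNoiseSd,
            ampNoiseScale = ampNoiseScale, pixelSize = pixelSize,
            fieldSize = fieldSize, movieLength = movieLength,
            visitorLifetimeSigma = visitorLifetimeSigma,
            visitorStepSd = visitorStepSd, strayStepSd = strayStepSd,
            postScissionStepScale = postScissionStepScale,
            maxLifetimeRetries = as.integer(maxLifetimeRetries))
  fracs <- c("dnm2EarlyFrac", "fracArpc3Positive", "fracVisitors",
             "fracDoubleBurst")
  for (f in fracs)
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$frameInterval <= 0) stop("frameInterval must be > 0")
  if (p$lifetimeSigma <= 0) stop("lifetimeSigma must be > 0")
  if (p$stallPlateau < 0 || p$arpc3OnsetLead < 0)
    stop("durations must be non-negative")
  class(p) <- "EventParams"
  p
}

.eventClasses <- c("cme_arpc3_negative", "cme_arpc3_late", "visitor",
                   "random_overlap_early")

.trackRows <- function(eventId, channel, frames, t, x, y, amp, pres, psd) {
  data.frame(event_id = eventId, channel = channel, frame = as.integer(frames),
             t = t, x = x, y = y, amplitude = amp,
             amplitude_present = pres, position_sd = psd,
             stringsAsFactors = FALSE)
}

.addAmpNoise <- function(amp, scale) {
  if (scale <= 0) return(amp)
  pmax(0, amp + rnorm(length(amp), 0, sqrt(scale * pmax(amp, 1))))
}

#' Generate one synthetic event
#'
#' Builds the per-frame track table for a single event of a given class,
#' together with its ground truth. CME events have a rising (optionally
#' plateaued) AP2 trace that decays after scission, a two-phase DNM2 trace
#' whose terminal burst peaks at the scission frame, and (for the late class)
#' an attached ARPC3 track displaced by `arpc3Offset` in a random direction
#' fixed within the event. Visitors are short-lived, motile tracks without a
#' DNM2 burst. `random_overlap_early` builds an ARPC3-negative CME event plus
#' an independent stray ARPC3 track transiting the site during its first
#' frames.
#'
#' @param params an [eventParams()] list.
#' @param classLabel one of `"cme_arpc3_negative"`, `"cme_arpc3_late"`,
#'   `"visitor"`, `"random_overlap_early"`.
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   consumed (used by [simulateDataset()]).
#' @param eventId event identifier.
#' @param anchor event anchor position (nm, length 2); random in the field if
#'   `NULL`.
#' @param tStart start time on the movie frame grid, seconds; random within
#'   the movie if `NULL`.
#' @param doubleBurst add a second, earlier DNM2 burst (resolvable bursts:
#'   the base lifetime is then drawn conditioned on >= 18 s).
#' @return list with elements `tracks` (data.frame of event channel rows),
#'   `third` (data.frame of attached/stray ARPC3 track rows, or `NULL`) and
#'   `truth` (one-row ground-truth data.frame).
#' @export
simulateEvent <- function(params, classLabel, seed = NULL, eventId = "ev1",
                          anchor = NULL, tStart = 0, doubleBurst = FALSE) {
  stopifnot(inherits(params, "EventParams"))
  if (!classLabel %in% .eventClasses)
    stop("invalid class label '", classLabel, "'; must be one of: ",
         paste(.eventClasses, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- params
  dt <- p$frameInterval
  if (is.null(anchor))
    anchor <- runif(2L, 0.05, 0.95) * p$fieldSize

  if (classLabel == "visitor")
    return(.simVisitor(p, eventId, anchor, tStart))

  stalled <- classLabel == "cme_arpc3_late"
  # doubles need temporally resolvable bursts; otherwise only degenerate
  # (non-positive) draws are rejected, keeping the base sample Rayleigh
  minBase <- if (doubleBurst) 18 else .Machine$double.eps
  base <- drawRayleighMin(p$lifetimeSigma, minBase, p$maxLifetimeRetries)
  L <- base + if (stalled) p$stallPlateau else 0
  s <- max(3L, as.integer(round(L / dt)))          # scission frame index
  tailFrames <- max(2L, as.integer(round(5 / dt))) # post-scission decay
  nf <- s + tailFrames + 1L
  i <- 0:(nf - 1L)
  if (is.null(tStart)) {
    movieFrames <- as.integer(floor(p$movieLength / dt))
    tStart <- dt * (sample.int(max(1L, movieFrames - nf + 1L), 1L) - 1L)
  }
  t <- tStart + i * dt
  ts <- tStart + s * dt

  # AP2: linear rise to peak (completed stallPlateau s early when stalled),
  # plateau, exponential decay (tau = 2 s) after scission
  plateauFrames <- if (stalled) as.integer(round(p$stallPlateau / dt)) else 0L
  riseFrames <- max(1L, s - plateauFrames)
  ap2 <- ifelse(i <= s,
                p$ap2PeakAmp * pmin(1, (i + 1) / (riseFrames + 1)),
                p$ap2PeakAmp * exp(-(i - s) * dt / 2))

  # DNM2: constant early phase + Gaussian terminal burst peaking at scission
  burstPeak <- 0.8 * p$ap2PeakAmp
  sdb <- p$dnm2BurstWidth / (2 * sqrt(2 * log(2)))
  dnm2 <- p$dnm2EarlyFrac * burstPeak +
    burstPeak * exp(-((t - ts)^2) / (2 * sdb^2))
  nPeaks <- 1L
  if (doubleBurst) {
    s2 <- s - max(as.integer(round(10 / dt)), as.integer(ceiling(0.4 * s)))
    s2 <- max(2L, s2)
    t2 <- tStart + s2 * dt
    dnm2 <- dnm2 + 0.85 * burstPeak * exp(-((t - t2)^2) / (2 * sdb^2))
    nPeaks <- 2L
  }

  # positions: isotropic jitter about the anchor before scission, faster
  # random walk afterwards
  jit <- function(sd0) {
    xy <- matrix(anchor, nf, 2L, byrow = TRUE)
    if (sd0 > 0) {
      xy <- xy + matrix(rnorm(2L * nf, 0, sd0), nf, 2L)
      post <- which(i > s)
      if (length(post)) {
        stepSd <- p$postScissionStepScale * sd0
        walk <- apply(matrix(rnorm(2L * length(post), 0, stepSd),
                             length(post), 2L), 2L, cumsum)
        xy[post, ] <- matrix(xy[s + 1L, ], length(post), 2L, byrow = TRUE) +
          walk
      }
    }
    xy
  }
  xyA <- jit(p$positionNoiseSd)
  xyD <- jit(p$positionNoiseSd)

  rows <- rbind(
    .trackRows(eventId, "AP2", i, t, xyA[, 1L], xyA[, 2L],
               .addAmpNoise(ap2, p$ampNoiseScale), TRUE, p$positionNoiseSd),
    .trackRows(eventId, "DNM2", i, t, xyD[, 1L], xyD[, 2L],
               .addAmpNoise(dnm2, p$ampNoiseScale), TRUE, p$positionNoiseSd))

  third <- NULL
  offx <- NA_real_; offy <- NA_real_; thirdId <- NA_character_
  if (classLabel == "cme_arpc3_late") {
    theta <- runif(1L, 0, 2 * pi)
    off <- p$arpc3Offset * c(cos(theta), sin(theta))
    offx <- off[1L]; offy <- off[2L]
    o <- max(0L, s - as.integer(round(p$arpc3OnsetLead / dt)))
    ia <- o:(nf - 1L)
    ta <- tStart + ia * dt
    arp <- ifelse(ia <= s,
                  0.7 * p$ap2PeakAmp * (ia - o + 1) / (s - o + 1),
                  0.7 * p$ap2PeakAmp * exp(-(ia - s) * dt / 2))
    na <- length(ia)
    xyT <- matrix(anchor + off, na, 2L, byrow = TRUE)
    if (p$positionNoiseSd > 0)
      xyT <- xyT + matrix(rnorm(2L * na, 0, p$positionNoiseSd), na, 2L)
    thirdId <- paste0(eventId, ".arp")
    third <- .trackRows(thirdId, "ARPC3", seq_len(na) - 1L, ta,
                        xyT[, 1L], xyT[, 2L],
                        .addAmpNoise(arp, p$ampNoiseScale), TRUE,
                        p$positionNoiseSd)
  } else if (classLabel == "random_overlap_early") {
    # independent stray ARPC3 track transiting the site in its first frames
    nTransit <- 5L
    u <- runif(1L, 0, 2 * pi); dirv <- c(cos(u), sin(u))
    perp <- c(-dirv[2L], dirv[1L]) * 50
    j <- 0:(nTransit - 1L)
    xyT <- t(vapply(j, function(k) anchor + (k - 2) * 60 * dirv + perp,
                    numeric(2L)))
    if (p$positionNoiseSd > 0)
      xyT <- xyT + matrix(rnorm(2L * nTransit, 0, p$positionNoiseSd),
                          nTransit, 2L)
    arp <- 0.6 * p$ap2PeakAmp * c(0.6, 0.9, 1, 0.9, 0.6)
    thirdId <- paste0(eventId, ".stray")
    third <- .trackRows(thirdId, "ARPC3", j, tStart + j * dt,
                        xyT[, 1L], xyT[, 2L],
                        .addAmpNoise(arp, p$ampNoiseScale), TRUE,
                        p$positionNoiseSd)
  }

  truth <- data.frame(event_id = eventId, class = classLabel,
                      lifetime = s * dt, base_lifetime = base,
                      scission_frame = s, t_scission = ts,
                      offset_x = offx, offset_y = offy,
                      n_peaks = nPeaks, third_id = thirdId,
                      stringsAsFactors = FALSE)
  list(tracks = rows, third = third, truth = truth)
}

.simVisitor <- function(p, eventId, anchor, tStart) {
  dt <- p$frameInterval
  L <- drawRayleighMin(p$visitorLifetimeSigma, 3 * dt, p$maxLifetimeRetries)
  nf <- max(4L, as.integer(round(L / dt)) + 1L)
  i <- 0:(nf - 1L)
  if (is.null(tStart)) {
    movieFrames <- as.integer(floor(p$movieLength / dt))
    tStart <- dt * (sample.int(max(1L, movieFrames - nf + 1L), 1L) - 1L)
  }
  t <- tStart + i * dt
  # diffusing coated-vesicle visitor: random walk, triangular AP2 hump,
  # no DNM2 burst (sporadic low-level detections only)
  steps <- matrix(rnorm(2L * nf, 0, p$visitorStepSd), nf, 2L)
  steps[1L, ] <- 0
  xy <- matrix(anchor, nf, 2L, byrow = TRUE) + apply(steps, 2L, cumsum)
  mid <- (nf - 1L) / 2
  ap2 <- 0.6 * p$ap2PeakAmp * (1 - abs(i - mid) / (mid + 1))
  presD <- runif(nf) < 0.25
  presA <- runif(nf) < 0.95   # dim motile spots drop out of detection
  dnm2 <- ifelse(presD, 0.1 * p$ap2PeakAmp, 0)
  rows <- rbind(
    .trackRows(eventId, "AP2", i, t, xy[, 1L], xy[, 2L],
               ifelse(presA, .addAmpNoise(ap2, p$ampNoiseScale), 0),
               presA, p$positionNoiseSd),
    .trackRows(eventId, "DNM2", i, t, xy[, 1L], xy[, 2L],
               ifelse(presD, .addAmpNoise(dnm2, p$ampNoiseScale), 0),
               presD, p$positionNoiseSd))
  truth <- data.frame(event_id = eventId, class = "visitor",
                      lifetime = (nf - 1L) * dt, base_lifetime = L,
                      scission_frame = NA_integer_, t_scission = NA_real_,
                      offset_x = NA_real_, offset_y = NA_real_,
                      n_peaks = 0L, third_id = NA_character_,
                      stringsAsFactors = FALSE)
  list(tracks = rows, third = NULL, truth = truth)
}

.simStray <- function(p, trackId) {
  dt <- p$frameInterval
  nf <- max(6L, as.integer(round(20 / dt)))
  movieFrames <- as.integer(floor(p$movieLength / dt))
  tStart <- dt * (sample.int(max(1L, movieFrames - nf + 1L), 1L) - 1L)
  i <- 0:(nf - 1L)
  start <- runif(2L, 0.02, 0.98) * p$fieldSize
  steps <- matrix(rnorm(2L * nf, 0, p$strayStepSd), nf, 2L)
  steps[1L, ] <- 0
  xy <- matrix(start, nf, 2L, byrow = TRUE) + apply(steps, 2L, cumsum)
  mid <- (nf - 1L) / 2
  amp <- 0.6 * p$ap2PeakAmp * (1 - abs(i - mid) / (mid + 1))
  .trackRows(trackId, "ARPC3", i, tStart + i * dt, xy[, 1L], xy[, 2L],
             .addAmpNoise(amp, p$ampNoiseScale), TRUE, p$positionNoiseSd)
}

#' Generate a synthetic track dataset with ground truth
#'
#' Draws event classes (visitor with probability `fracVisitors`; otherwise a
#' CME event, ARPC3-positive with probability `fracArpc3Positive`), places
#' events uniformly in the field and movie, and adds a homogeneous background
#' of stray diffusing ARPC3 tracks (`strayArpc3PerEvent` per event). An
#' ARPC3-negative event that receives a stray transit within 300 nm for at
#' least 3 frames, in its first half and more than 20 s before scission, is
#' relabelled `random_overlap_early` in the ground truth: random early
#' overlaps are a property of track density, which is what makes the
#' randomized-pairing control ([randomizeChannelPairing()]) preserve the
#' early fraction while destroying true late associations.
#'
#' @param params an [eventParams()] list.
#' @param nEvents number of events (>= 1).
#' @param seed integer seed; the dataset is bitwise-reproducible given it.
#' @param idPrefix prefix for event/track ids; defaults to a seed-derived
#'   prefix so independently generated datasets have disjoint id namespaces.
#' @return list with `events` (a [TrackSet-class] with AP2 and DNM2
#'   channels), `third` (a TrackSet of separately tracked ARPC3 tracks) and
#'   `truth` (ground-truth data.frame, one row per event).
#' @export
simulateDataset <- function(params, nEvents, seed,
                            idPrefix = sprintf("s%d.", seed)) {
  stopifnot(inherits(params, "EventParams"), nEvents >= 1)
  set.seed(stageSeed(seed, 1L))
  p <- params
  nEvents <- as.integer(nEvents)

  isVisitor <- runif(nEvents) < p$fracVisitors
  isPos <- !isVisitor & (runif(nEvents) < p$fracArpc3Positive)
  isDouble <- !isVisitor & (runif(nEvents) < p$fracDoubleBurst)
  classes <- ifelse(isVisitor, "visitor",
                    ifelse(isPos, "cme_arpc3_late", "cme_arpc3_negative"))

  evs <- vector("list", nEvents)
  for (k in seq_len(nEvents)) {
    evs[[k]] <- simulateEvent(p, classes[k], seed = NULL,
                              eventId = sprintf("%sev%04d", idPrefix, k),
                              anchor = NULL, tStart = NULL,
                              doubleBurst = isDouble[k])
  }
  tracks <- do.call(rbind, lapply(evs, `[[`, "tracks"))
  truth <- do.call(rbind, lapply(evs, `[[`, "truth"))
  thirdList <- Filter(Negate(is.null), lapply(evs, `[[`, "third"))

  nStray <- as.integer(round(p$strayArpc3PerEvent * nEvents))
  strays <- lapply(seq_len(nStray), function(k)
    .simStray(p, sprintf("%sstray%04d", idPrefix, k)))
  third <- do.call(rbind, c(thirdList, strays))
  if (is.null(third))
    third <- .trackRows(character(0), character(0), integer(0), numeric(0),
                        numeric(0), numeric(0), numeric(0), logical(0),
                        numeric(0))

  events <- TrackSet(tracks, p$frameInterval)
  thirdSet <- TrackSet(third, p$frameInterval)

  # relabel negatives that received a qualifying early stray transit
  neg <- truth$event_id[truth$class == "cme_arpc3_negative"]
  if (length(neg) && nEvents(thirdSet) > 0) {
    links <- linkThirdChannel(subsetEvents(events, neg), thirdSet,
                              linkRadius = 300, minOverlap = 3L)
    if (nrow(links)) {
      m <- match(links$event_id, truth$event_id)
      early <- !is.na(m) &
        links$t_first < truth$t_scission[m] - 0.5 * truth$lifetime[m] &
        truth$t_scission[m] - links$t_first > 20
      relabel <- links$event_id[early]
      truth$class[truth$event_id %in% relabel] <- "random_overlap_early"
      truth$third_id[match(links$event_id[early], truth$event_id)] <-
        links$track_id[early]
    }
  }
  rownames(truth) <- NULL
  list(events = events, third = thirdSet, truth = truth)
}

#' Generate a matched pair of localization clouds
#'
#' Channel B is channel A's generating distribution translated by `offset`;
#' both clouds are i.i.d. isotropic Gaussian scatter about their centers.
#'
#' @param offset numeric length-2 translation of channel B relative to
#'   channel A, nm.
#' @param nPerChannel localizations per channel (>= 1).
#' @param scatterSd isotropic scatter SD about each center, nm.
#' @param seed integer seed.
#' @param center channel A cloud center, nm.
#' @param roiId region label attached to both sets.
#' @return list of two [LocalizationSet-class] objects, `a` and `b`.
#' @export
simulateLocalizationPair <- function(offset, nPerChannel, scatterSd, seed,
                                     center = c(0, 0), roiId = "roi1") {
  stopifnot(nPerChannel >= 1, length(offset) == 2L)
  set.seed(as.integer(seed))
  n <- as.integer(nPerChannel)
  a <- matrix(center, n, 2L, byrow = TRUE)
  b <- matrix(center + offset, n, 2L, byrow = TRUE)
  if (scatterSd > 0) {
    a <- a + matrix(rnorm(2L * n, 0, scatterSd), n, 2L)
    b <- b + matrix(rnorm(2L * n, 0, scatterSd), n, 2L)
  }
  colnames(a) <- colnames(b) <- c("x", "y")
  list(a = LocalizationSet(a, "chA", roiId),
       b = LocalizationSet(b, "chB", roiId))
}

#' Randomize channel pairing between two datasets
#'
#' Emulates the control of pairing the third-channel (ARPC3) movie with AP2
#' and DNM2 movies from an unrelated acquisition: returns dataset A's events
#' with dataset B's third-channel tracks placed in the same field
#' coordinates, destroying all true ARPC3-event associations. Linking the
#' result measures the chance-overlap rate.
#'
#' @param datasetA,datasetB lists as returned by [simulateDataset()]; their
#'   id namespaces must be disjoint.
#' @param seed integer seed (fixes the deterministic track ordering).
#' @return list with `events` (from A), `third` (from B) and `truth` (A's
#'   ground truth with third-channel associations removed).
#' @export
randomizeChannelPairing <- function(datasetA, datasetB, seed = 1) {
  idsA <- c(eventIds(datasetA$events), eventIds(datasetA$third))
  idsB <- c(eventIds(datasetB$events), eventIds(datasetB$third))
  if (length(intersect(idsA, idsB)))
    stop("datasets share an id namespace; regenerate with distinct idPrefix")
  set.seed(as.integer(seed))
  truth <- datasetA$truth
  truth$third_id <- NA_character_
  list(events = datasetA$events, third = datasetB$third, truth = truth)
}
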