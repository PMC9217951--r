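# Linking separately-tracked third-channel (ARPC3 / N-WASP) tracks to CME
# events and classifying actin-assembly timing, with a bootstrap estimate of
# the actin-positive fraction.

#' Link third-channel tracks to CME events
#'
#' A third-channel track links to an event when their time-overlapping
#' significant frames number at least `minOverlap` and have median lateral
#' separation (to the event's AP2 positions) at most `linkRadius`. Each track
#' links to at most one event (nearest median separation wins) and each event
#' keeps at most one track. Linking is invariant to global translation of the
#' coordinate frame.
#'
#' @param events a [TrackSet-class] with an AP2 channel.
#' @param third a [TrackSet-class] of separately tracked third-channel
#'   tracks (one track per `event_id`).
#' @param linkRadius maximum median separation, nm (default 300: above the
#'   ~150 nm true actin offset plus positional noise).
#' @param minOverlap minimum number of overlapping frames (default 3).
#' @return data.frame with one row per linked pair: `track_id`, `event_id`,
#'   `median_sep` (nm), `n_overlap`, `t_first` (time of the first overlapping
#'   frame, s). Unlinked tracks are reported in attribute `"unlinked"`.
#' @export
linkThirdChannel <- function(events, third, linkRadius = 300,
                             minOverlap = 3L) {
  stopifnot(is(events, "TrackSet"), is(third, "TrackSet"))
  dt <- frameInterval(events)
  ed <- trackData(events)
  ed <- ed[ed$channel == "AP2" & ed$amplitude_present, , drop = FALSE]
  td <- trackData(third)
  td <- td[td$amplitude_present, , drop = FALSE]
  if (!nrow(ed) || !nrow(td))
    return(structure(data.frame(track_id = character(0),
                                event_id = character(0),
                                median_sep = numeric(0),
                                n_overlap = integer(0),
                                t_first = numeric(0)),
                     unlinked = unique(td$event_id)))
  ed$g <- as.integer(round(ed$t / dt))
  td$g <- as.integer(round(td$t / dt))

  summarize <- function(df) {
    data.frame(id = unname(tapply(df$event_id, df$event_id, `[`, 1L)),
               gmin = as.integer(tapply(df$g, df$event_id, min)),
               gmax = as.integer(tapply(df$g, df$event_id, max)),
               mx = as.numeric(tapply(df$x, df$event_id, median)),
               my = as.numeric(tapply(df$y, df$event_id, median)),
               stringsAsFactors = FALSE)
  }
  se <- summarize(ed)
  st <- summarize(td)
  evSplit <- split(ed[c("g", "x", "y", "t")], ed$event_id)
  trSplit <- split(td[c("g", "x", "y", "t")], td$event_id)

  pairs <- list()
  slack <- linkRadius + 2000  # coarse spatial prefilter on median positions
  for (k in seq_len(nrow(st))) {
    cand <- which(pmin(se$gmax, st$gmax[k]) - pmax(se$gmin, st$gmin[k]) + 1L >=
                    minOverlap &
                  sqrt((se$mx - st$mx[k])^2 + (se$my - st$my[k])^2) <= slack)
    if (!length(cand)) next
    tr <- trSplit[[st$id[k]]]
    for (e in cand) {
      ev <- evSplit[[se$id[e]]]
      m <- match(ev$g, tr$g)
      ok <- !is.na(m)
      if (sum(ok) < minOverlap) next
      d <- sqrt((ev$x[ok] - tr$x[m[ok]])^2 + (ev$y[ok] - tr$y[m[ok]])^2)
      if (median(d) <= linkRadius)
        pairs[[length(pairs) + 1L]] <-
          data.frame(track_id = st$id[k], event_id = se$id[e],
                     median_sep = median(d), n_overlap = sum(ok),
                     t_first = min(ev$t[ok]), stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs))
    return(structure(data.frame(track_id = character(0),
                                event_id = character(0),
                                median_sep = numeric(0),
                                n_overlap = integer(0),
                                t_first = numeric(0)),
                     unlinked = st$id))
  all <- do.call(rbind, pairs)
  # each track to its nearest event, then each event keeps its nearest track
  all <- all[order(all$median_sep), , drop = FALSE]
  all <- all[!duplicated(all$track_id), , drop = FALSE]
  all <- all[!duplicated(all$event_id), , drop = FALSE]
  rownames(all) <- NULL
  structure(all, unlinked = setdiff(st$id, all$track_id))
}

# Onset of sustained significant third-channel signal: first frame of a run
# of >= sustain frames with amplitude above 3 robust noise SDs.
.thirdOnset <- function(tr, sustain = 3L) {
  amp <- ifelse(tr$amplitude_present, tr$amplitude, 0)
  thr <- 3 * robustNoiseSd(amp)
  sig <- tr$amplitude_present & amp > thr
  if (!any(sig)) return(NA_real_)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain)
  if (!length(hit)) return(NA_real_)
  tr$t[starts[hit[1L]]]
}

#' Classify actin-assembly timing for annotated events
#'
#' An event is `negative` when no third-channel track is linked (or the
#' linked track never shows sustained significant signal, or its onset falls
#' at/after scission). Otherwise the onset is the first frame of at least 3
#' consecutive significant third-channel frames; the event is `early` when
#' the onset lies in the first half of the event's lifetime *and* more than
#' `earlyLead` seconds before scission, and `late` otherwise. The assembly
#' duration (first ARPC3 frame to the presumed scission time, the DNM2 peak)
#' is recorded for non-negative events.
#'
#' @param annotations annotation data.frame from [filterSinglePeak()].
#' @param events the corresponding [TrackSet-class] (unused beyond checking,
#'   kept for interface symmetry).
#' @param third third-channel [TrackSet-class].
#' @param links link table from [linkThirdChannel()].
#' @param earlyLead minimum pre-scission lead for the early class, seconds.
#' @return the annotation data.frame with added columns `arpc3_class`
#'   (`"negative"`, `"early"`, `"late"`), `arpc3_onset_t`,
#'   `assembly_duration` and `third_id`.
#' @export
classifyTiming <- function(annotations, events, third, links,
                           earlyLead = 20) {
  td <- trackData(third)
  trSplit <- split(td, td$event_id)
  ann <- annotations
  ann$arpc3_class <- "negative"
  ann$arpc3_onset_t <- NA_real_
  ann$assembly_duration <- NA_real_
  ann$third_id <- NA_character_
  m <- match(ann$event_id, links$event_id)
  for (k in which(!is.na(m))) {
    lk <- links[m[k], ]
    onset <- .thirdOnset(trSplit[[lk$track_id]])
    if (is.na(onset)) next                      # no sustained signal: negative
    if (onset >= ann$t_scission[k]) next        # appears only after scission
    ann$third_id[k] <- lk$track_id
    ann$arpc3_onset_t[k] <- onset
    ann$assembly_duration[k] <- ann$t_scission[k] - onset
    firstHalf <- onset < ann$t_ap2_onset[k] + 0.5 * ann$lifetime[k]
    ann$arpc3_class[k] <- if (firstHalf &&
                              ann$t_scission[k] - onset > earlyLead)
      "early" else "late"
  }
  ann
}

#' Fraction of actin-positive events with a bootstrap interval
#'
#' @param annotations annotation data.frame with an `arpc3_class` column.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @param level confidence level for the percentile interval.
#' @return list with `fraction`, `ci` (percentile bootstrap interval), `n`
#'   and the bootstrap replicate fractions (`replicates`).
#' @export
positiveFraction <- function(annotations, nBoot = 1000L, seed = 1L,
                             level = 0.95) {
  stopifnot(nrow(annotations) >= 1L)
  pos <- annotations$arpc3_class != "negative"
  n <- length(pos)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(nBoot),
                 function(i) mean(pos[sample.int(n, n, replace = TRUE)]),
                 numeric(1L))
  alpha <- (1 - level) / 2
  list(fraction = mean(pos),
       ci = unname(quantile(reps, c(alpha, 1 - alpha))),
       n = n, replicates = reps)
}
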