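# Event-level kinetic and geometric statistics: lifetimes, assembly
# durations, scission-aligned cohort traces, inter-channel separations,
# lateral motility, straightness and group comparisons.

#' Event lifetime and assembly duration
#'
#' The event lifetime runs from the first significant AP2 frame to the
#' presumed scission time (the DNM2 peak); the assembly duration runs from
#' the first ARPC3 frame to scission. Both are returned in seconds.
#'
#' @param annotations annotation data.frame ([filterSinglePeak()] /
#'   [classifyTiming()]).
#' @return numeric vector, one value per annotation row (named by event id).
#' @export
eventLifetime <- function(annotations) {
  lt <- annotations$t_scission - annotations$t_ap2_onset
  if (any(lt < 0))
    stop("scission precedes AP2 onset for event(s): ",
         paste(head(annotations$event_id[lt < 0], 5L), collapse = ", "))
  setNames(lt, annotations$event_id)
}

#' @rdname eventLifetime
#' @export
assemblyDuration <- function(annotations) {
  ann <- annotations[annotations$arpc3_class != "negative", , drop = FALSE]
  dur <- ann$t_scission - ann$arpc3_onset_t
  if (any(is.finite(dur) & dur < 0))
    stop("negative assembly duration for event(s): ",
         paste(head(ann$event_id[dur < 0], 5L), collapse = ", "))
  setNames(dur, ann$event_id)
}

.alignedTraces <- function(events, annotations, channel) {
  df <- trackData(events)
  df <- df[df$channel == channel, , drop = FALSE]
  m <- match(df$event_id, annotations$event_id)
  keep <- !is.na(m)
  df <- df[keep, , drop = FALSE]
  m <- m[keep]
  df$tau <- round((df$t - annotations$t_scission[m]) /
                    frameInterval(events)) * frameInterval(events)
  df
}

.alignedThird <- function(third, annotations, dt) {
  ann <- annotations[!is.na(annotations$third_id), , drop = FALSE]
  if (!nrow(ann)) return(NULL)
  td <- trackData(third)
  td <- td[td$event_id %in% ann$third_id, , drop = FALSE]
  m <- match(td$event_id, ann$third_id)
  td$tau <- round((td$t - ann$t_scission[m]) / dt) * dt
  td$event_id <- ann$event_id[m]   # re-key by the linked CME event
  td
}

#' Cohort-averaged intensity traces aligned at scission
#'
#' Events are grouped into cohorts by lifetime and aligned to the frame of
#' maximum DNM2 intensity (time = 0 s). Per cohort, channel and aligned
#' frame, the mean and SD of intensity are computed over the events that
#' possess that frame; the plotted error band is SD/4. Cohort percentages
#' are relative to the events retained in any cohort. With
#' `normalize = TRUE` each cohort/channel mean trace is scaled to 1 at its
#' peak.
#'
#' @param events a [TrackSet-class].
#' @param annotations annotation data.frame with `t_scission` and `lifetime`.
#' @param edges cohort bin edges in seconds (left-closed), default
#'   `c(10, 20, 40, 60, 120)`.
#' @param channels event channels to average.
#' @param third,links optional third-channel TrackSet plus link table; linked
#'   tracks are averaged as channel `"ARPC3"` on the same aligned axis.
#' @param normalize scale each mean trace to 1 at its peak.
#' @return list of class `"CohortSummary"`: `summary` (cohort, channel, tau,
#'   mean, sd, band, n), `cohorts` (cohort, n, percent), `edges`.
#' @export
cohortAverage <- function(events, annotations, edges = c(10, 20, 40, 60, 120),
                          channels = c("AP2", "DNM2"), third = NULL,
                          links = NULL, normalize = FALSE) {
  stopifnot(is(events, "TrackSet"), length(edges) >= 2L)
  dt <- frameInterval(events)
  ann <- annotations
  ann$cohort <- cut(ann$lifetime, edges, right = FALSE)
  dropped <- sum(is.na(ann$cohort))
  ann <- ann[!is.na(ann$cohort), , drop = FALSE]
  if (!nrow(ann)) stop("no events fall inside the cohort edges")
  empty <- setdiff(levels(ann$cohort), unique(as.character(ann$cohort)))
  if (length(empty))
    warning("empty cohort(s) dropped: ", paste(empty, collapse = ", "))
  pieces <- lapply(channels, function(ch) {
    df <- .alignedTraces(events, ann, ch)
    df$channel <- ch
    df
  })
  if (!is.null(third)) {
    ann2 <- ann
    if (!is.null(links) && !"third_id" %in% names(ann2)) {
      mm <- match(ann2$event_id, links$event_id)
      ann2$third_id <- links$track_id[mm]
    }
    tdf <- .alignedThird(third, ann2, dt)
    if (!is.null(tdf) && nrow(tdf)) {
      tdf$channel <- "ARPC3"
      pieces <- c(pieces, list(tdf))
    }
  }
  df <- do.call(rbind, lapply(pieces, function(p)
    p[c("event_id", "channel", "tau", "amplitude", "amplitude_present")]))
  df$cohort <- ann$cohort[match(df$event_id, ann$event_id)]
  df <- df[df$amplitude_present, , drop = FALSE]
  agg <- aggregate(df$amplitude,
                   by = list(cohort = df$cohort, channel = df$channel,
                             tau = df$tau),
                   FUN = function(v) c(mean(v), if (length(v) > 1L) sd(v)
                                       else 0, length(v)))
  out <- data.frame(cohort = agg$cohort, channel = agg$channel,
                    tau = agg$tau, mean = agg$x[, 1L], sd = agg$x[, 2L],
                    n = as.integer(agg$x[, 3L]))
  out$band <- out$sd / 4
  out <- out[order(out$cohort, out$channel, out$tau), , drop = FALSE]
  rownames(out) <- NULL
  if (normalize) {
    key <- paste(out$cohort, out$channel)
    peak <- tapply(out$mean, key, max)
    sc <- as.numeric(peak[key])
    sc[sc == 0] <- 1
    out$mean <- out$mean / sc
    out$sd <- out$sd / sc
    out$band <- out$band / sc
  }
  tab <- table(ann$cohort)
  tab <- tab[tab > 0]
  cohorts <- data.frame(cohort = names(tab), n = as.integer(tab),
                        percent = 100 * as.integer(tab) / nrow(ann))
  structure(list(summary = out, cohorts = cohorts, edges = edges,
                 n_dropped = dropped),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("CohortSummary:", nrow(x$cohorts), "cohort(s) over edges [",
      paste(x$edges, collapse = ", "), ") s;",
      sum(x$cohorts$n), "events\n")
  print(x$cohorts, row.names = FALSE)
  invisible(x)
}

#' Inter-channel center separation around scission
#'
#' Per event and aligned frame within `window` (seconds relative to
#' scission), the Euclidean distance between the fitted centers of two
#' channels, computed over frames where both are significant. Distances are
#' invariant to rotation and translation of the field.
#'
#' @param events a [TrackSet-class].
#' @param annotations annotation data.frame with `t_scission`.
#' @param chA,chB channel names; `chB = "ARPC3"` draws positions from the
#'   linked third-channel track (requires `third`; `third_id` column or
#'   `links`).
#' @param window aligned-time window in seconds, default `c(-10, 3)`.
#' @param third,links see [cohortAverage()].
#' @return data.frame `event_id`, `tau`, `distance` (nm). Scission-frame
#'   separations are the `tau == 0` rows.
#' @export
interchannelDistance <- function(events, annotations, chA = "AP2",
                                 chB = "DNM2", window = c(-10, 3),
                                 third = NULL, links = NULL) {
  dt <- frameInterval(events)
  ann <- annotations
  if (!is.null(links) && !"third_id" %in% names(ann)) {
    mm <- match(ann$event_id, links$event_id)
    ann$third_id <- links$track_id[mm]
  }
  a <- .alignedTraces(events, ann, chA)
  b <- if (!is.null(third) && !chB %in% channelNames(events))
    .alignedThird(third, ann, dt)
  else .alignedTraces(events, ann, chB)
  if (is.null(b) || !nrow(b))
    return(data.frame(event_id = character(0), tau = numeric(0),
                      distance = numeric(0)))
  a <- a[a$amplitude_present & a$tau >= window[1L] & a$tau <= window[2L], ]
  b <- b[b$amplitude_present & b$tau >= window[1L] & b$tau <= window[2L], ]
  key <- function(df) paste(df$event_id, df$tau)
  m <- match(key(a), key(b))
  ok <- !is.na(m)
  out <- data.frame(event_id = a$event_id[ok], tau = a$tau[ok],
                    distance = sqrt((a$x[ok] - b$x[m[ok]])^2 +
                                    (a$y[ok] - b$y[m[ok]])^2))
  out[order(out$event_id, out$tau), , drop = FALSE]
}

#' Lateral motility before or after scission
#'
#' Mean frame-to-frame AP2 displacement over a window of frames strictly
#' before or after the scission frame.
#'
#' @param events a [TrackSet-class].
#' @param annotations annotation data.frame with `t_scission`.
#' @param side `"before"` or `"after"` scission.
#' @param windowFrames window length in frames, default 10.
#' @return named numeric vector of nm/frame; events with fewer than 2 frames
#'   on the requested side are `NA` (reported in attribute `"insufficient"`).
#' @export
lateralMotility <- function(events, annotations, side = c("before", "after"),
                            windowFrames = 10L) {
  side <- match.arg(side)
  df <- .alignedTraces(events, annotations, "AP2")
  df <- df[df$amplitude_present, , drop = FALSE]
  dt <- frameInterval(events)
  w <- windowFrames * dt
  df <- if (side == "before")
    df[df$tau >= -w & df$tau <= 0, , drop = FALSE]
  else df[df$tau >= 0 & df$tau <= w, , drop = FALSE]
  out <- setNames(rep(NA_real_, nrow(annotations)), annotations$event_id)
  sp <- split(df[order(df$event_id, df$tau), c("event_id", "x", "y")],
              df$event_id[order(df$event_id, df$tau)])
  for (id in names(sp)) {
    xy <- as.matrix(sp[[id]][c("x", "y")])
    if (nrow(xy) >= 2L)
      out[id] <- mean(sqrt(rowSums(diff(xy)^2)))
  }
  structure(out, insufficient = names(out)[is.na(out)])
}

#' Trajectory straightness index
#'
#' Ratio comparing the end-to-end displacement of a trajectory to its total
#' path length. The default convention is end-to-end / path length, which
#' lies in (0, 1], equals 1 exactly for a straight, monotone path, and
#' increases for straighter trajectories; `convention = "path_over_net"`
#' returns the literal path / end-to-end ratio instead. A zero-length path
#' (stationary trajectory) is imputed as 1.
#'
#' @param xy numeric matrix of positions (one row per frame, columns x, y).
#' @param convention `"net_over_path"` (default) or `"path_over_net"`.
#' @return dimensionless straightness index.
#' @export
straightnessIndex <- function(xy, convention = c("net_over_path",
                                                 "path_over_net")) {
  convention <- match.arg(convention)
  xy <- as.matrix(xy)
  if (nrow(xy) < 2L) stop("a trajectory needs at least 2 positions")
  path <- sum(sqrt(rowSums(diff(xy)^2)))
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1L, ])^2))
  if (path == 0) return(1)
  if (convention == "net_over_path") net / path
  else { if (net == 0) Inf else path / net }
}

#' Fraction of events whose actin separation exceeds their own motility
#'
#' For each ARPC3-positive event, compares the AP2-ARPC3 separation at the
#' scission frame with that event's mean pre-scission frame-to-frame AP2
#' step; returns the fraction of events where the separation is larger
#' (the check that channel separations are not an artifact of puncta
#' movement between sequential channel acquisitions).
#'
#' @param events a [TrackSet-class].
#' @param annotations classified annotations ([classifyTiming()]).
#' @param third third-channel [TrackSet-class].
#' @param windowFrames motility window in frames, default 10.
#' @return list with `fraction`, `n`, and the per-event table (`detail`).
#' @export
separationExceedsMotility <- function(events, annotations, third,
                                      windowFrames = 10L) {
  ann <- annotations[annotations$arpc3_class != "negative" &
                       !is.na(annotations$third_id), , drop = FALSE]
  if (!nrow(ann))
    return(list(fraction = NA_real_, n = 0L,
                detail = data.frame(event_id = character(0))))
  d <- interchannelDistance(events, ann, chA = "AP2", chB = "ARPC3",
                            window = c(0, 0), third = third)
  mot <- lateralMotility(events, ann, side = "before",
                         windowFrames = windowFrames)
  m <- match(ann$event_id, d$event_id)
  detail <- data.frame(event_id = ann$event_id,
                       separation = d$distance[m],
                       motility = as.numeric(mot[ann$event_id]))
  ok <- complete.cases(detail)
  list(fraction = mean(detail$separation[ok] > detail$motility[ok]),
       n = sum(ok), detail = detail)
}

#' Two-group comparison by Welch's t or Kolmogorov-Smirnov test
#'
#' @param a,b numeric value vectors (each with at least 2 values).
#' @param test `"welch"` (two-sided Welch's t-test) or `"ks"` (two-sample,
#'   two-sided Kolmogorov-Smirnov test).
#' @return list with `statistic`, `p.value` and `test`.
#' @export
compareGroups <- function(a, b, test = c("welch", "ks")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (test == "welch") {
    if (sd(a) == 0 && sd(b) == 0)
      stop("degenerate variance in both groups; Welch's t-test undefined")
    ht <- t.test(a, b, var.equal = FALSE)
  } else {
    ht <- suppressWarnings(ks.test(a, b))
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value, test = test)
}
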