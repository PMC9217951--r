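#' @include utils.R
NULL

.trackCols <- c("event_id", "channel", "frame", "t", "x", "y",
                "amplitude", "amplitude_present", "position_sd")

#' TrackSet: a collection of tracked fluorescence events
#'
#' One row per event, channel and frame. Channels of an event share the frame
#' grid: a frame where a channel had no significant detection is kept with
#' `amplitude_present = FALSE` and `amplitude = 0`, so traces stay aligned.
#' Times are seconds from movie start, positions continuous nanometres with
#' origin at the field corner, frames 0-based per event.
#'
#' @slot tracks data.frame with columns `event_id`, `channel`, `frame`, `t`,
#'   `x`, `y`, `amplitude`, `amplitude_present`, `position_sd`.
#' @slot frameInterval frame spacing in seconds (constant across the set).
#'
#' @exportClass TrackSet
setClass("TrackSet",
         representation(tracks = "data.frame", frameInterval = "numeric"))

setValidity("TrackSet", function(object) {
  df <- object@tracks
  dt <- object@frameInterval
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    return("frameInterval must be a single positive number")
  miss <- setdiff(.trackCols, names(df))
  if (length(miss))
    return(paste("missing track columns:", paste(miss, collapse = ", ")))
  if (!nrow(df)) return(TRUE)
  if (!is.logical(df$amplitude_present))
    return("amplitude_present must be logical")
  key <- paste(df$event_id, df$channel, sep = "\001")
  same <- key[-1L] == key[-nrow(df)]
  if (any(same)) {
    ddt <- diff(df$t)[same]
    dfr <- diff(df$frame)[same]
    bad <- abs(ddt - dt) > 1e-6 * max(1, dt) | dfr != 1L
    if (any(bad)) {
      ev <- unique(df$event_id[-1L][same][bad])
      return(paste0("non-uniform frame spacing (expected ", dt,
                    " s) in event(s): ",
                    paste(head(ev, 5L), collapse = ", ")))
    }
  }
  pres <- df$amplitude_present
  if (any(pres & (!is.finite(df$x) | !is.finite(df$y)))) {
    ev <- unique(df$event_id[pres & (!is.finite(df$x) | !is.finite(df$y))])
    return(paste0("non-finite positions at significant frames in event(s): ",
                  paste(head(ev, 5L), collapse = ", ")))
  }
  # channels of one event must share the frame grid
  sig <- aggregate(df$frame,
                   by = list(event = df$event_id, channel = df$channel),
                   FUN = function(f) c(min(f), max(f), length(f)))
  span <- paste(sig$x[, 1L], sig$x[, 2L], sig$x[, 3L])
  nspan <- tapply(span, sig$event, function(s) length(unique(s)))
  if (any(nspan > 1L))
    return(paste0("channels do not share a frame grid in event(s): ",
                  paste(head(names(nspan)[nspan > 1L], 5L), collapse = ", ")))
  TRUE
})

#' Construct a TrackSet
#'
#' Rows are sorted by event, channel and frame; validity (uniform spacing,
#' shared channel grids, finite positions at significant frames) is enforced.
#'
#' @param tracks data.frame in the long track-table layout (see
#'   [TrackSet-class]).
#' @param frameInterval frame spacing in seconds.
#' @return a `TrackSet`.
#' @export
TrackSet <- function(tracks, frameInterval) {
  tracks <- as.data.frame(tracks)
  miss <- setdiff(.trackCols, names(tracks))
  if (length(miss))
    stop("missing track columns: ", paste(miss, collapse = ", "))
  tracks <- tracks[.trackCols]
  tracks$event_id <- as.character(tracks$event_id)
  tracks$channel <- as.character(tracks$channel)
  tracks$frame <- as.integer(tracks$frame)
  tracks$amplitude_present <- as.logical(tracks$amplitude_present)
  ord <- order(tracks$event_id, tracks$channel, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  rownames(tracks) <- NULL
  new("TrackSet", tracks = tracks, frameInterval = as.numeric(frameInterval))
}

#' LocalizationSet: single-molecule localizations for one channel in one ROI
#'
#' @slot points numeric matrix, one localization per row, columns x, y (and
#'   optionally z), in nanometres.
#' @slot channelLabel channel name.
#' @slot roiId region-of-interest identifier.
#' @exportClass LocalizationSet
setClass("LocalizationSet",
         representation(points = "matrix", channelLabel = "character",
                        roiId = "character"))

setValidity("LocalizationSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || nrow(p) < 1L) return("points must be a non-empty numeric matrix")
  if (!ncol(p) %in% c(2L, 3L)) return("points must have 2 (x,y) or 3 (x,y,z) columns")
  if (any(!is.finite(p))) return("all coordinates must be finite")
  TRUE
})

#' Construct a LocalizationSet
#'
#' @param points numeric matrix or data.frame of localization coordinates in
#'   nm (columns x, y and optionally z).
#' @param channelLabel,roiId identifying labels.
#' @return a `LocalizationSet`.
#' @export
LocalizationSet <- function(points, channelLabel = "ch", roiId = "roi") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  new("LocalizationSet", points = points,
      channelLabel = as.character(channelLabel), roiId = as.character(roiId))
}

#' PeakParams: a peak-defining parameter combination
#'
#' `minHeight` is the required peak height above the trace baseline, either in
#' units of the trace's robust noise SD (`heightUnits = "noise_sd"`, the
#' survey default) or in raw amplitude units. `minWidth` is the minimum full
#' width at half prominence and `minDistance` the minimum peak-to-peak
#' temporal separation, both in seconds. After a survey, `sigmaHat` and `gof`
#' hold the Rayleigh scale fitted to the single-peak lifetimes and its
#' one-sample Kolmogorov-Smirnov statistic.
#'
#' @slot minHeight,minWidth,minDistance numeric peak-defining parameters.
#' @slot sigmaHat fitted Rayleigh scale (seconds) or NA.
#' @slot gof KS goodness-of-fit statistic in \[0,1\] or NA.
#' @slot heightUnits `"noise_sd"` or `"absolute"`.
#' @exportClass PeakParams
setClass("PeakParams",
         representation(minHeight = "numeric", minWidth = "numeric",
                        minDistance = "numeric", sigmaHat = "numeric",
                        gof = "numeric", heightUnits = "character"))

setValidity("PeakParams", function(object) {
  if (object@minHeight <= 0 || object@minWidth <= 0 || object@minDistance <= 0)
    return("minHeight, minWidth and minDistance must all be positive")
  if (!is.na(object@gof) && (object@gof < 0 || object@gof > 1))
    return("gof must lie in [0, 1]")
  if (!object@heightUnits %in% c("noise_sd", "absolute"))
    return("heightUnits must be 'noise_sd' or 'absolute'")
  TRUE
})

#' Construct a PeakParams object
#'
#' @param minHeight,minWidth,minDistance positive peak-defining parameters
#'   (see [PeakParams-class]).
#' @param sigmaHat,gof optional Rayleigh fit results attached by
#'   [selectPeakParameters()].
#' @param heightUnits `"noise_sd"` (default) or `"absolute"`.
#' @return a `PeakParams`.
#' @export
peakParams <- function(minHeight, minWidth, minDistance,
                       sigmaHat = NA_real_, gof = NA_real_,
                       heightUnits = c("noise_sd", "absolute")) {
  heightUnits <- match.arg(heightUnits)
  new("PeakParams", minHeight = as.numeric(minHeight),
      minWidth = as.numeric(minWidth), minDistance = as.numeric(minDistance),
      sigmaHat = as.numeric(sigmaHat), gof = as.numeric(gof),
      heightUnits = heightUnits)
}

#' ClusterModel: PCA basis plus fitted Gaussian mixture
#'
#' @slot K number of mixture components.
#' @slot modelName mclust covariance model name (full covariance, `"VVV"`).
#' @slot parameters mixture parameters in mclust layout (`pro`, `mean`,
#'   `variance`), sufficient to score new data.
#' @slot basis PCA projection basis: `center`, `rotation`, `nComponents`,
#'   `varianceExplained`.
#' @slot bicTable BIC values per candidate K.
#' @slot seed seed recorded at fit time.
#' @slot converged logical convergence flag.
#' @exportClass ClusterModel
setClass("ClusterModel",
         representation(K = "integer", modelName = "character",
                        parameters = "list", basis = "list",
                        bicTable = "matrix", seed = "integer",
                        converged = "logical"))

setValidity("ClusterModel", function(object) {
  pro <- object@parameters$pro
  if (is.null(pro) || abs(sum(pro) - 1) > 1e-9)
    return("mixture weights must sum to 1 within 1e-9")
  sig <- object@parameters$variance$sigma
  if (!is.null(sig)) {
    for (k in seq_len(dim(sig)[3L])) {
      ok <- tryCatch({ chol(sig[, , k]); TRUE }, error = function(e) FALSE)
      if (!ok) return(paste0("covariance of component ", k,
                             " is not positive-definite"))
    }
  }
  TRUE
})

# ---- generics ----------------------------------------------------------

#' @rdname TrackSet-class
#' @param x,object a TrackSet (or, for `nClusters`, a ClusterModel).
#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))

#' @rdname TrackSet-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname TrackSet-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' @rdname TrackSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TrackSet-class
#' @param id an event identifier.
#' @export
setGeneric("getEvent", function(x, id) standardGeneric("getEvent"))

#' @rdname ClusterModel-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

setMethod("eventIds", "TrackSet", function(x) unique(x@tracks$event_id))
setMethod("nEvents", "TrackSet", function(x) length(unique(x@tracks$event_id)))
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)
setMethod("trackData", "TrackSet", function(x) x@tracks)
setMethod("channelNames", "TrackSet", function(x) sort(unique(x@tracks$channel)))
setMethod("getEvent", "TrackSet", function(x, id) {
  df <- x@tracks[x@tracks$event_id == id, , drop = FALSE]
  if (!nrow(df)) stop("unknown event_id: ", id)
  rownames(df) <- NULL
  df
})

#' Subset a TrackSet by event identifiers
#'
#' @param x a TrackSet.
#' @param ids character vector of event ids to keep.
#' @return a TrackSet restricted to `ids`.
#' @export
subsetEvents <- function(x, ids) {
  stopifnot(is(x, "TrackSet"))
  TrackSet(x@tracks[x@tracks$event_id %in% ids, , drop = FALSE],
           x@frameInterval)
}

setMethod("nClusters", "ClusterModel", function(x) x@K)

setMethod("show", "TrackSet", function(object) {
  df <- object@tracks
  cat("TrackSet with", length(unique(df$event_id)), "events,",
      length(unique(df$channel)), "channel(s) [",
      paste(sort(unique(df$channel)), collapse = ", "),
      "],", nrow(df), "rows; frame interval",
      object@frameInterval, "s\n")
})

setMethod("show", "LocalizationSet", function(object) {
  cat("LocalizationSet '", object@channelLabel, "' (roi ", object@roiId,
      "): ", nrow(object@points), " localizations in ",
      ncol(object@points), "D\n", sep = "")
})

setMethod("show", "PeakParams", function(object) {
  cat("PeakParams: minHeight ", object@minHeight, " (", object@heightUnits,
      "), minWidth ", object@minWidth, " s, minDistance ",
      object@minDistance, " s", sep = "")
  if (!is.na(object@gof))
    cat("; Rayleigh sigma ", signif(object@sigmaHat, 4), " s, KS gof ",
        signif(object@gof, 3), sep = "")
  cat("\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: ", object@K, " components (", object@modelName,
      "), ", object@basis$nComponents, " principal components (",
      round(100 * object@basis$varianceExplained, 1),
      "% variance), converged: ", object@converged, "\n", sep = "")
})
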