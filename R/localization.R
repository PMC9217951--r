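# Fixed-cell analysis: centroid distances between two-channel
# single-molecule localization clouds, and bead-based channel registration.
# Distances are computed in 2-D (xy), matching how the localization centroids
# are defined; centroid operations are exactly linear.

#' Centroid of a localization cloud
#'
#' Arithmetic mean of the xy positions.
#'
#' @param locs a [LocalizationSet-class] (a plain matrix of positions is
#'   also accepted).
#' @return numeric length-2 centroid (x, y), nm.
#' @export
centroid <- function(locs) {
  p <- if (is(locs, "LocalizationSet")) locs@points else as.matrix(locs)
  if (!nrow(p)) stop("cannot take the centroid of an empty localization set")
  colMeans(p[, 1:2, drop = FALSE])
}

#' Distance between the centroids of two localization clouds
#'
#' @param a,b [LocalizationSet-class] objects (or position matrices) for the
#'   two channels of one ROI.
#' @return Euclidean centroid distance, nm (symmetric in its arguments).
#' @export
centroidDistance <- function(a, b) {
  sqrt(sum((centroid(a) - centroid(b))^2))
}

#' Batch centroid distances over paired ROIs
#'
#' @param pairs list of `list(a = , b = )` localization-set pairs (one per
#'   ROI).
#' @return list with `table` (roi_id, centroid coordinates, distance,
#'   localization counts) and `histogram` (mean and SD of the distances).
#' @export
centroidDistanceTable <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    ca <- centroid(p$a); cb <- centroid(p$b)
    data.frame(roi_id = p$a@roiId, ax = ca[1L], ay = ca[2L],
               bx = cb[1L], by = cb[2L],
               distance = sqrt(sum((ca - cb)^2)),
               n_a = nrow(p$a@points), n_b = nrow(p$b@points),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab,
       histogram = list(mean = mean(tab$distance),
                        sd = if (nrow(tab) > 1L) sd(tab$distance) else 0,
                        n = nrow(tab)))
}

#' Estimate the inter-channel translation from matched beads
#'
#' The registration offset between two imaging channels is the mean pairwise
#' displacement of matched fluorescent-bead positions; only a translation is
#' estimated (sufficient to check that chromatic shifts are small relative
#' to the measured protein separations). Applying the correction to data is
#' an explicit, separate transform.
#'
#' @param beadsA,beadsB matched numeric matrices of bead positions (same
#'   number of rows, >= 3; columns x, y, nm).
#' @return list with `translation` (B minus A, nm), `residuals` (per-bead
#'   displacement minus the translation) and `rmse`.
#' @export
estimateChannelOffset <- function(beadsA, beadsB) {
  a <- as.matrix(beadsA); b <- as.matrix(beadsB)
  if (nrow(a) != nrow(b))
    stop("bead lists must be matched (got ", nrow(a), " vs ", nrow(b), ")")
  if (nrow(a) < 3L) stop("at least 3 matched beads are required")
  disp <- b[, 1:2, drop = FALSE] - a[, 1:2, drop = FALSE]
  tr <- colMeans(disp)
  resid <- sweep(disp, 2L, tr)
  list(translation = tr, residuals = resid,
       rmse = sqrt(mean(rowSums(resid^2))))
}

#' Apply a channel-registration translation to a TrackSet
#'
#' @param x a [TrackSet-class].
#' @param translation numeric length-2 offset (nm) to subtract from the
#'   positions of `channel`.
#' @param channel the channel to correct.
#' @return the corrected TrackSet; the applied transform is recorded in a
#'   message.
#' @export
applyChannelOffset <- function(x, translation, channel) {
  stopifnot(is(x, "TrackSet"), length(translation) == 2L)
  df <- trackData(x)
  sel <- df$channel == channel
  df$x[sel] <- df$x[sel] - translation[1L]
  df$y[sel] <- df$y[sel] - translation[2L]
  message("applied channel-offset correction (", signif(translation[1L], 4),
          ", ", signif(translation[2L], 4), ") nm to channel ", channel)
  TrackSet(df, frameInterval(x))
}
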