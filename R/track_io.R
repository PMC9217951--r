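# Plain-text track and localization tables. The track table is a versioned,
# tab-delimited long format (one row per event-frame-channel) chosen for
# diff-ability; a converter from a tracking front end's native output is the
# extension point and is deliberately not implemented here.

.trackFormatVersion <- "1"

#' Write a TrackSet to a delimited track table
#'
#' The header documents the format version, coordinate units, pixel size and
#' frame interval; rows are emitted in deterministic (event, channel, frame)
#' order. An empty TrackSet produces a valid header-only file.
#'
#' @param x a [TrackSet-class].
#' @param path output file path.
#' @param pixelSize pixel size recorded in the header, nm.
#' @return invisibly, `path`.
#' @export
writeTracks <- function(x, path, pixelSize = 108) {
  stopifnot(is(x, "TrackSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# cmetracks track table v", .trackFormatVersion),
    "# units: nm",
    paste0("# pixel_size_nm: ", format(pixelSize, digits = 12)),
    paste0("# frame_interval_s: ", format(x@frameInterval, digits = 12)),
    paste(.trackCols, collapse = "\t")), con)
  df <- x@tracks
  if (nrow(df)) {
    num <- vapply(df, is.numeric, logical(1L))
    out <- df
    out[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    out$frame <- as.character(df$frame)
    out$amplitude_present <- ifelse(df$amplitude_present, "TRUE", "FALSE")
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

.parseHeader <- function(path, n = 10L) {
  lines <- readLines(path, n = n)
  hdr <- lines[startsWith(lines, "#")]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.+)$", h))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- m[3L]
  }
  kv
}

#' Read a track table into a TrackSet
#'
#' Enforces the TrackSet invariants (uniform frame spacing, shared channel
#' grids, finite positions at significant frames) and resolves units to nm:
#' pixel-unit files are rescaled by the header's `pixel_size_nm`.
#'
#' @param path file written by [writeTracks()] (or in the same layout).
#' @return a [TrackSet-class].
#' @export
readTracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  kv <- .parseHeader(path)
  units <- kv[["units"]]
  if (is.null(units)) stop("track table header lacks a 'units:' line")
  if (!units %in% c("nm", "pixel"))
    stop("unknown units '", units, "' (expected 'nm' or 'pixel')")
  dtv <- kv[["frame_interval_s"]]
  if (is.null(dtv)) stop("track table header lacks 'frame_interval_s:'")
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   stringsAsFactors = FALSE)
  miss <- setdiff(.trackCols, names(df))
  if (length(miss))
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  if (units == "pixel") {
    px <- as.numeric(kv[["pixel_size_nm"]])
    if (!is.finite(px) || px <= 0)
      stop("pixel-unit track table requires a positive 'pixel_size_nm' header")
    df$x <- df$x * px
    df$y <- df$y * px
    df$position_sd <- df$position_sd * px
  }
  TrackSet(df, as.numeric(dtv))
}

#' Write / read localization tables
#'
#' Localization tables are tab-delimited with columns `x`, `y`, `z`,
#' `channel`, `roi` (coordinates in nm; `z` may be 0 for 2-D data).
#'
#' @param sets list of [LocalizationSet-class] objects.
#' @param path file path.
#' @return `writeLocalizations` invisibly returns `path`;
#'   `readLocalizations` returns a list of `LocalizationSet`, one per
#'   (roi, channel) combination, named `"roi/channel"`.
#' @export
writeLocalizations <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    p <- s@points
    data.frame(x = p[, 1L], y = p[, 2L],
               z = if (ncol(p) == 3L) p[, 3L] else 0,
               channel = s@channelLabel, roi = s@roiId,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cmetracks localization table v1", "# units: nm",
               paste(c("x", "y", "z", "channel", "roi"), collapse = "\t")),
             con)
  num <- c("x", "y", "z")
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   stringsAsFactors = FALSE)
  miss <- setdiff(c("x", "y", "z", "channel", "roi"), names(df))
  if (length(miss))
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "))
  keys <- unique(df[c("roi", "channel")])
  out <- vector("list", nrow(keys))
  names(out) <- paste(keys$roi, keys$channel, sep = "/")
  for (k in seq_len(nrow(keys))) {
    sub <- df[df$roi == keys$roi[k] & df$channel == keys$channel[k], ,
              drop = FALSE]
    pts <- as.matrix(sub[c("x", "y", "z")])
    if (all(pts[, 3L] == 0)) pts <- pts[, 1:2, drop = FALSE]
    out[[k]] <- LocalizationSet(pts, keys$channel[k], keys$roi[k])
  }
  out
}
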