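#' Tile a genome into fixed-width windows
#'
#' Windows tile each contig from coordinate 0 in steps of `window_bp`; the
#' final partial window is kept as-is (not length-normalized) and flagged
#' in the `partial` column so callers can exclude it if they wish.
#'
#' @param genome a [genome] object.
#' @param window_bp window width in bp (>= 1).
#' @return data.frame with columns `contig`, `start`, `end`, `partial`.
#' @export
tile_windows <- function(genome, window_bp = 1000L) {
  stopifnot(inherits(genome, "genome"), window_bp >= 1L)
  window_bp <- as.integer(window_bp)
  pieces <- lapply(names(genome$lengths), function(ctg) {
    L <- genome$lengths[[ctg]]
    starts <- seq.int(0L, L - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, L)
    data.frame(contig = ctg, start = starts, end = ends,
               partial = ends - starts < window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Construct a window track
#'
#' A window track is a set of genomic windows with one numeric value each
#' and a `value_kind` attribute recording what the values mean
#' (`"raw_count"`, `"normalized_enrichment"`, or
#' `"weighted_methylation_percent"`).
#'
#' @param windows data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `partial`.
#' @param values numeric vector, one value per window.
#' @param value_kind character scalar describing the values.
#' @return data.frame of class `window_track` with a `value` column and a
#'   `value_kind` attribute.
#' @export
window_track <- function(windows, values, value_kind) {
  stopifnot(nrow(windows) == length(values))
  if (value_kind == "normalized_enrichment" &&
      any(values < 0, na.rm = TRUE)) {
    stop("normalized enrichment values must be >= 0")
  }
  out <- windows
  out$value <- as.numeric(values)
  attr(out, "value_kind") <- value_kind
  class(out) <- c("window_track", "data.frame")
  out
}

#' Value kind of a track
#'
#' @param track a `window_track`.
#' @return The `value_kind` attribute.
#' @export
value_kind <- function(track) attr(track, "value_kind")

#' Write a window track as bedGraph
#'
#' Output is 0-based half-open, one line per window, no header line, with
#' values rendered to 10 significant digits so that a write/read round trip
#' preserves them to float precision. Windows must be sorted by
#' `(contig, start)` and non-overlapping within a contig.
#'
#' @param track a `window_track` (or data.frame with `contig`, `start`,
#'   `end`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  if (nrow(track) > 0L) {
    by_ctg <- split(seq_len(nrow(track)), track$contig)
    for (idx in by_ctg) {
      if (is.unsorted(track$start[idx], strictly = TRUE) &&
          length(idx) > 1L) {
        stop("track windows are not sorted by start within contig ",
             track$contig[idx[1L]])
      }
      if (length(idx) > 1L &&
          any(track$start[idx][-1L] < track$end[idx][-length(idx)])) {
        stop("overlapping windows within contig ", track$contig[idx[1L]])
      }
    }
    lines <- sprintf("%s\t%d\t%d\t%.10g", track$contig, track$start,
                     track$end, track$value)
    writeLines(lines, path)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Read a bedGraph file as a window track
#'
#' @param path bedGraph file written by [write_track()] (or any headerless
#'   4-column bedGraph).
#' @param value_kind value kind to attach to the result.
#' @return A `window_track`.
#' @export
read_track <- function(path, value_kind = "raw_count") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  if (file.size(path) == 0L) {
    return(window_track(data.frame(contig = character(), start = integer(),
                                   end = integer(),
                                   stringsAsFactors = FALSE),
                        numeric(), value_kind))
  }
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  window_track(data.frame(contig = as.character(tab[[1L]]),
                          start = as.integer(tab[[2L]]),
                          end = as.integer(tab[[3L]]),
                          stringsAsFactors = FALSE),
               as.numeric(tab[[4L]]), value_kind)
}
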