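#' Read a BED file of labelled intervals
#'
#' Intervals (methylated domains, DMRs, arbitrary regions) are BED rows in
#' 0-based half-open coordinates with an optional label in column 4.
#'
#' @param path BED file (>= 3 columns).
#' @param genome optional [genome] for validation.
#' @return data.frame with columns `contig`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
  out <- data.frame(contig = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]),
                    label = if (ncol(tab) >= 4L) as.character(tab[[4L]])
                            else ".",
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    stop("interval with start >= end at line ",
         which(out$start >= out$end)[1L])
  }
  if (!is.null(genome)) {
    check_intervals(out$contig, out$start, out$end, genome, "interval")
  }
  out
}

#' Write labelled intervals to a BED file
#'
#' @param intervals data.frame with `contig`, `start`, `end` and
#'   optionally `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  label <- if (!is.null(intervals$label)) intervals$label
           else if (!is.null(intervals$direction)) intervals$direction
           else "."
  out <- data.frame(intervals$contig, intervals$start, intervals$end,
                    label)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
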