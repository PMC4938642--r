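#' Read aligned fragments from BED6 or BEDPE
#'
#' Fragments are the unit of ChIP-seq and MNase-seq coverage: intervals in
#' 0-based half-open coordinates with a strand, whose length `end - start`
#' is the sequencing insert size. BED rows map directly to fragments; BEDPE
#' mate pairs are collapsed to a single fragment spanning the outermost
#' coordinates of the two mates, taking the strand of the first mate.
#' Multiplicity is preserved: no implicit deduplication happens on read
#' (see [deduplicate()]).
#'
#' @param path BED (>= 3 columns) or BEDPE (>= 10 columns) file.
#' @param genome optional [genome]; when supplied, fragments are validated
#'   against contig names and bounds.
#' @param format `"auto"` (detect by column count), `"bed"` or `"bedpe"`.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`.
#' @export
read_fragments <- function(path, genome = NULL,
                           format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = FALSE,
                           data.table = FALSE)
  if (nrow(tab) == 0L) {
    frags <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    return(frags)
  }
  if (format == "auto") {
    format <- if (ncol(tab) >= 10L && is.character(tab[[4L]])) "bedpe"
              else "bed"
  }
  if (format == "bed") {
    if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
    strand <- if (ncol(tab) >= 6L) as.character(tab[[6L]]) else "+"
    strand[!(strand %in% c("+", "-"))] <- "+"
    frags <- data.frame(contig = as.character(tab[[1L]]),
                        start = as.integer(tab[[2L]]),
                        end = as.integer(tab[[3L]]),
                        strand = strand, stringsAsFactors = FALSE)
  } else {
    if (ncol(tab) < 6L) stop("BEDPE file needs >= 6 columns: ", path)
    if (!all(tab[[1L]] == tab[[4L]])) {
      stop("BEDPE mates on different contigs at line ",
           which(tab[[1L]] != tab[[4L]])[1L])
    }
    strand <- if (ncol(tab) >= 9L) as.character(tab[[9L]]) else "+"
    strand[!(strand %in% c("+", "-"))] <- "+"
    frags <- data.frame(contig = as.character(tab[[1L]]),
                        start = pmin(as.integer(tab[[2L]]),
                                     as.integer(tab[[5L]])),
                        end = pmax(as.integer(tab[[3L]]),
                                   as.integer(tab[[6L]])),
                        strand = strand, stringsAsFactors = FALSE)
  }
  validate_fragments(frags, genome)
  frags
}

validate_fragments <- function(frags, genome = NULL) {
  if (any(is.na(frags$start)) || any(is.na(frags$end))) {
    stop("fragment with missing coordinates at row ",
         which(is.na(frags$start) | is.na(frags$end))[1L])
  }
  if (any(frags$start >= frags$end)) {
    stop("fragment with start >= end at row ",
         which(frags$start >= frags$end)[1L])
  }
  if (!is.null(genome)) {
    check_intervals(frags$contig, frags$start, frags$end, genome, "fragment")
  }
  invisible(TRUE)
}

#' Write fragments to a BED6 file
#'
#' @param frags fragment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  out <- data.frame(frags$contig, frags$start, frags$end,
                    ".", 0L, frags$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
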