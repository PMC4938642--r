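#' Genome object
#'
#' A genome is an ordered set of named contigs with lengths, an optional
#' nucleotide sequence per contig, and a designated mitochondrial contig.
#' The nuclear/mitochondrial partition drives both ChIP-seq background
#' normalization (mitochondrial windows define the enrichment unit) and
#' bisulfite nonconversion estimation (mitochondrial DNA is fully
#' unmethylated in *Neurospora*), so the mitochondrial contig is named
#' explicitly rather than guessed from contig size.
#'
#' @param lengths named integer vector of contig lengths (bp), in order.
#' @param mito_name name of the mitochondrial contig; must match exactly one
#'   contig.
#' @param sequences optional [Biostrings::DNAStringSet] with one entry per
#'   contig, widths equal to `lengths`.
#' @return An object of class `genome`: a list with elements `lengths`
#'   (named integer vector), `mito_name`, and `sequences` (`DNAStringSet` or
#'   `NULL`).
#' @export
genome <- function(lengths, mito_name, sequences = NULL) {
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("contig lengths must be a named vector")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  lengths <- as.integer(lengths)
  names(lengths) <- nm
  if (any(lengths < 1L)) stop("all contig lengths must be >= 1")
  if (!is.character(mito_name) || length(mito_name) != 1L) {
    stop("mito_name must be a single contig name")
  }
  if (sum(nm == mito_name) != 1L) {
    stop("mitochondrial contig '", mito_name, "' not found in genome")
  }
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      sequences <- Biostrings::DNAStringSet(sequences)
    }
    if (length(sequences) != length(lengths) ||
        !identical(names(sequences), nm)) {
      stop("sequences must have one entry per contig, in the same order")
    }
    if (!all(Biostrings::width(sequences) == lengths)) {
      stop("sequence widths do not match declared contig lengths")
    }
  }
  structure(list(lengths = lengths, mito_name = mito_name,
                 sequences = sequences),
            class = "genome")
}

#' Read a genome from a FASTA file
#'
#' Contigs are kept in file order and sequences are retained. Record names
#' are taken up to the first whitespace, as aligners do.
#'
#' @param path path to a FASTA file.
#' @param mito_name name of the mitochondrial contig; must be present in the
#'   file.
#' @return A [genome] object with sequences.
#' @export
read_genome <- function(path, mito_name) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, "", 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  genome(stats::setNames(Biostrings::width(seqs), names(seqs)),
         mito_name = mito_name, sequences = seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome a [genome] object with sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome"))
  if (is.null(genome$sequences)) stop("genome has no sequences to write")
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

#' Contig lengths of a genome
#'
#' @param genome a [genome] object.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  genome$lengths
}

#' Names of the nuclear (non-mitochondrial) contigs
#'
#' @param genome a [genome] object.
#' @return Character vector of contig names.
#' @export
nuclear_contigs <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  setdiff(names(genome$lengths), genome$mito_name)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$lengths), "contigs,",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  cat("  mitochondrial contig:", x$mito_name,
      sprintf("(%s bp)\n", format(x$lengths[[x$mito_name]], big.mark = ",")))
  cat("  sequences:", if (is.null(x$sequences)) "absent" else "present", "\n")
  invisible(x)
}

# internal: check that intervals (0-based half-open) lie within the genome
check_intervals <- function(contig, start, end, genome, what = "interval") {
  bad <- !(contig %in% names(genome$lengths))
  if (any(bad)) {
    stop(what, " on unknown contig: ",
         paste(unique(contig[bad]), collapse = ", "))
  }
  len <- genome$lengths[contig]
  if (any(start < 0L) || any(end > len)) {
    stop(what, " outside contig bounds")
  }
  invisible(TRUE)
}
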