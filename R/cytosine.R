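#' Read a per-cytosine bisulfite report
#'
#' The report is a tab-separated table with header
#' `contig  pos  strand  m  n`: for every cytosine (on either strand),
#' `m` is the count of unconverted (methylated-appearing) reads and `n`
#' the total read count. Positions are 1-based in the file, mirroring
#' per-cytosine caller outputs, and are converted to 0-based on read.
#' Lines starting with `#` are ignored (config headers written by this
#' package).
#'
#' @param path report TSV.
#' @param genome optional [genome] for coordinate validation.
#' @return data.frame with columns `contig`, `pos` (0-based), `strand`,
#'   `m`, `n`.
#' @export
read_cytosine_report <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  head_lines <- readLines(path, n = 50L)
  n_skip <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  tab <- data.table::fread(path, sep = "\t", header = TRUE, skip = n_skip,
                           data.table = FALSE)
  need <- c("contig", "pos", "strand", "m", "n")
  if (!all(need %in% names(tab))) {
    stop("cytosine report must have columns: ", paste(need, collapse = ", "))
  }
  rep <- data.frame(contig = as.character(tab$contig),
                    pos = as.integer(tab$pos) - 1L,
                    strand = as.character(tab$strand),
                    m = as.integer(tab$m), n = as.integer(tab$n),
                    stringsAsFactors = FALSE)
  validate_cytosine_report(rep, genome)
  rep
}

validate_cytosine_report <- function(report, genome = NULL) {
  if (!all(report$strand %in% c("+", "-"))) {
    stop("cytosine strand must be '+' or '-'")
  }
  if (any(report$n < 0L) || any(report$m < 0L) || any(report$m > report$n)) {
    stop("cytosine counts must satisfy 0 <= m <= n")
  }
  key <- paste(report$contig, report$pos, report$strand)
  if (anyDuplicated(key)) {
    stop("duplicate cytosine site: ", key[duplicated(key)][1L])
  }
  if (!is.null(genome)) {
    check_intervals(report$contig, report$pos, report$pos + 1L, genome,
                    "cytosine site")
  }
  invisible(TRUE)
}

#' Write a per-cytosine bisulfite report
#'
#' Positions are written 1-based, matching [read_cytosine_report()].
#'
#' @param report cytosine report data.frame (0-based `pos`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  out <- data.frame(contig = report$contig, pos = report$pos + 1L,
                    strand = report$strand, m = report$m, n = report$n)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
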