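#' Remove duplicate fragments
#'
#' Fragments identical in `(contig, start, end)` are collapsed to one
#' representative; strand is deliberately ignored in the duplicate key
#' because a paired-end fragment's two reads share outer coordinates
#' (matching how duplicate marking treats pairs). Output is sorted by
#' `(contig, start, end)` and therefore deterministic; the operation is
#' idempotent.
#'
#' @param fragments fragment data.frame.
#' @return Deduplicated, sorted fragment data.frame.
#' @export
deduplicate <- function(fragments) {
  key <- paste(fragments$contig, fragments$start, fragments$end)
  out <- fragments[!duplicated(key), , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insert-size statistics of a fragment set
#'
#' Fragment length (`end - start`) is the sequencing insert size. Reports
#' the count, mean, sample standard deviation (n - 1 denominator) and an
#' integer-bin length histogram.
#'
#' @param fragments fragment data.frame with at least 2 fragments.
#' @return Object of class `insert_size_stats`: list with `n_fragments`,
#'   `mean_bp`, `sd_bp`, and `histogram` (data.frame `length`, `count`).
#' @export
insert_size_stats <- function(fragments) {
  if (nrow(fragments) < 2L) {
    stop("insert_size_stats requires at least 2 fragments")
  }
  len <- fragments$end - fragments$start
  tab <- table(len)
  structure(list(n_fragments = nrow(fragments),
                 mean_bp = mean(len), sd_bp = stats::sd(len),
                 histogram = data.frame(
                   length = as.integer(names(tab)),
                   count = as.integer(tab), row.names = NULL)),
            class = "insert_size_stats")
}

#' @export
print.insert_size_stats <- function(x, ...) {
  cat(sprintf("insert size: %.1f +/- %.1f bp (n = %d fragments)\n",
              x$mean_bp, x$sd_bp, x$n_fragments))
  invisible(x)
}

#' Nucleosome-edge metaplot from MNase fragments
#'
#' Builds a 5'-end per-base track and aggregates it over genes at the TSS
#' with [gene_metaplot()]; profile peaks mark the promoter-proximal edges
#' of positioned nucleosomes, and the trough upstream of the TSS marks the
#' nucleosome-free region. With `strand_mode = "match_gene"` (default),
#' plus-strand 5' ends are used for `+` strand genes and minus-strand 5'
#' ends for `-` strand genes, so after the metaplot orientation flip the
#' oriented 5' end always marks the left (promoter-proximal) nucleosome
#' edge regardless of gene orientation. `strand_mode = "plus_only"` uses
#' genome plus-strand ends for every gene.
#'
#' @param fragments fragment data.frame; a warning is issued when the set
#'   still contains duplicates (see [deduplicate()]).
#' @param genes gene data.frame.
#' @param genome a [genome].
#' @param grouping optional [assign_quintiles()] result.
#' @param flank_bp,bin_bp metaplot geometry (defaults 1000/10).
#' @param strand_mode `"match_gene"` or `"plus_only"`.
#' @return A metaplot data.frame as returned by [gene_metaplot()].
#' @export
edge_profile <- function(fragments, genes, genome, grouping = NULL,
                         flank_bp = 1000L, bin_bp = 10L,
                         strand_mode = c("match_gene", "plus_only")) {
  strand_mode <- match.arg(strand_mode)
  key <- paste(fragments$contig, fragments$start, fragments$end)
  if (anyDuplicated(key)) {
    warning("fragment set contains duplicates; ",
            "consider deduplicate() before profiling")
  }
  plus_track <- basewise_coverage(fragments, genome,
                                  mode = "five_prime_end",
                                  strand_filter = "plus_only")
  signal <- if (strand_mode == "plus_only") {
    plus_track
  } else {
    list("+" = plus_track,
         "-" = basewise_coverage(fragments, genome,
                                 mode = "five_prime_end",
                                 strand_filter = "minus_only"))
  }
  gene_metaplot(signal, genes, anchor = "TSS", flank_bp = flank_bp,
                bin_bp = bin_bp, grouping = grouping)
}
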