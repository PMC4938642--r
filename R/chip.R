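#' Windowed fragment coverage
#'
#' Counts fragments per fixed-width window tiling the genome. The default
#' `overlap` rule counts a fragment in every window it intersects by at
#' least 1 bp (BEDtools `coverage` semantics, so a fragment straddling a
#' window boundary is counted in both windows); `start_in_window` assigns
#' each fragment once, by its start coordinate, which conserves the total
#' count exactly.
#'
#' @param fragments fragment data.frame.
#' @param genome a [genome].
#' @param window_bp window width in bp (default 1000).
#' @param count_rule `"overlap"` or `"start_in_window"`.
#' @return A `window_track` with `value_kind = "raw_count"`; partial final
#'   windows are flagged in the `partial` column.
#' @export
window_counts <- function(fragments, genome, window_bp = 1000L,
                          count_rule = c("overlap", "start_in_window")) {
  count_rule <- match.arg(count_rule)
  validate_fragments(fragments, genome)
  windows <- tile_windows(genome, window_bp)
  counts <- numeric(nrow(windows))
  for (ctg in names(genome$lengths)) {
    widx <- which(windows$contig == ctg)
    fidx <- which(fragments$contig == ctg)
    if (!length(fidx)) next
    if (count_rule == "overlap") {
      wr <- IRanges::IRanges(windows$start[widx] + 1L, windows$end[widx])
      fr <- IRanges::IRanges(fragments$start[fidx] + 1L,
                             fragments$end[fidx])
      counts[widx] <- IRanges::countOverlaps(wr, fr)
    } else {
      bin <- fragments$start[fidx] %/% as.integer(window_bp) + 1L
      counts[widx] <- tabulate(bin, nbins = length(widx))
    }
  }
  window_track(windows, counts, "raw_count")
}

#' Normalize a raw-count track to the mitochondrial median
#'
#' Divides every window's raw count by the median count over
#' mitochondrial-contig windows, converting counts into enrichment over
#' background: mitochondrial DNA is not enriched by immunoprecipitation of
#' a nuclear protein, so its median coverage defines the "no enrichment"
#' unit and maps to 1.0. With an even number of mitochondrial windows the
#' median is the midpoint of the two central values.
#'
#' @param track a `window_track` of raw counts covering the whole genome
#'   (including the mitochondrial contig).
#' @param genome a [genome] identifying the mitochondrial contig.
#' @return A `window_track` with `value_kind = "normalized_enrichment"`;
#'   mitochondrial windows are retained in the output. The mitochondrial
#'   median is attached as attribute `mito_median`.
#' @export
mito_normalize <- function(track, genome) {
  stopifnot(inherits(genome, "genome"))
  if (!identical(value_kind(track), "raw_count")) {
    stop("mito_normalize expects a raw_count track")
  }
  mito <- track$contig == genome$mito_name
  if (!any(mito)) {
    stop("track has no windows on mitochondrial contig '",
         genome$mito_name, "'")
  }
  med <- stats::median(track$value[mito])
  if (med == 0) {
    stop("median coverage on mitochondrial contig '", genome$mito_name,
         "' is zero; normalization undefined")
  }
  out <- window_track(track[, setdiff(names(track), "value"), drop = FALSE],
                      track$value / med, "normalized_enrichment")
  attr(out, "mito_median") <- med
  out
}

#' Per-base coverage track
#'
#' Computes base-resolution signal from fragments, either incrementing
#' every base a fragment covers (`full_fragment`) or only its strand-aware
#' 5' terminal base (`five_prime_end`: `start` for `+` fragments,
#' `end - 1` for `-` fragments; used for nucleosome-edge profiles where
#' plus-strand 5' ends mark nucleosome left edges). An optional strand
#' filter is applied before counting.
#'
#' @param fragments fragment data.frame.
#' @param genome a [genome].
#' @param mode `"full_fragment"` or `"five_prime_end"`.
#' @param strand_filter `"both"`, `"plus_only"` or `"minus_only"`.
#' @return An object of class `base_track`: list with `values` (named list
#'   of per-contig numeric vectors, one element per base) and
#'   `value_kind`.
#' @export
basewise_coverage <- function(fragments, genome,
                              mode = c("full_fragment", "five_prime_end"),
                              strand_filter = c("both", "plus_only",
                                                "minus_only")) {
  mode <- match.arg(mode)
  strand_filter <- match.arg(strand_filter)
  validate_fragments(fragments, genome)
  keep <- switch(strand_filter,
                 both = rep(TRUE, nrow(fragments)),
                 plus_only = fragments$strand == "+",
                 minus_only = fragments$strand == "-")
  fragments <- fragments[keep, , drop = FALSE]
  values <- lapply(names(genome$lengths), function(ctg) {
    L <- genome$lengths[[ctg]]
    f <- fragments[fragments$contig == ctg, , drop = FALSE]
    if (!nrow(f)) return(numeric(L))
    if (mode == "full_fragment") {
      cov <- IRanges::coverage(IRanges::IRanges(f$start + 1L, f$end),
                               width = L)
      as.numeric(cov)
    } else {
      pos <- ifelse(f$strand == "+", f$start, f$end - 1L)
      as.numeric(tabulate(pos + 1L, nbins = L))
    }
  })
  names(values) <- names(genome$lengths)
  structure(list(values = values, value_kind = "raw_count",
                 mode = mode, strand_filter = strand_filter),
            class = "base_track")
}

#' Scale a per-base track to unit genome-wide mean
#'
#' Divides all values by the genome-wide mean per-base signal, making
#' libraries of different sequencing depth comparable in metaplot overlays
#' (replicate curves plotted on a common scale).
#'
#' @param track a `base_track`.
#' @return A `base_track` with genome-wide mean 1 and
#'   `value_kind = "depth_normalized"`.
#' @export
scale_unit_mean <- function(track) {
  stopifnot(inherits(track, "base_track"))
  total <- sum(vapply(track$values, sum, 0))
  nbase <- sum(vapply(track$values, length, 0L))
  if (total == 0) stop("cannot scale an all-zero track")
  track$values <- lapply(track$values, function(v) v * nbase / total)
  track$value_kind <- "depth_normalized"
  track
}
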