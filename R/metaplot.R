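#' Assign genes to expression quintiles
#'
#' Genes are sorted by RPKM descending (ties broken by `gene_id`
#' ascending) and split into five contiguous groups of equal count, with
#' remainders going to the earliest (most expressed) groups. Quintile 1
#' holds the most expressed genes; quintile 5 the silent or rarely
#' expressed ones.
#'
#' @param genes gene data.frame with `gene_id` and `rpkm` (>= 5 genes).
#' @return An object of class `quintile_grouping`: list with `assignment`
#'   (data.frame `gene_id`, `quintile`) and `boundaries` (data.frame
#'   `quintile`, `max_rpkm`, `min_rpkm`, `n_genes`).
#' @export
assign_quintiles <- function(genes) {
  if (nrow(genes) < 5L) {
    stop("at least 5 genes are required for quintile grouping")
  }
  ord <- order(-genes$rpkm, genes$gene_id)
  n <- nrow(genes)
  sizes <- n %/% 5L + (seq_len(5L) <= n %% 5L)
  quintile <- rep(seq_len(5L), sizes)
  assignment <- data.frame(gene_id = genes$gene_id[ord],
                           quintile = quintile,
                           stringsAsFactors = FALSE)
  rpkm_sorted <- genes$rpkm[ord]
  boundaries <- data.frame(
    quintile = seq_len(5L),
    max_rpkm = tapply(rpkm_sorted, quintile, max),
    min_rpkm = tapply(rpkm_sorted, quintile, min),
    n_genes = as.integer(sizes), row.names = NULL)
  structure(list(assignment = assignment, boundaries = boundaries),
            class = "quintile_grouping")
}

#' @export
print.quintile_grouping <- function(x, ...) {
  cat("expression quintiles (Q1 = highest):\n")
  b <- x$boundaries
  for (i in seq_len(5L)) {
    cat(sprintf("  Q%d: %d genes, RPKM %.1f-%.1f\n", i, b$n_genes[i],
                b$max_rpkm[i], b$min_rpkm[i]))
  }
  invisible(x)
}

# resolve a base_track (or per-strand pair of them) for one gene
signal_vector <- function(signal, contig, strand) {
  if (inherits(signal, "base_track")) return(signal$values[[contig]])
  # list(`+` = base_track, `-` = base_track): strand-matched signal
  signal[[strand]]$values[[contig]]
}

# per-gene oriented bin values: rows = genes, cols = bins
gene_bin_matrix <- function(signal, genes, anchor, flank_bp, bin_bp) {
  stopifnot(nrow(genes) > 0L, bin_bp > 0L)
  if (flank_bp %% bin_bp != 0L) {
    stop("flank_bp must be a multiple of bin_bp")
  }
  nbin <- 2L * flank_bp %/% bin_bp
  anchors <- gene_anchors(genes, anchor)
  offsets <- seq.int(-flank_bp, flank_bp - 1L)
  bin_of <- rep(seq_len(nbin), each = bin_bp)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = nbin)
  for (i in seq_len(nrow(genes))) {
    v <- signal_vector(signal, genes$contig[i], genes$strand[i])
    pos <- if (genes$strand[i] == "+") anchors[i] + offsets
           else anchors[i] - offsets
    vals <- rep(NA_real_, length(pos))
    inside <- pos >= 0L & pos < length(v)
    vals[inside] <- v[pos[inside] + 1L]
    bin_mean <- tapply(vals, bin_of, mean, na.rm = TRUE)
    bin_mean[is.nan(bin_mean)] <- NA_real_
    mat[i, ] <- bin_mean
  }
  colnames(mat) <- seq.int(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  rownames(mat) <- genes$gene_id
  mat
}

#' Anchored gene metaplot
#'
#' Averages per-base signal over genes aligned at their TSS or TTS. For
#' each gene the window `[anchor - flank, anchor + flank)` is extracted in
#' gene orientation (minus-strand genes are reversed, so positive offsets
#' always point into the gene body at the TSS), averaged within fixed-width
#' bins, and then averaged across genes with equal weight per gene. Genes
#' truncated by contig edges contribute only their defined bases; bins
#' with no defined base for a gene are dropped from that gene's
#' contribution.
#'
#' @param signal a `base_track` from [basewise_coverage()], or a list
#'   `list("+" = , "-" = )` of two base tracks selected per gene strand
#'   (used for strand-matched nucleosome-edge profiles).
#' @param genes gene data.frame.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param flank_bp half-width of the window (must be a multiple of
#'   `bin_bp`; default 1000).
#' @param bin_bp bin width (default 10, the histogram resolution used
#'   throughout).
#' @param grouping optional [assign_quintiles()] result; when supplied one
#'   profile per quintile is returned.
#' @return data.frame with columns `group` (`"all"` or `"Q1"`..`"Q5"`),
#'   `offset` (bin left edge relative to the anchor), `value`, `n_genes`;
#'   attributes `anchor` and `bin_bp`.
#' @export
gene_metaplot <- function(signal, genes, anchor = c("TSS", "TTS"),
                          flank_bp = 1000L, bin_bp = 10L,
                          grouping = NULL) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("empty gene list")
  mat <- gene_bin_matrix(signal, genes, anchor, as.integer(flank_bp),
                         as.integer(bin_bp))
  groups <- if (is.null(grouping)) {
    list(all = seq_len(nrow(genes)))
  } else {
    stopifnot(inherits(grouping, "quintile_grouping"))
    q <- grouping$assignment$quintile[match(genes$gene_id,
                                            grouping$assignment$gene_id)]
    split(seq_len(nrow(genes)), paste0("Q", q))
  }
  offs <- as.integer(colnames(mat))
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    data.frame(group = g, offset = offs,
               value = colMeans(mat[idx, , drop = FALSE], na.rm = TRUE),
               n_genes = length(idx), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$value[is.nan(out$value)] <- NA_real_
  attr(out, "anchor") <- anchor
  attr(out, "bin_bp") <- as.integer(bin_bp)
  out
}

#' Expression-ordered heatmap matrix
#'
#' One row per gene (oriented as in [gene_metaplot()]), rows sorted by
#' RPKM descending with ties broken by `gene_id`; column means reproduce
#' the ungrouped metaplot profile.
#'
#' @inheritParams gene_metaplot
#' @param order_by only `"rpkm_desc"` is supported.
#' @return Numeric matrix (genes x bins) with gene IDs as row names and
#'   bin left-edge offsets as column names.
#' @export
heatmap_matrix <- function(signal, genes, anchor = c("TSS", "TTS"),
                           flank_bp = 1000L, bin_bp = 10L,
                           order_by = "rpkm_desc") {
  anchor <- match.arg(anchor)
  stopifnot(identical(order_by, "rpkm_desc"))
  if (nrow(genes) == 0L) stop("empty gene list")
  mat <- gene_bin_matrix(signal, genes, anchor, as.integer(flank_bp),
                         as.integer(bin_bp))
  mat[order(-genes$rpkm, genes$gene_id), , drop = FALSE]
}

#' Methylated-domain metaplot
#'
#' Aggregates per-cytosine counts over methylated domains scaled to a
#' common length: each domain body is split into 20 equal-length bins (5%
#' of the domain each) and each flank into 20 bins of 50 bp, for 60 bins
#' ordered upstream, body, downstream. Counts are pooled across all
#' domains per bin and each bin's value is the weighted methylation
#' percent of the pooled counts (coverage-weighted, matching the weighted
#' methylation level definition, unlike the per-gene equal weighting of
#' [gene_metaplot()]).
#'
#' @param report cytosine report data.frame.
#' @param domains data.frame of domain intervals (`contig`, `start`,
#'   `end`); domains shorter than `body_bins` bp are skipped with a
#'   warning.
#' @param flank_bins,flank_bin_bp flank geometry (default 20 bins of
#'   50 bp).
#' @param body_bins number of body bins (default 20, i.e. 5% of the body
#'   each).
#' @param min_coverage per-site coverage floor (default 3).
#' @return data.frame with columns `bin` (1..60), `section`
#'   (`upstream`/`body`/`downstream`), `position` (bp offset of the bin's
#'   left edge for flanks, percent of body length for the body), `value`
#'   (weighted methylation percent, NA when a bin has no qualifying
#'   coverage), and the pooled counts `m_pooled`, `n_pooled` behind each
#'   value; attribute `n_domains`.
#' @export
domain_metaplot <- function(report, domains, flank_bins = 20L,
                            flank_bin_bp = 50L, body_bins = 20L,
                            min_coverage = 3L) {
  if (nrow(domains) == 0L) stop("empty domain list")
  short <- domains$end - domains$start < body_bins
  if (any(short)) {
    warning(sum(short), " domain(s) shorter than ", body_bins,
            " bp skipped")
    domains <- domains[!short, , drop = FALSE]
    if (!nrow(domains)) stop("no domain long enough to bin")
  }
  nbin <- 2L * flank_bins + body_bins
  rep_f <- report[report$n >= min_coverage, , drop = FALSE]
  msum <- numeric(nbin); nsum <- numeric(nbin)
  for (i in seq_len(nrow(domains))) {
    ctg <- domains$contig[i]
    ds <- domains$start[i]; de <- domains$end[i]
    r <- rep_f[rep_f$contig == ctg, , drop = FALSE]
    if (!nrow(r)) next
    lo <- ds - flank_bins * flank_bin_bp
    hi <- de + flank_bins * flank_bin_bp
    r <- r[r$pos >= lo & r$pos < hi, , drop = FALSE]
    if (!nrow(r)) next
    bin <- integer(nrow(r))
    up <- r$pos < ds
    down <- r$pos >= de
    body <- !up & !down
    bin[up] <- flank_bins - (ds - 1L - r$pos[up]) %/% flank_bin_bp
    bin[body] <- flank_bins +
      pmin(body_bins - 1L,
           ((r$pos[body] - ds) * body_bins) %/% (de - ds)) + 1L
    bin[down] <- flank_bins + body_bins +
      (r$pos[down] - de) %/% flank_bin_bp + 1L
    add_m <- tapply(as.numeric(r$m), bin, sum)
    add_n <- tapply(as.numeric(r$n), bin, sum)
    at <- as.integer(names(add_m))
    msum[at] <- msum[at] + add_m
    nsum[at] <- nsum[at] + add_n
  }
  value <- ifelse(nsum > 0, 100 * msum / nsum, NA_real_)
  section <- rep(c("upstream", "body", "downstream"),
                 c(flank_bins, body_bins, flank_bins))
  position <- c(-flank_bins:-1 * flank_bin_bp,
                (seq_len(body_bins) - 1L) * (100 / body_bins),
                (seq_len(flank_bins) - 1L) * flank_bin_bp)
  out <- data.frame(bin = seq_len(nbin), section = section,
                    position = position, value = value,
                    m_pooled = msum, n_pooled = nsum,
                    stringsAsFactors = FALSE)
  attr(out, "n_domains") <- nrow(domains)
  out
}
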