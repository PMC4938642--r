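# shared fixtures and independent brute-force oracles

make_genome <- function(lengths = c(chr1 = 10000L, mito = 3000L),
                        mito_name = "mito", sequences = NULL) {
  genome(lengths, mito_name = mito_name, sequences = sequences)
}

make_fragments <- function(contig, start, end, strand = "+") {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end),
             strand = rep_len(strand, length(start)),
             stringsAsFactors = FALSE)
}

make_report <- function(contig, pos, strand, m, n) {
  data.frame(contig = contig, pos = as.integer(pos), strand = strand,
             m = as.integer(m), n = as.integer(n),
             stringsAsFactors = FALSE)
}

make_genes <- function(n, contig = "chr1", len = 500L, gap = 1500L,
                       strand = NULL, rpkm = NULL, start0 = 2000L) {
  starts <- start0 + (seq_len(n) - 1L) * (len + gap)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), contig = contig,
             strand = if (is.null(strand)) rep(c("+", "-"), length.out = n)
                      else rep_len(strand, n),
             start = starts, end = starts + len,
             rpkm = if (is.null(rpkm)) rev(seq_len(n)) else rpkm,
             stringsAsFactors = FALSE)
}

# per-base signal container built directly (bypasses basewise_coverage)
make_base_track <- function(genome, values = NULL) {
  if (is.null(values)) {
    values <- lapply(contig_lengths(genome), function(L) numeric(L))
  }
  structure(list(values = values, value_kind = "raw_count"),
            class = "base_track")
}

# brute-force windowed fragment counting by explicit interval intersection
bf_window_counts <- function(fragments, genome, window_bp,
                             rule = "overlap") {
  windows <- tile_windows(genome, window_bp)
  counts <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    for (f in seq_len(nrow(fragments))) {
      if (fragments$contig[f] != windows$contig[w]) next
      hit <- if (rule == "overlap") {
        fragments$start[f] < windows$end[w] &&
          fragments$end[f] > windows$start[w]
      } else {
        fragments$start[f] >= windows$start[w] &&
          fragments$start[f] < windows$end[w]
      }
      if (hit) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# brute-force anchored metaplot: explicit per-gene, per-base loop
bf_gene_metaplot <- function(base_track, genes, anchor, flank_bp, bin_bp) {
  nbin <- 2L * flank_bp %/% bin_bp
  per_gene <- matrix(NA_real_, nrow(genes), nbin)
  for (i in seq_len(nrow(genes))) {
    v <- base_track$values[[genes$contig[i]]]
    a <- gene_anchors(genes[i, , drop = FALSE], anchor)
    for (b in seq_len(nbin)) {
      acc <- c()
      for (o in ((b - 1L) * bin_bp):(b * bin_bp - 1L)) {
        off <- o - flank_bp
        pos <- if (genes$strand[i] == "+") a + off else a - off
        if (pos >= 0L && pos < length(v)) acc <- c(acc, v[pos + 1L])
      }
      if (length(acc)) per_gene[i, b] <- mean(acc)
    }
  }
  colMeans(per_gene, na.rm = TRUE)
}

# reference Benjamini-Hochberg step-up: q(k) = min_{j >= k} p(j) * T / j
bf_bh <- function(p) {
  T <- length(p)
  ord <- order(p)
  q_sorted <- numeric(T)
  for (k in seq_len(T)) {
    q_sorted[k] <- min(1, min(sort(p)[k:T] * T / (k:T)))
  }
  q <- numeric(T)
  q[ord] <- q_sorted
  q
}

# sum of m and n over report sites falling inside any of the intervals
pool_counts <- function(report, intervals, min_coverage = 3L) {
  keep <- report$n >= min_coverage
  r <- report[keep, , drop = FALSE]
  inside <- rep(FALSE, nrow(r))
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (r$contig == intervals$contig[i] &
                          r$pos >= intervals$start[i] &
                          r$pos < intervals$end[i])
  }
  c(m = sum(as.numeric(r$m[inside])), n = sum(as.numeric(r$n[inside])))
}
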