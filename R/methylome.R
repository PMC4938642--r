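#' Estimate the bisulfite nonconversion rate from mitochondrial DNA
#'
#' Mitochondrial DNA is fully unmethylated, so any unconverted
#' mitochondrial cytosine reads reflect incomplete bisulfite conversion.
#' The rate is estimated by pooling counts over all mitochondrial sites
#' (coverage-weighted): `sum(m) / sum(n)`, the maximum-likelihood estimate
#' of a shared error rate.
#'
#' @param report cytosine report data.frame.
#' @param genome a [genome] identifying the mitochondrial contig.
#' @return Nonconversion rate in `[0, 1]`.
#' @export
estimate_nonconversion <- function(report, genome) {
  stopifnot(inherits(genome, "genome"))
  mito <- report[report$contig == genome$mito_name, , drop = FALSE]
  if (!nrow(mito)) {
    stop("no mitochondrial sites ('", genome$mito_name,
         "') in the cytosine report")
  }
  total <- sum(as.numeric(mito$n))
  if (total == 0) {
    stop("zero total read coverage on mitochondrial contig '",
         genome$mito_name, "'")
  }
  sum(as.numeric(mito$m)) / total
}

#' Call per-cytosine methylation status
#'
#' Sites with coverage below `min_coverage` are labelled
#' `insufficient_coverage` and excluded from testing and from the
#' multiple-testing family. Each remaining site gets a one-sided binomial
#' test of `m` successes in `n` trials against the nonconversion rate
#' (`p = P(X >= m)`, `X ~ Binomial(n, nonconversion)`), Benjamini-Hochberg
#' correction over exactly the tested sites, and status `methylated` when
#' `q <= alpha`.
#'
#' @param report cytosine report data.frame.
#' @param nonconversion nonconversion rate in `[0, 1)`, typically from
#'   [estimate_nonconversion()].
#' @param min_coverage minimum site coverage (default 3).
#' @param alpha FDR threshold for calling a site methylated (default
#'   0.05).
#' @return data.frame of calls: report columns plus `p_value`, `q_value`
#'   (NA for untested sites) and `status` in
#'   `{methylated, unmethylated, insufficient_coverage}`.
#' @export
call_sites <- function(report, nonconversion, min_coverage = 3L,
                       alpha = 0.05) {
  if (nonconversion < 0 || nonconversion >= 1) {
    stop("nonconversion rate must be in [0, 1)")
  }
  stopifnot(min_coverage >= 1L, alpha > 0, alpha < 1)
  calls <- report
  tested <- report$n >= min_coverage
  p <- rep(NA_real_, nrow(report))
  p[tested] <- stats::pbinom(report$m[tested] - 1L, report$n[tested],
                             nonconversion, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(report))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  status <- rep("unmethylated", nrow(report))
  status[!tested] <- "insufficient_coverage"
  status[tested & !is.na(q) & q <= alpha] <- "methylated"
  calls$p_value <- p
  calls$q_value <- q
  calls$status <- status
  calls
}

#' Count methylated cytosines
#'
#' @param calls output of [call_sites()].
#' @return Number of sites with status `methylated`.
#' @export
count_methylated <- function(calls) {
  sum(calls$status == "methylated")
}

#' Weighted methylation level of regions
#'
#' The weighted methylation level of a region is
#' `100 * sum(m) / sum(n)` over its cytosine sites with coverage
#' `n >= min_coverage`; sites below the coverage floor are excluded from
#' both sums. A region with no qualifying site has an undefined level,
#' returned as `NA` (never silently 0).
#'
#' @param report cytosine report data.frame.
#' @param regions data.frame of intervals (`contig`, `start`, `end`), or
#'   `NULL` for the whole report.
#' @param min_coverage minimum site coverage (default 3).
#' @return Numeric vector of percentages, one per region (a single value
#'   when `regions` is `NULL`).
#' @export
weighted_level <- function(report, regions = NULL, min_coverage = 3L) {
  keep <- report$n >= min_coverage
  rep_f <- report[keep, , drop = FALSE]
  if (is.null(regions)) {
    if (!nrow(rep_f)) return(NA_real_)
    return(100 * sum(as.numeric(rep_f$m)) / sum(as.numeric(rep_f$n)))
  }
  vapply(seq_len(nrow(regions)), function(i) {
    sel <- rep_f$contig == regions$contig[i] &
      rep_f$pos >= regions$start[i] & rep_f$pos < regions$end[i]
    if (!any(sel)) return(NA_real_)
    100 * sum(as.numeric(rep_f$m[sel])) / sum(as.numeric(rep_f$n[sel]))
  }, 0)
}

#' Weighted methylation level in genomic windows
#'
#' Convenience wrapper computing [weighted_level()] for fixed windows
#' tiling the genome (e.g. 10 kb windows for chromosome-scale methylation
#' plots).
#'
#' @param report cytosine report data.frame.
#' @param genome a [genome].
#' @param window_bp window width (default 10000).
#' @param min_coverage minimum site coverage (default 3).
#' @return A `window_track` with
#'   `value_kind = "weighted_methylation_percent"`; windows without
#'   qualifying sites carry `NA`.
#' @export
methylation_track <- function(report, genome, window_bp = 10000L,
                              min_coverage = 3L) {
  windows <- tile_windows(genome, window_bp)
  keep <- report$n >= min_coverage
  rep_f <- report[keep, , drop = FALSE]
  vals <- rep(NA_real_, nrow(windows))
  for (ctg in unique(windows$contig)) {
    widx <- which(windows$contig == ctg)
    r <- rep_f[rep_f$contig == ctg, , drop = FALSE]
    if (!nrow(r)) next
    bin <- r$pos %/% as.integer(window_bp) + 1L
    msum <- tapply(as.numeric(r$m), bin, sum)
    nsum <- tapply(as.numeric(r$n), bin, sum)
    at <- as.integer(names(msum))
    v <- rep(NA_real_, length(widx))
    v[at] <- ifelse(nsum > 0, 100 * msum / nsum, NA_real_)
    vals[widx] <- v
  }
  window_track(windows, vals, "weighted_methylation_percent")
}

#' Compare per-site methylation levels at shared methylated sites
#'
#' Shared sites are `(contig, pos, strand)` triples called methylated in
#' both strains. For each strain, the per-site level `m/n` at shared
#' sites is binned (default 5% bins, twenty bins covering 0-100%) and
#' expressed as a percentage of shared sites, summing to 100 per strain.
#' A strain whose distribution sits further right is methylated at higher
#' frequency per cell population at the same sites.
#'
#' @param calls_a,calls_b outputs of [call_sites()] for the two strains
#'   over the same genome.
#' @param bin_percent bin width in percentage points (default 5).
#' @return data.frame with `bin_low`, `bin_high`, `percent_a`,
#'   `percent_b`; zero rows (with a warning) when no sites are shared.
#' @export
shared_site_distribution <- function(calls_a, calls_b, bin_percent = 5) {
  key_a <- paste(calls_a$contig, calls_a$pos, calls_a$strand)
  key_b <- paste(calls_b$contig, calls_b$pos, calls_b$strand)
  ma <- calls_a$status == "methylated"
  mb <- calls_b$status == "methylated"
  shared <- intersect(key_a[ma], key_b[mb])
  nbin <- as.integer(ceiling(100 / bin_percent))
  if (!length(shared)) {
    warning("no shared methylated sites between the two call sets")
    return(data.frame(bin_low = numeric(), bin_high = numeric(),
                      percent_a = numeric(), percent_b = numeric()))
  }
  level_pct <- function(calls, key) {
    idx <- match(shared, key)
    100 * calls$m[idx] / calls$n[idx]
  }
  binify <- function(lv) {
    bin <- pmin(floor(lv / bin_percent), nbin - 1L) + 1L
    100 * tabulate(bin, nbins = nbin) / length(lv)
  }
  data.frame(bin_low = bin_percent * (seq_len(nbin) - 1L),
             bin_high = pmin(bin_percent * seq_len(nbin), 100),
             percent_a = binify(level_pct(calls_a, key_a)),
             percent_b = binify(level_pct(calls_b, key_b)))
}

#' Find differentially methylated regions between two strains
#'
#' Sliding windows (`dmr_window_bp` wide, stepping `dmr_step_bp`) are
#' scored on cytosines covered at least `min_coverage` in *both* strains:
#' counts are pooled per window and strain, the 2x2 table
#' `(m_a, n_a - m_a; m_b, n_b - m_b)` is tested with a two-sided Fisher
#' exact test, and p-values are Benjamini-Hochberg corrected over the
#' tested windows (those with at least `dmr_min_sites` shared covered
#' sites). Windows that are significant at `dmr_alpha` *and* show an
#' absolute weighted-level difference of at least `dmr_min_diff`
#' percentage points are merged when separated by at most
#' `dmr_merge_gap_bp`, separately per direction of change.
#'
#' @param report_a,report_b cytosine reports for the two strains over the
#'   same genome.
#' @param genome a [genome].
#' @param dmr_window_bp,dmr_step_bp sliding-window geometry (defaults
#'   1000/100; the window must be at least as wide as the step).
#' @param dmr_min_diff minimum absolute weighted-level difference in
#'   percentage points (default 20).
#' @param dmr_alpha FDR threshold on windows (default 0.05).
#' @param dmr_merge_gap_bp maximum gap merged between significant windows
#'   (default 500).
#' @param min_coverage per-site coverage floor in both strains (default 3).
#' @param dmr_min_sites minimum shared covered sites per tested window
#'   (default 5).
#' @return data.frame of merged DMRs: `contig`, `start`, `end`,
#'   `direction` (`"higher_in_b"` or `"higher_in_a"`); zero rows when no
#'   window passes.
#' @export
find_dmrs <- function(report_a, report_b, genome,
                      dmr_window_bp = 1000L, dmr_step_bp = 100L,
                      dmr_min_diff = 20, dmr_alpha = 0.05,
                      dmr_merge_gap_bp = 500L, min_coverage = 3L,
                      dmr_min_sites = 5L) {
  stopifnot(inherits(genome, "genome"), dmr_window_bp >= dmr_step_bp)
  key_a <- paste(report_a$contig, report_a$pos, report_a$strand)
  key_b <- paste(report_b$contig, report_b$pos, report_b$strand)
  idx_b <- match(key_a, key_b)
  ok <- !is.na(idx_b) & report_a$n >= min_coverage &
    report_b$n[idx_b] >= min_coverage
  sites <- data.frame(contig = report_a$contig[ok],
                      pos = report_a$pos[ok],
                      m_a = as.numeric(report_a$m[ok]),
                      n_a = as.numeric(report_a$n[ok]),
                      m_b = as.numeric(report_b$m[idx_b[ok]]),
                      n_b = as.numeric(report_b$n[idx_b[ok]]),
                      stringsAsFactors = FALSE)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(sites)) return(empty)

  win <- list(); w <- 0L
  for (ctg in names(genome$lengths)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$pos), , drop = FALSE]
    L <- genome$lengths[[ctg]]
    starts <- seq.int(0L, max(0L, L - 1L), by = dmr_step_bp)
    ends <- pmin(starts + dmr_window_bp, L)
    # pooled window sums via cumulative sums over sorted site positions
    cum <- function(x) c(0, cumsum(x))
    lo <- findInterval(starts - 1L, s$pos) + 1L
    hi <- findInterval(ends - 1L, s$pos)
    nsite <- hi - lo + 1L
    keep <- nsite >= dmr_min_sites
    if (!any(keep)) next
    cm_a <- cum(s$m_a); cn_a <- cum(s$n_a)
    cm_b <- cum(s$m_b); cn_b <- cum(s$n_b)
    win[[length(win) + 1L]] <- data.frame(
      contig = ctg, start = starts[keep], end = ends[keep],
      m_a = cm_a[hi[keep] + 1L] - cm_a[lo[keep]],
      n_a = cn_a[hi[keep] + 1L] - cn_a[lo[keep]],
      m_b = cm_b[hi[keep] + 1L] - cm_b[lo[keep]],
      n_b = cn_b[hi[keep] + 1L] - cn_b[lo[keep]],
      stringsAsFactors = FALSE)
  }
  if (!length(win)) return(empty)
  win <- do.call(rbind, win)
  win <- win[win$n_a > 0 & win$n_b > 0, , drop = FALSE]
  if (!nrow(win)) return(empty)

  win$diff <- 100 * (win$m_b / win$n_b - win$m_a / win$n_a)
  # identical tables have p = 1 exactly; skip the Fisher computation there
  win$p <- vapply(seq_len(nrow(win)), function(i) {
    if (win$m_a[i] == win$m_b[i] && win$n_a[i] == win$n_b[i]) return(1)
    tab <- matrix(c(win$m_a[i], win$n_a[i] - win$m_a[i],
                    win$m_b[i], win$n_b[i] - win$m_b[i]),
                  nrow = 2L, byrow = TRUE)
    stats::fisher.test(round(tab))$p.value
  }, 0)
  win$q <- stats::p.adjust(win$p, method = "BH")
  sig <- win$q <= dmr_alpha & abs(win$diff) >= dmr_min_diff
  win <- win[sig, , drop = FALSE]
  if (!nrow(win)) return(empty)

  win$dir <- ifelse(win$diff > 0, "higher_in_b", "higher_in_a")
  win <- win[order(win$contig, win$dir, win$start), , drop = FALSE]
  grp_key <- paste(win$contig, win$dir)
  merged <- lapply(split(win, grp_key), function(g) {
    new_run <- c(TRUE, g$start[-1L] > g$end[-nrow(g)] + dmr_merge_gap_bp)
    run <- cumsum(new_run)
    data.frame(contig = g$contig[1L],
               start = tapply(g$start, run, min),
               end = tapply(g$end, run, max),
               direction = g$dir[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}
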