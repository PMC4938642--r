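#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator with defaults
#' chosen to emulate, at desk scale, the data-generating process the
#' analyses assume: a multi-contig nuclear genome plus a fully unmethylated
#' mitochondrial contig; genes on both strands with log-normal expression
#' and a silent fraction; non-overlapping heterochromatic "methylated
#' domain" intervals with elevated per-cytosine methylation; bisulfite
#' counts with a small nonconversion rate; ChIP fragments with a global
#' nuclear enrichment plus an expression-scaled promoter boost; and MNase
#' mononucleosome fragments from phased arrays downstream of a
#' nucleosome-free region (NFR).
#'
#' @param seed integer seed; mandatory, every simulator is a pure function
#'   of (inputs, seed).
#' @param n_nuclear_contigs,contig_length_bp,mito_length_bp genome shape.
#' @param n_genes,gene_length_bp gene count and fixed gene length.
#' @param rpkm_lognormal_mu,rpkm_lognormal_sigma log-normal parameters of
#'   expression (RPKM); `rpkm_zero_fraction` of genes are set to exactly 0
#'   (silent genes, populating the lowest quintile).
#' @param n_domains,domain_length_bp methylated-domain count and length.
#' @param domain_meth_freq,background_meth_freq true per-cytosine
#'   methylation frequency inside/outside domains (mitochondrial sites are
#'   always 0). The background default is 0: methylation in *Neurospora*
#'   is confined to heterochromatic RIP-relic domains, so outside them the
#'   only unconverted reads come from bisulfite nonconversion.
#' @param nonconversion_rate bisulfite nonconversion rate of unmethylated
#'   cytosines.
#' @param bs_mean_coverage mean Poisson sequencing depth per cytosine.
#' @param chip_nuclear_enrichment global nuclear-over-mitochondrial
#'   sampling weight of the tagged ChIP library (>= 1).
#' @param chip_promoter_boost,chip_promoter_window_bp additional sampling
#'   weight in the window upstream of each TSS, scaled by expression
#'   quintile rank (full boost in Q1, one fifth of it in Q5).
#' @param chip_n_fragments,chip_fragment_len_mean,chip_fragment_len_sd ChIP
#'   fragment count and truncated-normal length model (floor 50 bp).
#' @param mnase_nfr_width_bp,mnase_spacing_bp,mnase_jitter_sd_bp NFR width
#'   upstream of the TSS, nucleosome repeat spacing, and positional jitter
#'   of nucleosome edges.
#' @param mnase_fragment_len_mean,mnase_fragment_len_sd,mnase_n_fragments
#'   mononucleosome fragment length model (truncated normal, floor 50 bp)
#'   and count.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_nuclear_contigs = 2L,
                       contig_length_bp = 300000L,
                       mito_length_bp = 20000L,
                       n_genes = 150L,
                       gene_length_bp = 1500L,
                       rpkm_lognormal_mu = 2.3,
                       rpkm_lognormal_sigma = 2.0,
                       rpkm_zero_fraction = 0.2,
                       n_domains = 10L,
                       domain_length_bp = 5000L,
                       domain_meth_freq = 0.45,
                       background_meth_freq = 0,
                       nonconversion_rate = 0.005,
                       bs_mean_coverage = 20,
                       chip_nuclear_enrichment = 3,
                       chip_promoter_boost = 2,
                       chip_promoter_window_bp = 500L,
                       chip_n_fragments = 200000L,
                       chip_fragment_len_mean = 200,
                       chip_fragment_len_sd = 30,
                       mnase_nfr_width_bp = 150L,
                       mnase_spacing_bp = 200L,
                       mnase_jitter_sd_bp = 20,
                       mnase_fragment_len_mean = 140,
                       mnase_fragment_len_sd = 23,
                       mnase_n_fragments = 50000L) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  cfg <- list(seed = as.integer(seed),
              n_nuclear_contigs = as.integer(n_nuclear_contigs),
              contig_length_bp = as.integer(contig_length_bp),
              mito_length_bp = as.integer(mito_length_bp),
              n_genes = as.integer(n_genes),
              gene_length_bp = as.integer(gene_length_bp),
              rpkm_lognormal_mu = rpkm_lognormal_mu,
              rpkm_lognormal_sigma = rpkm_lognormal_sigma,
              rpkm_zero_fraction = rpkm_zero_fraction,
              n_domains = as.integer(n_domains),
              domain_length_bp = as.integer(domain_length_bp),
              domain_meth_freq = domain_meth_freq,
              background_meth_freq = background_meth_freq,
              nonconversion_rate = nonconversion_rate,
              bs_mean_coverage = bs_mean_coverage,
              chip_nuclear_enrichment = chip_nuclear_enrichment,
              chip_promoter_boost = chip_promoter_boost,
              chip_promoter_window_bp = as.integer(chip_promoter_window_bp),
              chip_n_fragments = as.integer(chip_n_fragments),
              chip_fragment_len_mean = chip_fragment_len_mean,
              chip_fragment_len_sd = chip_fragment_len_sd,
              mnase_nfr_width_bp = as.integer(mnase_nfr_width_bp),
              mnase_spacing_bp = as.integer(mnase_spacing_bp),
              mnase_jitter_sd_bp = mnase_jitter_sd_bp,
              mnase_fragment_len_mean = mnase_fragment_len_mean,
              mnase_fragment_len_sd = mnase_fragment_len_sd,
              mnase_n_fragments = as.integer(mnase_n_fragments))
  rates <- c("rpkm_zero_fraction", "domain_meth_freq",
             "background_meth_freq", "nonconversion_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  }
  lens <- c("n_nuclear_contigs", "contig_length_bp", "mito_length_bp",
            "gene_length_bp", "domain_length_bp")
  for (l in lens) if (cfg[[l]] < 1L) stop(l, " must be positive")
  if (cfg$n_genes < 0L || cfg$n_domains < 0L ||
      cfg$chip_n_fragments < 0L || cfg$mnase_n_fragments < 0L) {
    stop("counts must be non-negative")
  }
  if (cfg$bs_mean_coverage <= 0) stop("bs_mean_coverage must be positive")
  if (cfg$chip_nuclear_enrichment < 1 || cfg$chip_promoter_boost < 1) {
    stop("ChIP enrichment factors must be >= 1")
  }
  occupied <- as.numeric(cfg$n_genes) * cfg$gene_length_bp +
    as.numeric(cfg$n_domains) * cfg$domain_length_bp
  if (occupied > 0.8 * as.numeric(cfg$n_nuclear_contigs) *
        cfg$contig_length_bp) {
    stop("genes and domains cannot be placed without overlap: ",
         "requested features occupy > 80% of the nuclear genome")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with genes and methylated domains
#'
#' Nuclear contigs carry non-overlapping genes (random strands, log-normal
#' RPKM with a silent fraction set to exactly 0) and non-overlapping
#' methylated domains disjoint from genes; the mitochondrial contig
#' contains cytosines but belongs to no domain. Features are placed by
#' random assignment to contigs followed by uniform partition of the free
#' space into inter-feature gaps, which guarantees disjoint placement in a
#' single pass. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return list with elements `genome` (a [genome] with sequences),
#'   `genes` (gene data.frame) and `domains` (interval data.frame with
#'   `contig`, `start`, `end`, `label`).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    ctg_names <- c(paste0("chr", seq_len(cfg$n_nuclear_contigs)), "mito")
    lens <- stats::setNames(c(rep(cfg$contig_length_bp,
                                  cfg$n_nuclear_contigs),
                              cfg$mito_length_bp), ctg_names)
    seqs <- Biostrings::DNAStringSet(vapply(lens, random_dna, ""))
    names(seqs) <- ctg_names
    gen <- genome(lens, mito_name = "mito", sequences = seqs)

    item_len <- c(rep(cfg$gene_length_bp, cfg$n_genes),
                  rep(cfg$domain_length_bp, cfg$n_domains))
    item_kind <- rep(c("gene", "domain"), c(cfg$n_genes, cfg$n_domains))
    placed <- place_features(item_len, item_kind,
                             nuclear = nuclear_contigs(gen),
                             contig_len = cfg$contig_length_bp)

    genes <- placed[placed$kind == "gene", , drop = FALSE]
    domains <- placed[placed$kind == "domain", , drop = FALSE]
    genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
    domains <- domains[order(domains$contig, domains$start), , drop = FALSE]

    n_g <- nrow(genes)
    rpkm <- stats::rlnorm(n_g, cfg$rpkm_lognormal_mu,
                          cfg$rpkm_lognormal_sigma)
    n_zero <- round(cfg$rpkm_zero_fraction * n_g)
    if (n_zero > 0L) rpkm[sample.int(n_g, n_zero)] <- 0
    genes_df <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_g)),
      contig = genes$contig,
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      start = genes$start, end = genes$end, rpkm = rpkm,
      stringsAsFactors = FALSE, row.names = NULL)
    dom_df <- data.frame(
      contig = domains$contig, start = domains$start, end = domains$end,
      label = sprintf("domain_%03d", seq_len(nrow(domains))),
      stringsAsFactors = FALSE, row.names = NULL)
    list(genome = gen, genes = genes_df, domains = dom_df)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random disjoint placement: assign features to contigs (retrying if a
# contig overflows), then drop them into the contig in shuffled order with
# gaps drawn as a uniform partition of the free space.
place_features <- function(item_len, item_kind, nuclear, contig_len,
                           max_tries = 100L) {
  n <- length(item_len)
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  for (try in seq_len(max_tries)) {
    assign <- sample(nuclear, n, replace = TRUE)
    ok <- all(vapply(nuclear, function(ctg) {
      sum(item_len[assign == ctg]) <= contig_len
    }, TRUE))
    if (ok) break
    if (try == max_tries) {
      stop("could not assign features to contigs without overflow after ",
           max_tries, " tries")
    }
  }
  out <- vector("list", length(nuclear))
  for (i in seq_along(nuclear)) {
    ctg <- nuclear[i]
    idx <- which(assign == ctg)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    lens <- item_len[idx]
    free <- contig_len - sum(lens)
    gaps <- sort(floor(stats::runif(length(idx), 0, free + 1)))
    starts <- as.integer(gaps + cumsum(c(0L, lens[-length(lens)])))
    out[[i]] <- data.frame(contig = ctg, start = starts,
                           end = starts + lens, kind = item_kind[idx],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a per-cytosine bisulfite report
#'
#' Every cytosine in the genome sequence (C on the plus strand, G on the
#' minus strand; strands treated independently) receives a Poisson read
#' depth `n` with mean `cfg$bs_mean_coverage` and an unconverted count
#' `m ~ Binomial(n, f + (1 - f) * nonconversion)`, where the true
#' methylation frequency `f` is `domain_meth_freq` inside a methylated
#' domain, `background_meth_freq` elsewhere in the nuclear genome, and 0
#' on the mitochondrial contig (so pooled mitochondrial `m/n` estimates
#' the nonconversion rate alone). Deterministic given `seed`.
#'
#' @param genome a [genome] with sequences.
#' @param domains methylated-domain data.frame (`contig`, `start`, `end`).
#' @param cfg a [sim_config].
#' @param seed seed; defaults to `cfg$seed`.
#' @param domain_meth_freq override of `cfg$domain_meth_freq`, convenient
#'   when simulating strain pairs that differ only in domain methylation.
#' @return Cytosine report data.frame (`contig`, `pos`, `strand`, `m`,
#'   `n`), sorted by contig and position.
#' @export
simulate_bisulfite <- function(genome, domains, cfg, seed = cfg$seed,
                               domain_meth_freq = cfg$domain_meth_freq) {
  stopifnot(inherits(genome, "genome"), inherits(cfg, "sim_config"))
  if (is.null(genome$sequences)) {
    stop("simulate_bisulfite requires genome sequences")
  }
  withr::with_seed(as.integer(seed), {
    pieces <- lapply(names(genome$lengths), function(ctg) {
      seq <- genome$sequences[[ctg]]
      pos_c <- Biostrings::start(Biostrings::matchPattern("C", seq)) - 1L
      pos_g <- Biostrings::start(Biostrings::matchPattern("G", seq)) - 1L
      pos <- c(pos_c, pos_g)
      strand <- rep(c("+", "-"), c(length(pos_c), length(pos_g)))
      if (!length(pos)) return(NULL)
      f <- if (ctg == genome$mito_name) {
        rep(0, length(pos))
      } else {
        dom <- domains[domains$contig == ctg, , drop = FALSE]
        in_domain(pos, dom) * (domain_meth_freq - cfg$background_meth_freq) +
          cfg$background_meth_freq
      }
      n <- stats::rpois(length(pos), cfg$bs_mean_coverage)
      p_obs <- f + (1 - f) * cfg$nonconversion_rate
      m <- stats::rbinom(length(pos), n, p_obs)
      ord <- order(pos, strand)
      data.frame(contig = ctg, pos = pos[ord], strand = strand[ord],
                 m = m[ord], n = n[ord], stringsAsFactors = FALSE)
    })
    do.call(rbind, c(pieces[!vapply(pieces, is.null, TRUE)],
                     list(make.row.names = FALSE)))
  })
}

# 0/1 indicator: does 0-based position fall inside any interval?
in_domain <- function(pos, dom) {
  if (!nrow(dom)) return(numeric(length(pos)))
  ord <- order(dom$start)
  starts <- dom$start[ord]; ends <- dom$end[ord]
  idx <- findInterval(pos, starts)
  as.numeric(idx > 0L & pos < ends[pmax(idx, 1L)])
}

#' Simulate a ChIP-seq fragment set
#'
#' Fragment start positions are drawn base-by-base with sampling weight 1
#' on the mitochondrial contig; nuclear bases get weight
#' `chip_nuclear_enrichment` when `tagged = TRUE` (else 1, modelling a
#' no-epitope negative control whose normalized enrichment is ~1
#' genome-wide). In the tagged library, bases within
#' `chip_promoter_window_bp` upstream of each TSS are further multiplied
#' by a promoter boost that scales with expression quintile rank:
#' `1 + (chip_promoter_boost - 1) * (6 - q) / 5` for quintile `q` (so Q1
#' receives the full boost and Q5 a fifth of it). Fragment lengths are
#' truncated normal (floor 50 bp), strands uniform. Deterministic given
#' `seed`.
#'
#' @param genome a [genome].
#' @param genes gene data.frame with `rpkm` (used for quintile ranks).
#' @param cfg a [sim_config].
#' @param tagged logical: tagged strain (`TRUE`) or negative control.
#' @param seed seed; defaults to `cfg$seed`.
#' @return Fragment data.frame (`contig`, `start`, `end`, `strand`).
#' @export
simulate_chip <- function(genome, genes, cfg, tagged = TRUE,
                          seed = cfg$seed) {
  stopifnot(inherits(genome, "genome"), inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), {
    if (cfg$chip_n_fragments == 0L) {
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    weights <- lapply(names(genome$lengths), function(ctg) {
      L <- genome$lengths[[ctg]]
      if (ctg == genome$mito_name) return(rep(1, L))
      w <- rep(if (tagged) cfg$chip_nuclear_enrichment else 1, L)
      w
    })
    names(weights) <- names(genome$lengths)
    if (tagged && nrow(genes) >= 5L && cfg$chip_promoter_boost > 1) {
      q <- assign_quintiles(genes)$assignment
      qidx <- q$quintile[match(genes$gene_id, q$gene_id)]
      mult <- 1 + (cfg$chip_promoter_boost - 1) * (6 - qidx) / 5
      for (i in seq_len(nrow(genes))) {
        L <- genome$lengths[[genes$contig[i]]]
        if (genes$strand[i] == "+") {
          ps <- genes$start[i] - cfg$chip_promoter_window_bp
          pe <- genes$start[i]
        } else {
          ps <- genes$end[i]
          pe <- genes$end[i] + cfg$chip_promoter_window_bp
        }
        ps <- max(ps, 0L); pe <- min(pe, L)
        if (ps < pe) {
          rng <- (ps + 1L):pe  # 1-based into weight vector
          weights[[genes$contig[i]]][rng] <-
            weights[[genes$contig[i]]][rng] * mult[i]
        }
      }
    }
    totals <- vapply(weights, sum, 0)
    n_per <- as.vector(stats::rmultinom(1L, cfg$chip_n_fragments,
                                        totals / sum(totals)))
    pieces <- lapply(seq_along(weights), function(i) {
      n_i <- n_per[i]
      if (n_i == 0L) return(NULL)
      ctg <- names(weights)[i]
      L <- genome$lengths[[ctg]]
      start <- sample.int(L, n_i, replace = TRUE,
                          prob = weights[[i]]) - 1L
      len <- pmax(50, round(stats::rnorm(n_i, cfg$chip_fragment_len_mean,
                                         cfg$chip_fragment_len_sd)))
      end <- pmin(start + as.integer(len), L)
      keep <- start < end
      data.frame(contig = ctg, start = start[keep], end = end[keep],
                 strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(pieces[!vapply(pieces, is.null, TRUE)],
                     list(make.row.names = FALSE)))
  })
}

#' Simulate an MNase-seq mononucleosome fragment set
#'
#' For each gene, nucleosome edges are placed in gene orientation at
#' offsets `0, spacing, 2*spacing, ...` from the TSS (as many as fit in
#' the gene body), with no placements inside the nucleosome-free region of
#' width `mnase_nfr_width_bp` immediately upstream of the TSS. A sampled
#' genic fragment picks a nucleosome edge, adds `Normal(0, jitter)` to the
#' edge position, and extends one truncated-normal fragment length into
#' the gene; for a `-` strand gene the construction is mirror-imaged, so
#' the oriented 5' end always marks the promoter-proximal edge.
#' Intergenic background fragments are placed uniformly outside gene
#' bodies and NFRs, weighted as one nucleosome per `mnase_spacing_bp`.
#' Strands are uniform. Deterministic given `seed`.
#'
#' @param genome a [genome].
#' @param genes gene data.frame.
#' @param cfg a [sim_config]; `mnase_spacing_bp` must be at least the mean
#'   fragment length (shorter spacing would require physically overlapping
#'   nucleosomes).
#' @param seed seed; defaults to `cfg$seed`.
#' @return Fragment data.frame (`contig`, `start`, `end`, `strand`).
#' @export
simulate_mnase <- function(genome, genes, cfg, seed = cfg$seed) {
  stopifnot(inherits(genome, "genome"), inherits(cfg, "sim_config"))
  if (cfg$mnase_spacing_bp < cfg$mnase_fragment_len_mean) {
    stop("mnase_spacing_bp (", cfg$mnase_spacing_bp,
         ") is smaller than the mean fragment length (",
         cfg$mnase_fragment_len_mean, "): overlapping nucleosomes")
  }
  withr::with_seed(as.integer(seed), {
    if (cfg$mnase_n_fragments == 0L) {
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    sp <- cfg$mnase_spacing_bp
    glen <- genes$end - genes$start
    n_pos <- pmax(1L, (glen - as.integer(cfg$mnase_fragment_len_mean))
                  %/% sp + 1L)
    edge_gene <- rep(seq_len(nrow(genes)), n_pos)
    edge_k <- unlist(lapply(n_pos, function(k) seq_len(k) - 1L),
                     use.names = FALSE)
    total_pos <- length(edge_gene)

    allowed <- background_space(genome, genes, cfg$mnase_nfr_width_bp)
    bg_len <- sum(as.numeric(allowed$end - allowed$start))
    w_nuc <- as.numeric(total_pos) * sp
    p_bg <- bg_len / (bg_len + w_nuc)

    n <- cfg$mnase_n_fragments
    is_bg <- stats::runif(n) < p_bg
    n_bg <- sum(is_bg); n_nuc <- n - n_bg
    len <- pmax(50, round(stats::rnorm(n, cfg$mnase_fragment_len_mean,
                                       cfg$mnase_fragment_len_sd)))
    contig <- character(n); start <- integer(n); end <- integer(n)

    if (n_nuc > 0L) {
      pick <- if (total_pos > 0L) {
        sample.int(total_pos, n_nuc, replace = TRUE)
      } else integer(0)
      g <- edge_gene[pick]; k <- edge_k[pick]
      jit <- round(stats::rnorm(n_nuc, 0, cfg$mnase_jitter_sd_bp))
      plus <- genes$strand[g] == "+"
      fr_len <- as.integer(len[!is_bg])
      s <- integer(n_nuc); e <- integer(n_nuc)
      s[plus] <- genes$start[g][plus] + k[plus] * sp + jit[plus]
      e[plus] <- s[plus] + fr_len[plus]
      e[!plus] <- genes$end[g][!plus] - k[!plus] * sp + jit[!plus]
      s[!plus] <- e[!plus] - fr_len[!plus]
      contig[!is_bg] <- genes$contig[g]
      start[!is_bg] <- s; end[!is_bg] <- e
    }
    if (n_bg > 0L) {
      seg_len <- allowed$end - allowed$start
      seg <- sample.int(nrow(allowed), n_bg, replace = TRUE,
                        prob = seg_len)
      off <- floor(stats::runif(n_bg, 0, seg_len[seg]))
      s <- as.integer(allowed$start[seg] + off)
      contig[is_bg] <- allowed$contig[seg]
      start[is_bg] <- s
      end[is_bg] <- s + as.integer(len[is_bg])
    }
    L <- genome$lengths[contig]
    start <- pmax(start, 0L)
    end <- pmin(end, as.integer(L))
    keep <- start < end
    data.frame(contig = contig[keep], start = start[keep],
               end = end[keep],
               strand = sample(c("+", "-"), sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# genome space outside gene bodies and their upstream NFR windows
background_space <- function(genome, genes, nfr_bp) {
  pieces <- lapply(names(genome$lengths), function(ctg) {
    L <- genome$lengths[[ctg]]
    g <- genes[genes$contig == ctg, , drop = FALSE]
    if (!nrow(g)) {
      return(data.frame(contig = ctg, start = 0L, end = L,
                        stringsAsFactors = FALSE))
    }
    nfr_s <- ifelse(g$strand == "+", g$start - nfr_bp, g$end)
    nfr_e <- ifelse(g$strand == "+", g$start, g$end + nfr_bp)
    blocked <- IRanges::reduce(IRanges::IRanges(
      start = pmax(c(g$start, nfr_s), 0L) + 1L,
      end = pmin(c(g$end, nfr_e), L)))
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), blocked)
    if (!length(free)) return(NULL)
    data.frame(contig = ctg, start = IRanges::start(free) - 1L,
               end = IRanges::end(free), stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
}
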