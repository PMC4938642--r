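# a small configuration keeping simulator tests fast
small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_nuclear_contigs = 1L,
               contig_length_bp = 40000L, mito_length_bp = 5000L,
               n_genes = 10L, gene_length_bp = 900L,
               n_domains = 3L, domain_length_bp = 2000L,
               chip_n_fragments = 3000L, mnase_n_fragments = 3000L,
               bs_mean_coverage = 10)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("simulators are pure functions of the seed", {
  cfg <- small_cfg(seed = 5L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome$sequences),
                   as.character(b$genome$sequences))
  expect_identical(a$genes, b$genes)
  expect_identical(a$domains, b$domains)
  expect_identical(simulate_chip(a$genome, a$genes, cfg),
                   simulate_chip(b$genome, b$genes, cfg))
  expect_identical(simulate_mnase(a$genome, a$genes, cfg),
                   simulate_mnase(b$genome, b$genes, cfg))
  expect_identical(simulate_bisulfite(a$genome, a$domains, cfg),
                   simulate_bisulfite(b$genome, b$domains, cfg))

  other <- simulate_genome(small_cfg(seed = 6L))
  expect_false(identical(as.character(a$genome$sequences),
                         as.character(other$genome$sequences)))
  expect_false(identical(
    simulate_bisulfite(a$genome, a$domains, cfg, seed = 5L),
    simulate_bisulfite(a$genome, a$domains, cfg, seed = 99L)))
})

test_that("simulated genes and domains are placed disjointly", {
  for (seed in c(2L, 3L)) {
    sim <- simulate_genome(small_cfg(seed = seed))
    feats <- rbind(sim$genes[, c("contig", "start", "end")],
                   sim$domains[, c("contig", "start", "end")])
    for (ctg in unique(feats$contig)) {
      f <- feats[feats$contig == ctg, ]
      f <- f[order(f$start), ]
      if (nrow(f) > 1L) {
        expect_true(all(f$start[-1L] >= f$end[-nrow(f)]))
      }
    }
    expect_true(all(sim$domains$contig != "mito"))
  }
})

test_that("degenerate feature counts behave", {
  sim0 <- simulate_genome(small_cfg(seed = 1L, n_domains = 0L))
  expect_equal(nrow(sim0$domains), 0L)
  sim <- simulate_genome(small_cfg(seed = 1L))
  expect_equal(assign_quintiles(sim$genes)$boundaries$n_genes, rep(2L, 5L))
  cfg0 <- small_cfg(seed = 1L, chip_n_fragments = 0L)
  expect_equal(nrow(simulate_chip(sim$genome, sim$genes, cfg0)), 0L)
  expect_error(small_cfg(seed = 1L, n_genes = 100L, n_domains = 50L),
               "80%")
})

test_that("noise-free bisulfite counts hit the deterministic limits", {
  cfg <- small_cfg(seed = 8L, nonconversion_rate = 0,
                   background_meth_freq = 0, domain_meth_freq = 1)
  sim <- simulate_genome(cfg)
  bs <- simulate_bisulfite(sim$genome, sim$domains, cfg)
  dom <- sim$domains
  inside <- rep(FALSE, nrow(bs))
  for (i in seq_len(nrow(dom))) {
    inside <- inside | (bs$contig == dom$contig[i] &
                          bs$pos >= dom$start[i] & bs$pos < dom$end[i])
  }
  expect_true(all(bs$m[inside] == bs$n[inside]))
  expect_true(all(bs$m[!inside] == 0L))
})

test_that("pooled mitochondrial ratio recovers the nonconversion rate", {
  # mito 5 kb x 2 strands ~ 2500 sites x 10 reads >> 1e5 site-reads
  cfg <- small_cfg(seed = 12L, mito_length_bp = 10000L,
                   bs_mean_coverage = 20)
  sim <- simulate_genome(cfg)
  bs <- simulate_bisulfite(sim$genome, sim$domains, cfg)
  mito <- bs[bs$contig == "mito", ]
  expect_gt(sum(mito$n), 1e5)
  expect_equal(estimate_nonconversion(bs, sim$genome), 0.005,
               tolerance = 0.002 / 0.005)
  expect_equal(mean(bs$n), cfg$bs_mean_coverage, tolerance = 0.02)
})

test_that("noise-free nucleosome arrays phase exactly at the repeat spacing", {
  cfg <- sim_config(seed = 30L, n_nuclear_contigs = 1L,
                    contig_length_bp = 30000L, mito_length_bp = 2000L,
                    n_genes = 1L, gene_length_bp = 2000L, n_domains = 0L,
                    mnase_jitter_sd_bp = 0, mnase_n_fragments = 4000L)
  sim <- simulate_genome(cfg)
  gene <- sim$genes
  fr <- simulate_mnase(sim$genome, gene, cfg)
  # background fragments never lie fully inside a gene body, so fragments
  # with both endpoints in the gene are exactly the nucleosomal ones
  genic <- fr$start >= gene$start & fr$end <= gene$end
  offs <- if (gene$strand == "+") {
    fr$start[genic] - gene$start
  } else {
    (gene$end - 1L) - (fr$end[genic] - 1L)
  }
  expect_gt(sum(genic), 100L)
  expect_true(all(offs %% cfg$mnase_spacing_bp == 0L))
})

test_that("minus-strand genes mirror the plus-strand edge profile", {
  base <- list(seed = 31L, n_nuclear_contigs = 1L,
               contig_length_bp = 30000L, mito_length_bp = 2000L,
               n_genes = 1L, gene_length_bp = 2000L, n_domains = 0L,
               mnase_jitter_sd_bp = 0, mnase_n_fragments = 20000L)
  cfg <- do.call(sim_config, base)
  sim <- simulate_genome(cfg)
  gplus <- sim$genes; gplus$strand <- "+"
  gminus <- sim$genes; gminus$strand <- "-"
  prof_p <- suppressWarnings(
    edge_profile(simulate_mnase(sim$genome, gplus, cfg),
                 gplus, sim$genome, flank_bp = 600L))
  prof_m <- suppressWarnings(
    edge_profile(simulate_mnase(sim$genome, gminus, cfg),
                 gminus, sim$genome, flank_bp = 600L))
  peaks <- function(p) p$offset[p$value > 0 &
                                  p$offset >= 0 & p$offset < 600L]
  expect_equal(peaks(prof_p), peaks(prof_m))
  expect_equal(peaks(prof_p), c(0L, 200L, 400L))
})

test_that("unphysical nucleosome spacing is rejected", {
  expect_error(
    simulate_mnase(simulate_genome(small_cfg(1L))$genome,
                   simulate_genome(small_cfg(1L))$genes,
                   small_cfg(1L, mnase_spacing_bp = 100L)),
    "spacing")
})

test_that("sim_config validates rates and mandatory seed", {
  expect_error(sim_config(), "seed")
  expect_error(small_cfg(seed = 1L, domain_meth_freq = 1.2), "\\[0, 1\\]")
  expect_error(small_cfg(seed = 1L, nonconversion_rate = -0.1),
               "\\[0, 1\\]")
  expect_error(small_cfg(seed = 1L, chip_nuclear_enrichment = 0.5),
               ">= 1")
})
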