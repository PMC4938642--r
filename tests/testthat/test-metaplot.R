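test_that("quintile assignment splits ranked genes with remainders to the top groups", {
  genes <- make_genes(10L, rpkm = 10:1)
  q <- assign_quintiles(genes)
  expect_equal(q$assignment$quintile, rep(1:5, each = 2L))
  expect_equal(q$assignment$gene_id[q$assignment$quintile == 1L],
               c("g001", "g002"))
  expect_equal(q$assignment$gene_id[q$assignment$quintile == 5L],
               c("g009", "g010"))
  expect_equal(q$boundaries$max_rpkm, c(10, 8, 6, 4, 2))
  expect_equal(q$boundaries$min_rpkm, c(9, 7, 5, 3, 1))

  # all-tied genes fall back to gene_id order, equal group sizes
  tied <- assign_quintiles(make_genes(10L, rpkm = rep(0, 10L)))
  expect_equal(tied$assignment$gene_id, sprintf("g%03d", 1:10))
  expect_equal(tied$boundaries$n_genes, rep(2L, 5L))

  seven <- assign_quintiles(make_genes(7L))
  expect_equal(seven$boundaries$n_genes, c(2L, 2L, 1L, 1L, 1L))

  expect_error(assign_quintiles(make_genes(4L)), "at least 5")
})

test_that("a constant field gives a flat metaplot of that constant", {
  gen <- make_genome(c(chr1 = 20000L, mito = 1000L))
  bt <- make_base_track(gen)
  bt$values$chr1[] <- 1
  genes <- make_genes(6L)
  prof <- gene_metaplot(bt, genes, "TSS", flank_bp = 500L, bin_bp = 10L)
  expect_equal(prof$value, rep(1, 100L))
  expect_equal(prof$group, rep("all", 100L))
})

test_that("a unit impulse lands in the oriented bin containing its offset", {
  gen <- make_genome(c(chr1 = 20000L, mito = 1000L))
  gplus <- make_genes(1L, strand = "+")
  tss <- gene_anchors(gplus, "TSS")
  bt <- make_base_track(gen)
  bt$values$chr1[tss + 25L + 1L] <- 1
  prof <- gene_metaplot(bt, gplus, "TSS", flank_bp = 100L, bin_bp = 10L)
  expect_equal(prof$value[prof$offset == 20L], 0.1)
  expect_equal(sum(prof$value), 0.1)

  # the mirror impulse on a minus-strand gene maps to the same bin
  gminus <- make_genes(1L, strand = "-")
  tssm <- gene_anchors(gminus, "TSS")
  btm <- make_base_track(gen)
  btm$values$chr1[tssm - 25L + 1L] <- 1
  profm <- gene_metaplot(btm, gminus, "TSS", flank_bp = 100L, bin_bp = 10L)
  expect_equal(profm$value[profm$offset == 20L], 0.1)
  expect_equal(sum(profm$value), 0.1)
})

test_that("gene_metaplot matches the brute-force per-gene per-base oracle", {
  withr::with_seed(41, {
    gen <- make_genome(c(chr1 = 9000L, mito = 1000L))
    bt <- make_base_track(gen)
    bt$values$chr1 <- rpois(9000L, 2)
    starts <- sort(sample(200:8000, 20L))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:20), contig = "chr1",
                        strand = sample(c("+", "-"), 20L, TRUE),
                        start = starts, end = starts + 150L,
                        rpkm = rexp(20L), stringsAsFactors = FALSE)
    for (anchor in c("TSS", "TTS")) {
      got <- gene_metaplot(bt, genes, anchor, flank_bp = 300L,
                           bin_bp = 10L)
      expect_equal(got$value, bf_gene_metaplot(bt, genes, anchor,
                                               300L, 10L))
    }
  })
})

test_that("metaplots are invariant under strand flip plus signal mirror", {
  withr::with_seed(43, {
    L <- 8000L
    gen <- make_genome(c(chr1 = L, mito = 1000L))
    bt <- make_base_track(gen)
    bt$values$chr1 <- runif(L)
    starts <- sort(sample(1000:6000, 10L))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:10), contig = "chr1",
                        strand = sample(c("+", "-"), 10L, TRUE),
                        start = starts, end = starts + 400L,
                        rpkm = rexp(10L), stringsAsFactors = FALSE)
    flipped <- genes
    flipped$strand <- ifelse(genes$strand == "+", "-", "+")
    flipped$start <- L - genes$end
    flipped$end <- L - genes$start
    btf <- make_base_track(gen)
    btf$values$chr1 <- rev(bt$values$chr1)
    a <- gene_metaplot(bt, genes, "TSS", 500L, 10L)
    b <- gene_metaplot(btf, flipped, "TSS", 500L, 10L)
    expect_equal(a$value, b$value)
  })
})

test_that("group-size-weighted quintile profiles reproduce the all-genes profile", {
  withr::with_seed(47, {
    gen <- make_genome(c(chr1 = 40000L, mito = 1000L))
    bt <- make_base_track(gen)
    bt$values$chr1 <- rpois(40000L, 3)
    genes <- make_genes(13L, rpkm = rexp(13L))
    grouping <- assign_quintiles(genes)
    per_q <- gene_metaplot(bt, genes, "TSS", 400L, 10L,
                           grouping = grouping)
    all_g <- gene_metaplot(bt, genes, "TSS", 400L, 10L)
    weighted <- sapply(split(per_q, per_q$offset), function(d) {
      weighted.mean(d$value, d$n_genes)
    })
    expect_equal(unname(weighted[as.character(all_g$offset)]),
                 all_g$value)
  })
})

test_that("heatmap rows are expression-ordered and column means match the profile", {
  withr::with_seed(53, {
    gen <- make_genome(c(chr1 = 30000L, mito = 1000L))
    bt <- make_base_track(gen)
    bt$values$chr1 <- rpois(30000L, 2)
    genes <- make_genes(3L, rpkm = c(5, 1, 9))
    hm <- heatmap_matrix(bt, genes, "TSS", 300L, 10L)
    expect_equal(rownames(hm), c("g003", "g001", "g002"))
    prof <- gene_metaplot(bt, genes, "TSS", 300L, 10L)
    expect_equal(unname(colMeans(hm)), prof$value)

    flat <- make_base_track(gen)
    flat$values$chr1[] <- 2.5
    hm2 <- heatmap_matrix(flat, genes, "TSS", 300L, 10L)
    expect_true(all(hm2 == 2.5))
  })
})

test_that("domain metaplot saturates at 100% and pools counts coverage-weighted", {
  gen_len <- 10000L
  withr::with_seed(59, {
    pos <- sort(sample(0:(gen_len - 1L), 2500L))
    n <- rpois(2500L, 10) + 1L
    sat <- make_report("chr1", pos, "+", n, n)
    domains <- data.frame(contig = "chr1", start = c(2000L, 6000L),
                          end = c(3000L, 7500L))
    dm <- domain_metaplot(sat, domains, min_coverage = 1L)
    expect_equal(nrow(dm), 60L)
    expect_true(all(dm$value[!is.na(dm$value)] == 100))

    # coverage-weighted mean over body bins == pooled level of all bodies
    m <- rbinom(2500L, n, 0.5)
    rep0 <- make_report("chr1", pos, "+", m, n)
    dm2 <- domain_metaplot(rep0, domains, min_coverage = 1L)
    body <- dm2$section == "body"
    pooled <- pool_counts(rep0, domains, min_coverage = 1L)
    expect_equal(weighted.mean(dm2$value[body], dm2$n_pooled[body]),
                 100 * pooled[["m"]] / pooled[["n"]])
  })
})

test_that("short domains are skipped with a warning", {
  rep0 <- make_report("chr1", 1:50 * 2L, "+", 1L, 4L)
  domains <- data.frame(contig = "chr1", start = c(0L, 40L),
                        end = c(10L, 90L))
  expect_warning(dm <- domain_metaplot(rep0, domains, min_coverage = 1L),
                 "skipped")
  expect_equal(attr(dm, "n_domains"), 1L)
  expect_error(
    suppressWarnings(domain_metaplot(rep0, domains[1L, ],
                                     min_coverage = 1L)),
    "no domain")
})
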