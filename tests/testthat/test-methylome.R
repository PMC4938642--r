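test_that("nonconversion is the coverage-weighted pooled mitochondrial ratio", {
  gen <- make_genome(c(chr1 = 1000L, mito = 1000L))
  rep0 <- make_report(c("mito", "mito", "chr1"), c(10L, 20L, 5L),
                      "+", c(2L, 3L, 50L), c(400L, 600L, 100L))
  expect_equal(estimate_nonconversion(rep0, gen), 0.005)

  perfect <- make_report("mito", c(1L, 2L), "+", c(0L, 0L), c(10L, 20L))
  expect_equal(estimate_nonconversion(perfect, gen), 0)

  nuclear_only <- make_report("chr1", 5L, "+", 1L, 10L)
  expect_error(estimate_nonconversion(nuclear_only, gen),
               "no mitochondrial sites")
  uncovered <- make_report("mito", 5L, "+", 0L, 0L)
  expect_error(estimate_nonconversion(uncovered, gen), "zero total")
})

test_that("call_sites applies the coverage floor, binomial tail and BH gate", {
  rep0 <- make_report("chr1", c(1L, 2L, 3L, 4L), "+",
                      c(2L, 0L, 10L, 1L), c(2L, 8L, 10L, 9L))
  calls <- call_sites(rep0, nonconversion = 0.005, min_coverage = 3L)
  # n = 2 < 3: untested, no p-value, never in the BH family
  expect_equal(calls$status[1L], "insufficient_coverage")
  expect_true(is.na(calls$p_value[1L]))
  # m = 0: p is exactly 1, never methylated
  expect_equal(calls$p_value[2L], 1)
  expect_equal(calls$status[2L], "unmethylated")
  # fully methylated deep site: closed-form tail p = 0.005^10
  expect_equal(calls$p_value[3L], 0.005^10)
  expect_equal(calls$status[3L], "methylated")
  # BH family is exactly the tested sites
  tested_p <- calls$p_value[-1L]
  expect_equal(calls$q_value[-1L], bf_bh(tested_p))

  expect_error(call_sites(rep0, nonconversion = 1), "\\[0, 1\\)")
})

test_that("BH correction matches the step-up reference on random p-vectors", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4L))
  expect_equal(bf_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  withr::with_seed(21, {
    for (len in c(1L, 2L, 17L, 300L, 1000L)) {
      p <- runif(len)^sample(1:3, 1L)
      expect_equal(stats::p.adjust(p, "BH"), bf_bh(p))
    }
  })
})

test_that("count_methylated counts only methylated calls", {
  expect_equal(count_methylated(data.frame(status = character())), 0L)
  calls <- data.frame(status = c("insufficient_coverage", "unmethylated",
                                 "methylated", "methylated"))
  expect_equal(count_methylated(calls), 2L)
  expect_equal(count_methylated(
    data.frame(status = rep("insufficient_coverage", 5))), 0L)
})

test_that("weighted_level pools counts over qualifying sites", {
  rep0 <- make_report("chr1", c(10L, 20L), "+", c(3L, 7L), c(10L, 10L))
  region <- data.frame(contig = "chr1", start = 0L, end = 100L)
  expect_equal(weighted_level(rep0, region), 50)

  sat <- make_report("chr1", c(10L, 20L), "+", c(5L, 9L), c(5L, 9L))
  expect_equal(weighted_level(sat, region), 100)

  empty_reg <- data.frame(contig = "chr1", start = 500L, end = 600L)
  expect_true(is.na(weighted_level(rep0, empty_reg)))

  # sites below the coverage floor are excluded from both sums
  mixed <- make_report("chr1", c(10L, 20L), "+", c(2L, 5L), c(2L, 10L))
  expect_equal(weighted_level(mixed, region, min_coverage = 3L), 50)
})

test_that("weighted_level equals the coverage-weighted mean of site levels", {
  withr::with_seed(9, {
    n <- rpois(200L, 15)
    m <- rbinom(200L, n, 0.3)
    rep0 <- make_report("chr1", seq_len(200L) * 3L, "+", m, n)
    region <- data.frame(contig = "chr1", start = 0L, end = 1000L)
    keep <- n >= 3L
    oracle <- 100 * sum(m[keep] * 1) / sum(n[keep])
    oracle2 <- 100 * weighted.mean((m / n)[keep], w = n[keep])
    expect_equal(weighted_level(rep0, region), oracle)
    expect_equal(weighted_level(rep0, region), oracle2)
  })
})

test_that("raising m never decreases the methylated count or any weighted level", {
  withr::with_seed(33, {
    n <- rpois(500L, 10)
    m <- rbinom(500L, n, 0.2)
    rep0 <- make_report("chr1", seq_len(500L) * 2L, "+", m, n)
    bumped <- rep0
    bumped$m <- pmin(rep0$m + 1L, rep0$n)
    nc <- 0.01
    expect_gte(count_methylated(call_sites(bumped, nc)),
               count_methylated(call_sites(rep0, nc)))
    region <- data.frame(contig = "chr1", start = 0L, end = 2000L)
    expect_gte(weighted_level(bumped, region), weighted_level(rep0, region))
  })
})

test_that("methylation_track windows agree with weighted_level per window", {
  gen <- make_genome(c(chr1 = 3000L, mito = 1000L))
  withr::with_seed(13, {
    pos <- sort(sample(0:2999, 300L))
    n <- rpois(300L, 10)
    m <- rbinom(300L, n, 0.4)
    rep0 <- make_report("chr1", pos, "+", m, n)
  })
  tr <- methylation_track(rep0, gen, window_bp = 1000L)
  wins <- tr[tr$contig == "chr1", ]
  for (i in seq_len(nrow(wins))) {
    expect_equal(wins$value[i],
                 weighted_level(rep0, wins[i, c("contig", "start", "end")]))
  }
})

test_that("shared-site distributions are symmetric and saturate correctly", {
  rep0 <- make_report("chr1", 1:20 * 5L, "+", 18L, 20L)
  calls <- call_sites(rep0, 0.005)
  d <- shared_site_distribution(calls, calls)
  expect_equal(d$percent_a, d$percent_b)
  expect_equal(sum(d$percent_a), 100)

  sat <- make_report("chr1", 1:20 * 5L, "+", 20L, 20L)
  csat <- call_sites(sat, 0.005)
  dsat <- shared_site_distribution(csat, csat)
  expect_equal(dsat$percent_a[nrow(dsat)], 100)

  unm <- call_sites(make_report("chr1", 1:5 * 7L, "+", 0L, 20L), 0.005)
  expect_warning(d0 <- shared_site_distribution(calls, unm), "no shared")
  expect_equal(nrow(d0), 0L)
})

test_that("find_dmrs returns nothing for self-comparison or sub-threshold differences", {
  gen <- make_genome(c(chr1 = 20000L, mito = 2000L))
  withr::with_seed(17, {
    pos <- sort(sample(0:19999, 2000L))
    n <- rpois(2000L, 20) + 3L
    m <- rbinom(2000L, n, 0.3)
    rep_a <- make_report("chr1", pos, "+", m, n)
  })
  expect_equal(nrow(find_dmrs(rep_a, rep_a, gen)), 0L)

  # a uniform 5-point shift is gated out by dmr_min_diff = 20 regardless of p
  rep_b <- rep_a
  rep_b$m <- round(rep_a$n * pmin(1, rep_a$m / rep_a$n + 0.05))
  expect_equal(nrow(find_dmrs(rep_a, rep_b, gen, dmr_min_diff = 20)), 0L)
  # the same shift is found once the gate allows it
  expect_gt(nrow(find_dmrs(rep_a, rep_b, gen, dmr_min_diff = 2)), 0L)
})
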