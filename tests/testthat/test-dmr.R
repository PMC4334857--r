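test_that("candidate regions are the coalesced union of both peak lists", {
  ctrl <- genomic_intervals("chr1", 100, 300)
  case <- genomic_intervals("chr1", 250, 500)
  cand <- merge_candidate_regions(ctrl, case)
  expect_equal(cand[, c("start", "end")],
               data.frame(start = 100, end = 500), ignore_attr = TRUE)

  d1 <- genomic_intervals(c("chr1", "chr1"), c(0, 1000), c(100, 1100))
  d2 <- genomic_intervals("chr1", 5000, 5100)
  cand2 <- merge_candidate_regions(d1, d2)
  expect_equal(cand2$start, c(0, 1000, 5000))

  # brute-force bp membership oracle on random interval unions
  set.seed(23)
  for (rep in 1:3) {
    s1 <- sample.int(19000, 500); s2 <- sample.int(19000, 500)
    a <- genomic_intervals("chr1", s1, s1 + sample(50:500, 500, TRUE))
    b <- genomic_intervals("chr1", s2, s2 + sample(50:500, 500, TRUE))
    u <- merge_candidate_regions(a, b)
    expect_equal(bp_membership(u, 20000),
                 bp_membership(a, 20000) | bp_membership(b, 20000))
    # disjoint, sorted
    expect_true(all(u$start[-1] > u$end[-nrow(u)]))
  }
})

test_that("the continuity-corrected chi-square matches the textbook oracle", {
  # identical proportions: zero statistic
  r0 <- chisq_test_2x2(10, 990, 10, 990)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)

  r1 <- chisq_test_2x2(10, 990, 40, 960)
  o1 <- stats::chisq.test(matrix(c(10, 990, 40, 960), 2, byrow = TRUE),
                          correct = TRUE)
  expect_equal(r1$chi2, unname(o1$statistic), tolerance = 1e-9)
  expect_equal(r1$p_value, o1$p.value, tolerance = 1e-9)
  expect_equal(r1$chi2, 17.25, tolerance = 0.01)

  # row swap symmetry
  r2 <- chisq_test_2x2(40, 960, 10, 990)
  expect_equal(r2$chi2, r1$chi2)

  # 1000 random tables against stats::chisq.test with Yates correction
  set.seed(29)
  for (i in 1:1000) {
    tb <- rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1
    got <- chisq_test_2x2(tb[1], tb[2], tb[3], tb[4])
    want <- suppressWarnings(
      stats::chisq.test(matrix(tb, 2, byrow = TRUE), correct = TRUE))
    expect_equal(got$chi2, unname(want$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  }

  # degenerate margin
  rd <- chisq_test_2x2(0, 100, 0, 100)
  expect_equal(rd$chi2, 0)
  expect_equal(rd$p_value, 1)
  expect_error(chisq_test_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("BH adjustment equals its brute-force definition", {
  bh_brute <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    q <- rev(cummin(p[o] * m / rank(p, ties.method = "max")[o]))
    pmin(1, q)[order(order(p))]
  }
  set.seed(37)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p))
  }
})

# Helper: a two-sample comparison with counts placed by hand. Reads are
# single-bp intervals; extension 0 keeps them in place.
two_sample_dmr <- function(region_counts, urc = 1e6, ...) {
  cs <- toy_chrom_sizes(1, 1e6)
  mk <- function(n_in) {
    pos <- c(seq(1000, by = 2, length.out = n_in),
             seq(500000, by = 2, length.out = 1000))
    aligned_read_set(genomic_intervals("chr1", pos, pos + 1), urc = urc)
  }
  cand <- genomic_intervals("chr1", 0, 100000)
  call_dmrs(cand, mk(region_counts[1]), mk(region_counts[2]), cs,
            fragment_extension_bp = 0, ...)
}

test_that("the fold gate blocks sub-threshold folds regardless of p-value", {
  # 1.9-fold with enormous counts: q tiny but not emitted
  d <- two_sample_dmr(c(10000, 19000))
  expect_equal(nrow(d), 0)
  # 2.0-fold is emitted as hyper
  d2 <- two_sample_dmr(c(10000, 20000))
  expect_equal(d2$direction, "hyper")
  expect_gte(d2$fold, 2)
  # and the mirror image as hypo
  d3 <- two_sample_dmr(c(20000, 10000))
  expect_equal(d3$direction, "hypo")
})

test_that("tightening q or fold thresholds only shrinks the DMR set", {
  cfg <- sim_config(n_genes = 60, n_cgis = 40, reads_per_sample = 60000,
                    n_case_samples = 1, n_planted_hyper = 10,
                    n_planted_hypo = 10, seed = 12)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  cs <- sim$annotation$chrom_sizes
  cand <- merge_candidate_regions(call_peaks(reads$control, cs),
                                  call_peaks(reads$case1, cs))
  base <- call_dmrs(cand, reads$control, reads$case1, cs)
  tight_q <- call_dmrs(cand, reads$control, reads$case1, cs, q_max = 0.01)
  tight_f <- call_dmrs(cand, reads$control, reads$case1, cs, min_fold = 3)
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_true(all(key(tight_q) %in% key(base)))
  expect_true(all(key(tight_f) %in% key(base)))
  expect_lte(nrow(tight_q), nrow(base))
  expect_lte(nrow(tight_f), nrow(base))
})

# Construct a per-sample DMR list with one DMR overlapping segment
# [1000, 1500) by a chosen width.
support_fixture <- function(overlaps, direction = "hyper") {
  lapply(overlaps, function(w) {
    if (is.na(w)) {
      d <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0))
    } else {
      d <- data.frame(chrom = "chr1", start = 1500 - w, end = 2000,
                      direction = direction, stringsAsFactors = FALSE)
    }
    d
  })
}

test_that("ultra-DMR consensus enforces the >half support and >250 bp gates", {
  cs <- toy_chrom_sizes(1, 3000)
  # overlap 300 bp in 4 of 6 samples: segment [1000,1500) is ultra hyper
  dl <- support_fixture(c(300, 300, 300, 300, NA, NA))
  u <- ultra_dmrs(dl, cs)
  useg <- u[u$start == 1000, ]
  expect_equal(useg$direction, "hyper")
  expect_equal(useg$support, 4L)

  # 3 of 6 is not more than half
  u3 <- ultra_dmrs(support_fixture(c(300, 300, 300, NA, NA, NA)), cs)
  expect_false(any(u3$start == 1000))

  # exactly 250 bp overlap does not count (strict inequality)
  u250 <- ultra_dmrs(support_fixture(c(250, 250, 250, 250, 300, 300)), cs)
  expect_false(any(u250$start == 1000))
  u251 <- ultra_dmrs(support_fixture(c(251, 251, 251, 251, NA, NA)), cs)
  expect_true(any(u251$start == 1000))

  # 2 of 3 samples qualifies
  u23 <- ultra_dmrs(support_fixture(c(300, 300, NA)), cs)
  expect_equal(u23$support[u23$start == 1000], 2L)

  # a segment supported in both directions (each sample's DMR list holds a
  # hyper and a hypo region over it) is dropped
  both <- Map(rbind, support_fixture(c(300, 300, 300, 300)),
              support_fixture(c(300, 300, 300, 300), direction = "hypo"))
  expect_message(ub <- ultra_dmrs(both, cs), "both directions")
  expect_false(any(ub$start == 1000))
  expect_equal(attr(ub, "n_conflicts"), 2L)  # both segments the DMRs span
})

test_that("planted effects are recovered by the full two-sample comparison", {
  cfg <- sim_config(seed = 2, n_case_samples = 1)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  cs <- sim$annotation$chrom_sizes
  cand <- merge_candidate_regions(call_peaks(reads$control, cs),
                                  call_peaks(reads$case1, cs))
  dm <- call_dmrs(cand, reads$control, reads$case1, cs)
  tr <- sim$truth$regions
  ov <- vapply(seq_len(nrow(tr)), function(i) {
    d <- dm[dm$direction == tr$direction[i] & dm$chrom == tr$chrom[i], ]
    any(d$start < tr$end[i] & d$end > tr$start[i])
  }, TRUE)
  expect_gte(mean(ov), 0.9)
  # q_value >= p_value under BH, direction consistent with fold
  expect_true(all(dm$q_value >= dm$p_value - 1e-15))
  expect_true(all((dm$fold > 1) == (dm$direction == "hyper")))
})
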