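promoter_row <- function(strand = "+", tss = 10000, chrom = "chr1",
                         gene_id = "g1") {
  p <- genomic_intervals(chrom, tss - 2000, tss + 2000, strand = strand,
                         gene_id = gene_id, tss = tss)
  p$clipped <- FALSE
  p
}

test_that("promoter binarization marks peak-covered 100 bp windows", {
  prom <- promoter_row("+")
  peaks <- genomic_intervals("chr1", 8000, 8500)
  cgis <- genomic_intervals("chr1", 9500, 10500)
  m <- binarize_promoter(prom, peaks, cgis)
  expect_equal(which(m$methyl_mask), 1:5)
  expect_equal(which(m$cgi_mask), 16:25)
  expect_length(m$methyl_mask, 40)

  # no peaks: all-false mask
  m0 <- binarize_promoter(prom, peaks[0, ], cgis)
  expect_false(any(m0$methyl_mask))
})

test_that("minus-strand promoters are read 5' to 3' in gene orientation", {
  prom_minus <- promoter_row("-")
  peaks <- genomic_intervals("chr1", 8000, 8500)  # genomic-left 500 bp
  cgis <- genomic_intervals("chr1", 9500, 10500)
  m <- binarize_promoter(prom_minus, peaks, cgis)
  # coordinate-reversal oracle: genomic windows 1-5 become windows 36-40
  expect_equal(which(m$methyl_mask), 36:40)
  expect_equal(which(m$cgi_mask), 16:25)
})

test_that("each of the five patterns classifies from its fixture", {
  expect_equal(classify_pattern(mask_fixture(16:24, 15:25)), "CGI_CONFINED")
  expect_equal(classify_pattern(mask_fixture(1:5, 20:30)), "SHORE_5PRIME")
  expect_equal(classify_pattern(mask_fixture(35:40, 20:30)), "SHORE_3PRIME")
  expect_equal(classify_pattern(mask_fixture(c(10:19), 18:30)), "CGI_OVERLAP")
  expect_equal(classify_pattern(mask_fixture(10:20, integer(0))), "NO_CGI")
  expect_error(classify_pattern(mask_fixture(integer(0), 10:20)),
               "methylated")
})

test_that("the confinement rule uses the larger-than-half overlap condition", {
  # overlap 9 > |M|/2 = 4.5
  m <- mask_fixture(16:24, 15:25)
  expect_gt(sum(m$methyl_mask & m$cgi_mask), sum(m$methyl_mask) / 2)
  expect_equal(classify_pattern(m), "CGI_CONFINED")
  # overlap exactly half of M and of C: not confined
  half <- mask_fixture(11:20, 16:25)  # overlap 5 of |M| 10, |C| 10
  expect_equal(classify_pattern(half), "CGI_OVERLAP")
})

test_that("classification is invariant under strand reflection", {
  set.seed(53)
  cgis <- genomic_intervals("chr1", 9500, 10500)
  for (i in 1:25) {
    s <- sort(sample(seq(8000, 11800, by = 100), 2))
    peaks <- genomic_intervals("chr1", s[1], s[2] + 100)
    plus <- binarize_promoter(promoter_row("+"), peaks, cgis)
    # reflect everything about the TSS: peak and CGI mirror coordinates
    refl <- function(df) genomic_intervals(df$chrom, 2 * 10000 - df$end,
                                           2 * 10000 - df$start)
    minus <- binarize_promoter(promoter_row("-"), refl(peaks), refl(cgis))
    expect_equal(minus$methyl_mask, plus$methyl_mask)
    expect_equal(minus$cgi_mask, plus$cgi_mask)
    if (any(plus$methyl_mask))
      expect_equal(classify_pattern(minus), classify_pattern(plus))
  }
})

test_that("case- and control-specific promoters honor the support gates", {
  meth <- mask_fixture(1:5, 20:30)
  unmeth <- mask_fixture(integer(0), 20:30)

  # methylated in 4/6 cases, control unmethylated -> case specific
  calls <- select_specific_promoters(
    lapply(c(1, 1, 1, 1, 0, 0), function(x)
      list(if (x) meth else unmeth)), list(unmeth))
  expect_equal(calls$specificity, "case_specific")
  expect_equal(calls$pattern, "SHORE_5PRIME")
  expect_equal(calls$n_supporting_samples, 4L)

  # 3/6 is excluded
  none <- select_specific_promoters(
    lapply(c(1, 1, 1, 0, 0, 0), function(x)
      list(if (x) meth else unmeth)), list(unmeth))
  expect_equal(nrow(none), 0)

  # control methylated, no case methylation -> control specific
  ctrl <- select_specific_promoters(
    lapply(rep(0, 6), function(x) list(unmeth)), list(meth))
  expect_equal(ctrl$specificity, "control_specific")

  # control methylated but 3 cases methylated: neither category (3 > 6-4)
  mid <- select_specific_promoters(
    lapply(c(1, 1, 1, 0, 0, 0), function(x)
      list(if (x) meth else unmeth)), list(meth))
  expect_equal(nrow(mid), 0)
})

test_that("a classified promoter set forms a partition over patterns", {
  cfg <- sim_config(seed = 4, n_case_samples = 3, reads_per_sample = 100000)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  cs <- sim$annotation$chrom_sizes
  pk <- lapply(reads, call_peaks, chrom_sizes = cs)
  ctrl <- promoter_masks(sim$annotation, pk$control)
  cases <- lapply(names(pk)[-1], function(nm)
    promoter_masks(sim$annotation, pk[[nm]]))
  calls <- select_specific_promoters(cases, ctrl, min_case_support = 2)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$pattern %in% c("CGI_CONFINED", "SHORE_5PRIME",
                                       "SHORE_3PRIME", "CGI_OVERLAP",
                                       "NO_CGI")))
  expect_equal(anyDuplicated(calls$gene_id), 0)
  expect_true(all(nchar(calls$methyl_mask) == 40))
  # NO_CGI exactly when the promoter lacks CGI windows
  expect_equal(calls$pattern == "NO_CGI",
               !grepl("1", calls$cgi_mask))
})
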