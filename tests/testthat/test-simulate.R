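# The generator's own contracts: determinism, conservation, the fraction of
# CGI promoters, and the planted fold effect on normalized coverage.

small_cfg <- function(...) {
  defaults <- list(n_genes = 60, n_cgis = 40, reads_per_sample = 30000,
                   n_case_samples = 1, n_planted_hyper = 10,
                   n_planted_hypo = 10)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("a fixed seed reproduces reads and expression byte-identically", {
  cfg <- small_cfg(seed = 4)
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads$control$reads, b$reads$control$reads)
  expect_identical(a$reads$case1$reads, b$reads$case1$reads)
  expect_identical(a$expression, b$expression)

  # and the written artifacts too
  d1 <- tempfile(); d2 <- tempfile()
  simulate_methylome(cfg, out_dir = d1)
  simulate_methylome(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("reads written per sample equal the reported URC, within +/-20% of nominal", {
  cfg <- small_cfg(seed = 2)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  for (r in reads) {
    expect_equal(nrow(r$reads), r$urc)
    expect_true(abs(r$urc / cfg$reads_per_sample - 1) <= 0.2)
    # per-chromosome counts sum to the library size (conservation)
    expect_equal(sum(table(r$reads$chrom)), r$urc)
  }
})

test_that("planted regions are pairwise non-overlapping and inside the genome", {
  for (seed in 1:3) {
    sim <- simulate_genome(small_cfg(seed = seed))
    tr <- sim$truth$regions
    expect_true(all(tr$start >= 0 & tr$end <= 5e6 & tr$start < tr$end))
    gr <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(tr$start + 1, tr$end))
    expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0)
  }
})

test_that("about 60% of gene promoters carry a CGI", {
  fr <- vapply(1:10, function(seed) {
    sim <- simulate_genome(sim_config(seed = seed))
    mean(overlaps_any <- IRanges::overlapsAny(
      GenomicRanges::GRanges(sim$annotation$promoters$chrom,
                             IRanges::IRanges(sim$annotation$promoters$start + 1,
                                              sim$annotation$promoters$end)),
      GenomicRanges::GRanges(sim$annotation$cgis$chrom,
                             IRanges::IRanges(sim$annotation$cgis$start + 1,
                                              sim$annotation$cgis$end))))
  }, 0)
  expect_true(all(fr >= 0.5 & fr <= 0.7))
})

test_that("no CGIs means every promoter is CGI-free", {
  cfg <- small_cfg(seed = 3, n_cgis = 0,
                   feature_targets = c("no-CGI-promoter", "intergenic"))
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotation$cgis), 0)
  expect_equal(nrow(sim$annotation$shores), 0)
})

test_that("requests beyond genome capacity fail loudly", {
  expect_error(simulate_genome(sim_config(n_genes = 5000, seed = 1)),
               "capacity")
})

test_that("planted 4-fold hyper regions show a ~4-fold normalized coverage ratio", {
  ratios <- c()
  for (seed in 1:8) {
    cfg <- small_cfg(seed = seed, reads_per_sample = 60000)
    sim <- simulate_genome(cfg)
    reads <- simulate_reads(sim, cfg)
    cs <- sim$annotation$chrom_sizes
    tr <- sim$truth$regions[sim$truth$regions$direction == "hyper", ]
    a <- medipdmr:::count_reads_in_regions(reads$control, tr, cs)
    b <- medipdmr:::count_reads_in_regions(reads$case1, tr, cs)
    # ratio of totals: per-region ratios are unstable at low counts
    ratios <- c(ratios, (sum(b) / reads$case1$urc) /
                  (sum(a) / reads$control$urc))
  }
  expect_equal(mean(ratios), 4, tolerance = 0.1)
})

test_that("null effect (fold 1) leaves case and control rates identical", {
  cfg <- small_cfg(seed = 6, effect_fold = 1, reads_per_sample = 60000)
  sim <- simulate_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  cs <- sim$annotation$chrom_sizes
  tr <- sim$truth$regions
  a <- medipdmr:::count_reads_in_regions(reads$control, tr, cs)
  b <- medipdmr:::count_reads_in_regions(reads$case1, tr, cs)
  prop_ratio <- (sum(b) / reads$case1$urc) / (sum(a) / reads$control$urc)
  expect_equal(prop_ratio, 1, tolerance = 0.1)
})

test_that("expression coupling represses hyper-CGI genes about 2^coupling-fold", {
  fold <- c()
  for (seed in 1:20) {
    cfg <- small_cfg(seed = seed, expression_coupling_strength = log2(3))
    sim <- simulate_genome(cfg)
    ex <- simulate_expression(sim, cfg)
    rep_genes <- ex$gene_id %in% sim$truth$repressed_genes
    if (!any(rep_genes)) next
    case_mean <- rowMeans(ex[rep_genes, grep("^case", names(ex)),
                             drop = FALSE])
    ctrl_mean <- rowMeans(ex[rep_genes, grep("^control", names(ex)),
                             drop = FALSE])
    fold <- c(fold, case_mean / ctrl_mean)
  }
  expect_equal(mean(fold), 1 / 3, tolerance = 0.1)

  # no coupling: repressed set behaves like the rest
  cfg0 <- small_cfg(seed = 9, expression_coupling_strength = 0)
  sim0 <- simulate_genome(cfg0)
  ex0 <- simulate_expression(sim0, cfg0)
  rg <- ex0$gene_id %in% sim0$truth$repressed_genes
  lfc <- log2((rowMeans(ex0[, grep("^case", names(ex0)), drop = FALSE]) + 1) /
                (rowMeans(ex0[, grep("^control", names(ex0)),
                              drop = FALSE]) + 1))
  expect_lt(abs(mean(lfc[rg]) - mean(lfc[!rg])), 0.5)
})
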