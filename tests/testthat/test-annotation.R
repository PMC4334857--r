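test_that("cpgIslandExt parsing keeps coordinates and drops random chroms", {
  path <- tempfile()
  writeLines(c("chr1\t135124\t135563\tCpG: 30\t439\t30\t30\t60\t0.8",
               "chr1_random\t100\t600\tCpG: 10\t500\t10\t10\t60\t0.8",
               "# a comment",
               "chr2\t1000\t2500\tCpG: 80\t1500\t80\t80\t65\t0.9"), path)
  cgis <- suppressMessages(read_cgis(path))
  expect_equal(nrow(cgis), 2)
  expect_equal(cgis$end[1] - cgis$start[1], 439)
  expect_equal(cgis$cpg_count, c(30, 80))
  expect_equal(attr(cgis, "n_dropped_random"), 1L)
})

test_that("malformed annotation lines raise errors naming file and line", {
  path <- tempfile()
  writeLines(c("chr1\t100\t200\tCpG: 5\t100\t5", "chr1\tbroken"), path)
  expect_error(read_cgis(path), "line 2")
  path2 <- tempfile()
  writeLines("chr1\t100\tnot_a_number\tCpG: 5\t100\t5", path2)
  expect_error(read_cgis(path2), "non-numeric")
})

test_that("missing optional repeat input yields an empty track, not an error", {
  expect_equal(nrow(read_bed(NULL)), 0)
  expect_equal(nrow(read_bed(tempfile())), 0)
})

test_that("promoters are TSS +/- flank with strand symmetry and clipping", {
  genes <- genomic_intervals(c("chr1", "chr1", "chr1"),
                             c(10000, 5000, 400), c(20000, 9000, 3000),
                             strand = c("+", "-", "+"),
                             gene_id = c("gA", "gB", "gC"))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  prom <- suppressWarnings(derive_promoters(genes, flank_bp = 2000))
  expect_equal(prom$start, c(8000, 7000, 0))
  expect_equal(prom$end, c(12000, 11000, 2400))
  expect_true(prom$clipped[3] && !any(prom$clipped[1:2]))
  expect_warning(derive_promoters(genes), "clipped")
  unclipped <- prom[!prom$clipped, ]
  expect_true(all(unclipped$end - unclipped$start == 4000))
})

test_that("miRNA promoters are 2 kb upstream in strand orientation", {
  pre <- genomic_intervals(c("chr1", "chr1"), c(50000, 50000),
                           c(50100, 50100), strand = c("+", "-"))
  mp <- derive_mirna_promoters(pre)
  expect_equal(mp$start, c(48000, 50100))
  expect_equal(mp$end, c(50000, 52100))
})

test_that("shores flank CGIs, truncate at neighbours, never overlap a CGI", {
  cgis <- genomic_intervals("chr1", 10000, 11000)
  sh <- derive_shores(cgis)
  expect_equal(sh$start[sh$side == "5p"], 8000)
  expect_equal(sh$end[sh$side == "5p"], 10000)
  expect_equal(sh$start[sh$side == "3p"], 11000)
  expect_equal(sh$end[sh$side == "3p"], 13000)

  # two nearby CGIs: intervening shore pieces truncated
  two <- genomic_intervals(c("chr1", "chr1"), c(10000, 11500),
                           c(11000, 12000))
  sh2 <- derive_shores(two)
  expect_true(all(sh2$end[sh2$cgi_index == 1 & sh2$side == "3p"] <= 11500))
  expect_true(all(sh2$start[sh2$cgi_index == 2 & sh2$side == "5p"] >= 11000))

  # CGI at chromosome start: only a 3' shore
  edge <- genomic_intervals("chr1", 0, 400)
  sh3 <- derive_shores(edge)
  expect_equal(sh3$side, "3p")

  # exhaustive bp membership: no base is both shore and CGI
  set.seed(7)
  starts <- sort(sample.int(90000, 15)) + c(0, cumsum(rep(0, 14)))
  rc <- genomic_intervals("chr1", starts * 1, starts + sample(200:800, 15,
                                                              replace = TRUE))
  rc <- rc[rc$end <= 1e5, ]
  shr <- derive_shores(rc)
  expect_false(any(bp_membership(rc, 1e5) & bp_membership(shr, 1e5)))
})

test_that("CpG promoter classification matches direct-count oracle", {
  r1 <- classify_promoter_cpg("CGCGCGCG")
  expect_equal(r1$cpg_ratio, 2.0)
  expect_equal(r1$gc_content, 1.0)
  expect_equal(r1$cpg_class, "HCP")
  r2 <- classify_promoter_cpg("ACGTACGTACGT")
  expect_equal(r2$cpg_ratio, 4.0)
  expect_equal(r2$gc_content, 0.5)
  expect_equal(r2$cpg_class, "ICP")
  r3 <- classify_promoter_cpg("AAAATTTT")
  expect_equal(r3$cpg_ratio, 0)
  expect_equal(r3$cpg_class, "LCP")
  expect_error(classify_promoter_cpg(""), "non-empty")
})

test_that("CpG classification is invariant under reverse complement", {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(.2, .3, .3, .2)), collapse = "")
    a <- classify_promoter_cpg(s)
    b <- classify_promoter_cpg(revcomp(s))
    expect_equal(a$cpg_ratio, b$cpg_ratio)
    expect_equal(a$gc_content, b$gc_content)
    expect_equal(a$cpg_class, b$cpg_class)
  }
})

test_that("CGI length tertiles are exhaustive with boundaries to lower class", {
  cg <- genomic_intervals(rep("chr1", 3), c(0, 1000, 3000),
                          c(200, 1500, 6000))
  cl <- classify_cgi_length(cg)
  expect_equal(cl$length_class, c("short", "medium", "long"))

  same <- genomic_intervals(rep("chr1", 4), c(0, 1000, 2000, 3000),
                            c(500, 1500, 2500, 3500))
  expect_equal(classify_cgi_length(same)$length_class, rep("short", 4))

  expect_warning(classify_cgi_length(cg[1:2, ]), "medium")

  set.seed(5)
  lens <- round(rlnorm(300, log(700), 0.7))
  big <- genomic_intervals(rep("chr1", 300), seq(0, by = 20000,
                                                 length.out = 300),
                           seq(0, by = 20000, length.out = 300) + lens)
  cls <- classify_cgi_length(big)$length_class
  # sort-based oracle: tertile sizes equal up to ties
  expect_true(all(abs(table(cls) - 100) <= sum(duplicated(lens))))
  expect_equal(sum(table(cls)), 300)
})

test_that("annotation round-trips through write/read bit-exactly", {
  cs <- toy_chrom_sizes(2, 2e5)
  genes <- genomic_intervals(c("chr1", "chr2"), c(10000, 50000),
                             c(30000, 90000), strand = c("+", "-"),
                             gene_id = c("g1", "g2"))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$transcript_lengths <- list(c(1500, 900), 2500)
  genes$longest_transcript <- c(1500, 2500)
  cgis <- genomic_intervals("chr1", 9500, 10500, cpg_count = 40)
  ann <- build_annotation(cs, genes, cgis)
  dir <- tempfile(); write_annotation(ann, dir)
  ann2 <- read_annotation(file.path(dir, "genes.tsv"),
                          file.path(dir, "cgis.tsv"),
                          chrom_sizes_path = file.path(dir, "chrom.sizes"))
  expect_equal(ann2$genes[, c("chrom", "start", "end", "strand", "tss")],
               ann$genes[, c("chrom", "start", "end", "strand", "tss")])
  expect_equal(ann2$cgis[, c("chrom", "start", "end", "cpg_count")],
               as.data.frame(ann$cgis)[, c("chrom", "start", "end",
                                           "cpg_count")],
               ignore_attr = TRUE)
  expect_equal(ann2$shores$start, ann$shores$start)
})

test_that("intervals beyond chromosome size are rejected at validation", {
  cs <- toy_chrom_sizes(1, 1000)
  genes <- genomic_intervals("chr1", 100, 2000, strand = "+",
                             gene_id = "g1")
  genes$tss <- 100
  genes$transcript_lengths <- list(500)
  genes$longest_transcript <- 500
  expect_error(build_annotation(cs, genes, genomic_intervals("chr1", 0, 10,
                                                             cpg_count = 1)),
               "exceeds size")
})
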