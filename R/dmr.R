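# dmr: candidate regions from two samples' merged peaks, continuity-corrected
# chi-square test on read counts, BH false discovery control with a
# fold-change gate, and cross-sample ultra-DMR consensus on 500 bp segments.

#' Merge two samples' peaks into candidate regions
#'
#' The union of both peak lists with overlapping or book-ended intervals
#' coalesced; every input peak lies inside exactly one candidate.
#'
#' @param peaks_control,peaks_case coordinate-sorted peak tables.
#' @return `genomic_intervals` of candidate regions.
#' @export
merge_candidate_regions <- function(peaks_control, peaks_case) {
  cols <- c("chrom", "start", "end")
  both <- rbind(as.data.frame(peaks_control)[, cols, drop = FALSE],
                as.data.frame(peaks_case)[, cols, drop = FALSE])
  if (nrow(both) == 0) return(empty_intervals())
  reduce_intervals(both)
}

#' Continuity-corrected chi-square test for a 2x2 read-count table
#'
#' For a candidate region, `a`/`c` are reads inside the region in the
#' control/case sample and `b`/`d` the reads elsewhere (so `a + b` and
#' `c + d` are the library sizes). The Yates-corrected statistic is
#' `chi2 = n * max(0, |ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with `n = a+b+c+d`; the p-value is the chi-square(1 df) upper tail.
#' The continuity term is clamped at zero. A degenerate inner margin
#' (`a + c = 0` or `b + d = 0`) yields `chi2 = 0`, `p = 1`.
#'
#' All arguments are vectorized.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return list with `chi2` and `p_value`.
#' @export
chisq_test_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  n <- a + b + c + d
  num <- pmax(0, abs(a * d - b * c) - n / 2)
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den == 0, 0, n * num^2 / den)
  p <- ifelse(den == 0, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p_value = p)
}

# Count read (fragment) midpoints of a sample inside each region.
count_reads_in_regions <- function(reads, regions, chrom_sizes,
                                   extension_bp = 0) {
  counts <- numeric(nrow(regions))
  for (i in seq_len(nrow(chrom_sizes))) {
    chr <- chrom_sizes$chrom[i]
    idx <- which(regions$chrom == chr)
    if (length(idx) == 0) next
    mp <- sort(fragment_midpoints(reads$reads, extension_bp, chr,
                                  chrom_sizes$size[i]))
    counts[idx] <- count_in_windows(mp, regions$start[idx], regions$end[idx])
  }
  counts
}

#' Call differentially methylated regions between two samples
#'
#' For each candidate region, builds the 2x2 table of in-region vs elsewhere
#' reads for the control and case samples, applies [chisq_test_2x2()],
#' adjusts p-values across all candidates by Benjamini-Hochberg, and emits
#' regions with `q <= q_max` and a library-size-corrected fold change (ratio
#' of in-region read proportions, case over control) at least `min_fold` in
#' either direction. Direction is `hyper` when the case proportion exceeds
#' the control's. Candidates with zero reads in both samples are dropped
#' (count in attribute `n_dropped_empty`).
#'
#' @param candidates candidate regions from [merge_candidate_regions()].
#' @param reads_control,reads_case `aligned_read_set`s.
#' @param chrom_sizes data.frame (`chrom`, `size`).
#' @param q_max BH-adjusted significance cutoff (0.05).
#' @param min_fold minimum fold difference (2): emit if fold >= `min_fold`
#'   or fold <= `1/min_fold`.
#' @param fragment_extension_bp fragment extension used when counting reads,
#'   matching the peak caller (200).
#' @return data.frame of class `dmr_set`: chrom, start, end, a, b, c, d,
#'   chi2, p_value, q_value, fold, direction. Attribute `n_candidates` holds
#'   the number tested.
#' @export
call_dmrs <- function(candidates, reads_control, reads_case, chrom_sizes,
                      q_max = 0.05, min_fold = 2,
                      fragment_extension_bp = 200) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0), chi2 = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      fold = numeric(0), direction = character(0))
  if (nrow(candidates) == 0) {
    class(empty) <- c("dmr_set", "data.frame")
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  a <- count_reads_in_regions(reads_control, candidates, chrom_sizes,
                              fragment_extension_bp)
  c_ <- count_reads_in_regions(reads_case, candidates, chrom_sizes,
                               fragment_extension_bp)
  keep <- a + c_ > 0
  n_dropped <- sum(!keep)
  cand <- candidates[keep, , drop = FALSE]
  a <- a[keep]; c_ <- c_[keep]
  b <- reads_control$urc - a
  d <- reads_case$urc - c_
  tst <- chisq_test_2x2(a, b, c_, d)
  q <- stats::p.adjust(tst$p_value, method = "BH")
  prop_case <- c_ / (c_ + d)
  prop_ctrl <- a / (a + b)
  fold <- prop_case / prop_ctrl  # Inf when a == 0, valid hyper evidence
  res <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
                    a = a, b = b, c = c_, d = d,
                    chi2 = tst$chi2, p_value = tst$p_value, q_value = q,
                    fold = fold,
                    direction = ifelse(fold > 1, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  res <- res[res$q_value <= q_max &
               (res$fold >= min_fold | res$fold <= 1 / min_fold), ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("dmr_set", "data.frame")
  attr(res, "n_candidates") <- sum(keep)
  attr(res, "n_dropped_empty") <- n_dropped
  res
}

#' Cross-sample ultra-DMR consensus on fixed genome segments
#'
#' Divides the genome into `segment_bp` segments and, per segment and
#' direction, counts the case samples whose same-direction DMR overlaps the
#' segment by strictly more than `min_overlap_bp`. A segment is an ultra DMR
#' when its support exceeds half the number of samples (>= 4 of 6, >= 2 of
#' 3). A segment supported in both directions is ambiguous and dropped
#' (count in attribute `n_conflicts`).
#'
#' @param per_sample_dmrs list of `dmr_set`s, one per case sample, all from
#'   comparisons against the same control.
#' @param chrom_sizes data.frame (`chrom`, `size`).
#' @param segment_bp segment width (500).
#' @param min_overlap_bp strict overlap requirement (250).
#' @return data.frame of class `ultra_dmr_set`: chrom, start, end,
#'   direction, support, n_samples.
#' @export
ultra_dmrs <- function(per_sample_dmrs, chrom_sizes, segment_bp = 500,
                       min_overlap_bp = 250) {
  n_samples <- length(per_sample_dmrs)
  segs <- genome_bins(chrom_sizes, segment_bp)
  support <- matrix(0L, nrow(segs), 2,
                    dimnames = list(NULL, c("hyper", "hypo")))
  for (dmrs in per_sample_dmrs) {
    for (dir in c("hyper", "hypo")) {
      d <- as.data.frame(dmrs)[dmrs$direction == dir, , drop = FALSE]
      if (nrow(d) == 0) next
      hits <- overlap_pairs(segs, d)
      hits <- hits[hits$overlap_bp > min_overlap_bp, , drop = FALSE]
      seg_hit <- unique(hits$query)
      support[seg_hit, dir] <- support[seg_hit, dir] + 1L
    }
  }
  ok <- support > n_samples / 2
  conflict <- ok[, "hyper"] & ok[, "hypo"]
  n_conflicts <- sum(conflict)
  if (n_conflicts > 0)
    message(sprintf("ultra_dmrs: %d segments supported in both directions dropped",
                    n_conflicts))
  keep_hyper <- ok[, "hyper"] & !conflict
  keep_hypo <- ok[, "hypo"] & !conflict
  res <- rbind(
    data.frame(segs[keep_hyper, , drop = FALSE],
               direction = rep("hyper", sum(keep_hyper)),
               support = support[keep_hyper, "hyper"],
               stringsAsFactors = FALSE),
    data.frame(segs[keep_hypo, , drop = FALSE],
               direction = rep("hypo", sum(keep_hypo)),
               support = support[keep_hypo, "hypo"],
               stringsAsFactors = FALSE))
  res$n_samples <- rep(n_samples, nrow(res))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ultra_dmr_set", "data.frame")
  attr(res, "n_conflicts") <- n_conflicts
  res
}

#' Write DMRs as BED9+ TSV
#' @param dmrs a `dmr_set`.
#' @param path output path.
#' @param header optional named list echoed as `# key: value` lines.
#' @export
write_dmrs <- function(dmrs, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, as.character, "")), con)
  writeLines(paste("# chrom", "start", "end", "direction", "a", "b", "c", "d",
                   "chi2", "p_value", "q_value", "fold", sep = "\t"), con)
  if (nrow(dmrs) > 0)
    writeLines(paste(dmrs$chrom,
                     format(dmrs$start, scientific = FALSE, trim = TRUE),
                     format(dmrs$end, scientific = FALSE, trim = TRUE),
                     dmrs$direction, dmrs$a, dmrs$b, dmrs$c, dmrs$d,
                     format(dmrs$chi2, digits = 10, trim = TRUE),
                     format(dmrs$p_value, digits = 10, trim = TRUE),
                     format(dmrs$q_value, digits = 10, trim = TRUE),
                     format(dmrs$fold, digits = 10, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}
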