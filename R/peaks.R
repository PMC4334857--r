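# peaks: per-sample methylated-region detection by scanning sliding windows
# against a dynamic (locally adaptive) Poisson background, MACS-style:
# lambda_local = max(lambda_BG, lambda_5k, lambda_10k), peak if P < 1e-5.

#' Peak-calling parameters
#'
#' @param window_bp scan window width (500).
#' @param step_bp window step (100).
#' @param fragment_extension_bp reads are extended to fragments of this
#'   length from their 5' end before counting (200); 0 keeps reads as-is.
#' @param local_scales_bp spans for the local background estimates
#'   (5000 and 10000).
#' @param p_threshold Poisson upper-tail significance threshold (1e-5).
#' @param merge_gap_bp significant windows closer than this are merged (200).
#' @return list of class `peak_params`.
#' @export
peak_params <- function(window_bp = 500, step_bp = 100,
                        fragment_extension_bp = 200,
                        local_scales_bp = c(5000, 10000),
                        p_threshold = 1e-5, merge_gap_bp = 200) {
  stopifnot(step_bp <= window_bp, p_threshold > 0, p_threshold < 1)
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 fragment_extension_bp = fragment_extension_bp,
                 local_scales_bp = local_scales_bp,
                 p_threshold = p_threshold, merge_gap_bp = merge_gap_bp),
            class = "peak_params")
}

#' Poisson upper-tail p-value
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`: the survival function evaluated at
#' `k - 1`. `k = 0` gives exactly 1.
#'
#' @param k observed count (non-negative integer, vectorized).
#' @param lam expected count (> 0, vectorized).
#' @return upper-tail probability in (0, 1].
#' @export
poisson_pvalue <- function(k, lam) {
  if (any(k < 0)) stop("k must be >= 0")
  if (any(lam <= 0)) stop("lam must be > 0")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

# Count, for each of a set of half-open [lo, hi) windows, the number of
# sorted integer positions falling inside. O((nw + np) log np).
count_in_windows <- function(sorted_pos, lo, hi) {
  findInterval(hi - 0.5, sorted_pos) - findInterval(lo - 0.5, sorted_pos)
}

# Extend reads to fixed-length fragments from their 5' end and return
# fragment midpoints, clamped into [0, size).
fragment_midpoints <- function(reads, extension_bp, chrom, size) {
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) return(numeric(0))
  strand <- if ("strand" %in% names(r)) r$strand else rep("+", nrow(r))
  if (extension_bp > 0) {
    fs <- ifelse(strand == "-", r$end - extension_bp, r$start)
    fe <- fs + extension_bp
  } else {
    fs <- r$start; fe <- r$end
  }
  mid <- floor((fs + fe) / 2)
  pmin(pmax(mid, 0), size - 1)
}

#' Dynamic local Poisson rate for one window
#'
#' The expected count under the local background:
#' `lambda = max(lambda_BG, lambda_s for s in local_scales_bp)`, where each
#' local term counts fragment midpoints in the span of width `s` centered on
#' the window and rescales to window width. Spans are clipped at chromosome
#' bounds and rescaled by their realized width.
#'
#' @param window one-row interval (chrom, start, end).
#' @param midpoints sorted fragment midpoints on the window's chromosome.
#' @param genome_rate genome-wide midpoints per bp (total midpoints /
#'   genome length).
#' @param chrom_size the chromosome's length.
#' @param params a [peak_params()].
#' @return expected count (scalar).
#' @export
local_lambda <- function(window, midpoints, genome_rate, chrom_size,
                         params = peak_params()) {
  w <- window$end - window$start
  center <- (window$start + window$end) / 2
  lam <- genome_rate * w
  for (s in params$local_scales_bp) {
    lo <- max(0, center - s / 2)
    hi <- min(chrom_size, center + s / 2)
    cnt <- count_in_windows(midpoints, lo, hi)
    lam <- max(lam, cnt * w / (hi - lo))
  }
  lam
}

#' Call methylation peaks for one sample
#'
#' Slides `window_bp` windows at `step_bp` along every chromosome, counts
#' extended-fragment midpoints per window, computes the dynamic local
#' Poisson rate (max of the genome background and the centered 5 kb / 10 kb
#' local estimates) and the upper-tail p-value, then merges significant
#' windows (p < `p_threshold`) whose gap is at most `merge_gap_bp`. A merged
#' peak keeps the minimum p-value among member windows along with that
#' window's observed count (`window_count`) and rate (`lambda_local`), and
#' reports the distinct reads in the merged interval as `read_count`.
#'
#' @param sample an `aligned_read_set`.
#' @param chrom_sizes data.frame (`chrom`, `size`).
#' @param params a [peak_params()].
#' @return data.frame of class `peak_set`, coordinate-sorted: chrom, start,
#'   end, read_count, window_count, lambda_local, p_value.
#' @export
call_peaks <- function(sample, chrom_sizes, params = peak_params()) {
  genome_len <- sum(chrom_sizes$size)
  mids <- lapply(seq_len(nrow(chrom_sizes)), function(i)
    sort(fragment_midpoints(sample$reads, params$fragment_extension_bp,
                            chrom_sizes$chrom[i], chrom_sizes$size[i])))
  names(mids) <- chrom_sizes$chrom
  total <- sum(lengths(mids))
  out <- list()
  n_sig_windows <- 0L
  n_windows <- 0L
  if (total > 0) {
    genome_rate <- total / genome_len
    for (i in seq_len(nrow(chrom_sizes))) {
      chr <- chrom_sizes$chrom[i]
      sz <- chrom_sizes$size[i]
      mp <- mids[[chr]]
      ws <- seq(0, max(0, sz - 1), by = params$step_bp)
      we <- pmin(ws + params$window_bp, sz)
      wlen <- we - ws
      k <- count_in_windows(mp, ws, we)
      center <- (ws + we) / 2
      lam <- genome_rate * wlen
      for (s in params$local_scales_bp) {
        lo <- pmax(0, center - s / 2)
        hi <- pmin(sz, center + s / 2)
        lam <- pmax(lam, count_in_windows(mp, lo, hi) * wlen / (hi - lo))
      }
      p <- poisson_pvalue(k, lam)
      sig <- which(p < params$p_threshold)
      n_sig_windows <- n_sig_windows + length(sig)
      n_windows <- n_windows + length(ws)
      if (length(sig) == 0) next
      wins <- genomic_intervals(rep(chr, length(sig)), ws[sig], we[sig])
      merged <- reduce_intervals(wins, min_gap = params$merge_gap_bp)
      hit <- overlap_pairs(wins, merged)
      best <- vapply(seq_len(nrow(merged)), function(j) {
        members <- hit$query[hit$subject == j]
        members[which.min(p[sig][members])]
      }, 0L)
      out[[length(out) + 1]] <- data.frame(
        chrom = merged$chrom, start = merged$start, end = merged$end,
        read_count = count_in_windows(mp, merged$start, merged$end),
        window_count = k[sig][best],
        lambda_local = lam[sig][best],
        p_value = p[sig][best],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0) {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               read_count = numeric(0), window_count = numeric(0),
               lambda_local = numeric(0), p_value = numeric(0))
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("peak_set", "data.frame")
  attr(res, "params") <- params
  attr(res, "n_sig_windows") <- n_sig_windows
  attr(res, "n_windows") <- n_windows
  res
}

#' Write peaks as BED6+
#'
#' Columns: chrom, start, end, name, -log10(p), strand ".", read_count,
#' lambda_local.
#' @param peaks a `peak_set`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  score <- round(-log10(pmax(peaks$p_value, 1e-300)), 4)
  lines <- paste(peaks$chrom,
                 format(peaks$start, scientific = FALSE, trim = TRUE),
                 format(peaks$end, scientific = FALSE, trim = TRUE),
                 sprintf("peak_%d", seq_len(nrow(peaks))),
                 format(score, trim = TRUE), ".",
                 format(peaks$read_count, scientific = FALSE, trim = TRUE),
                 format(peaks$lambda_local, digits = 10, trim = TRUE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
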