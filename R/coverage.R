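# coverage: genome binning, Eq.-style library-size normalization
# (AM = RC * 1e6 / URC) and pairwise sample correlation of methylation maps.

#' Read a sample's aligned reads from BED
#'
#' @param path BED3+ file of read intervals.
#' @param urc unique mapped read count; defaults to the number of rows.
#' @return list of class `aligned_read_set` with `reads` (intervals) and `urc`.
#' @export
read_aligned_reads <- function(path, urc = NULL) {
  reads <- read_bed(path)
  aligned_read_set(reads, urc = urc)
}

#' Construct an aligned read set
#' @param reads interval table of read alignments.
#' @param urc unique mapped read count (>= nrow(reads) reads observed);
#'   defaults to `nrow(reads)`.
#' @return `aligned_read_set` list.
#' @export
aligned_read_set <- function(reads, urc = NULL) {
  if (is.null(urc)) urc <- nrow(reads)
  stopifnot(urc > 0 || nrow(reads) == 0)
  structure(list(reads = reads, urc = as.numeric(urc)),
            class = "aligned_read_set")
}

#' @export
print.aligned_read_set <- function(x, ...) {
  cat("aligned_read_set:", nrow(x$reads), "reads; URC =", x$urc, "\n")
  invisible(x)
}

read_midpoints <- function(reads) {
  floor((reads$start + reads$end) / 2)
}

#' Bin the genome and count reads per bin
#'
#' Tiles each chromosome with `bin_size_bp` bins (ragged final bin kept) and
#' assigns each read to exactly one bin by its fragment midpoint. Reads whose
#' midpoint falls beyond the chromosome end, or on an unknown chromosome, are
#' rejected and counted in the `n_rejected` attribute.
#'
#' @param reads an `aligned_read_set`.
#' @param bin_size_bp bin width; 10000 for global methylation maps, 500 for
#'   ultra-DMR segmentation.
#' @param chrom_sizes data.frame (`chrom`, `size`).
#' @return list of class `binned_coverage`: `bins` (chrom/start/end/rc),
#'   `urc`, `bin_size_bp`; `am` filled by [normalize_am()].
#' @export
bin_counts <- function(reads, bin_size_bp, chrom_sizes) {
  stopifnot(bin_size_bp >= 1)
  bins <- genome_bins(chrom_sizes, bin_size_bp)
  r <- reads$reads
  n_rejected <- 0L
  rc <- numeric(nrow(bins))
  if (nrow(r) > 0) {
    mid <- read_midpoints(r)
    for (i in seq_len(nrow(chrom_sizes))) {
      chr <- chrom_sizes$chrom[i]
      sz <- chrom_sizes$size[i]
      m <- mid[r$chrom == chr]
      bad <- m < 0 | m >= sz
      n_rejected <- n_rejected + sum(bad)
      m <- m[!bad]
      if (length(m) == 0) next
      nb <- ceiling(sz / bin_size_bp)
      counts <- tabulate(floor(m / bin_size_bp) + 1L, nbins = nb)
      rc[bins$chrom == chr] <- counts
    }
    n_rejected <- n_rejected + sum(!(r$chrom %in% chrom_sizes$chrom))
  }
  structure(list(bins = data.frame(bins, rc = rc), urc = reads$urc,
                 bin_size_bp = bin_size_bp, n_rejected = n_rejected),
            class = "binned_coverage")
}

# Tile every chromosome with fixed-size bins; last bin ragged.
genome_bins <- function(chrom_sizes, bin_size_bp) {
  parts <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    sz <- chrom_sizes$size[i]
    starts <- seq(0, sz - 1, by = bin_size_bp)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + bin_size_bp, sz),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Normalize binned counts by library size
#'
#' Fills the normalized depth `AM = RC * 1e6 / URC` for every bin, where RC
#' is the bin's read count and URC the sample's unique mapped read count.
#'
#' @param cov a `binned_coverage`.
#' @return `cov` with an `am` column in `$bins`.
#' @export
normalize_am <- function(cov) {
  if (is.null(cov$urc) || cov$urc <= 0) stop("URC must be positive")
  cov$bins$am <- cov$bins$rc * 1e6 / cov$urc
  cov
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat("binned_coverage:", nrow(x$bins), "bins of", x$bin_size_bp,
      "bp; URC =", x$urc, "\n")
  invisible(x)
}

#' Pairwise Pearson correlation of normalized methylation maps
#'
#' Computes Pearson r between every pair of samples' AM vectors over a shared
#' binning. Bins that are zero in all samples are excluded (they carry no
#' methylation signal). A sample whose remaining AM vector is constant has
#' undefined correlations, reported as NA.
#'
#' @param samples list of `binned_coverage` with identical bins, AM filled.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(samples) {
  stopifnot(length(samples) >= 1)
  ams <- lapply(samples, function(s) {
    if (is.null(s$bins$am)) s <- normalize_am(s)
    s$bins$am
  })
  n <- length(ams)
  len <- vapply(ams, length, 0L)
  if (length(unique(len)) != 1) stop("samples must share one binning")
  m <- do.call(cbind, ams)
  keep <- rowSums(m != 0) > 0
  m <- m[keep, , drop = FALSE]
  r <- matrix(NA_real_, n, n)
  nm <- names(samples)
  if (!is.null(nm)) dimnames(r) <- list(nm, nm)
  for (i in seq_len(n)) {
    r[i, i] <- 1
    if (i < n) for (j in seq((i + 1), n)) {
      if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
      } else {
        r[i, j] <- r[j, i] <- stats::cor(m[, i], m[, j])
      }
    }
  }
  r
}
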