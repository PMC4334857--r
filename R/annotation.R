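# genome_features: parse annotation inputs and derive the feature sets the
# analysis interrogates (promoters, CGIs, CGI shores, CpG promoter classes,
# CGI length classes, cytogenetic bands, repeats).

read_tsv_file <- function(path, col_names, what) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(stats::setNames(
      as.data.frame(replicate(length(col_names), character(0), simplify = FALSE)),
      col_names))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < length(col_names))
  if (length(bad) > 0)
    stop(sprintf("malformed %s line %d in '%s': expected >= %d tab-separated fields, got %d",
                 what, lineno[bad[1]], path, length(col_names), nf[bad[1]]))
  m <- t(vapply(fields, function(f) f[seq_along(col_names)], character(length(col_names))))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- col_names
  df
}

num_col <- function(x, path, what) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out)))
    stop(sprintf("malformed %s field in '%s': non-numeric value '%s'",
                 what, path, x[which(is.na(out))[1]]))
  out
}

#' Read chromosome sizes
#'
#' Two-column TSV: chromosome name, length in bp. Lines starting `#` ignored.
#' @param path file path.
#' @return data.frame with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  df <- read_tsv_file(path, c("chrom", "size"), "chrom sizes")
  data.frame(chrom = df$chrom,
             size = num_col(df$size, path, "chrom size"),
             stringsAsFactors = FALSE)
}

#' Read gene models from a refFlat-style TSV
#'
#' Columns: geneName, chrom, strand, txStart, txEnd, transcriptLengths
#' (comma-separated bp). Coordinates are 0-based half-open. The TSS is
#' txStart on the + strand and txEnd on the - strand.
#'
#' @param path file path.
#' @return `genomic_intervals` data.frame with `gene_id`, `strand`, `tss`,
#'   `transcript_lengths` (list column) and `longest_transcript`.
#' @export
read_genes <- function(path) {
  df <- read_tsv_file(path, c("geneName", "chrom", "strand", "txStart",
                              "txEnd", "transcriptLengths"), "gene model")
  if (nrow(df) == 0) return(empty_intervals(strand = TRUE))
  tl <- lapply(strsplit(df$transcriptLengths, ","),
               function(x) as.numeric(x[nzchar(x)]))
  if (any(vapply(tl, function(x) any(is.na(x)) || any(x <= 0) || length(x) == 0, TRUE)))
    stop("transcript lengths must be positive numbers in '", path, "'")
  start <- num_col(df$txStart, path, "txStart")
  end <- num_col(df$txEnd, path, "txEnd")
  g <- genomic_intervals(df$chrom, start, end, strand = df$strand,
                         gene_id = df$geneName)
  g$tss <- ifelse(g$strand == "-", g$end, g$start)
  g$transcript_lengths <- tl
  g$longest_transcript <- vapply(tl, max, numeric(1))
  g
}

#' Read CpG islands from a UCSC cpgIslandExt-style TSV
#'
#' Expected columns: chrom, chromStart, chromEnd, name, length, cpgNum
#' (further columns ignored). CGIs located on chromosomes whose name contains
#' "random" are excluded, and the number dropped is reported via a message.
#'
#' @param path file path.
#' @return `genomic_intervals` with `cpg_count`; attribute `n_dropped_random`.
#' @export
read_cgis <- function(path) {
  df <- read_tsv_file(path, c("chrom", "chromStart", "chromEnd", "name",
                              "length", "cpgNum"), "cpgIslandExt")
  if (nrow(df) == 0) {
    out <- empty_intervals()
    out$cpg_count <- numeric(0)
    attr(out, "n_dropped_random") <- 0L
    return(out)
  }
  is_random <- grepl("random", df$chrom)
  n_drop <- sum(is_random)
  if (n_drop > 0)
    message(sprintf("read_cgis: excluded %d CGIs on 'random' chromosomes", n_drop))
  df <- df[!is_random, , drop = FALSE]
  out <- genomic_intervals(df$chrom,
                           num_col(df$chromStart, path, "chromStart"),
                           num_col(df$chromEnd, path, "chromEnd"),
                           cpg_count = num_col(df$cpgNum, path, "cpgNum"))
  attr(out, "n_dropped_random") <- n_drop
  out
}

#' Read cytogenetic bands (UCSC cytoBand TSV)
#' @param path file path.
#' @return `genomic_intervals` with `band` and `stain` columns.
#' @export
read_bands <- function(path) {
  df <- read_tsv_file(path, c("chrom", "chromStart", "chromEnd", "name",
                              "gieStain"), "cytoBand")
  if (nrow(df) == 0) {
    out <- empty_intervals(); out$band <- character(0); out$stain <- character(0)
    return(out)
  }
  genomic_intervals(df$chrom,
                    num_col(df$chromStart, path, "chromStart"),
                    num_col(df$chromEnd, path, "chromEnd"),
                    band = paste0(sub("^chr", "", df$chrom), df$name),
                    stain = df$gieStain)
}

#' Read a BED file of intervals
#'
#' Minimal BED3+: chrom, start, end, optional name (e.g. repeat class) and
#' further ignored columns. `path = NULL` or a missing/empty file yields an
#' empty set.
#' @param path file path or NULL.
#' @return `genomic_intervals` with a `name` column.
#' @export
read_bed <- function(path) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    out <- empty_intervals(); out$name <- character(0)
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^track|^browser", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- empty_intervals(); out$name <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed BED line in '", path, "': fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1)
  start <- num_col(vapply(fields, `[`, "", 2), path, "BED start")
  end <- num_col(vapply(fields, `[`, "", 3), path, "BED end")
  nm <- vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", "")
  genomic_intervals(chrom, start, end, name = nm)
}

#' Assemble a genome annotation from its input files
#'
#' Parses gene models, CpG islands, cytogenetic bands, optional repeats and
#' chromosome sizes, validates every interval against its chromosome size,
#' and derives promoter (+/- `flank_bp` around the TSS) and CGI shore tracks.
#'
#' @param gene_path refFlat-style TSV (see [read_genes()]).
#' @param cgi_path UCSC cpgIslandExt-style TSV.
#' @param band_path UCSC cytoBand TSV (optional, NULL to skip).
#' @param repeat_path BED of repeat intervals (optional, NULL to skip).
#' @param chrom_sizes_path two-column TSV of chromosome sizes.
#' @param mirna_path optional BED of miRNA precursor intervals.
#' @param flank_bp promoter half-width around the TSS (default 2000).
#' @param shore_bp shore width flanking each CGI (default 2000).
#' @return list of class `genome_annotation` with elements `chrom_sizes`,
#'   `genes`, `promoters`, `mirna_promoters`, `cgis`, `shores`, `bands`,
#'   `repeats`.
#' @export
read_annotation <- function(gene_path, cgi_path, band_path = NULL,
                            repeat_path = NULL, chrom_sizes_path,
                            mirna_path = NULL,
                            flank_bp = 2000, shore_bp = 2000) {
  chrom_sizes <- read_chrom_sizes(chrom_sizes_path)
  genes <- read_genes(gene_path)
  cgis <- read_cgis(cgi_path)
  bands <- if (is.null(band_path)) NULL else read_bands(band_path)
  repeats <- read_bed(repeat_path)
  mirna <- if (is.null(mirna_path)) NULL else read_bed(mirna_path)
  build_annotation(chrom_sizes, genes, cgis, bands = bands, repeats = repeats,
                   mirna_precursors = mirna, flank_bp = flank_bp,
                   shore_bp = shore_bp)
}

#' Assemble a genome annotation from in-memory tables
#'
#' Same validation and derivation as [read_annotation()] but starting from
#' already-parsed interval tables (used by the simulator).
#' @inheritParams read_annotation
#' @param chrom_sizes data.frame (`chrom`, `size`).
#' @param genes,cgis,bands,repeats,mirna_precursors interval tables.
#' @return `genome_annotation` list.
#' @export
build_annotation <- function(chrom_sizes, genes, cgis, bands = NULL,
                             repeats = NULL, mirna_precursors = NULL,
                             flank_bp = 2000, shore_bp = 2000) {
  validate_against_sizes <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    sz <- chrom_sizes$size[match(df$chrom, chrom_sizes$chrom)]
    if (any(is.na(sz)))
      stop(what, " on unknown chromosome: ",
           unique(df$chrom[is.na(sz)])[1])
    bad <- which(df$end > sz)
    if (length(bad) > 0)
      stop(sprintf("%s interval [%d, %d) exceeds size of %s",
                   what, df$start[bad[1]], df$end[bad[1]], df$chrom[bad[1]]))
    invisible(NULL)
  }
  validate_against_sizes(genes, "gene")
  validate_against_sizes(cgis, "CGI")
  validate_against_sizes(bands, "band")
  validate_against_sizes(repeats, "repeat")

  if (is.null(repeats)) { repeats <- empty_intervals(); repeats$name <- character(0) }
  promoters <- derive_promoters(genes, flank_bp = flank_bp,
                                chrom_sizes = chrom_sizes)
  mirna_prom <- if (is.null(mirna_precursors) || nrow(mirna_precursors) == 0) {
    empty_intervals()
  } else {
    derive_mirna_promoters(mirna_precursors, chrom_sizes = chrom_sizes)
  }
  shores <- derive_shores(cgis, width_bp = shore_bp, chrom_sizes = chrom_sizes)
  ann <- list(chrom_sizes = chrom_sizes, genes = genes, promoters = promoters,
              mirna_promoters = mirna_prom, cgis = cgis, shores = shores,
              bands = bands, repeats = repeats,
              flank_bp = flank_bp, shore_bp = shore_bp)
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      nrow(x$chrom_sizes), "chromosomes;",
      nrow(x$genes), "genes;",
      nrow(x$cgis), "CGIs;",
      nrow(x$shores), "shores;",
      if (!is.null(x$bands)) nrow(x$bands) else 0, "bands;",
      nrow(x$repeats), "repeats\n")
  invisible(x)
}

#' Write annotation tables back to files
#'
#' Inverse of [read_annotation()] for the gene, CGI and chromosome-size
#' tables; coordinates round-trip bit-exactly.
#' @param annotation `genome_annotation`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, "genes.tsv")
  g <- annotation$genes
  gl <- vapply(g$transcript_lengths, function(x)
    paste(format(x, scientific = FALSE, trim = TRUE), collapse = ","), "")
  writeLines(paste(g$gene_id, g$chrom, g$strand,
                   format(g$start, scientific = FALSE, trim = TRUE),
                   format(g$end, scientific = FALSE, trim = TRUE),
                   gl, sep = "\t"), gp)
  cp <- file.path(dir, "cgis.tsv")
  cg <- annotation$cgis
  writeLines(paste(cg$chrom,
                   format(cg$start, scientific = FALSE, trim = TRUE),
                   format(cg$end, scientific = FALSE, trim = TRUE),
                   sprintf("CpG: %d", as.integer(cg$cpg_count)),
                   format(cg$end - cg$start, scientific = FALSE, trim = TRUE),
                   format(cg$cpg_count, scientific = FALSE, trim = TRUE),
                   sep = "\t"), cp)
  sp <- file.path(dir, "chrom.sizes")
  writeLines(paste(annotation$chrom_sizes$chrom,
                   format(annotation$chrom_sizes$size, scientific = FALSE,
                          trim = TRUE), sep = "\t"), sp)
  invisible(c(genes = gp, cgis = cp, chrom_sizes = sp))
}

#' Derive promoter intervals around gene TSSs
#'
#' A promoter is the interval `[tss - flank_bp, tss + flank_bp)`, clipped to
#' chromosome bounds (a warning reports clipped genes).
#'
#' @param genes gene table from [read_genes()] (needs `tss`, `strand`).
#' @param flank_bp half-width, default 2000 (4 kb promoters).
#' @param chrom_sizes optional size table for clipping.
#' @return `genomic_intervals` with `gene_id`, `strand`, `tss`, `clipped`.
#' @export
derive_promoters <- function(genes, flank_bp = 2000, chrom_sizes = NULL) {
  if (nrow(genes) == 0) {
    out <- empty_intervals(strand = TRUE)
    out$gene_id <- character(0); out$tss <- numeric(0); out$clipped <- logical(0)
    return(out)
  }
  start <- genes$tss - flank_bp
  end <- genes$tss + flank_bp
  clipped <- start < 0
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes$size[match(genes$chrom, chrom_sizes$chrom)]
    clipped <- clipped | end > sz
    end <- pmin(end, sz)
  }
  start <- pmax(start, 0)
  if (any(clipped))
    warning(sprintf("%d promoters clipped at chromosome bounds", sum(clipped)))
  genomic_intervals(genes$chrom, start, end, strand = genes$strand,
                    gene_id = genes$gene_id, tss = genes$tss,
                    clipped = clipped)
}

#' Derive putative miRNA promoters
#'
#' The 2 kb immediately upstream of each miRNA precursor, in strand
#' orientation (upstream of `start` on +, of `end` on -). Kept as a feature
#' track separate from gene promoters.
#'
#' @param mirna_precursors interval table, with `strand` if available.
#' @param upstream_bp promoter length, default 2000.
#' @param chrom_sizes optional for clipping.
#' @return `genomic_intervals` with `name`.
#' @export
derive_mirna_promoters <- function(mirna_precursors, upstream_bp = 2000,
                                   chrom_sizes = NULL) {
  m <- mirna_precursors
  if (nrow(m) == 0) return(empty_intervals())
  strand <- if ("strand" %in% names(m)) m$strand else rep("+", nrow(m))
  strand[strand == "."] <- "+"
  start <- ifelse(strand == "-", m$end, m$start - upstream_bp)
  end <- ifelse(strand == "-", m$end + upstream_bp, m$start)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes$size[match(m$chrom, chrom_sizes$chrom)]
    end <- pmin(end, sz)
  }
  keep <- start < end
  out <- genomic_intervals(m$chrom[keep], start[keep], end[keep],
                           strand = strand[keep])
  out$name <- if ("name" %in% names(m)) m$name[keep] else rep(".", sum(keep))
  out
}

#' Derive CpG island shores
#'
#' Each CGI contributes up to two flanking shore intervals of at most
#' `width_bp`, tagged 5'-shore (genomic left) and 3'-shore (genomic right).
#' A shore is truncated where a neighbouring CGI lies closer than
#' `width_bp`, so no base pair is ever both shore and CGI.
#'
#' @param cgis CGI table.
#' @param width_bp shore width, default 2000.
#' @param chrom_sizes optional for clipping at chromosome ends.
#' @return `genomic_intervals` with columns `side` ("5p"/"3p") and
#'   `cgi_index` (row of the parent CGI).
#' @export
derive_shores <- function(cgis, width_bp = 2000, chrom_sizes = NULL) {
  out <- empty_intervals()
  out$side <- character(0); out$cgi_index <- integer(0)
  if (nrow(cgis) == 0) return(out)
  # Work on merged island blocks so overlapping or nested CGIs can never
  # receive shore bp inside another island; each original CGI inherits the
  # shores of its block.
  blocks <- reduce_intervals(cgis[, c("chrom", "start", "end")])
  res <- vector("list", 2 * nrow(cgis))
  for (chr in unique(cgis$chrom)) {
    bidx <- which(blocks$chrom == chr)
    bs <- blocks$start[bidx]; be <- blocks$end[bidx]
    n <- length(bidx)
    cidx <- which(cgis$chrom == chr)
    # block containing each original CGI
    blk <- findInterval(cgis$start[cidx], bs)
    for (k in seq_along(cidx)) {
      j <- blk[k]
      # 5' shore: back from the block start, stopping at the previous block
      lo <- bs[j] - width_bp
      if (j > 1) lo <- max(lo, be[j - 1])
      lo <- max(lo, 0)
      if (lo < bs[j])
        res[[2 * cidx[k] - 1]] <- data.frame(chrom = chr, start = lo,
                                             end = bs[j], side = "5p",
                                             cgi_index = cidx[k])
      # 3' shore: forward from the block end, stopping at the next block
      hi <- be[j] + width_bp
      if (j < n) hi <- min(hi, bs[j + 1])
      if (!is.null(chrom_sizes)) {
        sz <- chrom_sizes$size[match(chr, chrom_sizes$chrom)]
        if (!is.na(sz)) hi <- min(hi, sz)
      }
      if (be[j] < hi)
        res[[2 * cidx[k]]] <- data.frame(chrom = chr, start = be[j],
                                         end = hi, side = "3p",
                                         cgi_index = cidx[k])
    }
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) return(out)
  df <- do.call(rbind, res)
  out <- genomic_intervals(df$chrom, df$start, df$end, side = df$side,
                           cgi_index = df$cgi_index)
  out
}

count_cpg <- function(seq) {
  # overlap-free count of CG dinucleotides
  if (nchar(seq) < 2) return(0L)
  lengths(regmatches(seq, gregexpr("CG", seq, fixed = TRUE)))
}

cpg_stats <- function(seq) {
  L <- nchar(seq)
  nC <- lengths(regmatches(seq, gregexpr("C", seq, fixed = TRUE)))
  nG <- lengths(regmatches(seq, gregexpr("G", seq, fixed = TRUE)))
  ncg <- count_cpg(seq)
  ratio <- if (nC == 0 || nG == 0) 0 else ncg * L / (nC * nG)
  c(ratio = ratio, gc = (nC + nG) / L)
}

#' Classify a promoter by CpG content (HCP / ICP / LCP)
#'
#' The CpG ratio of a sequence of length L is
#' `#CpG * L / (#C * #G)` (observed over expected CpG dinucleotides), and the
#' GC content is `(#C + #G) / L`. Classification follows the sliding-window
#' scheme of Weber-style promoter stratification: a promoter is HCP if some
#' `window_bp` window has CpG ratio >= `hcp_ratio` and GC >= `hcp_gc`; LCP if
#' no window reaches CpG ratio `lcp_ratio`; ICP otherwise. Sequences shorter
#' than `window_bp` are evaluated as a single window.
#'
#' @param sequence promoter sequence (A/C/G/T/N text).
#' @param window_bp sliding window, default 500 bp.
#' @param step_bp window step, default 5 bp.
#' @param hcp_ratio,hcp_gc HCP thresholds (0.75, 0.55).
#' @param lcp_ratio LCP threshold (0.48).
#' @return list with `cpg_ratio` and `gc_content` of the whole sequence and
#'   `cpg_class` in `c("HCP", "ICP", "LCP")`.
#' @export
classify_promoter_cpg <- function(sequence, window_bp = 500, step_bp = 5,
                                  hcp_ratio = 0.75, hcp_gc = 0.55,
                                  lcp_ratio = 0.48) {
  if (length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  whole <- cpg_stats(sequence)
  L <- nchar(sequence)
  if (L <= window_bp) {
    wins <- sequence
  } else {
    starts <- seq(1, L - window_bp + 1, by = step_bp)
    if (starts[length(starts)] != L - window_bp + 1)
      starts <- c(starts, L - window_bp + 1)
    wins <- substring(sequence, starts, starts + window_bp - 1)
  }
  wstats <- vapply(wins, cpg_stats, c(ratio = 0, gc = 0))
  is_hcp <- any(wstats["ratio", ] >= hcp_ratio & wstats["gc", ] >= hcp_gc)
  is_lcp <- all(wstats["ratio", ] < lcp_ratio)
  cls <- if (is_hcp) "HCP" else if (is_lcp) "LCP" else "ICP"
  list(cpg_ratio = unname(whole["ratio"]),
       gc_content = unname(whole["gc"]),
       cpg_class = cls)
}

#' Classify CGIs by length tertile
#'
#' Splits the CGI length distribution into short/medium/long classes at the
#' `1/3` and `long_quantile` empirical quantiles (type-1, so thresholds are
#' observed lengths); lengths equal to a boundary go to the lower class.
#' Fewer than 3 CGIs cannot define tertiles: all are classed "medium" with a
#' warning.
#'
#' @param cgis CGI table.
#' @param long_quantile upper cut, default 2/3.
#' @return `cgis` with a `length_class` column.
#' @export
classify_cgi_length <- function(cgis, long_quantile = 2/3) {
  len <- cgis$end - cgis$start
  if (nrow(cgis) < 3) {
    warning("fewer than 3 CGIs: all length classes set to 'medium'")
    cgis$length_class <- rep("medium", nrow(cgis))
    return(cgis)
  }
  t1 <- stats::quantile(len, long_quantile / 2, type = 1, names = FALSE)
  t2 <- stats::quantile(len, long_quantile, type = 1, names = FALSE)
  cls <- ifelse(len <= t1, "short", ifelse(len <= t2, "medium", "long"))
  cgis$length_class <- cls
  cgis
}
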