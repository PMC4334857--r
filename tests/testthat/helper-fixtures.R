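# Shared fixture builders: tiny genomes and annotation files written to
# tempdir at test time.

toy_chrom_sizes <- function(n = 1, size = 1e5) {
  data.frame(chrom = paste0("chr", seq_len(n)), size = rep(size, n),
             stringsAsFactors = FALSE)
}

write_chrom_sizes_file <- function(chrom_sizes, path = tempfile()) {
  writeLines(paste(chrom_sizes$chrom, chrom_sizes$size, sep = "\t"), path)
  path
}

write_gene_file <- function(df, path = tempfile()) {
  writeLines(paste(df$gene_id, df$chrom, df$strand, df$start, df$end,
                   df$lengths, sep = "\t"), path)
  path
}

write_cgi_file <- function(df, path = tempfile()) {
  writeLines(paste(df$chrom, df$start, df$end,
                   sprintf("CpG: %d", df$cpg), df$end - df$start, df$cpg,
                   "30", "60", "0.8", sep = "\t"), path)
  path
}

# A promoter_mask built directly from window index sets (1-based, already in
# gene orientation).
mask_fixture <- function(methyl_windows, cgi_windows, gene_id = "g",
                         n_windows = 40) {
  m <- rep(FALSE, n_windows); m[methyl_windows] <- TRUE
  cg <- rep(FALSE, n_windows); cg[cgi_windows] <- TRUE
  structure(list(gene_id = gene_id, methyl_mask = m, cgi_mask = cg,
                 clipped = FALSE), class = "promoter_mask")
}

# Uniform random read set on a toy genome (homogeneous null).
uniform_reads <- function(chrom_sizes, n_per_chrom, read_len = 200) {
  parts <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    start <- sample.int(chrom_sizes$size[i] - read_len, n_per_chrom,
                        replace = TRUE) - 1
    data.frame(chrom = chrom_sizes$chrom[i], start = sort(start),
               end = sort(start) + read_len, stringsAsFactors = FALSE)
  })
  aligned_read_set(do.call(rbind, parts))
}

# Brute-force base-pair membership of intervals on one small chromosome.
bp_membership <- function(df, size) {
  mem <- rep(FALSE, size)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i])
      mem[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  mem
}
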