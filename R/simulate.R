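# synthetic_data: seeded toy genomes, per-sample MeDIP-like reads with
# planted hyper/hypo regions, and coupled expression tables with a
# machine-readable truth table.
#
# The read model is an inhomogeneous Poisson process whose local rate is
# proportional to CpG density times methylation level, echoing MeDIP
# enrichment of methylated, CpG-bearing fragments. Promoter CGIs carry a
# hypomethylated baseline (TSS hypomethylation, the canonical landscape in
# somatic tissue); intergenic CGIs and the rest of the genome are methylated.
# Planted regions run at ~`planted_baseline` times the background read rate
# on their low side and `effect_fold` times that on the high side, so the
# low side stays below the peak threshold while the high side is a clear
# peak, and the case/control rate ratio is exactly `effect_fold`.

# Fixed RNG kinds so a given seed is byte-reproducible across R versions.
set_seed_all <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Defaults describe the package's standard toy study: a 2 x 5 Mb genome,
#' 300 genes, 200 CGIs, 200,000 reads per sample, six case samples and one
#' control (mirroring a six-case/one-control MeDIP-Seq design), and 100
#' planted differential regions at 4-fold effect spread over five genomic
#' feature targets.
#'
#' @param n_chromosomes number of chromosomes (2).
#' @param chrom_length_bp length of each chromosome (5e6).
#' @param n_genes genes in the toy genome (300).
#' @param n_cgis CpG islands; ~60% of genes receive a promoter CGI (200).
#' @param reads_per_sample nominal library size before the +/-20% per-sample
#'   variation (200000).
#' @param fragment_length_bp fixed MeDIP fragment length (200).
#' @param n_case_samples case samples sharing the planted regions (6).
#' @param n_planted_hyper,n_planted_hypo planted hyper-/hypomethylated
#'   regions (50 each).
#' @param effect_fold methylation fold effect of planted regions (4).
#' @param planted_baseline read-rate enrichment of a planted region's low
#'   side over background (2): hyper regions run at `planted_baseline` in
#'   the control and `planted_baseline * effect_fold` in cases, hypo
#'   regions the reverse; levels are expressed relative to the local CpG
#'   density, so the ratio holds in promoter CGIs too.
#' @param promoter_cgi_meth baseline methylation of promoter-overlapping
#'   CGIs (0.2, emulating TSS hypomethylation); intergenic CGIs stay fully
#'   methylated.
#' @param feature_targets features the planted regions cycle through.
#' @param expression_coupling_strength log2 expression effect tied to
#'   promoter-CGI hypermethylation (repression) and 3'-shore
#'   hypomethylation (activation); 1 = 2-fold.
#' @param n_expression_case,n_expression_control RNA samples (3 and 1).
#' @param seed integer seed; fixed seed gives byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length_bp = 5e6,
                       n_genes = 300, n_cgis = 200,
                       reads_per_sample = 200000, fragment_length_bp = 200,
                       n_case_samples = 6,
                       n_planted_hyper = 50, n_planted_hypo = 50,
                       effect_fold = 4, planted_baseline = 2,
                       promoter_cgi_meth = 0.2,
                       feature_targets = c("promoter-CGI", "5p-shore",
                                           "3p-shore", "no-CGI-promoter",
                                           "intergenic"),
                       expression_coupling_strength = 1,
                       n_expression_case = 3, n_expression_control = 1,
                       seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, n_genes = n_genes,
              n_cgis = n_cgis, reads_per_sample = reads_per_sample,
              fragment_length_bp = fragment_length_bp,
              n_case_samples = n_case_samples,
              n_planted_hyper = n_planted_hyper,
              n_planted_hypo = n_planted_hypo, effect_fold = effect_fold,
              planted_baseline = planted_baseline,
              promoter_cgi_meth = promoter_cgi_meth,
              feature_targets = feature_targets,
              expression_coupling_strength = expression_coupling_strength,
              n_expression_case = n_expression_case,
              n_expression_control = n_expression_control, seed = seed)
  counts <- c(cfg$n_chromosomes, cfg$chrom_length_bp, cfg$n_genes,
              cfg$reads_per_sample, cfg$fragment_length_bp,
              cfg$n_case_samples)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$effect_fold < 1) stop("effect_fold must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Internal geometry constants of the toy genome.
SIM_GENE_LEN_MIN <- 5000
SIM_GENE_LEN_MAX <- 18000
SIM_SLOT_MARGIN <- 5000
SIM_CPG_BG_RATE <- 0.01   # mean CpGs per bp outside CGIs
SIM_CPG_CGI_RATE <- 0.10  # ~10x elevation inside CGIs
SIM_NOISE_WEIGHT <- 0.001 # per-bp sampling weight floor (unmethylated noise)
SIM_ISOCHORE_BP <- 1e5    # block size of large-scale background variation
SIM_ISOCHORE_SD <- 0.5    # log-sd of per-block CpG intensity

#' Simulate a toy annotated genome with planted differential regions
#'
#' Places non-overlapping genes in genome "slots", gives ~60% of gene
#' promoters a CGI spanning the TSS (log-normal CGI lengths), elevates CpG
#' density ~10x inside CGIs over a background of ~1 CpG per 100 bp, and
#' plants `n_planted_hyper` + `n_planted_hypo` pairwise non-overlapping
#' regions cycling through `feature_targets`. Genes carrying a promoter-CGI
#' hyper event are designated repressed; genes carrying a 3'-shore hypo
#' event are designated overexpressed.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a `genome_annotation`), `cpg_map`
#'   (per-chromosome sorted CpG positions) and `truth` (list of class
#'   `truth_table`: `regions` data.frame with chrom/start/end/direction/
#'   fold/target_feature/gene_id, plus `repressed_genes`,
#'   `overexpressed_genes`).
#' @export
simulate_genome <- function(config = sim_config()) {
  set_seed_all(config$seed)
  chrom_sizes <- data.frame(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    size = rep(config$chrom_length_bp, config$n_chromosomes),
    stringsAsFactors = FALSE)
  genome_len <- sum(chrom_sizes$size)

  n_prom_cgi <- min(round(0.6 * config$n_genes), config$n_cgis)
  n_intergenic_cgi <- config$n_cgis - n_prom_cgi
  n_planted <- config$n_planted_hyper + config$n_planted_hypo
  targets <- rep_len(config$feature_targets, n_planted)
  n_intergenic_regions <- sum(targets == "intergenic")

  n_slots <- config$n_genes + n_intergenic_cgi + n_intergenic_regions
  slot_w <- floor(genome_len / n_slots)
  if (slot_w < SIM_GENE_LEN_MAX + 2 * SIM_SLOT_MARGIN)
    stop("requested features exceed genome capacity: ",
         n_slots, " slots of ", slot_w, " bp")
  slots_per_chrom <- floor(chrom_sizes$size / slot_w)
  if (sum(slots_per_chrom) < n_slots)
    stop("requested features exceed genome capacity")
  slot_chrom <- rep(chrom_sizes$chrom, slots_per_chrom)
  slot_start <- unlist(lapply(slots_per_chrom, function(k)
    (seq_len(k) - 1) * slot_w), use.names = FALSE)
  keep <- seq_len(n_slots)  # leftover slots stay empty
  slot_chrom <- slot_chrom[keep]; slot_start <- slot_start[keep]
  role <- sample(rep(c("gene", "icgi", "iregion"),
                     c(config$n_genes, n_intergenic_cgi,
                       n_intergenic_regions)))

  # genes
  gi <- which(role == "gene")
  glen <- round(stats::runif(length(gi), SIM_GENE_LEN_MIN, SIM_GENE_LEN_MAX))
  goff <- round(stats::runif(length(gi), SIM_SLOT_MARGIN,
                             slot_w - SIM_SLOT_MARGIN - glen))
  gstart <- slot_start[gi] + goff
  gstrand <- sample(c("+", "-"), length(gi), replace = TRUE)
  genes <- genomic_intervals(slot_chrom[gi], gstart, gstart + glen,
                             strand = gstrand,
                             gene_id = sprintf("gene%03d", seq_along(gi)))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$transcript_lengths <- lapply(glen, function(L) {
    k <- sample(1:3, 1)
    sort(round(stats::runif(k, 500, L)), decreasing = TRUE)
  })
  genes$longest_transcript <- vapply(genes$transcript_lengths, max, 0)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  # CGIs: promoter CGIs span randomly chosen TSSs; the rest sit mid-slot.
  cgi_len <- pmin(pmax(round(stats::rlnorm(config$n_cgis, log(600), 0.6)),
                       200), 3000)
  prom_genes <- sort(sample(nrow(genes), n_prom_cgi))
  u <- stats::runif(n_prom_cgi, 0.3, 0.7)
  pc_len <- cgi_len[seq_len(n_prom_cgi)]
  pc_start <- round(genes$tss[prom_genes] - u * pc_len)
  cgi_list <- data.frame(chrom = genes$chrom[prom_genes], start = pc_start,
                         end = pc_start + pc_len, stringsAsFactors = FALSE)
  ii <- which(role == "icgi")
  if (length(ii) > 0) {
    ic_len <- cgi_len[n_prom_cgi + seq_along(ii)]
    ic_start <- slot_start[ii] + round(slot_w / 2 - ic_len / 2)
    cgi_list <- rbind(cgi_list,
                      data.frame(chrom = slot_chrom[ii], start = ic_start,
                                 end = ic_start + ic_len,
                                 stringsAsFactors = FALSE))
  }
  cgi_list <- cgi_list[order(cgi_list$chrom, cgi_list$start), , drop = FALSE]

  # CpG position map: inhomogeneous Poisson background (log-normal
  # isochore-scale intensity per 100 kb block, giving the several-fold
  # large-scale CpG density variation of real genomes and hence the strong
  # between-sample correlation of 10 kb methylation maps) plus dense CpGs
  # inside CGIs.
  cpg_map <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    sz <- chrom_sizes$size[i]
    n_blocks <- ceiling(sz / SIM_ISOCHORE_BP)
    mult <- stats::rlnorm(n_blocks, 0, SIM_ISOCHORE_SD)
    pos <- unlist(lapply(seq_len(n_blocks), function(b) {
      b0 <- (b - 1) * SIM_ISOCHORE_BP
      bl <- min(SIM_ISOCHORE_BP, sz - b0)
      n <- stats::rpois(1, bl * SIM_CPG_BG_RATE * mult[b])
      b0 + sample.int(bl, n, replace = TRUE) - 1
    }), use.names = FALSE)
    pos <- sort(pos)
    on_chr <- cgi_list[cgi_list$chrom == chrom_sizes$chrom[i], , drop = FALSE]
    if (nrow(on_chr) > 0) {
      extra <- unlist(lapply(seq_len(nrow(on_chr)), function(j) {
        L <- on_chr$end[j] - on_chr$start[j]
        n <- stats::rpois(1, L * (SIM_CPG_CGI_RATE - SIM_CPG_BG_RATE))
        on_chr$start[j] + sample.int(L, n, replace = TRUE) - 1
      }), use.names = FALSE)
      pos <- sort(c(pos, extra))
    }
    pos
  })
  names(cpg_map) <- chrom_sizes$chrom

  cgis <- genomic_intervals(cgi_list$chrom, cgi_list$start, cgi_list$end)
  cgis$cpg_count <- vapply(seq_len(nrow(cgis)), function(j)
    count_in_windows(cpg_map[[cgis$chrom[j]]], cgis$start[j], cgis$end[j]),
    0)

  # map gene -> promoter CGI (post-sort indices)
  ann <- build_annotation(chrom_sizes, genes, cgis)
  prom_hits <- overlap_pairs(ann$promoters, cgis)

  # plant differential regions
  directions <- rep(c("hyper", "hypo"),
                    c(config$n_planted_hyper, config$n_planted_hypo))
  has_cgi <- seq_len(nrow(genes)) %in% prom_hits$query
  pool_cgi <- sample(which(has_cgi))
  pool_nocgi <- sample(which(!has_cgi))
  pool_iregion <- sample(which(role == "iregion"))
  regions <- vector("list", n_planted)
  for (j in seq_len(n_planted)) {
    tgt <- targets[j]
    if (tgt %in% c("promoter-CGI", "5p-shore", "3p-shore")) {
      if (length(pool_cgi) == 0)
        stop("requested features exceed genome capacity: no CGI-promoter genes left")
      g <- pool_cgi[1]; pool_cgi <- pool_cgi[-1]
      ci <- prom_hits$subject[match(g, prom_hits$query)]
      cs <- cgis$start[ci]; ce <- cgis$end[ci]
      minus <- genes$strand[g] == "-"
      # shore events occupy the distal 1.2 kb of the 2 kb shore, leaving
      # an 800 bp guard at the island edge: peak boundaries are resolved
      # only to window - step (400 bp) at strong enrichment, fragments
      # smear another ~200 bp, and the 100 bp pattern windows quantize a
      # further 100 bp; an event flush against the island would smear into
      # it and be unrecoverable by any classifier
      iv <- switch(tgt,
        "promoter-CGI" = c(cs, ce),
        "5p-shore" = if (minus) c(ce + 800, ce + 2000)
                     else c(cs - 2000, cs - 800),
        "3p-shore" = if (minus) c(cs - 2000, cs - 800)
                     else c(ce + 800, ce + 2000))
      regions[[j]] <- data.frame(chrom = genes$chrom[g],
                                 start = max(0, iv[1]),
                                 end = min(config$chrom_length_bp, iv[2]),
                                 gene_id = genes$gene_id[g],
                                 stringsAsFactors = FALSE)
    } else if (tgt == "no-CGI-promoter") {
      if (length(pool_nocgi) == 0)
        stop("requested features exceed genome capacity: no CGI-free promoters left")
      g <- pool_nocgi[1]; pool_nocgi <- pool_nocgi[-1]
      regions[[j]] <- data.frame(chrom = genes$chrom[g],
                                 start = genes$tss[g] - 1000,
                                 end = genes$tss[g] + 1000,
                                 gene_id = genes$gene_id[g],
                                 stringsAsFactors = FALSE)
    } else if (tgt == "intergenic") {
      if (length(pool_iregion) == 0)
        stop("requested features exceed genome capacity: no intergenic slots left")
      s <- pool_iregion[1]; pool_iregion <- pool_iregion[-1]
      mid <- slot_start[s] + round(slot_w / 2)
      regions[[j]] <- data.frame(chrom = slot_chrom[s], start = mid - 500,
                                 end = mid + 500, gene_id = NA_character_,
                                 stringsAsFactors = FALSE)
    } else stop("unknown feature target: ", tgt)
  }
  if (n_planted == 0) {
    regions <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), direction = character(0),
                          fold = numeric(0), target_feature = character(0),
                          gene_id = character(0), stringsAsFactors = FALSE)
  } else {
    regions <- do.call(rbind, regions)
    regions$direction <- directions
    regions$fold <- config$effect_fold
    regions$target_feature <- targets
    regions <- regions[, c("chrom", "start", "end", "direction", "fold",
                           "target_feature", "gene_id")]
  }

  truth <- list(
    regions = regions,
    repressed_genes = regions$gene_id[regions$direction == "hyper" &
                                        regions$target_feature == "promoter-CGI"],
    overexpressed_genes = regions$gene_id[regions$direction == "hypo" &
                                            regions$target_feature == "3p-shore"])
  class(truth) <- "truth_table"
  list(annotation = ann, cpg_map = cpg_map, truth = truth)
}

# Per-sample methylation multiplier over 100 bp cells of one chromosome.
# Baseline is 1 everywhere except promoter CGIs (hypomethylated at
# `promoter_cgi_meth`). Planted regions override: the low side targets a
# read rate of `planted_baseline` times background, the high side `fold`
# times that; inside CGIs the level is divided by the CpG density ratio so
# the achieved rates are density-independent. Hyper regions are high in
# cases, hypo regions high in the control.
meth_multiplier <- function(chrom, n_cells, cell_bp, truth, is_case,
                            config, annotation) {
  m <- rep(1, n_cells)
  prom_cgis <- annotation$cgis[overlaps_any(annotation$cgis,
                                            annotation$promoters), ,
                               drop = FALSE]
  cell_range <- function(start, end)
    (floor(start / cell_bp) + 1):min(n_cells, ceiling(end / cell_bp))
  pc <- prom_cgis[prom_cgis$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(pc)))
    m[cell_range(pc$start[j], pc$end[j])] <- config$promoter_cgi_meth
  density_ratio <- SIM_CPG_CGI_RATE / SIM_CPG_BG_RATE
  reg <- truth$regions[truth$regions$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(reg))) {
    cells <- cell_range(reg$start[j], reg$end[j])
    low <- config$planted_baseline /
      if (reg$target_feature[j] == "promoter-CGI") density_ratio else 1
    high <- (reg$direction[j] == "hyper") == is_case
    m[cells] <- if (high) low * reg$fold[j] else low
  }
  m
}

#' Simulate per-sample MeDIP-Seq reads
#'
#' Fragment midpoints are drawn from an inhomogeneous process with rate
#' proportional to (local CpG density + a small noise floor) times the
#' sample's methylation level; planted hyper regions have `effect_fold`
#' higher case methylation, planted hypo regions `effect_fold` higher
#' control methylation, both above a methylated `planted_baseline`. Fragments have fixed length and library sizes vary
#' +/-20% around `reads_per_sample`. Each sample uses its own RNG stream
#' (`seed + sample index`), so adding samples never perturbs existing ones.
#'
#' @param sim output of [simulate_genome()] (annotation, cpg_map, truth).
#' @param config the same [sim_config()].
#' @return named list of `aligned_read_set`s: `control`, `case1`, ...
#' @export
simulate_reads <- function(sim, config = sim_config()) {
  chrom_sizes <- sim$annotation$chrom_sizes
  cell_bp <- 100
  frag <- config$fragment_length_bp
  cells <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    sz <- chrom_sizes$size[i]
    n_cells <- ceiling(sz / cell_bp)
    cpg <- tabulate(floor(sim$cpg_map[[i]] / cell_bp) + 1L, nbins = n_cells)
    list(chrom = chrom_sizes$chrom[i], n = n_cells, cpg = cpg)
  })
  out <- list()
  for (s in 0:config$n_case_samples) {
    set_seed_all(config$seed + s)
    lib <- round(config$reads_per_sample * stats::runif(1, 0.8, 1.2))
    is_case <- s > 0
    # a fragment is captured in proportion to its total methylated-CpG
    # content: box-filter the methylated CpG density over the fragment
    # length, then add nonspecific background pulldown
    k_cells <- max(1L, round(frag / cell_bp))
    w <- unlist(lapply(cells, function(ch) {
      meth_cpg <- ch$cpg * meth_multiplier(ch$chrom, ch$n, cell_bp,
                                           sim$truth, is_case, config,
                                           sim$annotation)
      sm <- as.numeric(stats::filter(meth_cpg, rep(1 / k_cells, k_cells),
                                     sides = 2))
      sm[is.na(sm)] <- meth_cpg[is.na(sm)]
      sm + SIM_NOISE_WEIGHT * cell_bp
    }), use.names = FALSE)
    pick <- sample.int(length(w), lib, replace = TRUE, prob = w)
    offs <- cumsum(c(0, vapply(cells, function(ch) ch$n, 0)))
    reads_by_chr <- lapply(seq_along(cells), function(i) {
      local_cells <- pick[pick > offs[i] & pick <= offs[i + 1]] - offs[i]
      if (length(local_cells) == 0) return(NULL)
      mid <- (local_cells - 1) * cell_bp +
        sample.int(cell_bp, length(local_cells), replace = TRUE) - 1
      sz <- chrom_sizes$size[i]
      start <- pmax(0, pmin(mid - floor(frag / 2), sz - frag))
      data.frame(chrom = cells[[i]]$chrom, start = sort(start),
                 end = sort(start) + frag, stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, reads_by_chr[!vapply(reads_by_chr, is.null, TRUE)])
    rownames(reads) <- NULL
    class(reads) <- c("genomic_intervals", "data.frame")
    out[[if (s == 0) "control" else paste0("case", s)]] <-
      aligned_read_set(reads, urc = lib)
  }
  out
}

#' Simulate coupled gene expression counts
#'
#' Baseline per-gene means are log-normal; truth-designated repressed genes
#' (promoter-CGI hypermethylation) have case means divided by
#' `2^expression_coupling_strength`, overexpressed genes (3'-shore
#' hypomethylation) multiplied by it. Counts are Poisson around those means.
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return data.frame: gene_id, length (longest transcript), then one count
#'   column per control and case sample.
#' @export
simulate_expression <- function(sim, config = sim_config()) {
  set_seed_all(config$seed + 10000)
  genes <- sim$annotation$genes
  n <- nrow(genes)
  mu <- stats::rlnorm(n, log(500), 1)
  eff <- rep(1, n)
  coup <- 2^config$expression_coupling_strength
  eff[genes$gene_id %in% sim$truth$repressed_genes] <- 1 / coup
  eff[genes$gene_id %in% sim$truth$overexpressed_genes] <- coup
  df <- data.frame(gene_id = genes$gene_id,
                   length = genes$longest_transcript,
                   stringsAsFactors = FALSE)
  for (j in seq_len(config$n_expression_control))
    df[[paste0("control", j)]] <- stats::rpois(n, mu)
  for (j in seq_len(config$n_expression_case))
    df[[paste0("case", j)]] <- stats::rpois(n, mu * eff)
  df
}

#' Run the full simulator and optionally write its artifacts
#'
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, writes per-sample read BEDs, annotation
#'   tables, the truth table TSV, the expression TSV and the config as YAML.
#' @return list: `annotation`, `cpg_map`, `truth`, `reads` (named list of
#'   `aligned_read_set`), `expression`.
#' @export
simulate_methylome <- function(config = sim_config(), out_dir = NULL) {
  sim <- simulate_genome(config)
  reads <- simulate_reads(sim, config)
  expr <- simulate_expression(sim, config)
  res <- c(sim, list(reads = reads, expression = expr))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(sim$annotation, out_dir)
    for (nm in names(reads)) {
      r <- reads[[nm]]$reads
      writeLines(paste(r$chrom,
                       format(r$start, scientific = FALSE, trim = TRUE),
                       format(r$end, scientific = FALSE, trim = TRUE),
                       sep = "\t"),
                 file.path(out_dir, paste0(nm, ".bed")))
    }
    tr <- sim$truth$regions
    utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(yaml::as.yaml(unclass(config)),
               file.path(out_dir, "config.yaml"))
  }
  res
}
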