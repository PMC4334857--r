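# pipeline: orchestrate all stages end to end from one config, writing an
# artifact directory with peaks, DMRs, ultra DMRs, enrichment tables,
# pattern calls, expression integration and a summary JSON.

PIPELINE_THRESHOLDS <- list(p_threshold = 1e-5, q_max = 0.05, min_fold = 2,
                            segment_bp = 500, min_overlap_bp = 250,
                            min_case_support = 4, flank_bp = 2000,
                            shore_bp = 2000)

#' Validate a pipeline configuration
#'
#' A config is a list (or YAML file) with either a `simulate` block
#' (overrides for [sim_config()]) or an `input` block (paths: `gene_path`,
#' `cgi_path`, `chrom_sizes_path`, optional `band_path`, `repeat_path`,
#' `expression_path`, and `reads`, a named list of BED paths whose first
#' entry is the control), plus optional `thresholds` overrides
#' (p_threshold, q_max, min_fold, segment_bp, min_overlap_bp,
#' min_case_support, flank_bp, shore_bp), a `seed`, and `out_dir`. Unknown
#' keys are rejected.
#'
#' @param config list or path to a YAML file.
#' @return normalized config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "input", "thresholds", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$simulate) && is.null(config$input))
    stop("config requires either a 'simulate' or an 'input' block")
  if (is.null(config$out_dir)) stop("config requires 'out_dir'")
  if (is.null(config$seed)) config$seed <- 1
  th <- utils::modifyList(PIPELINE_THRESHOLDS,
                          as.list(config$thresholds %||% list()))
  extra <- setdiff(names(th), names(PIPELINE_THRESHOLDS))
  if (length(extra) > 0)
    stop("unknown threshold keys: ", paste(extra, collapse = ", "))
  config$thresholds <- th
  if (!is.null(config$input)) {
    req <- c("gene_path", "cgi_path", "chrom_sizes_path", "reads")
    miss <- setdiff(req, names(config$input))
    if (length(miss) > 0)
      stop("config input block missing field(s): ",
           paste(miss, collapse = ", "))
    if (length(config$input$reads) < 2)
      stop("config input 'reads' needs a control plus at least one case")
  }
  class(config) <- "pipeline_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full differential-methylation pipeline
#'
#' Stages, in dependency order: data acquisition (simulation or file
#' input), per-sample peak calling, per-case DMR calling against the
#' control, ultra-DMR consensus, feature (and band, when available)
#' enrichment, promoter pattern classification, and expression integration
#' (RPKM, ranking, GSEA of the hypermethylated-promoter-CGI and
#' 3'-shore-hypomethylated gene sets). Every output file is written under
#' `out_dir`; a `summary.json` reports per-stage counts, the echoed
#' thresholds and the config hash. A stage failure aborts with the stage
#' name; outputs written so far are moved under `out_dir/failed/`.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      existing <- setdiff(list.files(out_dir, full.names = TRUE), failed)
      file.copy(existing, failed, recursive = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- data ---
  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config,
                     utils::modifyList(list(seed = config$seed),
                                       as.list(config$simulate)))
      sim <- simulate_methylome(cfg, out_dir = file.path(out_dir, "data"))
      list(annotation = sim$annotation, reads = sim$reads,
           expression = sim$expression)
    } else {
      inp <- config$input
      ann <- read_annotation(inp$gene_path, inp$cgi_path,
                             band_path = inp$band_path,
                             repeat_path = inp$repeat_path,
                             chrom_sizes_path = inp$chrom_sizes_path,
                             flank_bp = th$flank_bp, shore_bp = th$shore_bp)
      reads <- lapply(inp$reads, read_aligned_reads)
      expr <- if (!is.null(inp$expression_path))
        utils::read.delim(inp$expression_path, stringsAsFactors = FALSE)
      list(annotation = ann, reads = reads, expression = expr)
    }
  })
  ann <- dat$annotation
  reads <- dat$reads
  expr_tab <- dat$expression
  chrom_sizes <- ann$chrom_sizes
  message(sprintf("stage data: %d samples, %d genes, %d CGIs",
                  length(reads), nrow(ann$genes), nrow(ann$cgis)))

  # --- peaks ---
  params <- peak_params(p_threshold = th$p_threshold)
  peaks <- stage("peaks", {
    pk <- lapply(reads, call_peaks, chrom_sizes = chrom_sizes,
                 params = params)
    dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
    for (nm in names(pk))
      write_peaks(pk[[nm]], file.path(out_dir, "peaks",
                                      paste0(nm, ".peaks.bed")))
    pk
  })
  message(sprintf("stage peaks: %s",
                  paste(names(peaks), vapply(peaks, nrow, 0L),
                        sep = "=", collapse = " ")))

  # --- dmrs ---
  case_names <- setdiff(names(reads), names(reads)[1])
  control_name <- names(reads)[1]
  dmr_list <- stage("dmrs", {
    dl <- lapply(case_names, function(nm) {
      cand <- merge_candidate_regions(peaks[[control_name]], peaks[[nm]])
      call_dmrs(cand, reads[[control_name]], reads[[nm]], chrom_sizes,
                q_max = th$q_max, min_fold = th$min_fold)
    })
    names(dl) <- case_names
    dir.create(file.path(out_dir, "dmrs"), showWarnings = FALSE)
    for (nm in case_names)
      write_dmrs(dl[[nm]], file.path(out_dir, "dmrs",
                                     paste0(nm, ".dmrs.tsv")),
                 header = th)
    dl
  })
  message(sprintf("stage dmrs: %s",
                  paste(case_names, vapply(dmr_list, nrow, 0L),
                        sep = "=", collapse = " ")))

  # --- ultra dmrs ---
  ultra <- stage("ultra_dmrs", {
    u <- ultra_dmrs(dmr_list, chrom_sizes, segment_bp = th$segment_bp,
                    min_overlap_bp = th$min_overlap_bp)
    utils::write.table(as.data.frame(u), file.path(out_dir, "ultra_dmrs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    u
  })
  message(sprintf("stage ultra_dmrs: %d segments", nrow(ultra)))

  # --- enrichment ---
  enr <- stage("enrichment", {
    e <- enrichment_test(ultra, ann, segment_bp = th$segment_bp)
    utils::write.table(e, file.path(out_dir, "feature_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ann$bands) && nrow(ann$bands) > 0) {
      b <- band_enrichment(ultra, ann, segment_bp = th$segment_bp)
      utils::write.table(b, file.path(out_dir, "band_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    e
  })

  # --- patterns ---
  calls <- stage("patterns", {
    control_masks <- promoter_masks(ann, peaks[[control_name]],
                                    flank_bp = th$flank_bp)
    case_mask_list <- lapply(case_names, function(nm)
      promoter_masks(ann, peaks[[nm]], flank_bp = th$flank_bp))
    pc <- select_specific_promoters(case_mask_list, control_masks,
                                    min_case_support = th$min_case_support)
    utils::write.table(as.data.frame(pc),
                       file.path(out_dir, "pattern_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pc
  })
  message(sprintf("stage patterns: %d promoter calls", nrow(calls)))

  # --- expression integration ---
  gsea <- NULL
  if (!is.null(expr_tab)) {
    gsea <- stage("expression", {
      count_cols <- setdiff(names(expr_tab), c("gene_id", "length"))
      ctrl_cols <- grep("^control", count_cols, value = TRUE)
      case_cols <- setdiff(count_cols, ctrl_cols)
      rpkm <- compute_rpkm(expr_tab[, count_cols, drop = FALSE],
                           expr_tab$length)
      rownames(rpkm) <- expr_tab$gene_id
      ranked <- rank_genes(rpkm[, case_cols, drop = FALSE],
                           rpkm[, ctrl_cols, drop = FALSE])
      sets <- methylation_gene_sets(ultra, ann)
      res <- list()
      for (nm in names(sets)) {
        set <- intersect(sets[[nm]], ranked$gene_id)
        if (length(set) >= 2 && length(set) < nrow(ranked))
          res[[nm]] <- gsea_permutation_p(ranked, set,
                                          seed = config$seed + 20000)
      }
      lines <- vapply(names(res), function(nm)
        sprintf("%s\t%d\t%.6f\t%.6g", nm, length(sets[[nm]]),
                res[[nm]]$es, res[[nm]]$perm_p), "")
      writeLines(c("# gene_set\tn_genes\tes\tperm_p", lines),
                 file.path(out_dir, "gsea_results.tsv"))
      res
    })
  }

  summary <- list(
    seed = config$seed,
    thresholds = th,
    n_samples = length(reads),
    n_peaks = vapply(peaks, nrow, 0L),
    n_dmrs = vapply(dmr_list, nrow, 0L),
    n_dmrs_hyper = vapply(dmr_list, function(d) sum(d$direction == "hyper"), 0L),
    n_dmrs_hypo = vapply(dmr_list, function(d) sum(d$direction == "hypo"), 0L),
    n_ultra_hyper = sum(ultra$direction == "hyper"),
    n_ultra_hypo = sum(ultra$direction == "hypo"),
    n_enriched_features = sum(enr$enriched),
    n_pattern_calls = as.list(table(calls$pattern)),
    gsea = lapply(gsea, function(g) list(es = g$es, perm_p = g$perm_p)))
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(yaml::as.yaml(unclass(config)), cfg_path)
  # hash the analytic configuration only: the output location must not
  # change the result's identity
  hash_path <- tempfile()
  core <- unclass(config)
  writeLines(yaml::as.yaml(core[setdiff(names(core), "out_dir")]), hash_path)
  summary$config_hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Methylation-defined gene sets for expression integration
#'
#' From consensus (ultra) DMRs: genes whose promoter CGI overlaps a
#' hypermethylated segment (`hyper_promoter_cgi`) and genes whose promoter
#' CGI's 3'-shore (gene orientation) overlaps a hypomethylated segment
#' (`hypo_3p_shore`).
#'
#' @param ultra ultra-DMR table.
#' @param annotation a `genome_annotation`.
#' @return named list of gene-id vectors.
#' @export
methylation_gene_sets <- function(ultra, annotation) {
  prom <- annotation$promoters
  cgis <- annotation$cgis
  shores <- annotation$shores
  hyper <- ultra[ultra$direction == "hyper", , drop = FALSE]
  hypo <- ultra[ultra$direction == "hypo", , drop = FALSE]
  # promoter CGIs: CGIs overlapping a promoter, tagged with the gene
  ph <- overlap_pairs(prom, cgis)
  hyper_genes <- character(0)
  hypo3_genes <- character(0)
  if (nrow(ph) > 0) {
    pc <- cgis[ph$subject, , drop = FALSE]
    hit <- overlaps_any(pc, hyper)
    hyper_genes <- unique(prom$gene_id[ph$query[hit]])
    # 3'-shore in gene orientation: genomic 3p side for + genes, 5p for -
    strand <- prom$strand[ph$query]
    side <- ifelse(strand == "-", "5p", "3p")
    sh_idx <- match(paste(ph$subject, side),
                    paste(shores$cgi_index, shores$side))
    has_shore <- !is.na(sh_idx)
    if (any(has_shore)) {
      sh <- shores[sh_idx[has_shore], , drop = FALSE]
      hit3 <- overlaps_any(sh, hypo)
      hypo3_genes <- unique(prom$gene_id[ph$query[has_shore][hit3]])
    }
  }
  list(hyper_promoter_cgi = hyper_genes, hypo_3p_shore = hypo3_genes)
}
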