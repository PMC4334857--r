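# expression: RPKM quantification, case/control gene ranking, a weighted
# Kolmogorov-Smirnov enrichment score with gene-set permutation, and
# hypergeometric pathway enrichment.

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` where C is the gene's read count, N the
#' sample's total mapped reads and L the gene length in bp (the longest
#' transcript when a gene has several).
#'
#' @param counts matrix or data.frame of counts (genes x samples).
#' @param lengths gene lengths in bp (> 0).
#' @param totals per-sample total mapped reads; defaults to column sums.
#' @return matrix of RPKM values, same shape as `counts`.
#' @export
compute_rpkm <- function(counts, lengths, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("totals must be positive")
  t(1e9 * t(counts / lengths) / totals)
}

#' Rank genes by case/control expression change
#'
#' Metric: `log2((mean case RPKM + pc) / (mean control RPKM + pc))`, sorted
#' descending; ties broken by gene id for determinism.
#'
#' @param case_rpkm,control_rpkm matrices (genes x samples) with identical
#'   rownames (gene ids).
#' @param pseudocount stabilizer (1).
#' @return data.frame (gene_id, metric) in ranked order.
#' @export
rank_genes <- function(case_rpkm, control_rpkm, pseudocount = 1) {
  case_rpkm <- as.matrix(case_rpkm)
  control_rpkm <- as.matrix(control_rpkm)
  ids <- rownames(case_rpkm)
  if (is.null(ids) || !identical(ids, rownames(control_rpkm)))
    stop("case and control must share one gene universe (rownames)")
  metric <- log2((rowMeans(case_rpkm) + pseudocount) /
                   (rowMeans(control_rpkm) + pseudocount))
  ord <- order(-metric, ids)
  data.frame(gene_id = ids[ord], metric = unname(metric[ord]),
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; genes in the set increment the running sum by
#' `|metric|^weight_p` normalized over the set, genes outside decrement by
#' `1 / (N - Nh)`. The enrichment score is the running sum's maximum
#' deviation from zero, signed. With `weight_p = 0` this is the classical
#' unweighted KS statistic between the set and non-set rank distributions.
#'
#' @param ranked data.frame from [rank_genes()] (gene_id, metric).
#' @param gene_set character vector, a strict non-empty subset of the
#'   ranked universe.
#' @param weight_p metric weight exponent (1).
#' @return enrichment score in [-1, 1].
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  n <- nrow(ranked)
  if (nh == 0 || nh == n)
    stop("gene_set must be a non-empty strict subset of the ranked universe")
  w <- abs(ranked$metric)^weight_p
  inc <- numeric(n)
  sw <- sum(w[hit])
  inc[hit] <- if (sw > 0) w[hit] / sw else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Permutation p-value for a gene set's enrichment score
#'
#' The null draws `n_perm` random gene sets of the same size from the
#' ranked universe (gene-set permutation; a single control sample precludes
#' phenotype permutation). `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`,
#' so p is always positive.
#'
#' @inheritParams gsea_es
#' @param n_perm permutations (1000).
#' @param seed RNG seed for the permutation stream.
#' @return list of class `gsea_result`: `es`, `perm_p`, `n_perm`, `seed`.
#' @export
gsea_permutation_p <- function(ranked, gene_set, weight_p = 1,
                               n_perm = 1000, seed = 1) {
  es <- gsea_es(ranked, gene_set, weight_p = weight_p)
  nh <- sum(ranked$gene_id %in% gene_set)
  n <- nrow(ranked)
  set_seed_all(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, nh)
    gsea_es(ranked, ranked$gene_id[idx], weight_p = weight_p)
  }, 0)
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, perm_p = p, n_perm = n_perm, seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, permutation p = %.4g (%d permutations)\n",
              x$es, x$perm_p, x$n_perm))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("malformed GMT line in '", path, "': need name, description, genes")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, "", 1))
}

#' Hypergeometric pathway enrichment
#'
#' For each gene set, the upper-tail hypergeometric probability of seeing at
#' least the observed overlap between `gene_list` and the set within
#' `universe`; BH adjustment across sets. A pathway is flagged when
#' `q < q_flag` and the overlap has at least `min_overlap` genes.
#'
#' @param gene_list genes of interest (subset of `universe`).
#' @param gmt_sets named list of gene sets (see [read_gmt()]); genes outside
#'   the universe are ignored.
#' @param universe the gene universe.
#' @param q_flag adjusted-p threshold (0.05).
#' @param min_overlap minimum overlapping genes (2).
#' @return data.frame: pathway_id, k_overlap, set_size, list_size,
#'   universe_size, p_value, q_value, flagged.
#' @export
pathway_hypergeom <- function(gene_list, gmt_sets, universe,
                              q_flag = 0.05, min_overlap = 2) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe must be non-empty")
  gene_list <- unique(intersect(gene_list, universe))
  rows <- lapply(names(gmt_sets), function(nm) {
    set <- intersect(gmt_sets[[nm]], universe)
    k <- length(intersect(gene_list, set))
    # P(X >= k), X ~ Hypergeom(white = |set|, drawn = |list|)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(gene_list), lower.tail = FALSE)
    data.frame(pathway_id = nm, k_overlap = k, set_size = length(set),
               list_size = length(gene_list),
               universe_size = length(universe), p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$flagged <- res$q_value < q_flag & res$k_overlap >= min_overlap
  rownames(res) <- NULL
  res
}
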