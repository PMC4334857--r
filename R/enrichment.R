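# enrichment: map DMRs/ultra-DMRs to genomic features and test per-feature
# and per-band enrichment with odds ratios and Fisher's exact test on equal
# 500 bp segment units.

# Named list of feature tracks from an annotation; repeats contribute one
# track per repeat class name when present.
feature_tracks <- function(annotation) {
  tr <- list(
    promoter = annotation$promoters,
    mirna_promoter = annotation$mirna_promoters,
    CGI = annotation$cgis,
    `5p-shore` = annotation$shores[annotation$shores$side == "5p", ,
                                   drop = FALSE],
    `3p-shore` = annotation$shores[annotation$shores$side == "3p", ,
                                   drop = FALSE],
    gene_body = annotation$genes)
  reps <- annotation$repeats
  if (!is.null(reps) && nrow(reps) > 0) {
    for (cls in sort(unique(reps$name)))
      tr[[cls]] <- reps[reps$name == cls, , drop = FALSE]
  }
  tr[vapply(tr, function(x) !is.null(x) && nrow(x) > 0, TRUE)]
}

#' Map regions to overlapping genomic features
#'
#' Each region receives every feature class it overlaps (a region can be
#' both promoter and CGI). A region overlapping nothing is assigned the
#' nearest feature within `max_distance_bp`, ties broken by smaller distance
#' then alphabetical class name; beyond that it is "intergenic".
#'
#' @param regions interval table.
#' @param annotation a `genome_annotation`.
#' @param max_distance_bp nearest-feature search radius (10000).
#' @return list (one character vector of feature classes per region).
#' @export
map_to_features <- function(regions, annotation, max_distance_bp = 10000) {
  tracks <- feature_tracks(annotation)
  n <- nrow(regions)
  assigned <- vector("list", n)
  for (nm in names(tracks)) {
    hit <- overlaps_any(regions, tracks[[nm]])
    for (i in which(hit)) assigned[[i]] <- c(assigned[[i]], nm)
  }
  none <- which(vapply(assigned, is.null, TRUE))
  for (i in none) {
    best_class <- NULL
    best_dist <- Inf
    for (nm in sort(names(tracks))) {
      tk <- tracks[[nm]]
      tk <- tk[tk$chrom == regions$chrom[i], , drop = FALSE]
      if (nrow(tk) == 0) next
      gaps <- pmax(tk$start - regions$end[i], regions$start[i] - tk$end)
      d <- min(gaps)
      if (d < best_dist) { best_dist <- d; best_class <- nm }
    }
    assigned[[i]] <- if (!is.null(best_class) && best_dist <= max_distance_bp)
      best_class else "intergenic"
  }
  assigned
}

# 2x2 odds ratio with optional Haldane 0.5 correction on zero cells.
odds_ratio_2x2 <- function(k_in, k_out, bg_in, bg_out) {
  cells <- c(k_in, k_out, bg_in, bg_out)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(or = (cells[1] * cells[4]) / (cells[2] * cells[3]),
       corrected = corrected)
}

#' Enrichment of region segments in genomic feature classes
#'
#' Units are fixed-width genome segments (the ultra-DMR grid). For each
#' feature class the 2x2 table crosses segment group (in `regions` vs the
#' rest of the genome) with feature overlap; the odds ratio is
#' `(k_in * bg_out) / (k_out * bg_in)` with a 0.5 continuity correction when
#' a cell is zero (flagged), significance is the two-sided Fisher exact
#' test, and p-values are BH-adjusted across classes. A class is enriched
#' when `q < q_flag` and OR > 1.
#'
#' @param regions interval table of interest (e.g. ultra DMRs).
#' @param annotation a `genome_annotation`.
#' @param segment_bp segment width (500).
#' @param q_flag adjusted-p threshold for the enriched flag (0.01).
#' @return data.frame: feature_class, k_in, k_out, bg_in, bg_out,
#'   odds_ratio, or_corrected, p_value, q_value, enriched.
#' @export
enrichment_test <- function(regions, annotation, segment_bp = 500,
                            q_flag = 0.01) {
  segs <- genome_bins(annotation$chrom_sizes, segment_bp)
  in_regions <- overlaps_any(segs, regions)
  tracks <- feature_tracks(annotation)
  rows <- lapply(names(tracks), function(nm) {
    in_feat <- overlaps_any(segs, tracks[[nm]])
    k_in <- sum(in_regions & in_feat)
    k_out <- sum(in_regions & !in_feat)
    bg_in <- sum(!in_regions & in_feat)
    bg_out <- sum(!in_regions & !in_feat)
    or <- odds_ratio_2x2(k_in, k_out, bg_in, bg_out)
    p <- stats::fisher.test(matrix(c(k_in, k_out, bg_in, bg_out), 2,
                                   byrow = TRUE))$p.value
    data.frame(feature_class = nm, k_in = k_in, k_out = k_out,
               bg_in = bg_in, bg_out = bg_out, odds_ratio = or$or,
               or_corrected = or$corrected, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$q_value < q_flag & res$odds_ratio > 1
  rownames(res) <- NULL
  res
}

#' Cytogenetic-band enrichment of ultra DMRs
#'
#' Per band, the same segment-unit 2x2 as [enrichment_test()]: segments in
#' the band vs outside, crossed with ultra-DMR membership. Bands with no
#' segments are skipped with a warning. Flagged bands satisfy `q < q_flag`
#' and OR > 1.
#'
#' @param ultra ultra-DMR table (or any interval table).
#' @param annotation `genome_annotation` whose `bands` is non-NULL.
#' @param segment_bp segment width (500).
#' @param q_flag adjusted-p threshold (0.01).
#' @return data.frame: band, k_in, k_out, bg_in, bg_out, odds_ratio,
#'   p_value, q_value, enriched.
#' @export
band_enrichment <- function(ultra, annotation, segment_bp = 500,
                            q_flag = 0.01) {
  bands <- annotation$bands
  if (is.null(bands) || nrow(bands) == 0)
    stop("annotation has no cytogenetic bands")
  segs <- genome_bins(annotation$chrom_sizes, segment_bp)
  is_ultra <- overlaps_any(segs, ultra)
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    in_band <- segs$chrom == bands$chrom[i] & segs$start < bands$end[i] &
      segs$end > bands$start[i]
    if (!any(in_band)) {
      warning("band ", bands$band[i], " contains no segments; skipped")
      return(NULL)
    }
    k_in <- sum(is_ultra & in_band)
    k_out <- sum(is_ultra & !in_band)
    bg_in <- sum(!is_ultra & in_band)
    bg_out <- sum(!is_ultra & !in_band)
    or <- odds_ratio_2x2(k_in, k_out, bg_in, bg_out)
    p <- stats::fisher.test(matrix(c(k_in, k_out, bg_in, bg_out), 2,
                                   byrow = TRUE))$p.value
    data.frame(band = bands$band[i], k_in = k_in, k_out = k_out,
               bg_in = bg_in, bg_out = bg_out, odds_ratio = or$or,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(band = character(0), k_in = numeric(0),
                      k_out = numeric(0), bg_in = numeric(0),
                      bg_out = numeric(0), odds_ratio = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      enriched = logical(0)))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$q_value < q_flag & res$odds_ratio > 1
  rownames(res) <- NULL
  res
}
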