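# patterns: 40-window binarization of promoter methylation, CGI masking,
# five-way pattern classification, and case-/control-specific promoter
# selection.

PATTERNS <- c("CGI_CONFINED", "SHORE_5PRIME", "SHORE_3PRIME", "CGI_OVERLAP",
              "NO_CGI")

#' Binarize a promoter into 40 methylation and CGI windows
#'
#' The promoter (TSS +/- 2 kb, 4000 bp) is divided into forty 100 bp
#' windows, ordered 5' to 3' in gene orientation (minus-strand promoters are
#' reversed). A window is "methylated" (1) when any peak overlaps it by at
#' least one bp; the CGI mask is built the same way from the CGI track.
#' Clipped promoters are padded with unmethylated windows on the clipped
#' side and flagged.
#'
#' @param promoter one-row promoter table (chrom, start, end, strand, tss,
#'   gene_id).
#' @param peaks one sample's peak intervals.
#' @param cgis CGI intervals.
#' @param n_windows number of windows (40).
#' @param flank_bp promoter half-width (2000).
#' @return list of class `promoter_mask`: `gene_id`, `methyl_mask`,
#'   `cgi_mask` (logical vectors of length `n_windows`), `clipped`.
#' @export
binarize_promoter <- function(promoter, peaks, cgis, n_windows = 40,
                              flank_bp = 2000) {
  win_bp <- 2 * flank_bp / n_windows
  # windows laid out on the ideal (unclipped) promoter; clipped windows
  # outside the chromosome stay unmethylated
  ideal_start <- promoter$tss - flank_bp
  ws <- ideal_start + (seq_len(n_windows) - 1) * win_bp
  we <- ws + win_bp
  mask_from <- function(track) {
    if (nrow(track) == 0) return(rep(FALSE, n_windows))
    tk <- track[track$chrom == promoter$chrom, , drop = FALSE]
    if (nrow(tk) == 0) return(rep(FALSE, n_windows))
    vapply(seq_len(n_windows), function(i)
      any(tk$start < we[i] & tk$end > ws[i]), TRUE)
  }
  methyl <- mask_from(peaks)
  cgi <- mask_from(cgis)
  clipped <- isTRUE(promoter$clipped)
  if (clipped) {
    outside <- we <= promoter$start | ws >= promoter$end
    methyl[outside] <- FALSE
  }
  if (promoter$strand == "-") {
    methyl <- rev(methyl)
    cgi <- rev(cgi)
  }
  structure(list(gene_id = promoter$gene_id, methyl_mask = methyl,
                 cgi_mask = cgi, clipped = clipped),
            class = "promoter_mask")
}

#' Classify a promoter's methylation pattern
#'
#' Five patterns, decided in this order: `NO_CGI` when the promoter has no
#' CGI windows; `CGI_CONFINED` when the methylated/CGI window overlap
#' exceeds half the methylated windows or half the CGI windows;
#' `SHORE_5PRIME` when all methylated windows lie 5' of the first CGI
#' window; `SHORE_3PRIME` when all lie 3' of the last CGI window;
#' `CGI_OVERLAP` otherwise (methylation touches the CGI without being
#' confined to it).
#'
#' @param mask a `promoter_mask` with at least one methylated window.
#' @return one of `"CGI_CONFINED"`, `"SHORE_5PRIME"`, `"SHORE_3PRIME"`,
#'   `"CGI_OVERLAP"`, `"NO_CGI"`.
#' @export
classify_pattern <- function(mask) {
  m <- mask$methyl_mask
  cg <- mask$cgi_mask
  if (!any(m)) stop("classify_pattern requires a methylated promoter")
  if (!any(cg)) return("NO_CGI")
  ov <- sum(m & cg)
  if (ov > sum(m) / 2 || ov > sum(cg) / 2) return("CGI_CONFINED")
  if (max(which(m)) < min(which(cg))) return("SHORE_5PRIME")
  if (min(which(m)) > max(which(cg))) return("SHORE_3PRIME")
  "CGI_OVERLAP"
}

#' Select case- and control-specific promoters and classify their patterns
#'
#' A promoter is methylated in a sample when its mask has any methylated
#' window. Case-specific promoters are methylated in at least
#' `min_case_support` case samples and unmethylated in the control; their
#' pattern is classified on the union of the supporting case masks.
#' Control-specific promoters are methylated in the control and in at most
#' `n_case - min_case_support` case samples; their pattern comes from the
#' control mask.
#'
#' @param case_masks list (one element per case sample) of lists of
#'   `promoter_mask`, all over the same promoter set in the same order.
#' @param control_masks list of `promoter_mask` for the control sample.
#' @param min_case_support minimum supporting case samples (4).
#' @return data.frame of class `pattern_calls`: gene_id, specificity,
#'   pattern, n_supporting_samples, methyl_mask, cgi_mask (40-char 0/1
#'   strings; the union mask used for classification).
#' @export
select_specific_promoters <- function(case_masks, control_masks,
                                      min_case_support = 4) {
  n_case <- length(case_masks)
  n_prom <- length(control_masks)
  stopifnot(all(vapply(case_masks, length, 0L) == n_prom))
  mask_str <- function(x) paste(as.integer(x), collapse = "")
  rows <- list()
  for (i in seq_len(n_prom)) {
    ctrl <- control_masks[[i]]
    case_meth <- vapply(case_masks, function(s) any(s[[i]]$methyl_mask), TRUE)
    n_support <- sum(case_meth)
    ctrl_meth <- any(ctrl$methyl_mask)
    if (!ctrl_meth && n_support >= min_case_support) {
      union_mask <- Reduce(`|`, lapply(case_masks[case_meth],
                                       function(s) s[[i]]$methyl_mask))
      mk <- list(methyl_mask = union_mask, cgi_mask = ctrl$cgi_mask)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = ctrl$gene_id, specificity = "case_specific",
        pattern = classify_pattern(mk), n_supporting_samples = n_support,
        methyl_mask = mask_str(union_mask), cgi_mask = mask_str(ctrl$cgi_mask),
        stringsAsFactors = FALSE)
    } else if (ctrl_meth && n_support <= n_case - min_case_support) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = ctrl$gene_id, specificity = "control_specific",
        pattern = classify_pattern(ctrl), n_supporting_samples = n_support,
        methyl_mask = mask_str(ctrl$methyl_mask),
        cgi_mask = mask_str(ctrl$cgi_mask), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows) == 0) {
    data.frame(gene_id = character(0), specificity = character(0),
               pattern = character(0), n_supporting_samples = integer(0),
               methyl_mask = character(0), cgi_mask = character(0))
  } else do.call(rbind, rows)
  class(res) <- c("pattern_calls", "data.frame")
  res
}

#' Build promoter masks for every promoter of an annotation
#'
#' Convenience wrapper over [binarize_promoter()] for one sample's peaks.
#' @param annotation a `genome_annotation`.
#' @param peaks one sample's peak table.
#' @param n_windows,flank_bp see [binarize_promoter()].
#' @return list of `promoter_mask`, one per promoter row.
#' @export
promoter_masks <- function(annotation, peaks, n_windows = 40,
                           flank_bp = 2000) {
  prom <- annotation$promoters
  lapply(seq_len(nrow(prom)), function(i)
    binarize_promoter(prom[i, , drop = FALSE], peaks, annotation$cgis,
                      n_windows = n_windows, flank_bp = flank_bp))
}
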