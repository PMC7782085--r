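## cnv_caller: two-step median normalization of amplicon counts, exact
## penalized least-squares segmentation of coordinate-ordered log2 ratios,
## and status calling at fixed log2 thresholds.

#' CNV status thresholds on the segment median log2 ratio
#'
#' The two outer thresholds are strict inequalities: a segment is a
#' homozygous deletion when its median log2 ratio is `< -1` and an
#' amplification when `> 2`. The intermediate classes (single-copy loss and
#' gain) are not part of the published calling rule and default to the ideal
#' single-copy values at 50% tumour content: `log2(1 - 0.5/2) ~ -0.415` for
#' a heterozygous deletion (inclusive `<=`) and `log2(1 + 0.5) ~ 0.585` for
#' a gain (inclusive `>=`); both are configurable and should be treated as
#' extrapolations.
#'
#' @param homdel,amp strict outer thresholds.
#' @param hetdel,gain inclusive intermediate thresholds.
#' @return named list of thresholds.
#' @export
cnv_thresholds <- function(homdel = -1, amp = 2,
                           hetdel = -0.41, gain = 0.58) {
  list(homdel = homdel, amp = amp, hetdel = hetdel, gain = gain)
}

#' Median-normalize a raw amplicon count matrix
#'
#' Raw counts are first divided by the median over all amplicons per barcode
#' (library-size step), then by the median over all barcodes per amplicon
#' (amplicon-efficiency step). Blacklisted amplicons are removed before
#' normalization; zero counts are replaced by a pseudocount before the log2.
#'
#' @param raw numeric matrix, rows = amplicon ids, columns = barcodes.
#' @param manifest optional [panel_manifest()]; when given, rows are
#'   restricted to its non-blacklisted amplicons (in manifest order).
#' @param pseudocount value substituted for zero counts.
#' @return list of class `normalized_matrix` with `values` (normalized
#'   ratios) and `log2`.
#' @export
normalize_counts <- function(raw, manifest = NULL, pseudocount = 0.5) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  if (ncol(raw) < 2)
    stop("normalization needs at least 2 barcodes")
  if (!is.null(manifest)) {
    keep <- manifest$id[!manifest$blacklisted]
    missing_ids <- setdiff(keep, rownames(raw))
    if (length(missing_ids))
      stop("count matrix lacks amplicon(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    raw <- raw[keep, , drop = FALSE]
  }
  zero_bc <- colSums(raw) == 0
  if (any(zero_bc))
    stop("barcode(s) with all-zero counts: ",
         paste(colnames(raw)[zero_bc], collapse = ", "))
  v <- raw
  v[v == 0] <- pseudocount
  v <- sweep(v, 2, apply(v, 2, median), "/")   # per-barcode median
  v <- sweep(v, 1, apply(v, 1, median), "/")   # per-amplicon median
  structure(list(values = v, log2 = log2(v)), class = "normalized_matrix")
}

#' Segment an ordered log2-ratio vector
#'
#' Exact dynamic-programming minimization of the within-segment sum of
#' squared deviations plus `penalty` per segment, over all partitions of the
#' vector into contiguous segments. The default penalty is a modified-BIC
#' form, `2 * sigma^2 * log(n)`, with `sigma` estimated robustly from the
#' median absolute successive difference (`median|x[i+1]-x[i]| /
#' (0.6745 * sqrt(2))`). Each segment is summarized by the median of its
#' log2 values.
#'
#' @param x numeric vector of log2 ratios, in genome-coordinate order.
#' @param penalty per-segment penalty (> 0); `NULL` for the default.
#' @return data.frame (start_idx, end_idx, n_amplicons, mean_log2,
#'   median_log2) partitioning `seq_along(x)`.
#' @export
segment_log2 <- function(x, penalty = NULL) {
  if (length(x) == 0)
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      n_amplicons = integer(0), mean_log2 = numeric(0),
                      median_log2 = numeric(0)))
  if (any(!is.finite(x))) stop("non-finite values in log2 vector")
  if (is.null(penalty)) {
    sigma <- if (length(x) >= 2)
      median(abs(diff(x))) / (0.6745 * sqrt(2)) else 0
    penalty <- max(2 * sigma^2 * log(length(x)), 1e-8)
  }
  if (penalty <= 0) stop("penalty must be > 0")
  ends <- dp_segment_ends(as.numeric(x), penalty)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  .fast_df(list(
    start_idx = starts, end_idx = ends,
    n_amplicons = ends - starts + 1L,
    mean_log2 = vapply(seq_along(ends), function(k)
      mean(x[starts[k]:ends[k]]), numeric(1)),
    median_log2 = vapply(seq_along(ends), function(k)
      median(x[starts[k]:ends[k]]), numeric(1))))
}

# data.frame constructor without the name-deparsing overhead (hot path)
.fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = if (length(lst[[1]]))
              seq_along(lst[[1]]) else integer(0))
}

#' Call the CNV status of segment medians
#'
#' @param median_log2 numeric vector of segment median log2 ratios.
#' @param thresholds a [cnv_thresholds()] list.
#' @return character vector in `c("homozygous_deletion",
#'   "heterozygous_deletion", "normal", "gain", "amplification")`.
#' @export
call_status <- function(median_log2, thresholds = cnv_thresholds()) {
  ifelse(median_log2 < thresholds$homdel, "homozygous_deletion",
  ifelse(median_log2 > thresholds$amp, "amplification",
  ifelse(median_log2 <= thresholds$hetdel, "heterozygous_deletion",
  ifelse(median_log2 >= thresholds$gain, "gain", "normal"))))
}

#' Segment one barcode's log2 profile along the panel
#'
#' Segments each chromosome independently (the ordered-amplicon axis does
#' not cross chromosome boundaries) and attaches CNV statuses.
#'
#' @param log2_vec named log2 vector over the analysed (non-blacklisted)
#'   amplicons, in manifest order.
#' @param manifest_used the manifest rows matching `log2_vec` (same order).
#' @param penalty,thresholds passed to [segment_log2()] / [call_status()].
#' @return data.frame of class `segmented_profile`: chrom, start_idx,
#'   end_idx (global amplicon indices), n_amplicons, median_log2, status.
#' @export
segment_profile <- function(log2_vec, manifest_used, penalty = NULL,
                            thresholds = cnv_thresholds()) {
  stopifnot(length(log2_vec) == nrow(manifest_used))
  segs <- lapply(unique(manifest_used$chrom), function(ch) {
    idx <- which(manifest_used$chrom == ch)
    s <- segment_log2(log2_vec[idx], penalty)
    s$start_idx <- idx[s$start_idx]
    s$end_idx <- idx[s$end_idx]
    s$chrom <- rep(ch, nrow(s))
    s
  })
  out <- do.call(rbind, segs)
  out$status <- call_status(out$median_log2, thresholds)
  out <- out[, c("chrom", "start_idx", "end_idx", "n_amplicons",
                 "mean_log2", "median_log2", "status")]
  class(out) <- c("segmented_profile", "data.frame")
  out
}

# map each amplicon index to its covering segment row
.segment_of <- function(profile, n_amplicons) {
  seg <- integer(n_amplicons)
  for (k in seq_len(nrow(profile)))
    seg[profile$start_idx[k]:profile$end_idx[k]] <- k
  seg
}

#' Gene-level CNV calls, optionally requiring dual-panel consensus
#'
#' A gene's status is the non-normal status covering the majority (> 50%) of
#' its analysed amplicons, else `"normal"`; its value is the median of the
#' covering-segment medians over the gene's amplicons. With
#' `panel_consensus = TRUE` a call is emitted only when both panels agree on
#' the status, and the reported value is taken from panel A; disagreements
#' are recorded in the `discordant_genes` attribute.
#'
#' @param profile_a [segment_profile()] of panel A.
#' @param manifest_used manifest rows the profiles were computed on.
#' @param profile_b panel B profile (required when `panel_consensus`).
#' @param panel_consensus require both panels to agree.
#' @return data.frame of class `cnv_calls` (gene, status, median_log2,
#'   n_amplicons, panel_id) holding the non-normal calls.
#' @export
gene_level_calls <- function(profile_a, manifest_used, profile_b = NULL,
                             panel_consensus = !is.null(profile_b)) {
  if (panel_consensus && is.null(profile_b))
    stop("panel_consensus requires both panel profiles")
  gf <- factor(manifest_used$gene, levels = unique(manifest_used$gene))
  gene_status <- function(profile) {
    seg_of <- .segment_of(profile, nrow(manifest_used))
    st <- split(profile$status[seg_of], gf)
    md <- split(profile$median_log2[seg_of], gf)
    status <- vapply(st, function(s) {
      nn <- s[s != "normal"]
      if (!length(nn)) return("normal")
      tab <- table(nn)
      if (max(tab) > length(s) / 2) names(tab)[which.max(tab)] else "normal"
    }, character(1), USE.NAMES = FALSE)
    .fast_df(list(gene = levels(gf), status = status,
                  median_log2 = vapply(md, median, numeric(1),
                                       USE.NAMES = FALSE),
                  n_amplicons = as.integer(table(gf))))
  }
  a <- gene_status(profile_a)
  if (panel_consensus) {
    b <- gene_status(profile_b)
    agree <- a$status == b$status
    discordant <- a$gene[!agree & (a$status != "normal" | b$status != "normal")]
    out <- a[agree & a$status != "normal", , drop = FALSE]
  } else {
    discordant <- character(0)
    out <- a[a$status != "normal", , drop = FALSE]
  }
  out$panel_id <- rep("A", nrow(out))
  rownames(out) <- NULL
  attr(out, "discordant_genes") <- discordant
  class(out) <- c("cnv_calls", "data.frame")
  out
}
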