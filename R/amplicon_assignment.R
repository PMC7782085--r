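## amplicon_assignment: read pairs -> per-amplicon raw counts + run QC.
## A pair is assigned to the unique amplicon whose start matches the 5' read
## start and whose end matches the 3' read end within +/- tolerance bases;
## pairs whose two ends match *different* amplicons are PCR fusions and are
## excluded; everything else is unassigned.

#' Assign read pairs to panel amplicons
#'
#' Both fragment extremities must match one amplicon's extremities within
#' `tolerance` bases. When two overlapping amplicons both satisfy the match,
#' the tie is broken by the smallest combined absolute offset, then by
#' manifest order (the ambiguity is counted in the `n_ambiguous` attribute).
#' A pair matching the start of one amplicon and the end of a different one
#' is classified `"FUSED"`; any other pair is `"UNASSIGNED"`.
#'
#' @param pairs a `read_pairs` data.frame (mapped, proper, non-singleton
#'   pairs; others should be tallied upstream by [count_amplicons()]).
#' @param manifest a [panel_manifest()].
#' @param tolerance maximum absolute offset per extremity in bases.
#' @return character vector (one element per pair) of amplicon ids,
#'   `"FUSED"` or `"UNASSIGNED"`, with attribute `n_ambiguous`.
#' @export
assign_pairs <- function(pairs, manifest, tolerance = 3) {
  n <- nrow(pairs)
  out <- rep("UNASSIGNED", n)
  if (n == 0) {
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  offs <- seq(-tolerance, tolerance)
  na <- nrow(manifest)
  smap <- data.frame(key = paste0(rep(manifest$chrom, each = length(offs)), ":",
                                  rep(manifest$start, each = length(offs)) +
                                    offs),
                     amp = rep(seq_len(na), each = length(offs)),
                     off = abs(rep(offs, na)), stringsAsFactors = FALSE)
  emap <- data.frame(key = paste0(rep(manifest$chrom, each = length(offs)), ":",
                                  rep(manifest$end, each = length(offs)) +
                                    offs),
                     amp = rep(seq_len(na), each = length(offs)),
                     off = abs(rep(offs, na)), stringsAsFactors = FALSE)
  pk1 <- paste0(pairs$chrom, ":", pairs$r1_start)
  pk2 <- paste0(pairs$chrom, ":", pairs$r2_end)
  c1 <- merge(data.frame(pair = seq_len(n), key = pk1,
                         stringsAsFactors = FALSE), smap, by = "key")
  c2 <- merge(data.frame(pair = seq_len(n), key = pk2,
                         stringsAsFactors = FALSE), emap, by = "key")
  both <- merge(c1[, c("pair", "amp", "off")], c2[, c("pair", "amp", "off")],
                by = c("pair", "amp"), suffixes = c("1", "2"))
  n_ambiguous <- 0L
  if (nrow(both)) {
    both$score <- both$off1 + both$off2
    both <- both[order(both$pair, both$score, both$amp), ]
    n_ambiguous <- sum(table(both$pair) > 1L)
    best <- both[!duplicated(both$pair), ]
    out[best$pair] <- manifest$id[best$amp]
  }
  fused <- intersect(unique(c1$pair), unique(c2$pair))
  fused <- setdiff(fused, if (nrow(both)) unique(both$pair) else integer(0))
  out[fused] <- "FUSED"
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' @rdname assign_pairs
#' @param pair a single-row `read_pairs` data.frame.
#' @export
assign_pair <- function(pair, manifest, tolerance = 3) {
  as.character(assign_pairs(pair, manifest, tolerance))
}

#' Primer-trimmed insert spans of amplicons
#'
#' The sequenced primers are part of the synthetic oligo, not of the sampled
#' genome, so coverage and pileup computations downstream must use the
#' insert `[start + fwd_primer_len, end - rev_primer_len)` only. Amplicons
#' whose trimmed span is empty are dropped (and counted).
#'
#' @param manifest a [panel_manifest()].
#' @param ids amplicon ids to trim (default all).
#' @return data.frame (id, chrom, insert_start, insert_end) with attribute
#'   `n_dropped` (empty inserts).
#' @export
trim_primers <- function(manifest, ids = manifest$id) {
  i <- match(ids, manifest$id)
  if (anyNA(i)) stop("unknown amplicon id(s)")
  out <- data.frame(id = manifest$id[i], chrom = manifest$chrom[i],
                    insert_start = manifest$start[i] + manifest$fwd_primer_len[i],
                    insert_end = manifest$end[i] - manifest$rev_primer_len[i],
                    stringsAsFactors = FALSE)
  empty <- out$insert_start >= out$insert_end
  res <- out[!empty, , drop = FALSE]
  attr(res, "n_dropped") <- sum(empty)
  res
}

#' Per-amplicon raw counts for one barcode
#'
#' Counts assigned pairs per amplicon; fused and unassigned pairs are
#' excluded from the counts but tallied, as are unmapped/improper pairs and
#' upstream singletons. The result is independent of the input order of the
#' alignment stream.
#'
#' @inheritParams assign_pairs
#' @param barcode_id,panel_id labels stored on the result.
#' @return list of class `sample_counts`: `raw` (named integer vector over
#'   all manifest amplicons), read tallies (`n_total_reads`, `n_aligned`,
#'   `n_assigned`; reads = 2 x pairs) and a `tally` breakdown in pairs
#'   (`assigned`, `unassigned`, `fused`, `singleton`, `unmapped`, `total`).
#' @export
count_amplicons <- function(pairs, manifest, tolerance = 3,
                            barcode_id = "A", panel_id = "A") {
  n_singleton <- attr(pairs, "n_singleton") %||% 0L
  n_unmapped_up <- attr(pairs, "n_unmapped") %||% 0L
  usable <- pairs$mapped & pairs$proper_pair
  res <- assign_pairs(pairs[usable, , drop = FALSE], manifest, tolerance)
  raw <- table(factor(res[!res %in% c("FUSED", "UNASSIGNED")],
                      levels = manifest$id))
  raw <- setNames(as.integer(raw), manifest$id)
  tally <- c(assigned = sum(!res %in% c("FUSED", "UNASSIGNED")),
             unassigned = sum(res == "UNASSIGNED"),
             fused = sum(res == "FUSED"),
             singleton = as.integer(n_singleton),
             unmapped = sum(!usable) + as.integer(n_unmapped_up))
  tally <- c(tally, total = sum(tally))
  structure(list(barcode_id = barcode_id, panel_id = panel_id, raw = raw,
                 n_total_reads = 2L * tally[["total"]],
                 n_aligned = 2L * as.integer(sum(usable)),
                 n_assigned = 2L * tally[["assigned"]],
                 tally = tally,
                 n_ambiguous = attr(res, "n_ambiguous")),
            class = "sample_counts")
}

#' Run-level quality-control report for one barcode
#'
#' Flags a run below one million sequenced reads, reports the percentage of
#' aligned and of aligned-and-processed (assigned) reads, and the fraction
#' of target coding bases covered at >= 100X / 300X / 1000X. Depth is
#' computed over primer-trimmed inserts only, each assigned pair covering
#' its amplicon's insert.
#'
#' @param counts a [count_amplicons()] result.
#' @param manifest a [panel_manifest()] (used to compute depth when `depth`
#'   is not supplied).
#' @param depth optional named list per chromosome of base-level depth
#'   [IRanges::RleList]-like structure; normally left `NULL`.
#' @param thresholds depth tiers to report.
#' @return list of class `qc_report`.
#' @export
qc_report <- function(counts, manifest, depth = NULL,
                      thresholds = c(100, 300, 1000)) {
  stopifnot(inherits(counts, "sample_counts"))
  if (is.null(depth)) {
    tr <- trim_primers(manifest)
    tr$count <- counts$raw[tr$id]
    cov <- lapply(split(tr, tr$chrom), function(d) {
      IRanges::coverage(IRanges::IRanges(d$insert_start + 1L, d$insert_end),
                        weight = as.numeric(d$count))
    })
    target_len <- sum(vapply(split(tr, tr$chrom), function(d)
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(d$insert_start + 1L, d$insert_end)))), numeric(1)))
  } else {
    cov <- depth
    target_len <- sum(vapply(cov, length, numeric(1)))
  }
  cov_at <- vapply(thresholds, function(thr) {
    covered <- sum(vapply(cov, function(r)
      sum(S4Vectors::runLength(r)[S4Vectors::runValue(r) >= thr]), numeric(1)))
    covered / target_len
  }, numeric(1))
  structure(list(
    n_total_reads = counts$n_total_reads,
    read_warning = counts$n_total_reads < 1e6,
    pct_aligned = 100 * counts$n_aligned / max(counts$n_total_reads, 1L),
    pct_aligned_processed = 100 * counts$n_assigned /
      max(counts$n_total_reads, 1L),
    coverage_pct_at = setNames(cov_at, paste0(thresholds, "X"))),
    class = "qc_report")
}
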