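## variant_filter: reportable variants from candidate calls / pileups at
## explicit thresholds, long-indel routing, and dual-panel consensus.

#' Report variants passing the depth / alt-read / allele-ratio filter
#'
#' A candidate is reported iff the alternative allele is supported by at
#' least `min_alt_reads` reads, the locus is covered by at least `min_depth`
#' reads, and the allelic ratio is at least `min_af`. All three gates are
#' inclusive (`>=`). The defaults are the pipeline's reporting thresholds:
#' 1 alt read, 30X, 1%.
#'
#' @param variants a [variant_table()] (or data.frame with `depth` and
#'   `alt_reads` columns), computed over primer-trimmed spans.
#' @param min_depth minimum locus depth (reads).
#' @param min_alt_reads minimum reads supporting the alternative allele.
#' @param min_af minimum allelic ratio (fraction).
#' @return the reported subset, same class as the input.
#' @export
report_variants <- function(variants, min_depth = 30, min_alt_reads = 1,
                            min_af = 0.01) {
  af <- ifelse(variants$depth > 0, variants$alt_reads / variants$depth, 0)
  keep <- variants$alt_reads >= min_alt_reads &
    variants$depth >= min_depth &
    af >= min_af
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Route indels by size
#'
#' Amplicon chemistry needs a dedicated split-read strategy for
#' intermediate-size indels: records with `indel_len > 10` bases are routed
#' to that path (`"intermediate_indel_path"`), smaller indels stay on the
#' standard pileup path (`"small_indel_path"`). Detection on the
#' intermediate path is outside this package; routing only tags the records.
#'
#' @param variants a [variant_table()]; every row must be an indel
#'   (`frameshift_indel` or `inframe_indel`, or `indel_len > 0`).
#' @return character vector of routes per record.
#' @export
route_indel <- function(variants) {
  is_indel <- variants$consequence %in% c("frameshift_indel", "inframe_indel") |
    variants$indel_len > 0
  if (!all(is_indel))
    stop("route_indel applies to indel records only")
  ifelse(variants$indel_len > 10, "intermediate_indel_path",
         "small_indel_path")
}

.variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Dual-panel consensus of reported variants
#'
#' The two barcodes of a sample ("panels" A and B) target both DNA strands
#' over the same loci; an alteration is retained only when found by both,
#' and the reported allele frequency and depth are taken from panel A.
#'
#' @param records_a,records_b reported [variant_table()]s of panels A and B.
#' @return consensus `variant_table` (panel A values), with attribute
#'   `n_dropped_a` = reported-in-A-only records that were discarded.
#' @export
panel_consensus <- function(records_a, records_b) {
  ka <- .variant_key(records_a)
  kb <- .variant_key(records_b)
  keep <- ka %in% kb
  out <- records_a[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_a") <- sum(!keep)
  out
}

#' Pileup-style allele counts to candidate records
#'
#' Turns per-site allele counts into a candidate [variant_table()], one row
#' per non-reference allele. This stands in for an external pileup caller;
#' the package's contract is the reporting filter, not base-level calling.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `depth` and
#'   one column per observed alternative allele count, or long format with
#'   `alt`, `alt_reads`.
#' @param gene,consequence annotations applied to all rows (vectors allowed).
#' @return a [variant_table()].
#' @export
pileup_to_records <- function(sites, gene = "NA", consequence = "missense") {
  stopifnot(all(c("chrom", "pos", "ref", "depth", "alt", "alt_reads") %in%
                  names(sites)))
  if (any(rowSums(sites[, "alt_reads", drop = FALSE]) > sites$depth))
    stop("allele counts exceed site depth")
  variant_table(data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = rep_len(gene, nrow(sites)),
    consequence = rep_len(consequence, nrow(sites)),
    depth = sites$depth, alt_reads = sites$alt_reads,
    stringsAsFactors = FALSE))
}
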