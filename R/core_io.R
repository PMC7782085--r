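## core_io: domain containers and readers/writers for the plain-text formats
## the pipeline touches. All genomic intervals are 0-based half-open
## internally; the only places that convention changes are the 1-based
## converters for SAM (POS) and VCF-like export.

#' Construct a panel manifest
#'
#' A panel manifest is the coordinate backbone of the pipeline: the ordered
#' list of PCR amplicons (0-based half-open intervals) with their primer
#' lengths, gene labels and an analysis blacklist flag. Amplicons are sorted
#' by (chrom, start); identifiers must be unique; each amplicon must be
#' longer than its two primers combined.
#'
#' @param amplicons data.frame with columns `chrom`, `start`, `end`, `id`,
#'   `gene`, `fwd_primer_len`, `rev_primer_len` and optionally `blacklisted`.
#' @param panel_id label of the sequencing panel/barcode set ("A" or "B");
#'   the two panels of a run target both DNA strands over the same loci.
#' @param genome_build free-text genome build label.
#' @return A `panel_manifest`: the validated, sorted amplicon data.frame with
#'   `panel_id` and `genome_build` attributes.
#' @export
panel_manifest <- function(amplicons, panel_id = "A", genome_build = "hg19") {
  required <- c("chrom", "start", "end", "id", "gene",
                "fwd_primer_len", "rev_primer_len")
  missing_cols <- setdiff(required, names(amplicons))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(amplicons$blacklisted)) amplicons$blacklisted <- FALSE
  amplicons$chrom <- as.character(amplicons$chrom)
  amplicons$id <- as.character(amplicons$id)
  amplicons$gene <- as.character(amplicons$gene)
  for (col in c("start", "end", "fwd_primer_len", "rev_primer_len"))
    amplicons[[col]] <- as.integer(amplicons[[col]])
  amplicons$blacklisted <- as.logical(amplicons$blacklisted)

  if (anyDuplicated(amplicons$id))
    stop("duplicate amplicon id(s): ",
         paste(unique(amplicons$id[duplicated(amplicons$id)]), collapse = ", "))
  bad <- which(amplicons$start >= amplicons$end)
  if (length(bad))
    stop("amplicon(s) with start >= end at row(s): ", paste(bad, collapse = ", "))
  short <- which(amplicons$end - amplicons$start <=
                   amplicons$fwd_primer_len + amplicons$rev_primer_len)
  if (length(short))
    stop("amplicon(s) shorter than their combined primers at row(s): ",
         paste(short, collapse = ", "))

  ord <- order(amplicons$chrom, amplicons$start, amplicons$end)
  if (!identical(ord, seq_len(nrow(amplicons))))
    message("manifest rows were not coordinate-sorted; sorting by (chrom, start)")
  amplicons <- amplicons[ord, , drop = FALSE]
  rownames(amplicons) <- NULL
  structure(amplicons,
            panel_id = panel_id,
            genome_build = genome_build,
            class = c("panel_manifest", "data.frame"))
}

#' Read a panel manifest from a BED-like TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `start`, `end`,
#' `id`, `gene`, `fwd_primer_len`, `rev_primer_len`, `blacklisted`
#' (0-based half-open coordinates, as in BED). Rows are validated and
#' coordinate-sorted; duplicate ids and degenerate intervals are rejected.
#'
#' @param path file path.
#' @inheritParams panel_manifest
#' @return A [panel_manifest()].
#' @export
read_panel_manifest <- function(path, panel_id = "A", genome_build = "hg19") {
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse manifest '", path, "': ",
                             conditionMessage(e)))
  for (col in c("start", "end", "fwd_primer_len", "rev_primer_len")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed manifest row at line ", bad[1] + 1L,
           " (column '", col, "')")
    df[[col]] <- v
  }
  panel_manifest(df, panel_id = panel_id, genome_build = genome_build)
}

#' Write a panel manifest to its BED-like TSV form
#'
#' Inverse of [read_panel_manifest()]: writing then re-reading a canonical
#' (sorted, validated) manifest is byte-identical.
#'
#' @param manifest a [panel_manifest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, c("chrom", "start", "end", "id", "gene",
                                    "fwd_primer_len", "rev_primer_len",
                                    "blacklisted")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a read-pair alignment table
#'
#' One row per sequenced fragment: `r1_start` is the 0-based mapped start of
#' the 5' read, `r2_end` the 0-based half-open end of the 3' read. Pairs with
#' `r1_start >= r2_end` are flagged invalid (`mapped = FALSE`).
#'
#' @param read_id,chrom character vectors.
#' @param r1_start,r2_end integer vectors (0-based half-open fragment span).
#' @param mapped,proper_pair logical vectors.
#' @return data.frame of class `read_pairs`.
#' @export
read_pairs <- function(read_id, chrom, r1_start, r2_end,
                       mapped = TRUE, proper_pair = TRUE) {
  df <- data.frame(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   r1_start = as.integer(r1_start),
                   r2_end = as.integer(r2_end),
                   mapped = rep_len(as.logical(mapped), length(read_id)),
                   proper_pair = rep_len(as.logical(proper_pair), length(read_id)),
                   stringsAsFactors = FALSE)
  bad <- df$mapped & df$r1_start >= df$r2_end
  if (any(bad)) df$mapped[bad] <- FALSE
  class(df) <- c("read_pairs", "data.frame")
  df
}

#' Read paired alignments from a SAM/BAM file
#'
#' Reads the minimal fields (QNAME, FLAG, RNAME, POS, CIGAR) through
#' Rsamtools, reconstructs fragment spans per read pair on the reference
#' (CIGAR-aware), and flags singleton/unmapped records, which downstream
#' counting discards. Unparseable records are skipped and counted.
#'
#' @param path a SAM or BAM file. SAM input is converted in a temporary
#'   directory via [Rsamtools::asBam()].
#' @return A `read_pairs` data.frame with attribute `n_skipped` (records that
#'   could not be paired or parsed) and `n_singleton`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = prm)[[1]]
  n <- length(rec$qname)
  if (n == 0) return(read_pairs(character(0), character(0),
                                integer(0), integer(0)))
  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  mate_unmapped <- bitwAnd(flag, 8L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  width <- rep(NA_integer_, n)
  ok <- !unmapped & !is.na(rec$cigar)
  width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[ok])
  start0 <- rec$pos - 1L # SAM POS is 1-based
  end0 <- start0 + width

  keep <- ok & !is.na(rec$qname)
  n_skipped <- sum(!ok & !unmapped)
  df <- data.frame(qname = rec$qname[keep], chrom = as.character(rec$rname[keep]),
                   start0 = start0[keep], end0 = end0[keep],
                   proper = proper[keep], mate_unmapped = mate_unmapped[keep],
                   stringsAsFactors = FALSE)
  cnt <- table(df$qname)
  singletons <- names(cnt)[cnt == 1L]
  is_single <- df$qname %in% singletons | df$mate_unmapped
  n_singleton <- length(unique(df$qname[is_single]))
  pairs_df <- df[!is_single, , drop = FALSE]
  out <- if (nrow(pairs_df)) {
    sp <- split(seq_len(nrow(pairs_df)), pairs_df$qname)
    r1s <- vapply(sp, function(i) min(pairs_df$start0[i]), integer(1))
    r2e <- vapply(sp, function(i) max(pairs_df$end0[i]), integer(1))
    chr <- vapply(sp, function(i) pairs_df$chrom[i[1]], character(1))
    prp <- vapply(sp, function(i) all(pairs_df$proper[i]), logical(1))
    read_pairs(names(sp), chr, r1s, r2e, mapped = TRUE, proper_pair = prp)
  } else {
    read_pairs(character(0), character(0), integer(0), integer(0))
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_singleton") <- n_singleton
  attr(out, "n_unmapped") <- sum(unmapped & !mate_unmapped)
  out
}

#' Write read pairs as a minimal SAM file
#'
#' Emits two 75 bp-style records per fragment (R1 at the fragment start, R2
#' ending at the fragment end) with proper-pair flags, so that
#' [read_alignments()] round-trips the fragment spans. Reference lengths in
#' the header are taken from the manifest extent.
#'
#' @param pairs a `read_pairs` data.frame.
#' @param manifest a [panel_manifest()] (for header `@SQ` lines).
#' @param path output path (".sam").
#' @param read_len nominal read length used to split a fragment into R1/R2.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, manifest, path, read_len = 75L) {
  chroms <- unique(c(manifest$chrom, pairs$chrom))
  ln <- vapply(chroms, function(ch) {
    mx <- max(c(manifest$end[manifest$chrom == ch],
                pairs$r2_end[pairs$chrom == ch], 0L))
    as.integer(mx + 1000L)
  }, integer(1))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, ln))
  lines <- hdr
  if (nrow(pairs)) {
    flag1 <- ifelse(pairs$proper_pair, 99L, 65L)   # paired, proper, mate rev
    flag2 <- ifelse(pairs$proper_pair, 147L, 129L)
    w1 <- pmin(read_len, pairs$r2_end - pairs$r1_start)
    w2 <- pmin(read_len, pairs$r2_end - pairs$r1_start)
    pos1 <- pairs$r1_start + 1L                    # to 1-based SAM POS
    pos2 <- pairs$r2_end - w2 + 1L
    tlen <- pairs$r2_end - pairs$r1_start
    rec1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                    pairs$read_id, flag1, pairs$chrom, pos1, w1, pos2, tlen)
    rec2 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                    pairs$read_id, flag2, pairs$chrom, pos2, w2, pos1, -tlen)
    lines <- c(lines, as.vector(rbind(rec1, rec2)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a per-amplicon count matrix
#'
#' TSV with amplicon ids as the first column (`amplicon_id`) and one column
#' per barcode.
#'
#' @param path file path.
#' @return For `read_count_matrix`, a numeric matrix (amplicons x barcodes).
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_count_matrix
#' @param counts numeric matrix, rows = amplicon ids, cols = barcode ids.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(amplicon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a candidate-variant table
#'
#' One row per candidate call with the columns the downstream filter and
#' validation rules consume. `pos` is 0-based; [write_variants()] exports
#' 1-based positions (VCF convention) and [read_variants()] converts back.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `depth`, `alt_reads`, and optionally `indel_len`,
#'   `exon_edge_distance`, `protein_change`.
#' @return data.frame of class `variant_table` with `allele_freq` computed.
#' @export
variant_table <- function(df) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "depth", "alt_reads")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$indel_len)) df$indel_len <- 0L
  if (is.null(df$exon_edge_distance)) df$exon_edge_distance <- NA_integer_
  if (is.null(df$protein_change)) df$protein_change <- NA_character_
  if (any(df$alt_reads > df$depth))
    stop("alt_reads exceeds depth in variant table")
  known <- c("missense", "nonsense", "synonymous", "frameshift_indel",
             "inframe_indel", "splice", "intragenic_large_del_dup")
  bad <- setdiff(unique(df$consequence), known)
  if (length(bad))
    stop("unknown consequence label(s): ", paste(bad, collapse = ", "))
  df$allele_freq <- ifelse(df$depth > 0, df$alt_reads / df$depth, 0)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' @rdname variant_table
#' @param variants a `variant_table`.
#' @param path file path.
#' @export
write_variants <- function(variants, path) {
  out <- as.data.frame(variants)
  out$pos <- out$pos + 1L # 1-based in VCF-like export
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname variant_table
#' @export
read_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$pos <- df$pos - 1L
  variant_table(df)
}

#' Assemble a knowledge base for variant interpretation
#'
#' The interpretation rules are driven entirely by pre-materialized tables
#' (no live database queries): per-gene roles, hotspot lists, missense
#' variants with literature support for loss of function, population allele
#' frequencies, and an actionability rule table.
#'
#' @param gene_roles data.frame(gene, role) with role in
#'   `c("oncogene", "tumour_suppressor")`.
#' @param hotspots data.frame(gene, protein_change, confidence) where
#'   confidence is `"established"` (known hotspot, class Pathogenic) or
#'   `"in_silico"` (class Likely_pathogenic).
#' @param known_inactivating_missense data.frame(gene, protein_change,
#'   confidence) for tumour-suppressor missense variants.
#' @param population_freqs data.frame(chrom, pos, ref, alt, freq) of germline
#'   population allele frequencies in `[0, 1]`.
#' @param actionable_rules data.frame(gene, alteration_class, actionable).
#' @return list of class `knowledge_base`.
#' @export
knowledge_base <- function(gene_roles,
                           hotspots = NULL,
                           known_inactivating_missense = NULL,
                           population_freqs = NULL,
                           actionable_rules = NULL) {
  empty_pc <- data.frame(gene = character(0), protein_change = character(0),
                         confidence = character(0), stringsAsFactors = FALSE)
  if (is.null(hotspots)) hotspots <- empty_pc
  if (is.null(known_inactivating_missense))
    known_inactivating_missense <- empty_pc
  if (is.null(population_freqs))
    population_freqs <- data.frame(chrom = character(0), pos = integer(0),
                                   ref = character(0), alt = character(0),
                                   freq = numeric(0), stringsAsFactors = FALSE)
  if (is.null(actionable_rules))
    actionable_rules <- data.frame(gene = character(0),
                                   alteration_class = character(0),
                                   actionable = logical(0),
                                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "role") %in% names(gene_roles)))
  bad <- setdiff(unique(gene_roles$role), c("oncogene", "tumour_suppressor"))
  if (length(bad)) stop("unknown gene role(s): ", paste(bad, collapse = ", "))
  if (nrow(population_freqs) &&
      (any(population_freqs$freq < 0) || any(population_freqs$freq > 1)))
    stop("population frequencies must lie in [0, 1]")
  structure(list(gene_roles = gene_roles,
                 hotspots = hotspots,
                 known_inactivating_missense = known_inactivating_missense,
                 population_freqs = population_freqs,
                 actionable_rules = actionable_rules),
            class = "knowledge_base")
}

#' Read/write a knowledge base directory of TSV tables
#'
#' The directory holds `gene_roles.tsv`, `hotspots.tsv`,
#' `inactivating_missense.tsv`, `popfreq.tsv`, `actionable.tsv`.
#'
#' @param dir directory path.
#' @return A [knowledge_base()].
#' @export
read_knowledge_base <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  knowledge_base(gene_roles = rd("gene_roles.tsv"),
                 hotspots = rd("hotspots.tsv"),
                 known_inactivating_missense = rd("inactivating_missense.tsv"),
                 population_freqs = rd("popfreq.tsv"),
                 actionable_rules = rd("actionable.tsv"))
}

#' @rdname read_knowledge_base
#' @param kb a [knowledge_base()].
#' @export
write_knowledge_base <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wr(kb$gene_roles, "gene_roles.tsv")
  wr(kb$hotspots, "hotspots.tsv")
  wr(kb$known_inactivating_missense, "inactivating_missense.tsv")
  wr(kb$population_freqs, "popfreq.tsv")
  wr(kb$actionable_rules, "actionable.tsv")
  invisible(dir)
}

#' Look up the role of a gene in a knowledge base
#' @param kb a [knowledge_base()].
#' @param gene gene symbol(s).
#' @return character vector of roles; errors if a gene has no role.
#' @export
gene_role <- function(kb, gene) {
  i <- match(gene, kb$gene_roles$gene)
  if (anyNA(i))
    stop("gene(s) without a role in the knowledge base: ",
         paste(unique(gene[is.na(i)]), collapse = ", "))
  kb$gene_roles$role[i]
}
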