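## concordance: pair the CNB and FNA validated results of one patient,
## classify each gene-level alteration as concordant or discordant, and
## compute the cohort statistics (pooled concordance, arcsine-square-root
## Pearson correlation of allele frequencies, per-pair segment correlation
## with Benjamini-Hochberg control, nonparametric QC group tests).

.status_rank <- c("Absent" = 0, "WT" = 0, "Normal" = 0, "NA" = 0,
                  "Gain" = 1, "Heterozygous deletion" = 1,
                  "Heterozygous mutation" = 1, "Composite heterozygous" = 2,
                  "Amplification" = 2, "Homozygous deletion" = 2,
                  "Homozygous mutation" = 2)

# status string of one side for a gene + alteration class
.side_status <- function(side, gene, class, special_het_rule) {
  v <- side$validated
  hit <- v[v$gene == gene & v$alteration_class == class, , drop = FALSE]
  ctx <- side$cnv_context
  if (class == "amplification") {
    if (nrow(hit)) return("Amplification")
    if (!is.null(ctx) && any(ctx$gene == gene & ctx$status == "gain"))
      return("Gain")
    return("Normal")
  }
  if (class == "homozygous_deletion") {
    if (nrow(hit)) return("Homozygous deletion")
    if (!is.null(ctx) &&
        any(ctx$gene == gene & ctx$status == "heterozygous_deletion"))
      return("Heterozygous deletion")
    return("Normal")
  }
  # pathogenic_variant
  if (nrow(hit)) {
    return(if (hit$zygosity[1] == "homozygous") "Homozygous mutation"
           else "Heterozygous mutation")
  }
  ch <- side$candidate_het
  if (special_het_rule && nrow(ch) && any(ch$gene == gene))
    return("Heterozygous mutation")
  "Absent"
}

#' Pair and classify one patient's CNB and FNA validated alterations
#'
#' Outer join on gene + alteration class over the two samples' validated
#' sets. Statuses are rendered in the reporting vocabulary ("Homozygous
#' deletion", "Heterozygous mutation", "Amplification", "Gain", "Normal",
#' "Absent"); a pair of identical statuses is concordant, anything else
#' (including het/hom zygosity mismatches and gain-versus-amplification) is
#' discordant. For tumour-suppressor variants only bi-allelic (homozygous)
#' findings are considered, except that a heterozygous-only finding stays
#' visible as a discordance when the partner sample has no finding in that
#' gene (`special_het_rule`). Discordant events are bucketed to the side
#' carrying the validated (or stronger) alteration.
#'
#' @param cnb,fna [validate_sample()] results of the two samples of one
#'   patient.
#' @param special_het_rule keep partner-less heterozygous tumour-suppressor
#'   findings visible (default TRUE).
#' @return data.frame of class `paired_alterations`: patient_id, gene,
#'   alteration_class, cnb_result, fna_result, concordant, bucket,
#'   actionable.
#' @export
pair_and_classify <- function(cnb, fna, special_het_rule = TRUE) {
  patient_id <- c(cnb$validated$patient_id, fna$validated$patient_id,
                  cnb$candidate_het$patient_id,
                  fna$candidate_het$patient_id, "?")[1]
  keys <- unique(rbind(
    cnb$validated[, c("gene", "alteration_class")],
    fna$validated[, c("gene", "alteration_class")]))
  # special rule: het-only TSG finding with a silent partner
  for (side_pair in list(list(a = cnb, b = fna), list(a = fna, b = cnb))) {
    ch <- side_pair$a$candidate_het
    if (!special_het_rule || !nrow(ch)) next
    for (g in unique(ch$gene)) {
      partner_has <- any(side_pair$b$validated$gene == g &
                           side_pair$b$validated$alteration_class ==
                           "pathogenic_variant") ||
        any(side_pair$b$candidate_het$gene == g)
      already <- any(keys$gene == g &
                       keys$alteration_class == "pathogenic_variant")
      if (!partner_has && !already)
        keys <- rbind(keys, data.frame(gene = g,
                                       alteration_class = "pathogenic_variant",
                                       stringsAsFactors = FALSE))
    }
  }
  if (!nrow(keys))
    return(structure(data.frame(patient_id = character(0), gene = character(0),
                                alteration_class = character(0),
                                cnb_result = character(0),
                                fna_result = character(0),
                                concordant = logical(0), bucket = character(0),
                                actionable = logical(0),
                                stringsAsFactors = FALSE),
                     class = c("paired_alterations", "data.frame")))
  keys <- keys[!duplicated(keys), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- keys$gene[i]; cls <- keys$alteration_class[i]
    s_c <- .side_status(cnb, g, cls, special_het_rule)
    s_f <- .side_status(fna, g, cls, special_het_rule)
    conc <- s_c == s_f
    val_c <- any(cnb$validated$gene == g &
                   cnb$validated$alteration_class == cls)
    val_f <- any(fna$validated$gene == g &
                   fna$validated$alteration_class == cls)
    bucket <- if (conc) "concordant"
      else if (val_c && !val_f) "cnb_only"
      else if (val_f && !val_c) "fna_only"
      else if (.status_rank[s_c] >= .status_rank[s_f]) "cnb_only"
      else "fna_only"
    action <- any(c(
      cnb$validated$actionable[cnb$validated$gene == g &
                                 cnb$validated$alteration_class == cls],
      fna$validated$actionable[fna$validated$gene == g &
                                 fna$validated$alteration_class == cls],
      cnb$candidate_het$actionable[cnb$candidate_het$gene == g &
                                     cls == "pathogenic_variant"],
      fna$candidate_het$actionable[fna$candidate_het$gene == g &
                                     cls == "pathogenic_variant"]), FALSE)
    data.frame(patient_id = patient_id, gene = g, alteration_class = cls,
               cnb_result = s_c, fna_result = s_f, concordant = conc,
               bucket = bucket, actionable = action, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$alteration_class), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_alterations", "data.frame")
  out
}

#' Category tallies of concordant / total validated alterations
#'
#' A small container for pre-counted concordance tallies (e.g. from a
#' published cohort): per category, the number of alterations detected in
#' both members of a pair and the total validated.
#'
#' @param variants,amplifications,homozygous_deletions length-2 integer
#'   vectors `c(concordant, total)`.
#' @return data.frame of class `concordance_tally`.
#' @export
concordance_tally <- function(variants, amplifications,
                              homozygous_deletions) {
  out <- data.frame(
    category = c("variants", "amplifications", "homozygous_deletions"),
    n_concordant = c(variants[1], amplifications[1], homozygous_deletions[1]),
    n_total = c(variants[2], amplifications[2], homozygous_deletions[2]),
    stringsAsFactors = FALSE)
  if (any(out$n_concordant > out$n_total))
    stop("concordant count exceeds total")
  class(out) <- c("concordance_tally", "data.frame")
  out
}

#' Cohort-level concordance summary
#'
#' Pools per-category tallies into the headline concordance figure:
#' per-category and pooled percentages are rounded to the nearest integer
#' (`round(100 * concordant / total)`); an empty cohort reports `NA`.
#' The method for `paired_alterations` additionally counts fully concordant
#' patients and actionability.
#'
#' @param x a `paired_alterations` data.frame (rbind over patients) or a
#'   [concordance_tally()].
#' @param ... further arguments; `patients` (character vector of all patient
#'   ids, so patients without alterations count as fully concordant).
#' @return list of class `cohort_report`.
#' @export
cohort_summary <- function(x, ...) UseMethod("cohort_summary")

.pct <- function(num, den) ifelse(den > 0, round(100 * num / den), NA)

#' @rdname cohort_summary
#' @export
cohort_summary.concordance_tally <- function(x, ...) {
  pooled_c <- sum(x$n_concordant); pooled_t <- sum(x$n_total)
  structure(list(
    categories = transform(as.data.frame(x),
                           pct_concordant = .pct(n_concordant, n_total)),
    n_concordant = pooled_c, n_total = pooled_t,
    pct_concordant = .pct(pooled_c, pooled_t)),
    class = "cohort_report")
}

#' @rdname cohort_summary
#' @param patients character vector of all patient ids in the cohort.
#' @export
cohort_summary.paired_alterations <- function(x, patients = NULL, ...) {
  cat_of <- c(pathogenic_variant = "variants",
              amplification = "amplifications",
              homozygous_deletion = "homozygous_deletions")
  x$category <- cat_of[x$alteration_class]
  cats <- data.frame(category = unname(cat_of[unique(names(cat_of))]),
                     stringsAsFactors = FALSE)
  cats$n_concordant <- vapply(cats$category, function(ct)
    sum(x$category == ct & x$concordant), integer(1))
  cats$n_cnb_only <- vapply(cats$category, function(ct)
    sum(x$category == ct & x$bucket == "cnb_only"), integer(1))
  cats$n_fna_only <- vapply(cats$category, function(ct)
    sum(x$category == ct & x$bucket == "fna_only"), integer(1))
  cats$n_total <- cats$n_concordant + cats$n_cnb_only + cats$n_fna_only
  cats$pct_concordant <- .pct(cats$n_concordant, cats$n_total)
  if (is.null(patients)) patients <- unique(x$patient_id)
  disc_pat <- unique(x$patient_id[!x$concordant])
  n_act <- sum(x$actionable)
  n_act_conc <- sum(x$actionable & x$concordant)
  structure(list(
    categories = cats,
    n_concordant = sum(cats$n_concordant), n_total = sum(cats$n_total),
    pct_concordant = .pct(sum(cats$n_concordant), sum(cats$n_total)),
    n_fully_concordant_patients = length(setdiff(patients, disc_pat)),
    n_discordant_patients = length(disc_pat),
    n_patients = length(patients),
    actionable = actionability_summary(n_act, sum(cats$n_total), n_act_conc)),
    class = "cohort_report")
}

#' Actionability arithmetic
#'
#' @param n_actionable validated alterations mapped to a candidate therapy.
#' @param n_validated all validated alterations.
#' @param n_actionable_concordant actionable alterations found in both
#'   members of their pair.
#' @return list with the three counts and rounded percentages
#'   (`pct_actionable` of validated; `pct_actionable_concordant` of
#'   actionable).
#' @export
actionability_summary <- function(n_actionable, n_validated,
                                  n_actionable_concordant) {
  list(n_actionable = n_actionable, n_validated = n_validated,
       n_actionable_concordant = n_actionable_concordant,
       pct_actionable = .pct(n_actionable, n_validated),
       pct_actionable_concordant = .pct(n_actionable_concordant,
                                        n_actionable))
}

#' Correlation of paired allele frequencies (arcsine square root)
#'
#' Pearson correlation of `asin(sqrt(f))`-transformed allele frequencies of
#' alterations detected in both members of a pair.
#'
#' @param af_cnb,af_fna paired allele-frequency vectors in `[0, 1]`.
#' @return Pearson r (NA with a warning if either transformed vector has
#'   zero variance or fewer than 3 pairs are available).
#' @export
af_correlation <- function(af_cnb, af_fna) {
  stopifnot(length(af_cnb) == length(af_fna))
  ok <- complete.cases(af_cnb, af_fna)
  af_cnb <- af_cnb[ok]; af_fna <- af_fna[ok]
  if (any(af_cnb < 0 | af_cnb > 1 | af_fna < 0 | af_fna > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (length(af_cnb) < 3) {
    warning("fewer than 3 paired allele frequencies")
    return(NA_real_)
  }
  x <- asin(sqrt(af_cnb)); y <- asin(sqrt(af_fna))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in transformed allele frequencies")
    return(NA_real_)
  }
  cor(x, y)
}

#' Per-pair correlation of copy-number profiles
#'
#' For each patient, the CNB and FNA segmented profiles are intersected on
#' the ordered-amplicon axis; each overlap piece contributes the pair of
#' segment median log2 ratios. Pairs with at least `min_overlap` pieces get
#' a Pearson correlation with a two-sided P-value; P-values are adjusted
#' across pairs by the Benjamini-Hochberg procedure and flagged significant
#' at FDR `fdr`.
#'
#' @param profile_pairs named list (per patient) of
#'   `list(cnb = , fna = )` [segment_profile()] results.
#' @param min_overlap minimum number of overlap pieces (default 3).
#' @param fdr false discovery rate for the significance flag.
#' @return data.frame (patient_id, n_overlap, r, p, p_adj, significant,
#'   excluded).
#' @export
cnv_pair_correlation <- function(profile_pairs, min_overlap = 3,
                                 fdr = 0.05) {
  per_pair <- lapply(names(profile_pairs), function(pid) {
    pp <- profile_pairs[[pid]]
    bounds <- sort(unique(c(pp$cnb$start_idx, pp$fna$start_idx,
                            pp$cnb$end_idx + 1L, pp$fna$end_idx + 1L)))
    starts <- utils::head(bounds, -1)
    covers <- function(prof, s)
      match(TRUE, prof$start_idx <= s & prof$end_idx >= s)
    ic <- vapply(starts, covers, integer(1), prof = pp$cnb)
    jf <- vapply(starts, covers, integer(1), prof = pp$fna)
    ok <- !is.na(ic) & !is.na(jf)
    vc <- pp$cnb$median_log2[ic[ok]]
    vf <- pp$fna$median_log2[jf[ok]]
    n <- sum(ok)
    if (n < min_overlap || sd(vc) == 0 || sd(vf) == 0)
      return(data.frame(patient_id = pid, n_overlap = n, r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- cor.test(vc, vf)
    data.frame(patient_id = pid, n_overlap = n, r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_pair)
  out$p_adj <- NA_real_
  usable <- !is.na(out$p)
  out$p_adj[usable] <- p.adjust(out$p[usable], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr
  out$excluded <- !usable
  out
}

.stars <- function(p) ifelse(is.na(p), "",
                      ifelse(p < 0.001, "***",
                      ifelse(p < 0.01, "**",
                      ifelse(p < 0.05, "*", ""))))

#' Dunn's post-hoc test of pairwise group differences in ranks
#'
#' Pairwise z statistics on mean ranks with the usual tie correction,
#' following a Kruskal-Wallis test; two-sided normal P-values with
#' multiplicity adjustment.
#'
#' @param x numeric response.
#' @param g group factor.
#' @param p_adjust_method passed to [stats::p.adjust()] (default
#'   Bonferroni, the usual companion of Dunn's test).
#' @return data.frame (group1, group2, z, p, p_adj, stars).
#' @export
dunn_test <- function(x, g, p_adjust_method = "bonferroni") {
  g <- factor(g)
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  lv <- levels(g)
  cmb <- utils::combn(lv, 2)
  z <- apply(cmb, 2, function(pair) {
    (mean_rank[pair[1]] - mean_rank[pair[2]]) /
      sqrt(s2 * (1 / n[pair[1]] + 1 / n[pair[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p, method = p_adjust_method)
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], z = as.numeric(z),
             p = as.numeric(p), p_adj = as.numeric(p_adj),
             stars = .stars(as.numeric(p_adj)), stringsAsFactors = FALSE)
}

#' Nonparametric QC comparisons between CNB and FNA groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per QC metric between
#' the CNB and FNA sample groups, plus a Kruskal-Wallis test (with Dunn's
#' post hoc) of DNA concentration across the `<50 / 50-100 / >100` ng/uL
#' strata crossed with sample type.
#'
#' @param cnb,fna data.frames of per-sample QC metrics (one row per sample).
#' @param metrics metric column names to compare (defaults to the columns
#'   shared by both inputs among the standard QC set).
#' @param conc_col DNA concentration column used for the strata analysis.
#' @return list with `mann_whitney` (metric, p, stars), `kruskal_p`, and
#'   `dunn` (pairwise strata comparisons); strata entries are NULL when the
#'   concentration column is absent.
#' @export
qc_group_tests <- function(cnb, fna, metrics = NULL,
                           conc_col = "dna_conc_ng_ul") {
  std <- c("tumour_cell_fraction", "dna_conc_ng_ul", "ratio_260_280",
           "ratio_260_230", "n_reads", "pct_mapped", "pct_on_target",
           "pct_depth_100x")
  if (is.null(metrics))
    metrics <- intersect(std, intersect(names(cnb), names(fna)))
  mw <- do.call(rbind, lapply(metrics, function(m) {
    a <- cnb[[m]]; b <- fna[[m]]
    p <- if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) NA_real_ else
      suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(metric = m, p = p, stars = .stars(p),
               stringsAsFactors = FALSE)
  }))
  kw_p <- NULL; dunn <- NULL
  if (conc_col %in% names(cnb) && conc_col %in% names(fna)) {
    conc <- c(cnb[[conc_col]], fna[[conc_col]])
    typ <- c(rep("CNB", nrow(cnb)), rep("FNA", nrow(fna)))
    stratum <- cut(conc, c(-Inf, 50, 100, Inf),
                   labels = c("<50", "50-100", ">100"))
    grp <- interaction(typ, stratum, sep = ":")
    if (nlevels(droplevels(grp)) >= 2 && all(table(droplevels(grp)) >= 1)) {
      kw_p <- kruskal.test(conc, droplevels(grp))$p.value
      dunn <- dunn_test(conc, droplevels(grp))
    }
  }
  list(mann_whitney = mw, kruskal_p = kw_p, dunn = dunn)
}

#' Read a published-style discordance ledger (gene / CNB result / FNA
#' result / patient)
#'
#' @param path TSV with columns `gene`, `cnb_result`, `fna_result`,
#'   `patient_id`, `tumour_location`, `biopsy_site`.
#' @return data.frame.
#' @export
read_discordance_table <- function(path) {
  # "NA" is a reporting vocabulary entry (no result), not a missing value
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  stopifnot(all(c("gene", "cnb_result", "fna_result", "patient_id") %in%
                  names(df)))
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Reconstruct per-patient validated inputs from a status ledger
#'
#' Inverse rendering of the reporting vocabulary: builds, for each patient
#' in a discordance ledger, the minimal pair of [validate_sample()]-shaped
#' inputs that [pair_and_classify()] would render with exactly the listed
#' statuses. Gene roles are looked up in `kb` (a trailing "/B" on a compound
#' gene label is ignored for the lookup).
#'
#' @param ledger a [read_discordance_table()] result.
#' @param kb a [knowledge_base()] with roles for the listed genes.
#' @return named list per patient of `list(cnb = , fna = )`.
#' @export
sides_from_status_ledger <- function(ledger, kb) {
  empty <- data.frame(patient_id = character(0), sample_id = character(0),
                      gene = character(0), alteration_class = character(0),
                      zygosity = character(0), allele_freq = numeric(0),
                      pathogenicity_class = character(0),
                      actionable = logical(0), evidence_trace = character(0),
                      stringsAsFactors = FALSE)
  mk_side <- function(pid, genes, statuses, sample_id) {
    validated <- empty; cand <- empty
    ctx <- data.frame(gene = character(0), status = character(0),
                      stringsAsFactors = FALSE)
    add_val <- function(gene, class, zyg) {
      validated <<- rbind(validated, data.frame(
        patient_id = pid, sample_id = sample_id, gene = gene,
        alteration_class = class, zygosity = zyg, allele_freq = NA_real_,
        pathogenicity_class = "Pathogenic", actionable = TRUE,
        evidence_trace = "ledger", stringsAsFactors = FALSE))
    }
    for (i in seq_along(genes)) {
      g <- genes[i]; s <- statuses[i]
      base_gene <- sub("/.*$", "", g)
      role <- kb$gene_roles$role[match(base_gene, kb$gene_roles$gene)]
      if (is.na(role)) stop("no role for gene ", g)
      if (s == "Amplification") add_val(g, "amplification", NA_character_)
      else if (s == "Gain")
        ctx <- rbind(ctx, data.frame(gene = g, status = "gain",
                                     stringsAsFactors = FALSE))
      else if (s == "Homozygous deletion")
        add_val(g, "homozygous_deletion", NA_character_)
      else if (s == "Heterozygous deletion")
        ctx <- rbind(ctx, data.frame(gene = g,
                                     status = "heterozygous_deletion",
                                     stringsAsFactors = FALSE))
      else if (s == "Homozygous mutation")
        add_val(g, "pathogenic_variant", "homozygous")
      else if (s == "Heterozygous mutation") {
        if (role == "oncogene") add_val(g, "pathogenic_variant",
                                        "heterozygous")
        else cand <- rbind(cand, data.frame(
          patient_id = pid, sample_id = sample_id, gene = g,
          alteration_class = "pathogenic_variant",
          zygosity = "heterozygous", allele_freq = NA_real_,
          pathogenicity_class = "Pathogenic", actionable = TRUE,
          evidence_trace = "ledger,single_het_no_second_hit",
          stringsAsFactors = FALSE))
      } else if (!s %in% c("Normal", "NA", "WT", "Absent"))
        stop("unknown ledger status: ", s)
    }
    structure(list(validated = validated, candidate_het = cand,
                   cnv_context = ctx), class = "validated_sample")
  }
  pids <- unique(ledger$patient_id)
  out <- lapply(pids, function(pid) {
    rows <- ledger[ledger$patient_id == pid, , drop = FALSE]
    list(cnb = mk_side(pid, rows$gene, rows$cnb_result,
                       paste0(pid, "_CNB")),
         fna = mk_side(pid, rows$gene, rows$fna_result,
                       paste0(pid, "_FNA")))
  })
  names(out) <- pids
  out
}
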