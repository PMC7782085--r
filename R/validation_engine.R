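## validation_engine: deterministic rule cascade turning reported variants +
## CNV calls into gene-level validated pathogenic alterations ("Validated
## data"). Oncogenes are validated through activating hotspot variants or
## amplification; tumour suppressors require bi-allelic inactivation
## (homozygous inactivating variant, composite heterozygous variants,
## inactivating variant + loss of heterozygosity, or homozygous deletion).

.PATHOGENIC <- c("Pathogenic", "Likely_pathogenic")

#' Classify a variant's pathogenicity
#'
#' Deterministic cascade driven by the knowledge base:
#' \enumerate{
#'   \item population frequency > 0.1% -> `Benign` (germline polymorphism);
#'   \item oncogene: missense / in-frame indel present in the hotspot table
#'     -> `Pathogenic` (or `Likely_pathogenic` when the hotspot evidence is
#'     tagged `in_silico`); synonymous, nonsense, frameshift and splice
#'     changes are not activating -> `Benign` / `Likely_benign`; other
#'     missense -> `Uncertain_significance`;
#'   \item tumour suppressor: nonsense, frameshift, splice, intragenic large
#'     deletion/duplication, or missense listed as inactivating ->
#'     `Pathogenic` (`Likely_pathogenic` for `in_silico` evidence);
#'     synonymous within 2 bp of an exon boundary (possible splice effect)
#'     -> `Uncertain_significance`, otherwise `Likely_benign`; unknown
#'     missense or in-frame indel -> `Uncertain_significance`.
#' }
#'
#' @param variants a [variant_table()].
#' @param kb a [knowledge_base()]; every gene must have a role.
#' @return data.frame with `pathogenicity_class` and `trace` (comma-joined
#'   rule ids) per record.
#' @export
classify_variant <- function(variants, kb) {
  n <- nrow(variants)
  if (n == 0)
    return(data.frame(pathogenicity_class = character(0),
                      trace = character(0), stringsAsFactors = FALSE))
  role <- gene_role(kb, variants$gene)
  pf_key <- .variant_key(kb$population_freqs)
  pf <- kb$population_freqs$freq[match(.variant_key(variants), pf_key)]
  pf[is.na(pf)] <- 0
  hs_key <- paste(kb$hotspots$gene, kb$hotspots$protein_change)
  im_key <- paste(kb$known_inactivating_missense$gene,
                  kb$known_inactivating_missense$protein_change)
  v_key <- paste(variants$gene, variants$protein_change)
  hs_conf <- kb$hotspots$confidence[match(v_key, hs_key)]
  im_conf <- kb$known_inactivating_missense$confidence[match(v_key, im_key)]

  cls <- character(n)
  trace <- character(n)
  for (i in seq_len(n)) {
    csq <- variants$consequence[i]
    if (pf[i] > 0.001) {
      cls[i] <- "Benign"; trace[i] <- "popfreq_gt_0.1pct"
    } else if (role[i] == "oncogene") {
      if (csq %in% c("missense", "inframe_indel") && !is.na(hs_conf[i])) {
        if (hs_conf[i] == "in_silico") {
          cls[i] <- "Likely_pathogenic"; trace[i] <- "oncogene_hotspot_insilico"
        } else {
          cls[i] <- "Pathogenic"; trace[i] <- "oncogene_hotspot"
        }
      } else if (csq == "synonymous") {
        cls[i] <- "Benign"; trace[i] <- "oncogene_synonymous_not_activating"
      } else if (csq %in% c("nonsense", "frameshift_indel", "splice",
                            "intragenic_large_del_dup")) {
        cls[i] <- "Likely_benign"; trace[i] <- "oncogene_loss_not_activating"
      } else {
        cls[i] <- "Uncertain_significance"; trace[i] <- "oncogene_non_hotspot"
      }
    } else { # tumour suppressor
      if (csq %in% c("nonsense", "frameshift_indel", "splice",
                     "intragenic_large_del_dup")) {
        cls[i] <- "Pathogenic"; trace[i] <- paste0("tsg_inactivating_", csq)
      } else if (csq == "missense" && !is.na(im_conf[i])) {
        if (im_conf[i] == "in_silico") {
          cls[i] <- "Likely_pathogenic"
          trace[i] <- "tsg_known_inactivating_missense_insilico"
        } else {
          cls[i] <- "Pathogenic"; trace[i] <- "tsg_known_inactivating_missense"
        }
      } else if (csq == "synonymous") {
        edge <- variants$exon_edge_distance[i]
        if (!is.na(edge) && edge <= 2) {
          cls[i] <- "Uncertain_significance"
          trace[i] <- "tsg_synonymous_exon_edge"
        } else {
          cls[i] <- "Likely_benign"; trace[i] <- "tsg_synonymous"
        }
      } else {
        cls[i] <- "Uncertain_significance"; trace[i] <- "tsg_unknown_missense"
      }
    }
  }
  data.frame(pathogenicity_class = cls, trace = trace,
             stringsAsFactors = FALSE)
}

#' Allele-frequency gate for validation
#'
#' Only variants with allele frequency >= 5% (inclusive) are considered for
#' validation.
#'
#' @param variants a [variant_table()].
#' @param min_af gate value.
#' @return logical vector.
#' @export
apply_af_gate <- function(variants, min_af = 0.05) {
  variants$allele_freq >= min_af
}

#' Call the zygosity of a somatic variant from its allele frequency
#'
#' Without a matched normal, zygosity is inferred from the dilution model:
#' in a sample with tumour-cell fraction `tcf`, a clonal heterozygous
#' variant is expected at AF `0.5 * tcf` and a homozygous one at `tcf`; each
#' variant is assigned the nearer expectation. A co-located heterozygous
#' deletion call upgrades a het-AF variant to homozygous (mutation plus loss
#' of the wild-type allele).
#'
#' @param variants a [variant_table()].
#' @param tcf tumour-cell fraction in `(0, 1]`.
#' @param cnv_calls optional [gene_level_calls()] result for the sample.
#' @return character vector `"heterozygous"` / `"homozygous"`.
#' @export
call_zygosity <- function(variants, tcf, cnv_calls = NULL) {
  stopifnot(tcf > 0, tcf <= 1)
  het_exp <- 0.5 * tcf
  hom_exp <- tcf
  z <- ifelse(abs(variants$allele_freq - het_exp) <
                abs(variants$allele_freq - hom_exp),
              "heterozygous", "homozygous")
  if (!is.null(cnv_calls) && nrow(cnv_calls)) {
    hetdel_genes <- cnv_calls$gene[cnv_calls$status == "heterozygous_deletion"]
    z[z == "heterozygous" & variants$gene %in% hetdel_genes] <- "homozygous"
  }
  z
}

#' Tumour-suppressor bi-allelic inactivation test
#'
#' A tumour-suppressor gene is validated as inactivated iff one of:
#' (a) a homozygous inactivating variant; (b) >= 2 distinct heterozygous
#' inactivating variants (composite heterozygous); (c) one heterozygous
#' inactivating variant plus loss-of-heterozygosity evidence (a co-located
#' deletion call); (d) a homozygous deletion call.
#'
#' @param gene gene symbol.
#' @param variants pathogenic-classified, AF-gated [variant_table()] rows of
#'   this gene, with a `zygosity` column.
#' @param cnv_calls [gene_level_calls()] rows of this sample.
#' @return list(validated = logical, branch = rule id or NA).
#' @export
tsg_inactivation <- function(gene, variants, cnv_calls = NULL) {
  gv <- variants[variants$gene == gene, , drop = FALSE]
  gc <- if (is.null(cnv_calls)) NULL else
    cnv_calls[cnv_calls$gene == gene, , drop = FALSE]
  has_homdel <- !is.null(gc) && any(gc$status == "homozygous_deletion")
  has_hetdel <- !is.null(gc) && any(gc$status == "heterozygous_deletion")
  n_hom <- sum(gv$zygosity == "homozygous")
  het_keys <- unique(.variant_key(gv[gv$zygosity == "heterozygous", ,
                                     drop = FALSE]))
  if (n_hom >= 1)
    return(list(validated = TRUE, branch = "homozygous_inactivating"))
  if (length(het_keys) >= 2)
    return(list(validated = TRUE, branch = "composite_heterozygous"))
  if (length(het_keys) == 1 && has_hetdel)
    return(list(validated = TRUE, branch = "inactivating_plus_loh"))
  if (has_homdel)
    return(list(validated = TRUE, branch = "homozygous_deletion"))
  list(validated = FALSE, branch = NA_character_)
}

#' Validate one sample's alterations
#'
#' Applies the full validation algorithm to one sample's reported variants
#' and gene-level CNV calls: pathogenicity classification, the >= 5% AF
#' gate, zygosity calling, the oncogene path (pathogenic / likely-pathogenic
#' variant, or amplification) and the tumour-suppressor bi-allelic path
#' (see [tsg_inactivation()]); every validated alteration carries its
#' evidence trace and an actionability tag from the knowledge base.
#'
#' @param variants reported (and, normally, dual-panel consensus)
#'   [variant_table()] of the sample.
#' @param cnv_calls [gene_level_calls()] of the sample.
#' @param kb a [knowledge_base()].
#' @param tcf the sample's tumour-cell fraction.
#' @param sample_id,patient_id labels copied to the output.
#' @param include_likely_pathogenic count `Likely_pathogenic` variants as
#'   validatable alongside `Pathogenic`.
#' @return list of class `validated_sample`: `validated` (data.frame of
#'   gene-level validated alterations: gene, alteration_class, zygosity,
#'   allele_freq, pathogenicity_class, actionable, evidence_trace),
#'   `candidate_het` (pathogenic tumour-suppressor heterozygous variants
#'   lacking a second hit — not validated, kept for pair display),
#'   `cnv_context` (the input CNV calls).
#' @export
validate_sample <- function(variants, cnv_calls, kb, tcf,
                            sample_id = "S", patient_id = "P",
                            include_likely_pathogenic = TRUE) {
  ok_classes <- if (include_likely_pathogenic) .PATHOGENIC else "Pathogenic"
  if (nrow(variants)) {
    cl <- classify_variant(variants, kb)
    variants$pathogenicity_class <- cl$pathogenicity_class
    variants$trace <- cl$trace
    variants$af_pass <- apply_af_gate(variants)
    variants$zygosity <- call_zygosity(variants, tcf, cnv_calls)
    path <- variants[variants$pathogenicity_class %in% ok_classes &
                       variants$af_pass, , drop = FALSE]
  } else {
    path <- variants
    path$pathogenicity_class <- character(0)
    path$trace <- character(0)
    path$zygosity <- character(0)
  }
  roles <- kb$gene_roles

  act <- function(gene, class) {
    i <- match(paste(gene, class),
               paste(kb$actionable_rules$gene,
                     kb$actionable_rules$alteration_class))
    !is.na(i) & kb$actionable_rules$actionable[i]
  }
  rows <- list()
  add <- function(gene, class, zygosity, af, pclass, trace)
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = patient_id, sample_id = sample_id, gene = gene,
      alteration_class = class, zygosity = zygosity, allele_freq = af,
      pathogenicity_class = pclass, actionable = act(gene, class),
      evidence_trace = trace, stringsAsFactors = FALSE)

  candidate_het <- list()
  for (g in unique(c(path$gene, if (!is.null(cnv_calls)) cnv_calls$gene))) {
    role <- roles$role[match(g, roles$gene)]
    gv <- path[path$gene == g, , drop = FALSE]
    gc <- if (is.null(cnv_calls)) NULL else
      cnv_calls[cnv_calls$gene == g, , drop = FALSE]
    if (is.na(role)) next
    if (role == "oncogene") {
      for (i in seq_len(nrow(gv)))
        add(g, "pathogenic_variant", gv$zygosity[i], gv$allele_freq[i],
            gv$pathogenicity_class[i],
            paste("report_filter", "af_gate_5pct", gv$trace[i], sep = ","))
      if (!is.null(gc) && any(gc$status == "amplification"))
        add(g, "amplification", NA_character_,
            NA_real_, "Pathogenic",
            paste("cnv_amplification_log2_gt_2",
                  "panel_consensus", sep = ","))
    } else {
      res <- tsg_inactivation(g, gv, cnv_calls)
      if (res$validated && res$branch == "homozygous_deletion") {
        add(g, "homozygous_deletion", NA_character_, NA_real_, "Pathogenic",
            "cnv_homdel_log2_lt_-1")
      } else if (res$validated) {
        zyg <- if (res$branch == "homozygous_inactivating") "homozygous"
        else "heterozygous"
        af <- max(gv$allele_freq)
        add(g, "pathogenic_variant", zyg, af, gv$pathogenicity_class[1],
            paste("report_filter", "af_gate_5pct", res$branch,
                  paste(unique(gv$trace), collapse = "|"), sep = ","))
        if (!is.null(gc) && any(gc$status == "homozygous_deletion"))
          add(g, "homozygous_deletion", NA_character_, NA_real_,
              "Pathogenic", "cnv_homdel_log2_lt_-1")
      } else {
        if (!is.null(gc) && any(gc$status == "homozygous_deletion"))
          add(g, "homozygous_deletion", NA_character_, NA_real_,
              "Pathogenic", "cnv_homdel_log2_lt_-1")
        if (nrow(gv))
          candidate_het[[length(candidate_het) + 1L]] <- data.frame(
            patient_id = patient_id, sample_id = sample_id, gene = g,
            alteration_class = "pathogenic_variant",
            zygosity = "heterozygous",
            allele_freq = max(gv$allele_freq),
            pathogenicity_class = gv$pathogenicity_class[1],
            actionable = act(g, "pathogenic_variant"),
            evidence_trace = paste("single_het_no_second_hit",
                                   gv$trace[1], sep = ","),
            stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(patient_id = character(0), sample_id = character(0),
                      gene = character(0), alteration_class = character(0),
                      zygosity = character(0), allele_freq = numeric(0),
                      pathogenicity_class = character(0),
                      actionable = logical(0), evidence_trace = character(0),
                      stringsAsFactors = FALSE)
  validated <- if (length(rows)) do.call(rbind, rows) else empty
  cand <- if (length(candidate_het)) do.call(rbind, candidate_het) else empty
  structure(list(validated = validated, candidate_het = cand,
                 cnv_context = cnv_calls),
            class = "validated_sample")
}
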