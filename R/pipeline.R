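## pipeline: end-to-end orchestration on a simulated (or equivalently
## structured) cohort — normalization, segmentation and gene-level CNV
## calls per panel with consensus, variant filtering with dual-panel
## consensus, per-sample validation, per-patient pairing and cohort
## statistics — plus evaluation of planted-truth recovery.

#' Run the full paired-cohort pipeline on a simulated cohort
#'
#' For each panel (barcode replicate) the raw count matrix is median-
#' normalized across all barcodes of the run; each sample's ordered log2
#' profile is segmented per chromosome and turned into gene-level CNV calls
#' requiring dual-panel status consensus (values reported from panel A).
#' Candidate variants are filtered at the reporting thresholds per panel,
#' intersected across panels, and validated per sample. Patients are then
#' paired (CNB vs FNA) and summarized.
#'
#' @param sim an [simulate_cohort()] result.
#' @param penalty segmentation penalty (NULL = data-driven default).
#' @param thresholds a [cnv_thresholds()] list.
#' @param special_het_rule see [pair_and_classify()].
#' @return list of class `cohort_pipeline`: `sample_results` (per sample:
#'   validated set, panel-A profile), `paired` (all patients' paired
#'   alterations), `report` ([cohort_summary()]), `af_pairs`, `af_r`,
#'   `cnv_corr` ([cnv_pair_correlation()]), `qc_tests`
#'   ([qc_group_tests()]).
#' @export
run_cohort_pipeline <- function(sim, penalty = NULL,
                                thresholds = cnv_thresholds(),
                                special_het_rule = TRUE) {
  manifest_used <- sim$manifest[!sim$manifest$blacklisted, , drop = FALSE]
  log2m <- lapply(sim$counts, function(m)
    normalize_counts(m, sim$manifest)$log2)
  samples <- sim$samples
  sample_results <- vector("list", nrow(samples))
  names(sample_results) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    prof <- lapply(log2m, function(m)
      segment_profile(m[, sid], manifest_used, penalty, thresholds))
    cnv <- gene_level_calls(prof$A, manifest_used, prof$B,
                            panel_consensus = TRUE)
    va <- report_variants(sim$variants$A[[sid]])
    vb <- report_variants(sim$variants$B[[sid]])
    cons <- panel_consensus(va, vb)
    val <- validate_sample(cons, cnv, sim$kb,
                           tcf = samples$tumour_cell_fraction[s],
                           sample_id = sid,
                           patient_id = samples$patient_id[s])
    sample_results[[sid]] <- list(validated = val, profile_a = prof$A,
                                  cnv_calls = cnv)
  }
  pids <- sim$pairs$patient_id
  paired_list <- lapply(seq_along(pids), function(i) {
    cnb <- sample_results[[sim$pairs$cnb_sample_id[i]]]$validated
    fna <- sample_results[[sim$pairs$fna_sample_id[i]]]$validated
    pr <- pair_and_classify(cnb, fna, special_het_rule)
    if (nrow(pr)) pr$patient_id <- pids[i]
    pr
  })
  paired <- do.call(rbind, paired_list)
  class(paired) <- c("paired_alterations", "data.frame")
  report <- cohort_summary(paired, patients = pids)

  # allele frequencies of variants detected in both members of a pair
  af_pairs <- do.call(rbind, lapply(seq_along(pids), function(i) {
    pr <- paired_list[[i]]
    pr <- pr[pr$concordant & pr$alteration_class == "pathogenic_variant", ,
             drop = FALSE]
    if (!nrow(pr)) return(NULL)
    cnb <- sample_results[[sim$pairs$cnb_sample_id[i]]]$validated$validated
    fna <- sample_results[[sim$pairs$fna_sample_id[i]]]$validated$validated
    data.frame(
      patient_id = pids[i], gene = pr$gene,
      af_cnb = cnb$allele_freq[match(pr$gene, cnb$gene)],
      af_fna = fna$allele_freq[match(pr$gene, fna$gene)],
      stringsAsFactors = FALSE)
  }))
  af_r <- if (!is.null(af_pairs) && nrow(af_pairs) >= 3)
    suppressWarnings(af_correlation(af_pairs$af_cnb, af_pairs$af_fna))
  else NA_real_

  profile_pairs <- lapply(seq_along(pids), function(i)
    list(cnb = sample_results[[sim$pairs$cnb_sample_id[i]]]$profile_a,
         fna = sample_results[[sim$pairs$fna_sample_id[i]]]$profile_a))
  names(profile_pairs) <- pids
  cnv_corr <- cnv_pair_correlation(profile_pairs)

  qc <- qc_group_tests(samples[samples$sample_type == "CNB", , drop = FALSE],
                       samples[samples$sample_type == "FNA", , drop = FALSE])
  structure(list(sample_results = sample_results, paired = paired,
                 report = report, af_pairs = af_pairs, af_r = af_r,
                 cnv_corr = cnv_corr, qc_tests = qc),
            class = "cohort_pipeline")
}

# noiseless expected detectability of one truth event in one sample,
# with an indeterminate band around the decision thresholds
.expected_cnv <- function(state, copies, tcf, residual_scale,
                          thresholds, margin) {
  l2 <- if (state == "amp") log2((2 * (1 - tcf) + copies * tcf) / 2)
  else log2(residual_scale * (1 - tcf))
  if (state == "amp") {
    if (l2 > thresholds$amp + margin) return(TRUE)
    if (l2 < thresholds$amp - margin) return(FALSE)
  } else {
    if (l2 < thresholds$homdel - margin) return(TRUE)
    if (l2 > thresholds$homdel + margin) return(FALSE)
  }
  NA
}

#' Evaluate recovery of planted truth by the pipeline
#'
#' Compares the validated alterations of every sample against the
#' generator's truth, event by event (gene x alteration class). Recall is
#' measured against the events *expected detectable* in each sample under
#' the noiseless dilution model — an amplification (deletion) is expected
#' when its diluted log2 ratio clears the calling threshold by
#' `log2_margin`, a variant when its diluted allele fraction clears the 5%
#' validation gate by `af_margin`; events inside the indeterminate band are
#' excluded from the denominators. CNV recall is additionally restricted to
#' samples with cellularity >= `min_cellularity`, events spanning >=
#' `min_event_amplicons` analysed amplicons and amplifications of >=
#' `min_amp_copies` copies. Precision counts a validated call as true if a
#' matching planted event exists for that patient.
#'
#' @param sim an [simulate_cohort()] result.
#' @param run the matching [run_cohort_pipeline()] result.
#' @param min_cellularity,min_event_amplicons,min_amp_copies CNV recall
#'   conditioning (see Details).
#' @param log2_margin,af_margin indeterminate-band half-widths.
#' @return list with per-class recall/precision and the underlying counts.
#' @export
evaluate_recovery <- function(sim, run, min_cellularity = 0.5,
                              min_event_amplicons = 8, min_amp_copies = 8,
                              log2_margin = 0.15, af_margin = 0.01) {
  thresholds <- cnv_thresholds()
  rs <- sim$config$dropout_model$residual_scale
  manifest_used <- sim$manifest[!sim$manifest$blacklisted, , drop = FALSE]
  analysed_amp <- table(manifest_used$gene)
  samples <- sim$samples

  # truth variant events: one per (patient, gene) among driver rows
  tv <- sim$truth$variants
  tv <- tv[tv$origin == "driver", , drop = FALSE]
  var_events <- unique(tv[, c("patient_id", "gene")])
  cnv_events <- sim$truth$cnv

  stats <- list(
    variant = c(expected = 0L, recovered = 0L),
    amplification = c(expected = 0L, recovered = 0L),
    homdel = c(expected = 0L, recovered = 0L))
  calls <- list(
    variant = c(called = 0L, true = 0L),
    amplification = c(called = 0L, true = 0L),
    homdel = c(called = 0L, true = 0L))

  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    pid <- samples$patient_id[s]
    tcf <- samples$tumour_cell_fraction[s]
    val <- run$sample_results[[sid]]$validated$validated

    ve <- var_events[var_events$patient_id == pid, , drop = FALSE]
    for (i in seq_len(nrow(ve))) {
      rows <- tv[tv$patient_id == pid & tv$gene == ve$gene[i], ,
                 drop = FALSE]
      zf <- ifelse(rows$zygosity == "homozygous", 1, 0.5)
      afs <- rows$ccf * tcf * zf
      exp_af <- min(afs) # composite events need every constituent variant
      expected <- if (exp_af >= 0.05 + af_margin) TRUE
        else if (exp_af < 0.05 - af_margin) FALSE else NA
      if (is.na(expected) || !expected) next
      stats$variant["expected"] <- stats$variant["expected"] + 1L
      hit <- any(val$gene == ve$gene[i] &
                   val$alteration_class == "pathogenic_variant")
      if (hit) stats$variant["recovered"] <- stats$variant["recovered"] + 1L
    }

    ce <- cnv_events[cnv_events$patient_id == pid, , drop = FALSE]
    for (i in seq_len(nrow(ce))) {
      if (tcf < min_cellularity) next
      n_amp <- analysed_amp[ce$gene[i]]
      if (is.na(n_amp) || n_amp < min_event_amplicons) next
      if (ce$state[i] == "amp" && ce$copies[i] < min_amp_copies) next
      expected <- .expected_cnv(ce$state[i], ce$copies[i], tcf, rs,
                                thresholds, log2_margin)
      if (is.na(expected) || !expected) next
      key <- if (ce$state[i] == "amp") "amplification" else "homdel"
      cls <- if (ce$state[i] == "amp") "amplification" else
        "homozygous_deletion"
      stats[[key]]["expected"] <- stats[[key]]["expected"] + 1L
      if (any(val$gene == ce$gene[i] & val$alteration_class == cls))
        stats[[key]]["recovered"] <- stats[[key]]["recovered"] + 1L
    }

    # precision: every validated call must trace back to a planted event
    for (i in seq_len(nrow(val))) {
      cls <- val$alteration_class[i]
      key <- switch(cls, pathogenic_variant = "variant",
                    amplification = "amplification",
                    homozygous_deletion = "homdel")
      calls[[key]]["called"] <- calls[[key]]["called"] + 1L
      true_hit <- if (cls == "pathogenic_variant")
        any(var_events$patient_id == pid & var_events$gene == val$gene[i])
      else any(cnv_events$patient_id == pid &
                 cnv_events$gene == val$gene[i] &
                 cnv_events$state ==
                 ifelse(cls == "amplification", "amp", "homdel"))
      if (true_hit) calls[[key]]["true"] <- calls[[key]]["true"] + 1L
    }
  }
  per_class <- lapply(names(stats), function(k) {
    e <- stats[[k]]["expected"]; r <- stats[[k]]["recovered"]
    c_ <- calls[[k]]["called"]; t_ <- calls[[k]]["true"]
    list(n_expected = unname(e), n_recovered = unname(r),
         recall = if (e > 0) unname(r / e) else NA_real_,
         n_called = unname(c_), n_true_calls = unname(t_),
         precision = if (c_ > 0) unname(t_ / c_) else NA_real_)
  })
  names(per_class) <- names(stats)
  tot_e <- sum(vapply(stats, `[`, integer(1), "expected"))
  tot_r <- sum(vapply(stats, `[`, integer(1), "recovered"))
  tot_c <- sum(vapply(calls, `[`, integer(1), "called"))
  tot_t <- sum(vapply(calls, `[`, integer(1), "true"))
  per_class$overall <- list(
    n_expected = tot_e, n_recovered = tot_r,
    recall = if (tot_e > 0) tot_r / tot_e else NA_real_,
    n_called = tot_c, n_true_calls = tot_t,
    precision = if (tot_c > 0) tot_t / tot_c else NA_real_)
  per_class
}

#' Replicated recovery / concordance study over seeded cohorts
#'
#' Runs [simulate_cohort()] + [run_cohort_pipeline()] +
#' [evaluate_recovery()] for `n_seeds` consecutive seeds and collects, per
#' seed, pooled recall/precision and the per-category concordance
#' percentages.
#'
#' @param n_seeds number of replicate cohorts.
#' @param base_seed seed of the first replicate (replicate k uses
#'   `base_seed + k - 1`).
#' @param config_fn function(seed) returning a [sim_config()] (defaults to
#'   the standard configuration).
#' @return data.frame, one row per seed.
#' @export
recovery_study <- function(n_seeds = 100, base_seed = 1000L,
                           config_fn = function(seed) sim_config(seed = seed)) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    seed <- base_seed + k - 1L
    sim <- simulate_cohort(config_fn(seed))
    run <- run_cohort_pipeline(sim)
    rec <- evaluate_recovery(sim, run)
    cats <- run$report$categories
    pick <- function(ct, col) {
      v <- cats[[col]][cats$category == ct]
      if (length(v)) v else NA
    }
    data.frame(
      seed = seed,
      recall = rec$overall$recall,
      precision = rec$overall$precision,
      recall_variant = rec$variant$recall,
      recall_amp = rec$amplification$recall,
      recall_homdel = rec$homdel$recall,
      e_variant = rec$variant$n_expected, r_variant = rec$variant$n_recovered,
      e_amp = rec$amplification$n_expected,
      r_amp = rec$amplification$n_recovered,
      e_homdel = rec$homdel$n_expected, r_homdel = rec$homdel$n_recovered,
      called_variant = rec$variant$n_called,
      true_variant = rec$variant$n_true_calls,
      called_amp = rec$amplification$n_called,
      true_amp = rec$amplification$n_true_calls,
      called_homdel = rec$homdel$n_called,
      true_homdel = rec$homdel$n_true_calls,
      n_expected = rec$overall$n_expected,
      pct_variants = pick("variants", "pct_concordant"),
      pct_amplifications = pick("amplifications", "pct_concordant"),
      pct_homdels = pick("homozygous_deletions", "pct_concordant"),
      pct_pooled = run$report$pct_concordant,
      n_homdel_events = pick("homozygous_deletions", "n_total"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
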