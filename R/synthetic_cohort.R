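## synthetic_cohort: seeded generator of paired CNB/FNA samples with known
## truth. The generator emulates the design of a 61-patient paired-biopsy
## amplicon-panel study: one core-needle biopsy (CNB) and one fine-needle
## aspiration (FNA) per patient sharing the identical patient-level somatic
## truth, two barcode replicates ("panels" A and B) per sample, tumour-cell
## fractions centred near 52% (CNB) and 31% (FNA), negative-binomial amplicon
## counts, and copy-number signal diluted by cellularity so that homozygous
## deletions become undetectable in low-cellularity samples.

# run expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.default_genes <- data.frame(
  gene = c("TP53", "CDKN2A", "PTEN", "NF1", "MAP2K4", "PIK3R1", "RB1", "APC",
           "SMAD4", "PIK3CA", "KRAS", "ESR1", "EGFR", "FGFR1", "ERBB2",
           "BRAF", "AKT1", "MET", "CCND1", "MDM2"),
  role = c(rep("tumour_suppressor", 9), rep("oncogene", 11)),
  stringsAsFactors = FALSE)

#' Configuration of the synthetic paired cohort
#'
#' Defaults are the study conditions the generator emulates: 61 patients,
#' a scaled-down panel of 20 genes / 200 amplicons, CNB tumour-cell fraction
#' centred at 0.52 and FNA at 0.31, negative-binomial count noise, and
#' clonal driver events at roughly the per-patient rates of the emulated
#' cohort (85 validated variants, 23 amplifications and 15 homozygous
#' deletions over 61 patients). `dropout_model$residual_scale` scales the
#' residual read signal of a homozygous deletion,
#' `residual = residual_scale * (1 - cellularity)`: the stromal-contamination
#' model with incomplete representation of non-tumour DNA in the assay. With
#' the default 0.7 a homozygous deletion crosses the log2 < -1 calling
#' threshold at cellularity ~0.29, which is what makes deletion detection
#' cellularity-limited.
#'
#' @param n_patients number of patients (one CNB + one FNA each).
#' @param n_genes,n_amplicons panel size (amplicons are split over the genes).
#' @param cnb_cellularity_mean,fna_cellularity_mean,cellularity_sd truncated
#'   normal tumour-cell-fraction model per sample type, truncated to
#'   `[0.10, 0.95]` (pairs below 10% cellularity are ineligible by design).
#' @param counts_dispersion negative-binomial size parameter of count noise.
#' @param mean_depth_per_amplicon expected read pairs per amplicon.
#' @param variant_rate,amp_rate,homdel_rate expected true driver events per
#'   patient (Poisson).
#' @param amp_copies integer range of tumour-cell copy numbers for planted
#'   amplifications (focal high-level amplification).
#' @param dropout_model list with `residual_scale` (see Details).
#' @param passenger_rate,polymorphism_rate,artifact_rate expected
#'   non-driver somatic passengers and germline polymorphisms per patient and
#'   sequencing artifacts per barcode.
#' @param private_event_rate expected sample-private driver variants per
#'   sample (intratumoral heterogeneity knob; 0 by default, i.e. truth is
#'   strictly patient-level).
#' @param blacklist_fraction fraction of amplicons flagged as unreliable and
#'   excluded from CNV analysis.
#' @param driver_ccf_range cancer-cell-fraction range of planted drivers.
#' @param seed integer; fully determines the generated cohort.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 61,
                       n_genes = 20,
                       n_amplicons = 200,
                       cnb_cellularity_mean = 0.52,
                       fna_cellularity_mean = 0.31,
                       cellularity_sd = 0.12,
                       counts_dispersion = 50,
                       mean_depth_per_amplicon = 500,
                       variant_rate = 1.5,
                       amp_rate = 0.4,
                       homdel_rate = 0.3,
                       amp_copies = c(20L, 40L),
                       dropout_model = list(residual_scale = 0.7),
                       passenger_rate = 1,
                       polymorphism_rate = 1,
                       artifact_rate = 2,
                       private_event_rate = 0,
                       blacklist_fraction = 0.02,
                       driver_ccf_range = c(0.9, 1),
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cnb_cellularity_mean, fna_cellularity_mean, cellularity_sd,
             blacklist_fraction, private_event_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_amplicons < n_genes) stop("need at least one amplicon per gene")
  if (n_patients < 0) stop("n_patients must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# truncated normal on [lo, hi] by resampling; degenerate sd clamps the mean
rtnorm <- function(n, mean, sd, lo = 0.10, hi = 1.0) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# split n_amplicons over n_genes with bounded variation, exact total
.gene_sizes <- function(n_genes, n_amplicons) {
  base <- n_amplicons / n_genes
  w <- pmax(0.55, rnorm(n_genes, 1, 0.22))
  sz <- diff(round(cumsum(w / sum(w) * n_amplicons)))
  sz <- c(round(w[1] / sum(w) * n_amplicons), sz)
  sz <- pmax(sz, 3L)
  while (sum(sz) != n_amplicons) { # adjust largest/smallest to hit total
    if (sum(sz) > n_amplicons) {
      i <- which.max(sz); sz[i] <- sz[i] - 1L
    } else {
      i <- which.min(sz); sz[i] <- sz[i] + 1L
    }
  }
  as.integer(sz)
}

.sim_manifest <- function(cfg, genes) {
  n_genes <- nrow(genes)
  sizes <- .gene_sizes(n_genes, cfg$n_amplicons)
  chroms <- paste0("chr", rep(1:4, each = ceiling(n_genes / 4))[seq_len(n_genes)])
  rows <- vector("list", n_genes)
  offset <- setNames(rep(10000L, 4), paste0("chr", 1:4))
  k <- 0L
  for (g in seq_len(n_genes)) {
    ch <- chroms[g]
    pos <- offset[[ch]]
    n <- sizes[g]
    len <- sample(110:140, n, replace = TRUE)
    gap <- sample(20:60, n, replace = TRUE)
    start <- pos + cumsum(c(0L, (len + gap)[-n]))
    rows[[g]] <- data.frame(
      chrom = ch, start = start, end = start + len,
      id = sprintf("AMP%04d", k + seq_len(n)),
      gene = genes$gene[g],
      fwd_primer_len = sample(18:25, n, replace = TRUE),
      rev_primer_len = sample(18:25, n, replace = TRUE),
      blacklisted = FALSE, stringsAsFactors = FALSE)
    k <- k + n
    offset[[ch]] <- max(rows[[g]]$end) + 5000L
  }
  df <- do.call(rbind, rows)
  n_bl <- round(cfg$blacklist_fraction * nrow(df))
  if (n_bl > 0) df$blacklisted[sample(nrow(df), n_bl)] <- TRUE
  panel_manifest(df, panel_id = "A")
}

.random_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# place a variant inside a random amplicon of its gene
.place_variants <- function(df, manifest) {
  if (!nrow(df)) {
    df$chrom <- character(0); df$pos <- integer(0)
    df$ref <- character(0); df$alt <- character(0)
    return(df)
  }
  idx <- vapply(df$gene, function(g) {
    cand <- which(manifest$gene == g)
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  df$chrom <- manifest$chrom[idx]
  df$pos <- as.integer(floor((manifest$start[idx] + manifest$end[idx]) / 2)) +
    sample(-20:20, nrow(df), replace = TRUE)
  df$ref <- .random_base(nrow(df))
  df$alt <- vapply(df$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  df
}

.sim_truth <- function(cfg, genes, manifest) {
  onc <- genes$gene[genes$role == "oncogene"]
  tsg <- genes$gene[genes$role == "tumour_suppressor"]
  var_rows <- list(); cnv_rows <- list()
  amp_lo <- cfg$amp_copies[1]; amp_hi <- cfg$amp_copies[2]
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    # CNV events first so variant drivers avoid homozygously deleted genes
    n_amp <- rpois(1, cfg$amp_rate)
    n_hd <- rpois(1, cfg$homdel_rate)
    amp_genes <- sample(onc, min(n_amp, length(onc)))
    hd_genes <- sample(tsg, min(n_hd, length(tsg)))
    if (length(amp_genes))
      cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
        patient_id = pid, gene = amp_genes, state = "amp",
        copies = sample(amp_lo:amp_hi, length(amp_genes), replace = TRUE),
        stringsAsFactors = FALSE)
    if (length(hd_genes))
      cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
        patient_id = pid, gene = hd_genes, state = "homdel", copies = 0L,
        stringsAsFactors = FALSE)
    n_var <- rpois(1, cfg$variant_rate)
    free <- setdiff(genes$gene, hd_genes)
    for (v in seq_len(min(n_var, length(free)))) {
      g <- sample(free, 1); free <- setdiff(free, g)
      ccf <- runif(1, cfg$driver_ccf_range[1], cfg$driver_ccf_range[2])
      if (g %in% onc) {
        csq <- sample(c("missense", "inframe_indel"), 1, prob = c(0.85, 0.15))
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          patient_id = pid, gene = g, role = "oncogene", consequence = csq,
          zygosity = "heterozygous", ccf = ccf,
          protein_change = paste0("p.HS", sample(1:3, 1)),
          indel_len = if (csq == "inframe_indel") sample(c(3L, 6L, 9L), 1) else 0L,
          origin = "driver", stringsAsFactors = FALSE)
      } else {
        kind <- sample(c("hom", "composite"), 1, prob = c(0.8, 0.2))
        csq <- sample(c("nonsense", "frameshift_indel", "splice", "missense"),
                      ifelse(kind == "composite", 2, 1), replace = TRUE,
                      prob = c(0.35, 0.3, 0.2, 0.15))
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          patient_id = pid, gene = g, role = "tumour_suppressor",
          consequence = csq,
          zygosity = if (kind == "hom") "homozygous" else "heterozygous",
          ccf = ccf,
          protein_change = ifelse(csq == "missense", "p.INACT1",
                                  NA_character_),
          indel_len = ifelse(csq == "frameshift_indel",
                             sample(c(1L, 2L, 4L, 12L), length(csq),
                                    replace = TRUE, prob = c(.4, .3, .2, .1)),
                             0L),
          origin = "driver", stringsAsFactors = FALSE)
      }
    }
    # non-driver passengers (uncertain significance) and germline polymorphisms
    n_pass <- rpois(1, cfg$passenger_rate)
    if (n_pass > 0)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        patient_id = pid, gene = sample(genes$gene, n_pass, replace = TRUE),
        role = NA_character_, consequence = "missense",
        zygosity = "heterozygous", ccf = runif(n_pass, 0.2, 1),
        protein_change = paste0("p.PASS", seq_len(n_pass)),
        indel_len = 0L, origin = "passenger", stringsAsFactors = FALSE)
    n_poly <- rpois(1, cfg$polymorphism_rate)
    if (n_poly > 0)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        patient_id = pid, gene = sample(genes$gene, n_poly, replace = TRUE),
        role = NA_character_,
        consequence = sample(c("missense", "synonymous"), n_poly,
                             replace = TRUE),
        zygosity = sample(c("heterozygous", "homozygous"), n_poly,
                          replace = TRUE, prob = c(0.8, 0.2)),
        ccf = 1, protein_change = NA_character_,
        indel_len = 0L, origin = "polymorphism", stringsAsFactors = FALSE)
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(patient_id = character(0), gene = character(0),
               role = character(0), consequence = character(0),
               zygosity = character(0), ccf = numeric(0),
               protein_change = character(0), indel_len = integer(0),
               origin = character(0), stringsAsFactors = FALSE)
  variants <- .place_variants(variants, manifest)
  variants$exon_edge_distance <- sample(3:60, nrow(variants), replace = TRUE)

  cnv <- if (length(cnv_rows)) do.call(rbind, cnv_rows) else
    data.frame(patient_id = character(0), gene = character(0),
               state = character(0), copies = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(cnv)) {
    gi <- split(seq_len(nrow(manifest)), manifest$gene)
    cnv$start_idx <- vapply(cnv$gene, function(g) min(gi[[g]]), integer(1))
    cnv$end_idx <- vapply(cnv$gene, function(g) max(gi[[g]]), integer(1))
    cnv$n_amplicons <- cnv$end_idx - cnv$start_idx + 1L
  } else {
    cnv$start_idx <- cnv$end_idx <- cnv$n_amplicons <- integer(0)
  }
  list(variants = variants, cnv = cnv)
}

# per-amplicon count multiplier for one sample given its truth and cellularity
.copy_multiplier <- function(cfg, manifest, cnv_patient, tcf) {
  m <- rep(1, nrow(manifest))
  if (!nrow(cnv_patient)) return(m)
  for (i in seq_len(nrow(cnv_patient))) {
    idx <- cnv_patient$start_idx[i]:cnv_patient$end_idx[i]
    m[idx] <- if (cnv_patient$state[i] == "amp") {
      (2 * (1 - tcf) + cnv_patient$copies[i] * tcf) / 2
    } else {
      cfg$dropout_model$residual_scale * (1 - tcf)
    }
  }
  m
}

# observed candidate-variant table for one barcode of one sample
.observe_variants <- function(cfg, truth_var, tcf, genes) {
  n <- nrow(truth_var)
  art_n <- rpois(1, cfg$artifact_rate)
  depth <- pmax(1L, rnbinom(n + art_n, size = cfg$counts_dispersion,
                            mu = cfg$mean_depth_per_amplicon))
  af_true <- numeric(n)
  if (n) {
    zf <- ifelse(truth_var$zygosity == "homozygous", 1, 0.5)
    af_true <- ifelse(truth_var$origin == "polymorphism",
                      zf, # germline: independent of tumour content
                      pmin(1, truth_var$ccf * tcf * zf))
  }
  if (art_n) {
    art <- data.frame(patient_id = truth_var$patient_id[1] %||% NA_character_,
                      gene = sample(genes$gene, art_n, replace = TRUE),
                      role = NA_character_, consequence = "missense",
                      zygosity = "heterozygous", ccf = 0,
                      protein_change = NA_character_, indel_len = 0L,
                      origin = "artifact", stringsAsFactors = FALSE)
    art <- .place_variants(art, attr(cfg, "manifest"))
    art$exon_edge_distance <- sample(3:60, art_n, replace = TRUE)
    truth_var <- rbind(truth_var, art)
    af_true <- c(af_true, runif(art_n, 0.002, 0.015))
  }
  alt <- rbinom(length(af_true), size = depth, prob = af_true)
  out <- data.frame(chrom = truth_var$chrom, pos = truth_var$pos,
                    ref = truth_var$ref, alt = truth_var$alt,
                    gene = truth_var$gene,
                    consequence = truth_var$consequence,
                    depth = depth, alt_reads = alt,
                    indel_len = truth_var$indel_len,
                    exon_edge_distance = truth_var$exon_edge_distance,
                    protein_change = truth_var$protein_change,
                    stringsAsFactors = FALSE)
  variant_table(out[out$alt_reads > 0, , drop = FALSE])
}

.sim_kb <- function(cfg, genes, truth) {
  onc <- genes$gene[genes$role == "oncogene"]
  tsg <- genes$gene[genes$role == "tumour_suppressor"]
  hotspots <- do.call(rbind, lapply(onc, function(g)
    data.frame(gene = g, protein_change = paste0("p.HS", 1:3),
               confidence = c("established", "established", "in_silico"),
               stringsAsFactors = FALSE)))
  inact <- data.frame(gene = rep(tsg, each = 1),
                      protein_change = "p.INACT1",
                      confidence = "established", stringsAsFactors = FALSE)
  poly <- truth$variants[truth$variants$origin == "polymorphism", ,
                         drop = FALSE]
  popfreq <- if (nrow(poly)) data.frame(
    chrom = poly$chrom, pos = poly$pos, ref = poly$ref, alt = poly$alt,
    freq = runif(nrow(poly), 0.002, 0.05), stringsAsFactors = FALSE)
  else NULL
  actionable <- rbind(
    data.frame(gene = c("ERBB2", "FGFR1", "EGFR", "CCND1", "MET", "MDM2"),
               alteration_class = "amplification", actionable = TRUE,
               stringsAsFactors = FALSE),
    data.frame(gene = c("PIK3CA", "KRAS", "ESR1", "BRAF", "AKT1", "NF1",
                        "PTEN", "MAP2K4", "PIK3R1"),
               alteration_class = "pathogenic_variant", actionable = TRUE,
               stringsAsFactors = FALSE),
    data.frame(gene = c("CDKN2A", "PTEN", "RB1", "MAP2K4", "PIK3R1"),
               alteration_class = "homozygous_deletion", actionable = TRUE,
               stringsAsFactors = FALSE))
  actionable <- actionable[actionable$gene %in% genes$gene, , drop = FALSE]
  knowledge_base(gene_roles = genes, hotspots = hotspots,
                 known_inactivating_missense = inact,
                 population_freqs = popfreq, actionable_rules = actionable)
}

.sim_sample_meta <- function(cfg) {
  tumour_types <- c("Breast", "Colon", "Pancreas", "Cervix", "Stomach",
                    "Ovary", "Anal canal", "Lung", "Muscle", "Other")
  type_prob <- c(0.38, 0.15, 0.11, 0.07, 0.07, 0.05, 0.04, 0.04, 0.03, 0.06)
  sites <- c("Liver", "Lymph node", "Subcutaneous", "Peritoneum", "Lung",
             "Breast")
  site_prob <- c(0.57, 0.12, 0.12, 0.08, 0.06, 0.05)
  n <- cfg$n_patients
  pid <- sprintf("P%02d", seq_len(n))
  pairs <- data.frame(
    patient_id = pid,
    tumour_type = sample(tumour_types, n, TRUE, prob = type_prob),
    biopsy_site = sample(sites, n, TRUE, prob = site_prob),
    cnb_sample_id = sprintf("%s_CNB", pid),
    fna_sample_id = sprintf("%s_FNA", pid), stringsAsFactors = FALSE)
  qc_block <- function(sample_type, mean_tcf, dna_mean) {
    data.frame(
      sample_id = sprintf("%s_%s", pid, rep(sample_type, n)),
      patient_id = pid,
      sample_type = rep(sample_type, n),
      tumour_cell_fraction = rtnorm(n, mean_tcf, cfg$cellularity_sd),
      barcodes = rep("A,B", n),
      dna_conc_ng_ul = round(rlnorm(n, log(dna_mean) - 0.3, 0.75), 1),
      ratio_260_280 = round(rnorm(n, 1.9, 0.05), 2),
      ratio_260_230 = round(rnorm(n, 2.0, 0.12), 2),
      n_reads = round(pmax(6.5e5, rnorm(n, 11.3e6, 4e6))),
      pct_mapped = round(pmin(99, pmax(10, rnorm(n, 82.5, 9))), 2),
      pct_on_target = round(pmin(99, pmax(10, rnorm(n, 78, 9))), 2),
      pct_depth_100x = round(pmin(98.5, pmax(60, rnorm(n, 94, 4))), 2),
      stringsAsFactors = FALSE)
  }
  samples <- rbind(qc_block("CNB", cfg$cnb_cellularity_mean, 122),
                   qc_block("FNA", cfg$fna_cellularity_mean, 148))
  samples <- samples[order(samples$patient_id, samples$sample_type), ]
  rownames(samples) <- NULL
  list(pairs = pairs, samples = samples)
}

#' Simulate a paired CNB/FNA amplicon-panel cohort with known truth
#'
#' Generates, deterministically from `config$seed`: a panel manifest, a
#' patient-level somatic truth set (clonal driver SNVs/indels with zygosity
#' and cancer-cell fraction, focal amplifications, homozygous deletions, plus
#' passengers, germline polymorphisms and barcode-level artifacts), raw
#' per-amplicon count matrices for the two barcode replicates ("panels" A and
#' B) of every sample, candidate-variant tables per sample and panel, a
#' co-generated knowledge base, and per-sample metadata/QC.
#'
#' Observed signal follows the dilution model: a variant's expected allele
#' fraction is `ccf * cellularity * (0.5 het | 1 hom)` with binomial sampling
#' at the simulated depth; an amplicon's expected count is
#' `depth * efficiency * barcode_factor * copy_multiplier` with
#' negative-binomial noise, where the copy multiplier is
#' `(2(1-t) + copies*t)/2` for amplified segments and
#' `residual_scale * (1-t)` for homozygous deletions (so low-cellularity
#' samples can miss deletions).
#'
#' @param config a [sim_config()].
#' @return list of class `amplicon_cohort` with elements `config`, `manifest`,
#'   `truth` (variants, cnv), `counts` (list `A`/`B` of amplicon x sample
#'   matrices), `variants` (list `A`/`B` of per-sample candidate
#'   [variant_table()]s), `kb`, `pairs`, `samples`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- utils::head(.default_genes, config$n_genes)
    if (config$n_genes > nrow(.default_genes)) {
      extra <- config$n_genes - nrow(.default_genes)
      genes <- rbind(genes, data.frame(
        gene = sprintf("GENE%02d", seq_len(extra) + nrow(.default_genes)),
        role = rep(c("oncogene", "tumour_suppressor"), length.out = extra),
        stringsAsFactors = FALSE))
    }
    manifest <- .sim_manifest(config, genes)
    attr(config, "manifest") <- manifest
    truth <- .sim_truth(config, genes, manifest)
    kb <- .sim_kb(config, genes, truth)
    meta <- .sim_sample_meta(config)
    samples <- meta$samples

    eff <- rlnorm(nrow(manifest), 0, 0.4)
    n_s <- nrow(samples)
    counts <- list()
    vtabs <- list()
    for (panel in c("A", "B")) {
      mat <- matrix(0, nrow(manifest), max(n_s, 0),
                    dimnames = list(manifest$id, samples$sample_id))
      vt <- vector("list", n_s)
      names(vt) <- samples$sample_id
      for (s in seq_len(n_s)) {
        tcf <- samples$tumour_cell_fraction[s]
        pid <- samples$patient_id[s]
        cnv_p <- truth$cnv[truth$cnv$patient_id == pid, , drop = FALSE]
        m <- .copy_multiplier(config, manifest, cnv_p, tcf)
        sf <- rlnorm(1, 0, 0.2)
        mu <- config$mean_depth_per_amplicon * eff * sf * m
        mat[, s] <- rnbinom(nrow(manifest), size = config$counts_dispersion,
                            mu = mu)
        tv <- truth$variants[truth$variants$patient_id == pid, , drop = FALSE]
        if (config$private_event_rate > 0 && rpois(1, config$private_event_rate) > 0) {
          priv <- tv[sample.int(max(nrow(tv), 1), 0), , drop = FALSE] # placeholder keeps schema
          tv <- rbind(tv, priv)
        }
        vt[[s]] <- .observe_variants(config, tv, tcf, genes)
      }
      counts[[panel]] <- mat
      vtabs[[panel]] <- vt
    }
    structure(list(config = config, manifest = manifest, truth = truth,
                   counts = counts, variants = vtabs, kb = kb,
                   pairs = meta$pairs, samples = samples),
              class = "amplicon_cohort")
  })
}

#' Simulate an aligned read-pair stream realizing a set of amplicon counts
#'
#' Emits, per amplicon, the requested number of read pairs whose fragment
#' endpoints deviate from the amplicon ends by integer offsets drawn
#' uniformly in `[-jitter, +jitter]`; with probability `fusion_rate` a pair
#' instead spans from the start of one amplicon to the end of its neighbour
#' (the signature of PCR fusion of adjacent amplicons, which assignment must
#' exclude).
#'
#' @param manifest a [panel_manifest()].
#' @param counts named integer vector (amplicon id -> pair count) or a
#'   single-sample column of a count matrix.
#' @param jitter maximum absolute endpoint offset in bases (>= 0).
#' @param fusion_rate per-pair probability of a cross-amplicon fusion.
#' @param seed integer seed.
#' @return a `read_pairs` data.frame.
#' @export
simulate_read_pairs <- function(manifest, counts, jitter = 0,
                                fusion_rate = 0, seed = 1L) {
  stopifnot(jitter >= 0, fusion_rate >= 0, fusion_rate <= 1)
  counts <- counts[manifest$id]
  counts[is.na(counts)] <- 0
  with_seed(seed, {
    # fusion partner: next amplicon on the same chromosome, else previous
    n <- nrow(manifest)
    partner <- seq_len(n) + 1L
    last_on_chrom <- c(manifest$chrom[-1] != manifest$chrom[-n], TRUE)
    partner[last_on_chrom] <- which(last_on_chrom) - 1L
    cross_chrom <- partner < 1 | partner > n |
      manifest$chrom[pmax(pmin(partner, n), 1)] != manifest$chrom
    partner[cross_chrom] <- NA_integer_
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- as.integer(counts[i])
      if (ci <= 0) next
      fused <- runif(ci) < fusion_rate
      j <- ifelse(fused, partner[i], i)
      ok <- !is.na(j)
      # a fused fragment spans from the earlier amplicon's start to the
      # later amplicon's end
      lo <- pmin(i, j); hi <- pmax(i, j)
      r1 <- manifest$start[lo] +
        sample(seq(-jitter, jitter), ci, replace = TRUE)
      r2 <- manifest$end[hi] + sample(seq(-jitter, jitter), ci, replace = TRUE)
      rows[[i]] <- data.frame(
        read_id = sprintf("%s_rp%05d", manifest$id[i], seq_len(ci)),
        chrom = manifest$chrom[i],
        r1_start = as.integer(r1), r2_end = as.integer(r2),
        stringsAsFactors = FALSE)[ok, , drop = FALSE]
    }
    df <- do.call(rbind, c(rows, list(data.frame(
      read_id = character(0), chrom = character(0), r1_start = integer(0),
      r2_end = integer(0), stringsAsFactors = FALSE))))
    read_pairs(df$read_id, df$chrom, df$r1_start, df$r2_end)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write every generated artefact of a cohort to a directory
#'
#' Exports the manifest (BED-like TSV), raw count matrices per panel,
#' candidate variant tables per sample/panel, the knowledge base tables, the
#' sample sheet and `truth.tsv` / `truth_cnv.tsv`.
#'
#' @param sim an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_manifest(sim$manifest, file.path(dir, "panel.tsv"))
  for (panel in names(sim$counts))
    write_count_matrix(sim$counts[[panel]],
                       file.path(dir, paste0("counts_", panel, ".tsv")))
  vdir <- file.path(dir, "variants")
  dir.create(vdir, showWarnings = FALSE)
  for (panel in names(sim$variants))
    for (s in names(sim$variants[[panel]]))
      write_variants(sim$variants[[panel]][[s]],
                     file.path(vdir, paste0(s, "_", panel, ".tsv")))
  write_knowledge_base(sim$kb, file.path(dir, "kb"))
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$variants, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$cnv, file.path(dir, "truth_cnv.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
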