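# Shared fixtures and independent oracles used across test files.

# -- small panel: 3 well-separated amplicons on one chromosome -------------
tiny_manifest <- function() {
  panel_manifest(data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 500L),
    end = c(200L, 400L, 600L),
    id = c("A1", "A2", "A3"),
    gene = c("G1", "G1", "G2"),
    fwd_primer_len = 10L, rev_primer_len = 10L,
    blacklisted = FALSE, stringsAsFactors = FALSE))
}

# scaled-down simulation configuration for fast unit tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_patients = 8, n_genes = 10, n_amplicons = 80,
             seed = seed, ...)
}

# -- brute-force penalized least-squares segmentation ----------------------
# enumerate all 2^(n-1) breakpoint subsets; returns the minimal objective
brute_segment_cost <- function(x, penalty) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    cost <- sum(vapply(seq_along(starts), function(k)
      sse(x[starts[k]:ends[k]]), numeric(1))) + penalty * length(starts)
    if (cost < best) best <- cost
  }
  best
}

dp_cost <- function(x, penalty) {
  seg <- segment_log2(x, penalty)
  sum(vapply(seq_len(nrow(seg)), function(k) {
    v <- x[seg$start_idx[k]:seg$end_idx[k]]
    sum((v - mean(v))^2)
  }, numeric(1))) + penalty * nrow(seg)
}

# -- brute-force Benjamini-Hochberg step-up --------------------------------
# adjusted value by definition: adj_(k) = min_{j >= k} m * p_(j) / j
brute_bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(1, adj_sorted)
  adj
}

# rejections at level q by the literal step-up rule: max k with
# p_(k) <= k * q / m, reject all hypotheses with p <= p_(k)
brute_bh_reject <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * q / m)
  if (!length(ks)) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# -- exact Mann-Whitney permutation p-value (no ties) ----------------------
perm_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# -- minimal knowledge base for validation tests ---------------------------
mini_kb <- function() {
  knowledge_base(
    gene_roles = data.frame(
      gene = c("KRAS", "ERBB2", "TP53", "CDKN2A"),
      role = c("oncogene", "oncogene", "tumour_suppressor",
               "tumour_suppressor"),
      stringsAsFactors = FALSE),
    hotspots = data.frame(gene = "KRAS", protein_change = "p.G12D",
                          confidence = "established",
                          stringsAsFactors = FALSE),
    known_inactivating_missense = data.frame(
      gene = "TP53", protein_change = "p.R175H",
      confidence = "established", stringsAsFactors = FALSE),
    population_freqs = data.frame(chrom = "chr9", pos = 999L, ref = "G",
                                  alt = "A", freq = 0.002,
                                  stringsAsFactors = FALSE),
    actionable_rules = data.frame(
      gene = c("KRAS", "ERBB2", "CDKN2A"),
      alteration_class = c("pathogenic_variant", "amplification",
                           "homozygous_deletion"),
      actionable = TRUE, stringsAsFactors = FALSE))
}

# one variant_table row with overridable fields
vrow <- function(chrom = "chr1", pos = 150L, ref = "C", alt = "T",
                 gene = "KRAS", consequence = "missense", depth = 1000L,
                 alt_reads = 300L, indel_len = 0L,
                 exon_edge_distance = 30L, protein_change = "p.G12D") {
  variant_table(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           gene = gene, consequence = consequence,
                           depth = depth, alt_reads = alt_reads,
                           indel_len = indel_len,
                           exon_edge_distance = exon_edge_distance,
                           protein_change = protein_change,
                           stringsAsFactors = FALSE))
}

# hand-built gene-level CNV call table
cnv_call_row <- function(gene, status, median_log2 = -1.5) {
  structure(data.frame(gene = gene, status = status,
                       median_log2 = median_log2, n_amplicons = 10L,
                       panel_id = "A", stringsAsFactors = FALSE),
            class = c("cnv_calls", "data.frame"))
}

# empty validated side (for pair tests)
empty_side <- function(patient_id = "P01", sample_id = "S") {
  validate_sample(vrow()[0, ], NULL, mini_kb(), tcf = 0.5,
                  sample_id = sample_id, patient_id = patient_id)
}
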