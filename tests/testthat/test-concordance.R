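kb <- mini_kb()

# build a validated side from shorthand: list(gene = status); an empty or
# all-"Normal" shorthand yields a side with no findings
side_of <- function(pid, statuses) {
  if (!length(statuses)) statuses <- c(TP53 = "Normal")
  led <- data.frame(gene = names(statuses), cnb_result = unname(statuses),
                    fna_result = "Absent", patient_id = pid,
                    stringsAsFactors = FALSE)
  sides_from_status_ledger(led, kb)[[pid]]$cnb
}

test_that("pairing classifies matching and mismatching statuses", {
  cnb <- side_of("P1", c(CDKN2A = "Homozygous deletion"))
  fna <- side_of("P1", c(CDKN2A = "Homozygous deletion"))
  pr <- pair_and_classify(cnb, fna)
  expect_true(pr$concordant)

  # deletion seen in FNA only
  pr2 <- pair_and_classify(side_of("P2", c(CDKN2A = "Normal")),
                           side_of("P2", c(CDKN2A = "Homozygous deletion")))
  expect_false(pr2$concordant)
  expect_equal(pr2$bucket, "fna_only")

  # hom/het mismatch is discordant but listed once
  pr3 <- pair_and_classify(
    side_of("P3", c(CDKN2A = "Homozygous deletion")),
    side_of("P3", c(CDKN2A = "Heterozygous deletion")))
  expect_equal(nrow(pr3), 1)
  expect_false(pr3$concordant)
  expect_equal(pr3$fna_result, "Heterozygous deletion")

  # gain versus amplification is discordant
  pr4 <- pair_and_classify(side_of("P4", c(ERBB2 = "Gain")),
                           side_of("P4", c(ERBB2 = "Amplification")))
  expect_false(pr4$concordant)
  expect_equal(pr4$bucket, "fna_only")
})

test_that("heterozygous-only tumour-suppressor findings follow the display rule", {
  het <- side_of("P5", c(TP53 = "Heterozygous mutation"))
  none <- side_of("P5", c(TP53 = "WT"))
  pr <- pair_and_classify(het, none, special_het_rule = TRUE)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$cnb_result, "Heterozygous mutation")
  expect_equal(pr$fna_result, "Absent")
  expect_false(pr$concordant)
  # with the rule off the unvalidated finding disappears
  expect_equal(nrow(pair_and_classify(het, none, special_het_rule = FALSE)),
               0)
  # het on both sides is not listed (neither is validated)
  het2 <- side_of("P5", c(TP53 = "Heterozygous mutation"))
  expect_equal(nrow(pair_and_classify(het, het2)), 0)
})

test_that("cohort summary pools tallies with integer-rounded percentages", {
  tal <- concordance_tally(variants = c(69, 85), amplifications = c(21, 23),
                           homozygous_deletions = c(8, 15))
  rep <- cohort_summary(tal)
  expect_equal(rep$n_concordant, 98)
  expect_equal(rep$n_total, 123)
  expect_equal(rep$pct_concordant, 80) # 79.67 rounds to 80
  expect_equal(rep$categories$pct_concordant, c(81, 91, 53))

  all_conc <- concordance_tally(c(5, 5), c(2, 2), c(1, 1))
  expect_equal(cohort_summary(all_conc)$pct_concordant, 100)
  empty <- concordance_tally(c(0, 0), c(0, 0), c(0, 0))
  expect_true(is.na(cohort_summary(empty)$pct_concordant))
  expect_error(concordance_tally(c(6, 5), c(0, 0), c(0, 0)), "exceeds")
})

test_that("paired summaries conserve events and respect symmetry", {
  sim <- simulate_cohort(small_config(seed = 9L))
  run <- run_cohort_pipeline(sim)
  pr <- run$paired
  rep <- run$report
  # outer-join conservation: every event lands in exactly one bucket
  expect_equal(rep$n_total, nrow(pr))
  expect_equal(sum(rep$categories$n_concordant) +
                 sum(rep$categories$n_cnb_only) +
                 sum(rep$categories$n_fna_only), nrow(pr))
  expect_equal(rep$n_fully_concordant_patients + rep$n_discordant_patients,
               nrow(sim$pairs))

  # swapping the members swaps the one-sided buckets
  swapped <- do.call(rbind, lapply(sim$pairs$patient_id, function(pid) {
    cnb <- run$sample_results[[paste0(pid, "_CNB")]]$validated
    fna <- run$sample_results[[paste0(pid, "_FNA")]]$validated
    pair_and_classify(fna, cnb)
  }))
  class(swapped) <- c("paired_alterations", "data.frame")
  rep_sw <- cohort_summary(swapped, patients = sim$pairs$patient_id)
  expect_equal(rep_sw$categories$n_cnb_only, rep$categories$n_fna_only)
  expect_equal(rep_sw$categories$n_fna_only, rep$categories$n_cnb_only)
  expect_equal(rep_sw$n_concordant, rep$n_concordant)
})

test_that("allele-frequency correlation uses the arcsine-root transform", {
  af <- c(0.1, 0.2, 0.4, 0.05, 0.33)
  expect_equal(af_correlation(af, af), 1)
  # matches an independent re-computation of the formula
  set.seed(2)
  x <- runif(20); y <- pmin(1, pmax(0, x + rnorm(20, 0, 0.1)))
  expect_equal(af_correlation(x, y),
               cor(asin(sqrt(x)), asin(sqrt(y))), tolerance = 1e-12)
  # closed-form endpoints of the transform
  expect_equal(asin(sqrt(0)), 0)
  expect_equal(asin(sqrt(1)), pi / 2)
  expect_warning(r <- af_correlation(rep(0.2, 5), af), "zero variance")
  expect_true(is.na(r))
  expect_warning(af_correlation(c(0.1, 0.2), c(0.1, 0.2)), "fewer than 3")
})

test_that("per-pair segment correlation adjusts across pairs", {
  seg <- function(med) {
    n <- length(med)
    structure(data.frame(
      chrom = "chr1", start_idx = seq(1, 10 * n, by = 10),
      end_idx = seq(10, 10 * n, by = 10), n_amplicons = 10L,
      mean_log2 = med, median_log2 = med,
      status = call_status(med), stringsAsFactors = FALSE),
      class = c("segmented_profile", "data.frame"))
  }
  ident <- list(cnb = seg(c(0, -1.5, 0, 2.4)), fna = seg(c(0, -1.5, 0, 2.4)))
  noisy <- list(cnb = seg(c(0, -1.5, 0, 2.4)),
                fna = seg(c(0.1, -0.2, 0.05, 0.0)))
  flat <- list(cnb = seg(0), fna = seg(0)) # single segment -> excluded
  res <- cnv_pair_correlation(list(p1 = ident, p2 = noisy, p3 = flat))
  expect_equal(res$r[res$patient_id == "p1"], 1)
  expect_true(res$excluded[res$patient_id == "p3"])
  usable <- !is.na(res$p)
  expect_equal(res$p_adj[usable], p.adjust(res$p[usable], "BH"))
  expect_true(res$significant[res$patient_id == "p1"])
})

test_that("Benjamini-Hochberg equals its brute-force definition", {
  # the worked case: four evenly spaced p-values all adjust to the largest
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p4, "BH"), rep(0.04, 4))
  expect_true(all(brute_bh_reject(p4, 0.05)))
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), brute_bh_adjust(p), tolerance = 1e-12)
    expect_equal(p.adjust(p, "BH") <= 0.05, brute_bh_reject(p, 0.05))
  }
})

test_that("independent profiles rarely pass the FDR filter", {
  set.seed(8)
  seg <- function(med) structure(data.frame(
    chrom = "chr1", start_idx = seq(1, 91, by = 10),
    end_idx = seq(10, 100, by = 10), n_amplicons = 10L,
    mean_log2 = med, median_log2 = med, status = call_status(med),
    stringsAsFactors = FALSE), class = c("segmented_profile", "data.frame"))
  null_pairs <- lapply(1:100, function(i)
    list(cnb = seg(rnorm(10, 0, 0.3)), fna = seg(rnorm(10, 0, 0.3))))
  names(null_pairs) <- sprintf("n%03d", 1:100)
  res <- cnv_pair_correlation(null_pairs)
  expect_lte(sum(res$significant), 5)
})

test_that("QC group tests behave on null and separated groups", {
  set.seed(12)
  same <- data.frame(tumour_cell_fraction = runif(30, 0.3, 0.7))
  qc0 <- qc_group_tests(same, same, metrics = "tumour_cell_fraction")
  expect_gt(qc0$mann_whitney$p, 0.99)
  expect_equal(qc0$mann_whitney$stars, "")

  # the cellularity gap of the default generator is detectable at n = 61
  sim <- simulate_cohort(sim_config(seed = 4L))
  qc <- qc_group_tests(sim$samples[sim$samples$sample_type == "CNB", ],
                       sim$samples[sim$samples$sample_type == "FNA", ])
  p_tcf <- qc$mann_whitney$p[qc$mann_whitney$metric ==
                               "tumour_cell_fraction"]
  expect_lt(p_tcf, 0.001)
  expect_true(!is.null(qc$kruskal_p))
  expect_true(all(c("group1", "group2", "p_adj") %in% names(qc$dunn)))
})

test_that("Dunn's test separates shifted groups and spares equal ones", {
  set.seed(6)
  x <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 3))
  g <- rep(c("a", "b", "c"), each = 20)
  d <- dunn_test(x, g)
  expect_gt(d$p_adj[d$group1 == "a" & d$group2 == "b"], 0.2)
  expect_lt(d$p_adj[d$group1 == "a" & d$group2 == "c"], 0.001)
})
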