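test_that("normalization satisfies both median invariants", {
  for (seed in 1:5) {
    set.seed(seed)
    raw <- matrix(rnbinom(31 * 7, size = 20, mu = 400), 31, 7,
                  dimnames = list(sprintf("a%02d", 1:31), letters[1:7]))
    nm <- normalize_counts(raw)
    # replicate the two steps independently (oracle) and compare
    v <- raw; v[v == 0] <- 0.5
    step1 <- sweep(v, 2, apply(v, 2, median), "/")
    expect_equal(unname(apply(step1, 2, median)), rep(1, 7))
    step2 <- sweep(step1, 1, apply(step1, 1, median), "/")
    expect_equal(unname(apply(step2, 1, median)), rep(1, 31))
    expect_equal(nm$values, step2)
    expect_equal(nm$log2, log2(step2))
  }
})

test_that("hand-computable normalizations come out exactly", {
  # 3 amplicons x 2 identical barcodes: both steps divide everything away
  m <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  nm <- normalize_counts(m)
  expect_equal(unname(nm$values), matrix(1, 3, 2))
  # constant matrix
  cm <- normalize_counts(matrix(7, 5, 3, dimnames = list(letters[1:5], NULL)))
  expect_equal(unname(cm$log2), matrix(0, 5, 3))
  # a barcode with every count doubled is absorbed by the per-barcode median
  set.seed(1)
  base <- matrix(rnbinom(45, size = 30, mu = 300), 15, 3)
  rownames(base) <- sprintf("a%02d", 1:15)
  doubled <- cbind(base, 2 * base[, 1])
  nm2 <- normalize_counts(doubled)
  expect_equal(nm2$values[, 4], nm2$values[, 1], tolerance = 1e-12)
})

test_that("normalization is idempotent on copy-structured matrices", {
  # rank-one efficiency x library-size structure, with an amplification on
  # the highest-efficiency amplicon (medians untouched)
  set.seed(42)
  e <- sort(rlnorm(15, 0, 0.5)) # max is last
  s <- rlnorm(5, 0, 0.3)
  v <- outer(e, s)
  v[15, 3] <- v[15, 3] * 4
  rownames(v) <- sprintf("a%02d", 1:15)
  n1 <- normalize_counts(v)
  n2 <- normalize_counts(n1$values)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
})

test_that("degenerate barcodes and blacklisted amplicons are handled", {
  raw <- matrix(c(1, 2, 3, 0, 0, 0), ncol = 2,
                dimnames = list(c("A1", "A2", "A3"), c("ok", "dead")))
  expect_error(normalize_counts(raw), "all-zero")
  expect_error(normalize_counts(raw[, 1, drop = FALSE]), "at least 2")
  m <- tiny_manifest()
  m$blacklisted[2] <- TRUE
  good <- matrix(10, 3, 2, dimnames = list(m$id, c("x", "y")))
  nm <- normalize_counts(good, m)
  expect_equal(rownames(nm$values), c("A1", "A3"))
})

test_that("segmentation recovers noiseless change-points exactly", {
  flat <- rep(0.3, 40)
  expect_equal(nrow(segment_log2(flat)), 1)
  step <- c(rep(0, 20), rep(-2, 20))
  seg <- segment_log2(step)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end_idx[1], 20)
  expect_equal(seg$median_log2, c(0, -2))
  expect_error(segment_log2(c(1, NA, 2)), "non-finite")
  expect_error(segment_log2(1:3, penalty = 0), "penalty")
})

test_that("dynamic programming equals exhaustive search on short vectors", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    x <- rnorm(n) + sample(c(0, 2), n, replace = TRUE)
    penalty <- runif(1, 0.05, 3)
    expect_equal(dp_cost(x, penalty), brute_segment_cost(x, penalty),
                 tolerance = 1e-9)
  }
})

test_that("status thresholds are strict at the published boundaries", {
  expect_equal(call_status(-1.5), "homozygous_deletion")
  expect_equal(call_status(-1.0), "heterozygous_deletion") # not homdel
  expect_equal(call_status(2.5), "amplification")
  expect_equal(call_status(2.0), "gain")                   # not amplification
  expect_equal(call_status(0), "normal")
  expect_equal(call_status(-0.41), "heterozygous_deletion")
  expect_equal(call_status(0.58), "gain")
})

test_that("gene-level consensus keeps agreeing calls with panel A values", {
  mu <- as.data.frame(tiny_manifest()) # G1: A1,A2; G2: A3
  prof <- function(v) segment_profile(v, mu)
  a <- prof(c(2.6, 2.4, 0.0))
  b_same <- prof(c(2.2, 2.3, 0.1))
  b_diff <- prof(c(0.0, 0.1, 0.0))
  cons <- gene_level_calls(a, mu, b_same)
  expect_equal(cons$gene, "G1")
  expect_equal(cons$status, "amplification")
  expect_equal(cons$median_log2, 2.5) # reported from panel A
  none <- gene_level_calls(a, mu, b_diff)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "discordant_genes"), "G1")
  solo <- gene_level_calls(a, mu, panel_consensus = FALSE)
  expect_equal(solo$gene, "G1")
})

test_that("homozygous-deletion recall does not improve at lower cellularity", {
  # same truth, cellularity forced to 0.5 versus 0.3 for every sample
  raw_recall <- function(tcf_mean) {
    cfg <- sim_config(n_patients = 25, n_genes = 10, n_amplicons = 100,
                      cnb_cellularity_mean = tcf_mean,
                      fna_cellularity_mean = tcf_mean, cellularity_sd = 0,
                      homdel_rate = 1.2, amp_rate = 0, variant_rate = 0,
                      passenger_rate = 0, polymorphism_rate = 0,
                      artifact_rate = 0, seed = 77L)
    sim <- simulate_cohort(cfg)
    run <- run_cohort_pipeline(sim)
    hits <- 0L; tot <- 0L
    for (s in sim$samples$sample_id) {
      pid <- sim$samples$patient_id[sim$samples$sample_id == s]
      ev <- sim$truth$cnv[sim$truth$cnv$patient_id == pid &
                            sim$truth$cnv$state == "homdel", ]
      val <- run$sample_results[[s]]$validated$validated
      tot <- tot + nrow(ev)
      hits <- hits + sum(ev$gene %in%
                           val$gene[val$alteration_class ==
                                      "homozygous_deletion"])
    }
    hits / tot
  }
  r_low <- raw_recall(0.3)
  r_high <- raw_recall(0.5)
  expect_lte(r_low, r_high)
  expect_gt(r_high, 0.9) # deletions are detectable at adequate cellularity
})
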