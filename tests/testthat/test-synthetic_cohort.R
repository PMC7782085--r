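test_that("cohort simulation is fully determined by the seed", {
  a <- simulate_cohort(small_config(seed = 5L))
  b <- simulate_cohort(small_config(seed = 5L))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$variants$A[[1]], b$variants$A[[1]])
  expect_identical(a$samples, b$samples)
  c <- simulate_cohort(small_config(seed = 6L))
  expect_false(identical(a$counts$A, c$counts$A))
})

test_that("zero-patient configuration yields empty but valid outputs", {
  sim <- simulate_cohort(sim_config(n_patients = 0, seed = 1))
  expect_equal(ncol(sim$counts$A), 0)
  expect_equal(nrow(sim$truth$variants), 0)
  expect_equal(nrow(sim$samples), 0)
  expect_s3_class(sim$manifest, "panel_manifest")
})

test_that("pure-tumour clonal heterozygous variants sit at AF 0.5", {
  cfg <- sim_config(n_patients = 6, n_genes = 10, n_amplicons = 60,
                    cnb_cellularity_mean = 1, fna_cellularity_mean = 1,
                    cellularity_sd = 0, mean_depth_per_amplicon = 5e4,
                    variant_rate = 3, amp_rate = 0, homdel_rate = 0,
                    passenger_rate = 0, polymorphism_rate = 0,
                    artifact_rate = 0, driver_ccf_range = c(1, 1),
                    seed = 11L)
  sim <- simulate_cohort(cfg)
  tv <- sim$truth$variants
  for (s in names(sim$variants$A)) {
    obs <- sim$variants$A[[s]]
    pid <- sim$samples$patient_id[sim$samples$sample_id == s]
    truth_p <- tv[tv$patient_id == pid, ]
    for (i in seq_len(nrow(obs))) {
      z <- truth_p$zygosity[truth_p$gene == obs$gene[i]][1]
      expected <- if (z == "homozygous") 1 else 0.5
      expect_lt(abs(obs$allele_freq[i] - expected), 0.02)
    }
  }
})

test_that("a planted amplification pushes normalized log2 to its closed form", {
  # copies k at cellularity t on a flat background: multiplier (2(1-t)+kt)/2;
  # k = 8, t = 1 gives exactly 4, i.e. log2 = 2, untouched by the two median
  # divisions when fewer than half the amplicons/barcodes are altered
  counts <- matrix(100, nrow = 21, ncol = 5,
                   dimnames = list(sprintf("a%02d", 1:21), letters[1:5]))
  span <- 5:12
  counts[span, 3] <- 100 * (2 * (1 - 1) + 8 * 1) / 2
  nm <- normalize_counts(counts)
  expect_equal(unname(nm$log2[span, 3]), rep(2, length(span)))
  expect_equal(unname(nm$log2[-span, ]), matrix(0, 13, 5), tolerance = 1e-12)
})

test_that("read-pair simulation round-trips counts through assignment", {
  m <- tiny_manifest()
  counts <- c(A1 = 17L, A2 = 5L, A3 = 0L)
  pairs <- simulate_read_pairs(m, counts, jitter = 0, fusion_rate = 0,
                               seed = 3L)
  sc <- count_amplicons(pairs, m, tolerance = 3)
  expect_equal(sc$raw, counts)

  # jitter within tolerance still recovers exactly
  pairs_j <- simulate_read_pairs(m, counts, jitter = 3, fusion_rate = 0,
                                 seed = 3L)
  expect_equal(count_amplicons(pairs_j, m, tolerance = 3)$raw, counts)

  # jitter beyond tolerance loses some pairs
  pairs_5 <- simulate_read_pairs(m, c(A1 = 200L, A2 = 0L, A3 = 0L),
                                 jitter = 5, fusion_rate = 0, seed = 3L)
  sc5 <- count_amplicons(pairs_5, m, tolerance = 3)
  expect_lt(sc5$raw[["A1"]], 200L)
  expect_gt(sc5$tally[["unassigned"]], 0)
})

test_that("full fusion on a two-amplicon panel leaves nothing assignable", {
  m2 <- panel_manifest(data.frame(
    chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
    id = c("B1", "B2"), gene = "G", fwd_primer_len = 10L,
    rev_primer_len = 10L, stringsAsFactors = FALSE))
  pairs <- simulate_read_pairs(m2, c(B1 = 30L, B2 = 30L), jitter = 0,
                               fusion_rate = 1, seed = 2L)
  sc <- count_amplicons(pairs, m2)
  expect_equal(unname(sc$raw), c(0L, 0L))
  expect_equal(sc$tally[["fused"]], 60L)
})

test_that("observed allele fractions recover the dilution model", {
  # mean absolute error of observed AF against ccf x cellularity x zygosity
  cfg <- sim_config(n_patients = 210, seed = 21L)
  sim <- simulate_cohort(cfg)
  tv <- sim$truth$variants
  tv <- tv[tv$origin == "driver", ]
  errs <- c()
  for (s in sim$samples$sample_id) {
    obs <- sim$variants$A[[s]]
    pid <- sim$samples$patient_id[sim$samples$sample_id == s]
    tcf <- sim$samples$tumour_cell_fraction[sim$samples$sample_id == s]
    tp <- tv[tv$patient_id == pid, ]
    if (!nrow(tp)) next
    key_t <- paste(tp$chrom, tp$pos, tp$ref, tp$alt)
    key_o <- paste(obs$chrom, obs$pos, obs$ref, obs$alt)
    i <- match(key_t, key_o)
    ok <- !is.na(i)
    zf <- ifelse(tp$zygosity == "homozygous", 1, 0.5)
    expected <- pmin(1, tp$ccf * tcf * zf)
    errs <- c(errs, abs(obs$allele_freq[i[ok]] - expected[ok]))
  }
  expect_gt(length(errs), 200)
  expect_lt(mean(errs), 0.03)
})
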