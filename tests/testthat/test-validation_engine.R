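kb <- mini_kb()

test_that("the pathogenicity cascade follows gene role and evidence", {
  cls <- function(v) classify_variant(v, kb)$pathogenicity_class
  # oncogene hotspot missense
  expect_equal(cls(vrow()), "Pathogenic")
  # population frequency 0.2% overrides everything
  poly <- vrow(chrom = "chr9", pos = 999L, ref = "G", alt = "A",
               gene = "KRAS", protein_change = "p.G12D")
  expect_equal(cls(poly), "Benign")
  # oncogene non-hotspot missense
  expect_equal(cls(vrow(protein_change = "p.X99X")),
               "Uncertain_significance")
  # oncogene truncating events are not activating
  expect_equal(cls(vrow(consequence = "nonsense", protein_change = NA)),
               "Likely_benign")
  expect_equal(cls(vrow(consequence = "synonymous", protein_change = NA)),
               "Benign")
  # tumour suppressor inactivating classes
  for (csq in c("nonsense", "frameshift_indel", "splice",
                "intragenic_large_del_dup"))
    expect_equal(cls(vrow(gene = "TP53", consequence = csq,
                          protein_change = NA)), "Pathogenic")
  expect_equal(cls(vrow(gene = "TP53", protein_change = "p.R175H")),
               "Pathogenic")
  expect_equal(cls(vrow(gene = "TP53", protein_change = "p.Other")),
               "Uncertain_significance")
  # synonymous near an exon boundary can alter splicing
  expect_equal(cls(vrow(gene = "TP53", consequence = "synonymous",
                        exon_edge_distance = 1L, protein_change = NA)),
               "Uncertain_significance")
  expect_equal(cls(vrow(gene = "TP53", consequence = "synonymous",
                        exon_edge_distance = 5L, protein_change = NA)),
               "Likely_benign")
  expect_error(classify_variant(vrow(gene = "NOPE"), kb), "without a role")
})

test_that("the 5% allele-frequency gate is inclusive", {
  expect_true(apply_af_gate(vrow(depth = 1000L, alt_reads = 50L)))  # 5.0%
  expect_false(apply_af_gate(vrow(depth = 1000L, alt_reads = 49L))) # 4.9%
  expect_true(apply_af_gate(vrow(depth = 100L, alt_reads = 100L)))  # 100%
})

test_that("zygosity is the nearer dilution expectation, upgraded by LOH", {
  z <- function(af, tcf, cnv = NULL)
    call_zygosity(vrow(depth = 1000L, alt_reads = as.integer(af * 1000)),
                  tcf, cnv)
  expect_equal(z(0.26, 0.5), "heterozygous") # |0.26-0.25| < |0.26-0.50|
  expect_equal(z(0.48, 0.5), "homozygous")
  expect_equal(z(0.19, 0.4), "heterozygous")
  expect_equal(z(0.19, 0.4, cnv_call_row("KRAS", "heterozygous_deletion")),
               "homozygous") # mutation + loss of the wild-type allele
})

test_that("tumour-suppressor validation requires bi-allelic inactivation", {
  het1 <- vrow(gene = "TP53", consequence = "nonsense", protein_change = NA)
  het1$zygosity <- "heterozygous"
  expect_false(tsg_inactivation("TP53", het1)$validated)

  second <- vrow(gene = "TP53", pos = 777L,
                 consequence = "frameshift_indel", indel_len = 2L,
                 protein_change = NA)
  second$zygosity <- "heterozygous"
  het2 <- rbind(het1, second)
  r2 <- tsg_inactivation("TP53", het2)
  expect_true(r2$validated)
  expect_equal(r2$branch, "composite_heterozygous")

  r3 <- tsg_inactivation("TP53", het1,
                         cnv_call_row("TP53", "heterozygous_deletion"))
  expect_true(r3$validated)
  expect_equal(r3$branch, "inactivating_plus_loh")

  hom <- het1; hom$zygosity <- "homozygous"
  expect_equal(tsg_inactivation("TP53", hom)$branch,
               "homozygous_inactivating")

  r5 <- tsg_inactivation("CDKN2A", het1[0, ],
                         cnv_call_row("CDKN2A", "homozygous_deletion"))
  expect_equal(r5$branch, "homozygous_deletion")
})

test_that("sample validation composes the gates end to end", {
  expect_equal(nrow(validate_sample(vrow()[0, ], NULL, kb, 0.5)$validated), 0)

  variants <- vrow(depth = 1000L, alt_reads = 300L) # KRAS hotspot AF 0.30
  cnv <- cnv_call_row("CDKN2A", "homozygous_deletion")
  out <- validate_sample(variants, cnv, kb, tcf = 0.6,
                         sample_id = "P01_CNB", patient_id = "P01")
  v <- out$validated
  expect_equal(nrow(v), 2)
  kras <- v[v$gene == "KRAS", ]
  expect_equal(kras$alteration_class, "pathogenic_variant")
  expect_equal(kras$zygosity, "heterozygous") # 0.30 ~ 0.5 * 0.6
  expect_true(kras$actionable)
  cd <- v[v$gene == "CDKN2A", ]
  expect_equal(cd$alteration_class, "homozygous_deletion")
  expect_true(cd$actionable)

  # below the AF gate nothing is validated
  low <- vrow(depth = 1000L, alt_reads = 45L) # 4.5%
  expect_equal(nrow(validate_sample(low, NULL, kb, 0.6)$validated), 0)

  # identical inputs give identical outputs (determinism)
  out2 <- validate_sample(variants, cnv, kb, tcf = 0.6,
                          sample_id = "P01_CNB", patient_id = "P01")
  expect_identical(out, out2)
})

test_that("every validated variant satisfies the composed gates", {
  sim <- simulate_cohort(small_config(seed = 3L))
  run <- run_cohort_pipeline(sim)
  for (sr in run$sample_results) {
    v <- sr$validated$validated
    vv <- v[v$alteration_class == "pathogenic_variant", ]
    if (!nrow(vv)) next
    expect_true(all(vv$allele_freq >= 0.05))
    expect_true(all(vv$pathogenicity_class %in%
                      c("Pathogenic", "Likely_pathogenic")))
    expect_true(all(nzchar(vv$evidence_trace)))
    expect_true(all(grepl("af_gate_5pct", vv$evidence_trace)))
  }
})
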