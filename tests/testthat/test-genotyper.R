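spec <- apoe_target_spec()

hap_call <- function(label, classification = "intact", edited = FALSE,
                     fraction = 1, n_reads = 100L) {
  make_call(classification = classification, edited = edited,
            fraction = fraction, n_reads = n_reads,
            allele_seq = mosaicbe:::haplotype_sequence(label, spec))
}

test_that("the epsilon haplotype table is reproduced exactly", {
  expect_equal(call_apoe_haplotype("TGC", "TGC"), "e2")
  expect_equal(call_apoe_haplotype("TGC", "CGC"), "e3")
  expect_equal(call_apoe_haplotype("CGC", "TGC"), "e3r")
  expect_equal(call_apoe_haplotype("CGC", "CGC"), "e4")
  expect_match(call_apoe_haplotype("AGC", "CGC"), "^unclassified:")
})

test_that("converting codon 158 Arg to Cys maps e4 to e3r and e3 to e2", {
  # closure of the label algebra under a 158 C-to-T edit
  edit158 <- function(c112) call_apoe_haplotype(c112, "TGC")
  expect_equal(edit158("CGC"), "e3r") # from e4 (112R/158R)
  expect_equal(edit158("TGC"), "e2")  # from e3 (112C/158R)
})

test_that("heterozygous efficiencies follow the ploidy mapping", {
  two_types <- make_calls(
    hap_call("e3r", "targeted_substitution", edited = TRUE, fraction = 0.31,
             n_reads = 31L),
    hap_call("e4", fraction = 0.69, n_reads = 69L)
  )
  g3_minor <- genotype_blastomere(two_types, 3, edited_read_fraction = 0.31,
                                  spec = spec)
  expect_equal(g3_minor$allelic_efficiency, 33.3)
  g3_major <- genotype_blastomere(two_types, 3, edited_read_fraction = 0.68,
                                  spec = spec)
  expect_equal(g3_major$allelic_efficiency, 66.7)
  g2 <- genotype_blastomere(two_types, 2, spec = spec)
  expect_equal(g2$allelic_efficiency, 50)
  expect_equal(g2$genotype_class, "heterozygous")
  expect_equal(sort(g2$allele_labels[[1]]), c("e3r", "e4"))
})

test_that("single allele types are homozygous at 0% or 100%", {
  wt <- genotype_blastomere(hap_call("e4"), 2, spec = spec)
  expect_equal(wt$genotype_class, "homozygous_wt")
  expect_equal(wt$allelic_efficiency, 0)
  expect_false(wt$e4_free)
  ed <- genotype_blastomere(
    hap_call("e3r", "targeted_substitution", edited = TRUE), 2, spec = spec)
  expect_equal(ed$genotype_class, "homozygous_edited")
  expect_equal(ed$allelic_efficiency, 100)
  expect_true(ed$e4_free)
})

test_that("the read-fraction default drives the 3PN copy assignment", {
  two_types <- make_calls(
    hap_call("e3r", "targeted_substitution", edited = TRUE, fraction = 2 / 3,
             n_reads = 66L),
    hap_call("e4", fraction = 1 / 3, n_reads = 34L)
  )
  g <- genotype_blastomere(two_types, 3, spec = spec)
  expect_equal(g$allelic_efficiency, 66.7)
  expect_equal(sort(g$allele_labels[[1]]), c("e3r", "e3r", "e4"))
})

test_that("excess allele types flag the blastomere and exclude it", {
  three <- make_calls(hap_call("e4"), hap_call("e3"),
                      hap_call("e3r", "targeted_substitution", edited = TRUE))
  g <- genotype_blastomere(three, 2, spec = spec)
  expect_true(g$excess_alleles)
  expect_true(is.na(g$allelic_efficiency))
})

test_that("embryo summaries reproduce printed-count arithmetic", {
  g <- make_genotype_rows(291, 209)
  s <- embryo_summary(g, parental_haplotypes = c("e3", "e4"))
  expect_equal(s$pct_blastomeres_edited, 71.8)
  expect_equal(sum(s$frequency_table$pre_pct), 100)
  expect_equal(sum(s$frequency_table$post_pct), 100, tolerance = 1e-9)
})

test_that("the e4-free fraction counts blastomeres without any e4 copy", {
  rows <- lapply(1:6, function(i) {
    df <- make_genotype_rows(1, as.integer(i <= 5))
    df$blastomere_id <- sprintf("b%d", i)
    # 3 of 6 blastomeres fully converted: no e4 label left
    df$allele_labels <- list(if (i <= 3) c("e3r", "e3r") else c("e3r", "e4"))
    df$e4_free <- i <= 3
    df
  })
  s <- embryo_summary(do.call(rbind, rows), parental_haplotypes = c("e4", "e4"))
  expect_equal(s$e4_free_pct, 50)
})

test_that("frequency tables sum to 100 and track parental input", {
  g <- make_genotype_rows(8, 0, labels_wt = c("e3", "e4"))
  s <- embryo_summary(g, parental_haplotypes = c("e3", "e4"))
  expect_equal(s$allelic_conversion_pct, 0)
  ft <- s$frequency_table
  expect_equal(ft$post_pct, ft$pre_pct)
  expect_equal(sum(ft$pre_pct), 100)
})

test_that("cohort tables stratify and pool printed counts", {
  s1 <- embryo_summary(make_genotype_rows(126, 119), c("e3", "e3"), "E1")
  s2 <- embryo_summary(make_genotype_rows(37, 34), c("e3", "e3"), "E2")
  ct <- cohort_table(list(s1, s2), c("3PN", "2PN"))
  expect_equal(ct$by_stratum$pct_edited[ct$by_stratum$parental_genotype == "3PN"],
               94.4)
  expect_equal(ct$by_stratum$pct_edited[ct$by_stratum$parental_genotype == "2PN"],
               91.9)
  empty <- cohort_table(list())
  expect_equal(nrow(empty$by_stratum), 0L)
})
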