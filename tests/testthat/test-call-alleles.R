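spec <- apoe_target_spec()
amp <- spec$amplicon_seq
edited <- paste0(substr(amp, 1, 165), "T", substr(amp, 167, 240))

test_that("reference-only reads yield a single intact allele at fraction 1", {
  calls <- call_alleles(rep(amp, 30), spec, blastomere_id = "b1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$classification, "intact")
  expect_equal(calls$fraction, 1)
  expect_false(calls$edited)
})

test_that("a 50/50 mixture is called as intact plus targeted substitution", {
  calls <- call_alleles(c(rep(amp, 40), rep(edited, 40)), spec)
  expect_setequal(calls$classification, c("intact", "targeted_substitution"))
  expect_equal(sort(calls$fraction), c(0.5, 0.5))
  expect_equal(sum(calls$edited), 1L)
})

test_that("non-target substitutions classify as NTS", {
  # protospacer position 11 (amplicon 171) holds G; G>A there is a bystander
  expect_equal(substr(amp, 171, 171), "G")
  nts <- paste0(substr(amp, 1, 170), "A", substr(amp, 172, 240))
  calls <- call_alleles(rep(nts, 20), spec)
  expect_equal(calls$classification, "NTS")
  expect_false(calls$edited)
})

test_that("a targeted conversion plus bystander is NTS but still edited", {
  both <- paste0(substr(edited, 1, 170), "A", substr(edited, 172, 240))
  calls <- call_alleles(rep(both, 20), spec)
  expect_equal(calls$classification, "NTS")
  expect_true(calls$edited)
})

test_that("window-overlapping indels dominate the classification", {
  del <- paste0(substr(edited, 1, 169), substr(edited, 172, 240))
  calls <- call_alleles(rep(del, 20), spec)
  expect_equal(calls$classification, "indel")
  expect_false(calls$edited)
})

test_that("noise signatures are discarded and fractions renormalize to 1", {
  noisy <- paste0(substr(amp, 1, 168), "A", substr(amp, 170, 240))
  reads <- c(rep(amp, 60), rep(edited, 37), rep(noisy, 3))
  calls <- call_alleles(reads, spec, min_reads = 5, min_fraction = 0.10)
  expect_equal(nrow(calls), 2L)
  expect_equal(sum(calls$fraction), 1)
  expect_false("NTS" %in% calls$classification)
})

test_that("read support thresholds apply both as count and as fraction", {
  reads <- c(rep(amp, 12), rep(edited, 6))
  # 6 reads but 33% -> kept
  expect_equal(nrow(call_alleles(reads, spec, min_reads = 5,
                                 min_fraction = 0.10)), 2L)
  # min_fraction 0.5 discards the minority signature
  expect_equal(nrow(call_alleles(reads, spec, min_reads = 5,
                                 min_fraction = 0.5)), 1L)
})

test_that("unalignable reads are counted and an all-junk input warns", {
  set.seed(77)
  junk <- vapply(1:8, function(i) random_seq(240), character(1))
  expect_warning(calls <- call_alleles(junk, spec), "no read aligned")
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "n_unalignable"), 8L)

  mixed <- c(rep(amp, 20), junk[1:4])
  calls2 <- call_alleles(mixed, spec)
  expect_equal(attr(calls2, "n_unalignable"), 4L)
  expect_equal(calls2$n_reads, 20L)
})

test_that("haplotype-defining positions outside the window are genotyped", {
  # e3 allele differs from the e4 reference at codon 112 (amplicon 28),
  # outside the quantification window; the call stays intact but the
  # reconstructed allele sequence carries the haplotype base.
  e3 <- mosaicbe:::haplotype_sequence("e3", spec)
  calls <- call_alleles(rep(e3, 20), spec)
  expect_equal(calls$classification, "intact")
  expect_equal(substr(calls$allele_seq, 28, 30), "TGC")
})

test_that("allele calling is invariant under read duplication", {
  reads <- c(rep(amp, 10), rep(edited, 30))
  c1 <- call_alleles(reads, spec)
  c2 <- call_alleles(rep(reads, 3), spec)
  expect_equal(c1$fraction, c2$fraction)
  expect_equal(c1$classification, c2$classification)
  p1 <- editing_profile(c1, spec)
  p2 <- editing_profile(c2, spec)
  expect_equal(p1$by_position$rate, p2$by_position$rate)
})
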