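test_that("configuration invariants are enforced", {
  expect_error(sim_config(ploidy = 4), "ploidy")
  expect_error(sim_config(p_convert = 1.2), "probability")
  expect_error(sim_config(seq_error = 0.6), "seq_error")
  expect_error(sim_config(injected_blastomeres = 9), "0..8")
  expect_error(sim_config(genome_length = 20), "genome_length")
  expect_error(simulate_amplicon_reads(character(), 10, 0, 1), "empty")
})

test_that("each embryo carries ploidy x 8 allele copies and injection flags", {
  for (pl in c(2L, 3L)) {
    cfg <- sim_config(seed = 5, n_embryos = 3, ploidy = pl,
                      injected_blastomeres = 6)
    cohort <- simulate_embryo_cohort(cfg)
    expect_equal(nrow(cohort$alleles), 3L * 8L * pl)
    per_b <- table(cohort$alleles$blastomere_id)
    expect_true(all(per_b == pl))
    expect_equal(sum(cohort$blastomeres$injected), 3L * 6L)
    # un-injected blastomeres carry only parental alleles
    uninj <- cohort$alleles[!cohort$alleles$injected, ]
    expect_true(all(uninj$haplotype_post == uninj$haplotype_pre))
    expect_false(any(uninj$converted))
  }
})

test_that("zero and certain conversion probabilities are degenerate", {
  cfg0 <- sim_config(seed = 6, n_embryos = 4, p_convert = 0, p_bystander = 0,
                     p_indel = 0)
  c0 <- simulate_embryo_cohort(cfg0)
  parental <- vapply(c0$alleles$haplotype_pre,
                     function(h) mosaicbe:::haplotype_sequence(h, c0$spec),
                     character(1))
  expect_true(all(c0$alleles$seq == parental))
  cfg1 <- sim_config(seed = 6, n_embryos = 4, p_convert = 1, p_bystander = 0,
                     p_indel = 0, parental_haplotypes = rep(list(c("e3", "e4")), 4))
  c1 <- simulate_embryo_cohort(cfg1)
  inj <- c1$alleles[c1$alleles$injected, ]
  expect_true(all(inj$converted))
  expect_true(all(inj$haplotype_post %in% c("e2", "e3r")))
})

test_that("the empirical conversion fraction recovers p_convert", {
  cfg <- sim_config(seed = 8, n_embryos = 200, ploidy = 2, p_convert = 0.6,
                    p_bystander = 0, p_indel = 0)
  cohort <- simulate_embryo_cohort(cfg)
  inj <- cohort$alleles[cohort$alleles$injected, ]
  phat <- mean(inj$converted)
  se <- sqrt(0.6 * 0.4 / nrow(inj))
  expect_lt(abs(phat - 0.6), 3 * se)
})

test_that("embryo k is identical regardless of cohort size", {
  c3 <- simulate_embryo_cohort(sim_config(seed = 9, n_embryos = 3))
  c8 <- simulate_embryo_cohort(sim_config(seed = 9, n_embryos = 8))
  a3 <- c3$alleles[c3$alleles$embryo_id == "E003", ]
  a8 <- c8$alleles[c8$alleles$embryo_id == "E003", ]
  rownames(a3) <- rownames(a8) <- NULL
  expect_identical(a3, a8)
})

test_that("error-free reads reproduce the allele sequences exactly", {
  reads <- simulate_amplicon_reads("ACGTACGTAC", depth = 25, seq_error = 0,
                                   seed = 42)
  expect_true(all(reads$seq == "ACGTACGTAC"))
  expect_true(all(nchar(reads$qual) == 10))
})

test_that("reads sample the allele copies uniformly", {
  a <- strrep("A", 50); b <- strrep("C", 50)
  reads <- simulate_amplicon_reads(c(a, b), depth = 400, seq_error = 0,
                                   seed = 7)
  n_a <- sum(reads$seq == a)
  se <- sqrt(400 * 0.25)
  expect_lt(abs(n_a - 200), 3 * se)
})

test_that("identical seeds give byte-identical FASTQ files", {
  cfg <- sim_config(seed = 10, n_embryos = 1, read_depth = 30)
  cohort <- simulate_embryo_cohort(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort_reads(cohort, out_dir = d1)
  simulate_cohort_reads(cohort, out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(length(f1), 8L)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_fastq(f1[1])
  expect_equal(length(back), 30L)
})

test_that("RNA tables straddle the filters and carry the planted signature", {
  cfg <- sim_config(seed = 15, rna_background_snv_rate = 300,
                    rna_cu_excess = 10, n_rna_cells = 4)
  gfp <- simulate_rna_snv_tables(cfg, "GFP-only")
  be3 <- simulate_rna_snv_tables(cfg, "BE3-like")
  pooled_gfp <- do.call(rbind, gfp)
  pooled_be3 <- do.call(rbind, be3)
  # filter is exercised: some but not all records pass
  kept <- filter_rna_snvs(pooled_gfp)
  expect_gt(nrow(kept), 0)
  expect_lt(nrow(kept), nrow(pooled_gfp))
  # BE3-like excess is exclusively C>T / G>A
  expect_gt(nrow(pooled_be3), 2 * nrow(pooled_gfp))
  expect_gt(cu_proportion(pooled_be3), 0.8)
  # records forced to DP 19 are fully removed downstream
  shallow <- pooled_gfp
  shallow$DP <- 19
  expect_equal(nrow(filter_rna_snvs(shallow)), 0L)
})

test_that("with no excess the BE3-like condition matches the background", {
  cfg <- sim_config(seed = 16, rna_background_snv_rate = 500,
                    rna_cu_excess = 0, n_rna_cells = 10)
  be3 <- do.call(rbind, simulate_rna_snv_tables(cfg, "BE3-like"))
  cu <- cu_proportion(be3)
  se <- sqrt((2 / 12) * (10 / 12) / nrow(be3))
  expect_lt(abs(cu - 2 / 12), 3 * se)
})

test_that("planted genome truth is consistent with its own sequence", {
  cfg <- sim_config(seed = 17, genome_length = 6000, n_planted_offtargets = 8)
  sim <- simulate_genome_with_offtargets(cfg, "ACTGTCGCGTGATAACCTGG")
  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    span <- substr(g, tr$start + 1, tr$start + 23)
    observed <- if (tr$strand == "+") span else
      mosaicbe:::reverse_complement(span)
    expect_equal(observed, tr$site_seq)
  }
})
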