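test_that("candidate regions pad +/-200 bp and merge overlaps", {
  one <- candidate_regions(make_snv(pos = 1000L))
  # 0-based half-open [799, 1200) == 1-based [800, 1200]
  expect_equal(GenomicRanges::start(one), 800L)
  expect_equal(GenomicRanges::end(one), 1200L)
  two <- candidate_regions(rbind(make_snv(pos = 1000L), make_snv(pos = 1100L)))
  expect_equal(length(two), 1L)
  expect_equal(GenomicRanges::width(two), 501L)
  expect_equal(length(candidate_regions(make_snv()[0, ])), 0L)
})

test_that("consensus requires all three callers and strict AF > 0.10", {
  v1 <- make_snv(pos = 500L, AF = 0.4)
  v2 <- make_snv(pos = 900L, AF = 0.10)   # exactly at the floor
  v3 <- make_snv(pos = 1300L, AF = 0.3)
  all3 <- rbind(v1, v2, v3)
  two_of_three <- rbind(v1, v2)
  regions <- candidate_regions(all3)
  cons <- consensus_variants(list(all3, all3, all3), regions)
  expect_equal(cons$pos, c(500L, 1300L))   # AF == 0.10 excluded
  cons2 <- consensus_variants(list(all3, two_of_three, all3), regions)
  expect_equal(cons2$pos, 500L)            # v3 only in 2 of 3 sets
  expect_error(consensus_variants(list(all3, all3), regions), "three")
})

test_that("missing AF falls back to the minimum reported fraction", {
  a <- make_snv(pos = 100L, AF = 0.5)
  b <- make_snv(pos = 100L, AF = NA)
  c <- make_snv(pos = 100L, AF = 0.2)
  cons <- consensus_variants(list(a, b, c), regions = NULL)
  expect_equal(cons$AF, 0.2)
  low <- make_snv(pos = 100L, AF = 0.05)
  expect_equal(nrow(consensus_variants(list(a, b, low), regions = NULL)), 0L)
})

test_that("de novo calls require absence of the alt allele in both parents", {
  child <- rbind(make_snv(pos = 10L, ref = "G", alt = "A"),
                 make_snv(pos = 20L, ref = "G", alt = "A"),
                 make_snv(pos = 30L, ref = "C", alt = "T"))
  father <- make_snv(pos = 20L, ref = "G", alt = "A")
  mother <- make_snv(pos = 99L)
  dn <- denovo_call(child, father, mother)
  expect_equal(dn$pos, c(10L, 30L))
  expect_equal(denovo_call(child, child[0, ], child[0, ]), child)
})

test_that("repeat and known-site exclusion respects coordinate conventions", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t150", bed)  # 0-based half-open: 1-based 100..150
  inside <- make_snv(pos = 100L)
  outside <- make_snv(pos = 99L)
  kept <- exclude_regions(rbind(inside, outside), repeat_bed = bed)
  expect_equal(kept$pos, 99L)
  expect_equal(exclude_regions(rbind(inside, outside)),
               rbind(inside, outside))
  known <- make_snv(pos = 99L)
  expect_equal(nrow(exclude_regions(kept, known_sites = known)), 0L)
})

test_that("malformed BED lines raise an error naming the line", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\tx"), bed)
  expect_error(exclude_regions(make_snv(pos = 5L), repeat_bed = bed), "line 2")
})

test_that("the SNV spectrum covers the 12 types and pools C·G-to-T·A", {
  all_ct <- do.call(rbind, lapply(1:4, function(i) make_snv(pos = i)))
  sp <- snv_spectrum(all_ct)
  expect_equal(sp$cg_ta_share, 1.0)
  one <- snv_spectrum(make_snv(ref = "A", alt = "G"))
  expect_equal(sum(one$spectrum$proportion == 1), 1L)
  expect_equal(sum(one$spectrum$proportion), 1)
  indel <- make_snv(ref = "AT", alt = "A")
  sp2 <- snv_spectrum(indel)
  expect_equal(sp2$n_indel, 1L)
  expect_true(is.na(sp2$cg_ta_share))
})

test_that("perfect simulated callers give exact set-algebra recovery", {
  cfg <- sim_config(seed = 11, caller_sensitivity = 1, caller_fpr = 0,
                    n_denovo = 40L, n_inherited = 60L, af_range = c(0.2, 0.6))
  cs <- simulate_wgs_callsets(cfg)
  dn <- denovo_pipeline(cs$child, cs$father, cs$mother)
  expect_setequal(mosaicbe:::variant_key(dn), mosaicbe:::variant_key(cs$truth))
})

test_that("a dead caller empties the consensus", {
  cfg <- sim_config(seed = 12, caller_sensitivity = c(1, 0, 1),
                    caller_fpr = 0, n_denovo = 20L, n_inherited = 20L,
                    af_range = c(0.2, 0.6))
  cs <- simulate_wgs_callsets(cfg)
  dn <- denovo_pipeline(cs$child, cs$father, cs$mother)
  expect_equal(nrow(dn), 0L)
})

test_that("pipeline results obey the set-algebra invariants", {
  cfg <- sim_config(seed = 13, caller_sensitivity = 0.9, caller_fpr = 5,
                    n_denovo = 50L, n_inherited = 50L, af_range = c(0.15, 0.6))
  cs <- simulate_wgs_callsets(cfg)
  regions <- candidate_regions(cs$child[[1]])
  cons <- consensus_variants(cs$child, regions)
  dn <- denovo_call(cons, cs$father, cs$mother)
  keys <- lapply(cs$child, mosaicbe:::variant_key)
  expect_true(all(mosaicbe:::variant_key(cons) %in% Reduce(intersect, keys)))
  expect_true(all(mosaicbe:::variant_key(dn) %in% mosaicbe:::variant_key(cons)))
  # recall never exceeds the weakest caller (here jointly limited)
  recall <- mean(mosaicbe:::variant_key(cs$truth) %in% mosaicbe:::variant_key(dn))
  expect_lte(recall, 0.9 + 1e-9)
})

test_that("consensus recall tracks the product of caller sensitivities", {
  cfg <- sim_config(seed = 14, caller_sensitivity = 0.9, caller_fpr = 0,
                    n_denovo = 400L, n_inherited = 0L, af_range = c(0.2, 0.6))
  cs <- simulate_wgs_callsets(cfg)
  dn <- denovo_pipeline(cs$child, cs$father, cs$mother)
  recall <- nrow(dn) / 400
  p <- 0.9^3
  se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(recall - p), 3 * se)
})
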