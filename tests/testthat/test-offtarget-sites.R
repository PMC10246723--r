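PROTO <- "ACTGTCGCGTGATAACCTGG"

test_that("an exact planted site is found at its coordinate", {
  set.seed(2)
  g <- paste0(random_seq(100), PROTO, "AGG", random_seq(100))
  hits <- find_offtarget_sites(c(chr1 = g), PROTO)
  exact <- hits[hits$mismatch_count == 0, ]
  expect_true(nrow(exact) >= 1)
  expect_true(100L %in% exact$start)  # 0-based
  expect_equal(exact$site_seq[exact$start == 100], paste0(PROTO, "AGG"))
})

test_that("sites beyond the mismatch cap are absent", {
  pc <- strsplit(PROTO, "")[[1]]
  flip <- c(A = "G", C = "A", G = "C", T = "A")
  pc[c(1, 2, 4, 6)] <- flip[pc[c(1, 2, 4, 6)]]  # exactly 4 mismatches
  p4 <- paste(pc, collapse = "")
  set.seed(3)
  g <- paste0(random_seq(50), p4, "TGG", random_seq(50))
  hits3 <- find_offtarget_sites(c(chr1 = g), PROTO, max_mm = 3)
  expect_false(49L %in% hits3$start)
  hits4 <- find_offtarget_sites(c(chr1 = g), PROTO, max_mm = 4)
  expect_true(50L %in% hits4$start)
})

test_that("minus-strand sites are reported in protospacer orientation", {
  site <- paste0(PROTO, "CGG")
  set.seed(4)
  g <- paste0(random_seq(60), mosaicbe:::reverse_complement(site),
              random_seq(60))
  hits <- find_offtarget_sites(c(chr1 = g), PROTO)
  minus <- hits[hits$strand == "-" & hits$mismatch_count == 0, ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$start, 60L)
  expect_equal(minus$site_seq, site)
})

test_that("the scanner equals the exhaustive oracle on planted genomes", {
  cfg <- sim_config(seed = 31, genome_length = 8000L,
                    n_planted_offtargets = 12L)
  sim <- simulate_genome_with_offtargets(cfg, PROTO)
  got <- find_offtarget_sites(sim$genome, PROTO, max_mm = 3)
  oracle <- oracle_offtarget_scan(sim$genome[["chr1"]], PROTO, max_mm = 3)
  expect_equal(got$start, oracle$start)
  expect_equal(got$strand, oracle$strand)
  expect_equal(got$mismatch_count, oracle$mismatch_count)
})

test_that("all planted sites within the cap are recovered against truth", {
  cfg <- sim_config(seed = 32, genome_length = 20000L,
                    n_planted_offtargets = 20L)
  sim <- simulate_genome_with_offtargets(cfg, PROTO)
  got <- find_offtarget_sites(sim$genome, PROTO, max_mm = 3)
  truth3 <- sim$truth[sim$truth$mismatches <= 3, ]
  key <- function(df) paste(df$start, df$strand)
  expect_true(all(key(truth3) %in% key(got)))
  # mismatch counts agree with truth at the planted coordinates
  idx <- match(key(truth3), key(got))
  expect_equal(got$mismatch_count[idx], truth3$mismatches)
  # planted 4-mismatch sites stay out at max_mm = 3
  truth4 <- sim$truth[sim$truth$mismatches == 4, ]
  expect_false(any(key(truth4) %in% key(got)))
})

test_that("scan output is invariant under genome reverse complementation", {
  cfg <- sim_config(seed = 33, genome_length = 5000L,
                    n_planted_offtargets = 8L)
  sim <- simulate_genome_with_offtargets(cfg, PROTO)
  fwd <- find_offtarget_sites(sim$genome, PROTO)
  L <- nchar(sim$genome[["chr1"]])
  rev <- find_offtarget_sites(
    c(chr1 = mosaicbe:::reverse_complement(sim$genome[["chr1"]])), PROTO)
  # a site at 0-based start s on + maps to start L - s - 23 on - and vice versa
  mirror <- data.frame(start = L - fwd$start - 23L,
                       strand = ifelse(fwd$strand == "+", "-", "+"),
                       mismatch_count = fwd$mismatch_count)
  key <- function(df) sort(paste(df$start, df$strand, df$mismatch_count))
  expect_equal(key(rev), key(mirror))
})

test_that("raising the mismatch cap never removes sites", {
  cfg <- sim_config(seed = 34, genome_length = 5000L,
                    n_planted_offtargets = 10L)
  sim <- simulate_genome_with_offtargets(cfg, PROTO)
  key <- function(df) paste(df$start, df$strand)
  h1 <- find_offtarget_sites(sim$genome, PROTO, max_mm = 1)
  h3 <- find_offtarget_sites(sim$genome, PROTO, max_mm = 3)
  expect_true(all(key(h1) %in% key(h3)))
  expect_error(find_offtarget_sites(sim$genome, "ACGT"), "20 nt")
})

test_that("per-site comparisons report missing groups as NA and rank stably", {
  sites <- data.frame(site_id = c("s1", "s2", "s3"))
  inj <- data.frame(site_id = c("s1", "s2"), mutated_reads = c(0, 5),
                    DP = c(100, 50))
  uninj <- data.frame(site_id = c("s1", "s3"), mutated_reads = c(0, 0),
                      DP = c(100, 80))
  cmp <- site_editing_comparison(sites, inj, uninj)
  expect_equal(cmp$rate_injected, c(0, 0.1, NA))
  expect_equal(cmp$rate_uninjected, c(0, NA, 0))
  expect_equal(cmp$rate_diff, c(0, NA, NA))
  empty <- site_editing_comparison(sites[0, , drop = FALSE], inj, uninj)
  expect_equal(nrow(empty), 0L)
})
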