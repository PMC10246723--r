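#' Simulation configuration for a mosaic-embryo cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode the
#' study conditions the pipeline is exercised under: 8-cell embryos with 6 of
#' 8 blastomeres injected, diploid (2PN) or triploid (3PN) zygotes, a
#' per-allele targeted C-to-T conversion probability of 0.6 (the observed
#' allelic conversion scale at the APOE locus), small bystander (0.02) and
#' indel (0.01) probabilities, amplicon depth 100 at a 0.3% per-base
#' substitution error rate, a background of 100 transcriptome SNVs per cell
#' with a 10x C·G-to-U·A excess for the BE3-like editor, and three imperfect
#' variant callers (sensitivity 0.95, ~10 false calls each) around 50 planted
#' de novo SNVs.
#'
#' @param seed master integer seed; identical configs reproduce byte-identical
#'   outputs.
#' @param n_embryos number of embryos.
#' @param ploidy 2 (2PN) or 3 (3PN).
#' @param parental_haplotypes `NULL` (cohort mixture mirroring the study:
#'   for 2PN half e3/e3, 40% e3/e4, 10% e4/e4; for 3PN 70% e3-only, 30%
#'   carrying one e4) or a list of per-embryo label vectors of length
#'   `ploidy`.
#' @param injected_blastomeres how many of the 8 blastomeres are injected
#'   (default 6).
#' @param p_convert probability that a target C on one allele copy is
#'   converted C-to-T.
#' @param p_bystander per-allele probability of a nontargeted substitution
#'   within the quantification window.
#' @param p_indel per-allele indel probability.
#' @param read_depth amplicon reads per blastomere.
#' @param seq_error per-base substitution error rate (in `[0, 0.5)`).
#' @param rna_background_snv_rate expected background SNVs per cell
#'   (Poisson mean).
#' @param rna_cu_excess multiplicative C·G-to-U·A excess of a BE3-like
#'   editor: the expected count of extra C-to-T/G-to-A SNVs is
#'   `rna_cu_excess * rna_background_snv_rate`.
#' @param n_rna_cells cells per RNA condition.
#' @param caller_sensitivity per-caller detection probability (length 3,
#'   recycled).
#' @param caller_fpr expected caller-specific false-positive calls per caller.
#' @param n_denovo planted de novo SNVs.
#' @param n_inherited inherited (parental) variants shared with the child.
#' @param af_range range the simulated allele fractions are drawn from
#'   (uniform); the default straddles the 10% consensus floor.
#' @param genome_length length (nt) of the synthetic genome.
#' @param n_planted_offtargets planted off-target sites (0-4 mismatches).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_embryos = 10L,
                       ploidy = 2L,
                       parental_haplotypes = NULL,
                       injected_blastomeres = 6L,
                       p_convert = 0.6,
                       p_bystander = 0.02,
                       p_indel = 0.01,
                       read_depth = 100L,
                       seq_error = 0.003,
                       rna_background_snv_rate = 100,
                       rna_cu_excess = 10,
                       n_rna_cells = 8L,
                       caller_sensitivity = c(0.95, 0.95, 0.95),
                       caller_fpr = 10,
                       n_denovo = 50L,
                       n_inherited = 100L,
                       af_range = c(0.02, 0.6),
                       genome_length = 50000L,
                       n_planted_offtargets = 20L) {
  if (!ploidy %in% c(2L, 3L)) stopf("ploidy must be 2 or 3")
  check_prob(p_convert, "p_convert")
  check_prob(p_bystander, "p_bystander")
  check_prob(p_indel, "p_indel")
  check_prob(caller_sensitivity, "caller_sensitivity")
  if (seq_error < 0 || seq_error >= 0.5) stopf("seq_error must lie in [0, 0.5)")
  if (injected_blastomeres < 0 || injected_blastomeres > 8) {
    stopf("injected_blastomeres must lie in 0..8")
  }
  if (read_depth < 1) stopf("read_depth must be >= 1")
  if (n_denovo < 0) stopf("n_denovo must be >= 0")
  if (genome_length <= 23) stopf("genome_length must exceed 23")
  if (!is.null(parental_haplotypes)) {
    if (!is.list(parental_haplotypes) ||
        length(parental_haplotypes) != n_embryos ||
        any(lengths(parental_haplotypes) != ploidy)) {
      stopf("parental_haplotypes must be a list of %d vectors of length %d",
            n_embryos, ploidy)
    }
  }
  caller_sensitivity <- rep_len(caller_sensitivity, 3L)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: %d %dPN embryos, %d/8 injected, ",
                     "p_convert %.2f, p_bystander %.3f, p_indel %.3f, ",
                     "depth %d @ %.2f%% error\n"),
              x$seed, x$n_embryos, ifelse(x$ploidy == 2, 2, 3),
              x$injected_blastomeres, x$p_convert, x$p_bystander, x$p_indel,
              x$read_depth, 100 * x$seq_error))
  invisible(x)
}

# Deterministic per-embryo default: embryo k's parental genotype depends only
# on k (not the cohort size), cycling through a 10-embryo mixture that mirrors
# the study's cohorts (2PN: 5 e3/e3, 4 e3/e4, 1 e4/e4; 3PN: 7 e3-only, 3 with
# one e4 allele).
default_parental_haplotypes <- function(n, ploidy) {
  if (ploidy == 2L) {
    cycle <- c(rep(list(c("e3", "e3")), 5), rep(list(c("e3", "e4")), 4),
               list(c("e4", "e4")))
  } else {
    cycle <- c(rep(list(c("e3", "e3", "e3")), 7),
               rep(list(c("e3", "e3", "e4")), 3))
  }
  cycle[((seq_len(n) - 1L) %% 10L) + 1L]
}
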