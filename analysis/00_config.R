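# Shared configuration for the analysis workflow.
#
# Two cohorts mirror the study arms: 29 triploid (3PN) embryos and 10 diploid
# (2PN) embryos, 8-cell stage, 6 of 8 blastomeres injected, APOE-like
# codon-158 target. Amplicon depth 100 at 0.3% per-base error; targeted
# conversion probability 0.6 with 2% bystander and 1% indel rates.

library(mosaicbe)

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE)

cohort_configs <- list(
  cohort_3pn = sim_config(seed = 301L, n_embryos = 29L, ploidy = 3L,
                          injected_blastomeres = 6L),
  cohort_2pn = sim_config(seed = 302L, n_embryos = 10L, ploidy = 2L,
                          injected_blastomeres = 6L)
)

rna_config <- sim_config(seed = 303L, rna_background_snv_rate = 100,
                         rna_cu_excess = 10, n_rna_cells = 8L)

wgs_config <- sim_config(seed = 304L, caller_sensitivity = 0.95,
                         caller_fpr = 10, n_denovo = 50L, n_inherited = 100L)

scan_config <- sim_config(seed = 305L, genome_length = 50000L,
                          n_planted_offtargets = 20L)
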