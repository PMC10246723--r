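#!/usr/bin/env Rscript
# Stage 1: simulate the mosaic-embryo cohorts and write every pipeline input
# (per-blastomere FASTQ, target spec, blastomere manifest, ground truth).

source(file.path("analysis", "00_config.R"))

for (name in names(cohort_configs)) {
  cfg <- cohort_configs[[name]]
  out <- file.path(RESULTS, name)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cohort <- simulate_embryo_cohort(cfg)
  simulate_cohort_reads(cohort, out_dir = file.path(out, "fastq"))
  write_target_spec(cohort$spec, file.path(out, "target_spec.yaml"))
  write.table(cohort$blastomeres, file.path(out, "blastomeres.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$alleles, file.path(out, "truth_alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  inj <- cohort$alleles[cohort$alleles$injected, ]
  cat(sprintf(
    "%s: %d embryos (%dPN), %d blastomeres, truth conversion %.1f%% of allele copies\n",
    name, cfg$n_embryos, cfg$ploidy, nrow(cohort$blastomeres),
    100 * mean(inj$converted)))
}
cat("inputs written under results/<cohort>/\n")
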