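#!/usr/bin/env Rscript
# Stage 2: align the amplicon reads written by stage 1, call alleles, genotype
# every blastomere ploidy-aware, and summarize editing outcomes per embryo and
# per cohort (genotype tables, allelic-frequency change, editing profile).

source(file.path("analysis", "00_config.R"))

for (name in names(cohort_configs)) {
  out <- file.path(RESULTS, name)
  spec <- read_target_spec(file.path(out, "target_spec.yaml"))
  meta <- read.table(file.path(out, "blastomeres.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

  fq <- list.files(file.path(out, "fastq"), full.names = TRUE)
  ids <- sub("\\.fastq$", "", basename(fq))
  calls <- lapply(seq_along(fq), function(i) {
    call_alleles(read_fastq(fq[i]), spec, blastomere_id = ids[i])
  })
  names(calls) <- ids

  flat <- do.call(rbind, lapply(calls, function(df) {
    df[, setdiff(names(df), "diffs"), drop = FALSE]
  }))
  write.table(flat, file.path(out, "allele_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  prof <- editing_profile(do.call(rbind, calls), spec)
  write.table(prof$by_position, file.path(out, "editing_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  geno <- genotype_cohort(calls, list(blastomeres = meta), spec)
  write.table(geno$genotypes[, setdiff(names(geno$genotypes), "allele_labels")],
              file.path(out, "genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct <- cohort_table(geno$summaries, geno$parental_genotype)
  write.table(ct$by_stratum, file.path(out, "cohort_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  freq <- do.call(rbind, Map(function(s, id) cbind(embryo_id = id,
                                                   s$frequency_table),
                             geno$summaries, names(geno$summaries)))
  write.table(freq, file.path(out, "frequency_change.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  inj <- geno$genotypes[geno$genotypes$injected & !geno$genotypes$excess_alleles, ]
  pooled <- ct$pooled_frequencies
  cat(sprintf("%s: %d/%d injected blastomeres edited (%.1f%%); allelic conversion %.1f%%\n",
              name, sum(inj$edited_copies > 0), nrow(inj),
              100 * mean(inj$edited_copies > 0),
              mean(inj$allelic_efficiency)))
  cat(sprintf("  on-site C-to-T rate %.3f | NTS %.3f | indel %.3f\n",
              prof$onsite_rate, prof$nts_rate, prof$indel_rate))
  cat(sprintf("  post-injection e2 %.1f%% / e3r %.1f%% (pre 0%%)\n",
              pooled$post_pct[pooled$label == "e2"],
              pooled$post_pct[pooled$label == "e3r"]))
}
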