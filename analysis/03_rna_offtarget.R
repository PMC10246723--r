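#!/usr/bin/env Rscript
# Stage 3: deaminase RNA off-target assessment. Simulates single-cell RNA SNV
# call tables for blastomeres injected with GFP only, a YE1-like editor
# (background-level deamination) and a BE3-like editor (strong C·G-to-U·A
# excess), applies the quality filter and background subtraction, and
# summarizes per-condition SNV burdens and C·G-to-U·A proportions.

source(file.path("analysis", "00_config.R"))

out <- file.path(RESULTS, "rna_offtarget")
dir.create(out, showWarnings = FALSE)

conds <- c("GFP-only", "YE1-like", "BE3-like")
tables <- lapply(conds, function(cc) simulate_rna_snv_tables(rna_config, cc))
names(tables) <- conds

# the GFP-only cells of the same embryos act as the un-injected SNP control;
# here a shared inherited-SNP set is emulated by the sites common to all
# GFP-only cells (none are planted, so subtraction is exercised but sparse)
filtered <- lapply(tables, function(cells) lapply(cells, filter_rna_snvs))

summary_tab <- group_comparison(
  unlist(filtered, recursive = FALSE),
  rep(conds, times = vapply(filtered, length, numeric(1)))
)
write.table(summary_tab, file.path(out, "condition_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(summary_tab))) {
  cat(sprintf("%-9s %d cells | SNVs/cell %.1f +/- %.1f | C·G>U·A %.3f\n",
              summary_tab$condition[i], summary_tab$n_cells[i],
              summary_tab$mean_snv[i], summary_tab$se_snv[i],
              summary_tab$mean_cu[i]))
}
cat("A YE1-like editor is indistinguishable from GFP-only background;\n")
cat("the BE3-like editor shows the elevated burden and C-to-U signature.\n")
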