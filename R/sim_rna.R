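SNV_TYPES <- {
  b <- c("A", "C", "G", "T")
  t <- as.vector(t(outer(b, b, paste, sep = ">")))
  t[substr(t, 1, 1) != substr(t, 3, 3)]
}

#' Simulate single-cell RNA SNV call tables
#'
#' Per cell, a Poisson number of background SNVs is drawn with base-change
#' types uniform over the 12 substitution types; GFP-only and YE1-like
#' conditions share this background distribution, while the BE3-like
#' condition adds `rna_cu_excess * rna_background_snv_rate` expected extra
#' SNVs that are exclusively C-to-T or G-to-A (the deaminase signature read
#' off either cDNA strand). Quality annotations (DP, FS, MQ, QD) are drawn to
#' straddle the downstream filter thresholds so the filter is exercised; the
#' excess records use the same distributions, leaving the post-filter
#' C·G-to-U·A proportion at its closed-form expectation
#' `(background/6 + excess) / (background + excess)`.
#'
#' @param config a [sim_config()].
#' @param condition one of `"GFP-only"`, `"YE1-like"`, `"BE3-like"`.
#' @return list of per-cell variant record data frames (names `cell_1`, ...),
#'   in the [write_variant_tsv()] layout.
#' @export
simulate_rna_snv_tables <- function(config, condition = c("GFP-only",
                                                          "YE1-like",
                                                          "BE3-like")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  cond_code <- match(condition, c("GFP-only", "YE1-like", "BE3-like"))
  cells <- vector("list", config$n_rna_cells)
  names(cells) <- sprintf("cell_%d", seq_len(config$n_rna_cells))
  for (ci in seq_len(config$n_rna_cells)) {
    set.seed(derive_seed(config$seed, 303L, cond_code, ci))
    n_bg <- rpois(1L, config$rna_background_snv_rate)
    types <- sample(SNV_TYPES, n_bg, replace = TRUE)
    if (condition == "BE3-like" && config$rna_cu_excess > 0) {
      n_ex <- rpois(1L, config$rna_cu_excess * config$rna_background_snv_rate)
      types <- c(types, sample(c("C>T", "G>A"), n_ex, replace = TRUE))
    }
    n <- length(types)
    if (n == 0) {
      cells[[ci]] <- empty_variant_table()
      next
    }
    dp <- sample(10:60, n, replace = TRUE)
    af <- runif(n, 0.1, 0.9)
    cells[[ci]] <- data.frame(
      chrom = "chrTX",
      pos = sample.int(5000000L, n),
      ref = substr(types, 1, 1),
      alt = substr(types, 3, 3),
      DP = dp,
      AF = round(af, 4),
      FS = round(runif(n, 0, 45), 2),
      MQ = round(runif(n, 10, 60), 2),
      QD = round(runif(n, 0, 6), 2),
      sample = sprintf("%s_cell_%d", condition, ci),
      mutated_reads = rbinom(n, dp, af),
      stringsAsFactors = FALSE
    )
  }
  cells
}
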