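#' Quality-filter RNA SNV records
#'
#' Retains single-cell RNA SNVs with read depth >= 20, Fisher strand value
#' <= 30, RMS mapping quality >= 20 and quality-by-depth >= 2.0 (boundary
#' values pass). Records missing any of the four annotations are rejected and
#' logged per record via `message()`.
#'
#' @param records variant records data frame with columns `DP`, `FS`, `MQ`,
#'   `QD` (see [write_variant_tsv()] for the layout).
#' @param min_dp,max_fs,min_mq,min_qd thresholds (defaults as above).
#' @return the passing subset of `records`.
#' @export
filter_rna_snvs <- function(records, min_dp = 20, max_fs = 30, min_mq = 20,
                            min_qd = 2.0) {
  if (nrow(records) == 0) return(records)
  need <- c("DP", "FS", "MQ", "QD")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stopf("records lack annotation column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  incomplete <- !stats::complete.cases(records[, need])
  if (any(incomplete)) {
    for (i in which(incomplete)) {
      message(sprintf("record %s:%s %s>%s rejected: missing quality annotation",
                      records$chrom[i], records$pos[i], records$ref[i],
                      records$alt[i]))
    }
    records <- records[!incomplete, , drop = FALSE]
  }
  keep <- records$DP >= min_dp & records$FS <= max_fs &
    records$MQ >= min_mq & records$QD >= min_qd
  records[keep, , drop = FALSE]
}

#' Subtract known and control-derived variant sites
#'
#' Removes records whose site identity (chrom, pos, ref, alt) appears in a
#' known-site list (e.g. dbSNP) or among high-confidence variants of
#' un-injected control blastomeres of the same embryo — such variants are
#' treated as inherited SNPs, not editing events. The same position with a
#' different alt allele is retained.
#'
#' @param treated variant records to be filtered.
#' @param known_sites optional data frame with chrom/pos/ref/alt.
#' @param uninjected_control optional data frame of control-blastomere
#'   records (chrom/pos/ref/alt).
#' @return the retained subset of `treated`.
#' @export
subtract_background <- function(treated, known_sites = NULL,
                                uninjected_control = NULL) {
  if (nrow(treated) == 0) return(treated)
  drop_keys <- character()
  if (!is.null(known_sites) && nrow(known_sites) > 0) {
    drop_keys <- c(drop_keys, variant_key(known_sites))
  }
  if (!is.null(uninjected_control) && nrow(uninjected_control) > 0) {
    drop_keys <- c(drop_keys, variant_key(uninjected_control))
  }
  treated[!(variant_key(treated) %in% drop_keys), , drop = FALSE]
}

#' Proportion of C·G to U·A (C-to-T plus G-to-A) SNVs
#'
#' Because cDNA sequencing reads either strand of an mRNA molecule, a
#' deaminated C is observed as C-to-T when the reference shows C and as
#' G-to-A when it shows G; the deaminase signature is therefore counted as
#' the pooled C-to-T + G-to-A share of all SNVs.
#'
#' @param records variant records (SNVs).
#' @return proportion in `[0,1]`; `NA_real_` for empty input (undefined, not
#'   zero).
#' @export
cu_proportion <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  cu <- (records$ref == "C" & records$alt == "T") |
    (records$ref == "G" & records$alt == "A")
  sum(cu) / nrow(records)
}

#' Per-site editing rate
#'
#' Number of mutated reads divided by the sequencing depth at the site.
#'
#' @param mutated_reads,DP numeric vectors (recycled).
#' @return numeric vector of rates; `NA_real_` where depth is zero.
#' @export
editing_rate <- function(mutated_reads, DP) {
  if (any(mutated_reads > DP, na.rm = TRUE)) {
    stopf("mutated_reads must not exceed DP")
  }
  ifelse(DP > 0, mutated_reads / DP, NA_real_)
}

#' log2(RPKM + 1) expression transform
#'
#' Reads per kilobase of transcript per million mapped reads, on the
#' log2(x + 1) scale. Doubling counts and library size together leaves the
#' value unchanged.
#'
#' @param gene_counts read counts per gene.
#' @param gene_lengths_kb transcript lengths in kilobases (> 0).
#' @param library_size_millions mapped reads in millions (> 0).
#' @return numeric vector of log2(RPKM + 1) values.
#' @export
rpkm_log <- function(gene_counts, gene_lengths_kb, library_size_millions) {
  if (any(gene_lengths_kb <= 0)) stopf("gene lengths must be positive")
  if (any(library_size_millions <= 0)) stopf("library size must be positive")
  log2(gene_counts / (gene_lengths_kb * library_size_millions) + 1)
}

#' Per-condition SNV count and C·G-to-U·A summaries
#'
#' Summarizes per-cell off-target SNV burdens by condition (mean +/- SE of
#' SNV counts and of per-cell C·G-to-U·A proportions). No hypothesis test is
#' performed. SE is reported as `NA` for single-cell conditions.
#'
#' @param cell_tables list of per-cell variant record tables.
#' @param condition character vector, one condition label per cell.
#' @return data frame: condition, n_cells, mean_snv, se_snv, mean_cu, se_cu.
#' @export
group_comparison <- function(cell_tables, condition) {
  stopifnot(length(cell_tables) == length(condition))
  if (length(cell_tables) == 0) stopf("at least one cell is required")
  counts <- vapply(cell_tables, nrow, numeric(1))
  cu <- vapply(cell_tables, cu_proportion, numeric(1))
  conds <- unique(condition)
  se <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  do.call(rbind, lapply(conds, function(cc) {
    sel <- condition == cc
    data.frame(condition = cc, n_cells = sum(sel),
               mean_snv = mean(counts[sel]), se_snv = se(counts[sel]),
               mean_cu = mean(cu[sel], na.rm = TRUE),
               se_cu = se(cu[sel][!is.na(cu[sel])]),
               stringsAsFactors = FALSE)
  }))
}
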