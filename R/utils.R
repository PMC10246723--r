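BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed from a master seed
#'
#' A single master seed drives every simulation; per-unit sub-seeds (embryo,
#' blastomere, stage) are derived arithmetically so that unit k is identical
#' regardless of how many other units are simulated in the same run.
#'
#' @param seed master integer seed.
#' @param ... integer indices identifying the unit (embryo, blastomere, ...).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in seq_along(idx)) {
    x <- (x * 48271 + as.double(idx[i]) * 2246822519 + 104729) %% 2147483647
  }
  as.integer(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stopf("'%s' must be a probability in [0, 1]", name)
  }
  invisible(x)
}

# Substitute characters at 1-based positions of a single string.
subst_chars <- function(seq, pos, bases) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- bases
  paste(chars, collapse = "")
}

variant_key <- function(df, with_ref = TRUE) {
  if (with_ref) {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    paste(df$chrom, df$pos, df$alt, sep = ":")
  }
}

empty_variant_table <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), DP = numeric(), AF = numeric(), FS = numeric(),
    MQ = numeric(), QD = numeric(), sample = character(),
    mutated_reads = numeric(), stringsAsFactors = FALSE
  )
}

#' Write a variant table as VCF-like TSV
#'
#' Columns: chrom, pos (1-based), ref, alt, DP, AF, FS, MQ, QD, sample,
#' mutated_reads. The inverse of [read_variant_tsv()].
#'
#' @param df variant records data frame.
#' @param path output file.
#' @export
write_variant_tsv <- function(df, path) {
  cols <- c("chrom", "pos", "ref", "alt", "DP", "AF", "FS", "MQ", "QD",
            "sample", "mutated_reads")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a VCF-like TSV variant table
#' @param path file written by [write_variant_tsv()] (or equivalent columns).
#' @export
read_variant_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
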