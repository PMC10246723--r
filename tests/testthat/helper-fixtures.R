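# Fixture builders shared across tests.

# Small bespoke target spec: 60-nt amplicon, protospacer at 21-40 (PAM 41-43),
# target C at protospacer position 6 (amplicon 26). `codon26` sets amplicon
# bases 26-28 so codon-consequence scenarios can be composed.
make_small_spec <- function(codon26 = "CAA", coding_strand = "+",
                            frame_anchor = 26L, target_positions = 6L) {
  set.seed(99)
  chars <- sample(c("A", "C", "G", "T"), 60, TRUE)
  chars[26:28] <- strsplit(codon26, "")[[1]]
  chars[41:43] <- c("A", "G", "G")
  amp <- paste(chars, collapse = "")
  target_spec(
    amplicon_id = "mini", amplicon_seq = amp, protospacer_start = 21L,
    target_positions = target_positions, frame_anchor = frame_anchor,
    coding_strand = coding_strand
  )
}

# A one-row allele-call table without running the aligner.
make_call <- function(blastomere_id = "b1", classification = "intact",
                      edited = FALSE, fraction = 1, n_reads = 100L,
                      allele_seq = "", signature = "",
                      diffs = data.frame(type = character(), pos = integer(),
                                         len = integer(), ref = character(),
                                         alt = character())) {
  df <- data.frame(
    blastomere_id = blastomere_id, allele_id = "allele_01",
    signature = signature, allele_seq = allele_seq,
    n_reads = as.integer(n_reads), fraction = fraction,
    classification = classification, edited = edited,
    codon_consequence = NA_character_, stringsAsFactors = FALSE
  )
  df$diffs <- list(diffs)
  df
}

# Stack make_call rows.
make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# A genotype-call table with given counts, for printed-count statistics.
make_genotype_rows <- function(n, n_edited, ploidy = 2L, injected = TRUE,
                               efficiency_edited = 50, labels_edited = c("e3r", "e4"),
                               labels_wt = c("e4", "e4")) {
  rows <- lapply(seq_len(n), function(i) {
    edited <- i <= n_edited
    df <- data.frame(
      blastomere_id = sprintf("b%03d", i), ploidy = ploidy,
      n_allele_types = 2L,
      genotype_class = if (edited) "heterozygous" else "homozygous_wt",
      allelic_efficiency = if (edited) efficiency_edited else 0,
      edited_copies = if (edited) 1L else 0L,
      contains_NTS = FALSE, contains_indel = FALSE,
      e4_free = FALSE, excess_alleles = FALSE,
      injected = injected, stringsAsFactors = FALSE
    )
    df$allele_labels <- list(if (edited) labels_edited else labels_wt)
    df
  })
  do.call(rbind, rows)
}

# Variant record builder.
make_snv <- function(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
                     DP = 50, AF = 0.5, FS = 10, MQ = 40, QD = 5,
                     sample = "s1", mutated_reads = 10) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, DP = DP,
             AF = AF, FS = FS, MQ = MQ, QD = QD, sample = sample,
             mutated_reads = mutated_reads, stringsAsFactors = FALSE)
}
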