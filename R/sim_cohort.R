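# Synthetic APOE-like amplicon: 240 nt, protospacer at 161-180 (target C at
# protospacer position 6 = amplicon 166, the first base of codon 158), PAM
# AGG at 181-183, codon 112 at amplicon 28-30, reading frame anchored at 28.
# The reference carries CGC (Arg) at both codons, i.e. the e4 haplotype.
APOE_AMPLICON <- paste0(
  "GATCGCGATCCATACGACAAAACGTATCGCTCATCGAGAACAATCACAAAGCCGCGAGCC",
  "AGTTTTCCCCATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACG",
  "CTTACACTGGCTTCCACCCTGTTGATTTAAAAAAAATCACACTGTCGCGTGATAACCTGG",
  "AGGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGC"
)

#' Built-in APOE-like amplicon target specification
#'
#' A synthetic 240-nt amplicon modelled on the APOE codon-158 editing design:
#' the protospacer holds the first base of codon 158 (C of CGC, Arg) at
#' editing-window position 6, with codon 112 on the same amplicon 138 bp
#' upstream so that epsilon haplotypes can be read from a single allele
#' sequence. A targeted C-to-T at position 6 converts Arg158 to Cys158,
#' mapping e4 to e3r and e3 to e2.
#'
#' @return a [target_spec()] with `apoe_codons` set.
#' @export
apoe_target_spec <- function() {
  target_spec(
    amplicon_id = "APOE_158",
    amplicon_seq = APOE_AMPLICON,
    protospacer_start = 161L,
    protospacer_strand = "+",
    target_positions = 6L,
    pam = "NGG",
    onsite_window = c(5L, 7L),
    frame_anchor = 28L,
    coding_strand = "+",
    apoe_codons = list(c112 = 28L, c158 = 166L)
  )
}

# Allele sequence of a parental haplotype on the APOE-like amplicon.
haplotype_sequence <- function(label, spec) {
  seqs <- spec$amplicon_seq
  cd <- spec$apoe_codons
  set112 <- function(s, base) subst_chars(s, cd$c112, base)
  set158 <- function(s, base) subst_chars(s, cd$c158, base)
  switch(label,
    e2  = set158(set112(seqs, "T"), "T"),
    e3  = set112(seqs, "T"),
    e3r = set158(seqs, "T"),
    e4  = seqs,
    stopf("unknown haplotype label '%s'", label)
  )
}

#' Simulate a mosaic embryo cohort with ground truth
#'
#' Each embryo contributes 8 blastomeres carrying `ploidy` allele copies of
#' the parental haplotypes; the first `injected_blastomeres` blastomeres are
#' injected and their allele copies are edited independently: every target C
#' converts C-to-T with probability `p_convert`, a bystander substitution is
#' placed at a random non-target quantification-window position with
#' probability `p_bystander`, and a 1-3 nt deletion starts at a random window
#' position with probability `p_indel`. Un-injected blastomeres carry only
#' parental alleles. Per-blastomere sub-seeds are derived from the master
#' seed, so embryo k is identical regardless of cohort size.
#'
#' @param config a [sim_config()].
#' @param spec a [target_spec()] (default [apoe_target_spec()]).
#' @return list with `alleles` (one row per allele copy: embryo_id,
#'   blastomere_id, copy, injected, haplotype_pre, haplotype_post, converted,
#'   has_bystander, has_indel, seq), `blastomeres` (per-blastomere table),
#'   `spec`, and `config`. The `alleles` table is the generator's ground
#'   truth (`SimTruth`).
#' @export
simulate_embryo_cohort <- function(config, spec = apoe_target_spec()) {
  stopifnot(inherits(config, "sim_config"))
  haps <- config$parental_haplotypes
  if (is.null(haps)) {
    haps <- default_parental_haplotypes(config$n_embryos, config$ploidy)
  }
  qw <- spec$quantification_window
  target_amp <- proto_to_amplicon(spec, spec$target_positions)
  protected <- unique(c(target_amp,
                        unlist(lapply(spec$apoe_codons, function(p) p:(p + 2L)))))
  window_pos <- qw[1]:qw[2]
  bystander_pos <- setdiff(window_pos, protected)

  rows <- vector("list", config$n_embryos * 8L * config$ploidy)
  r <- 1L
  for (e in seq_len(config$n_embryos)) {
    embryo_id <- sprintf("E%03d", e)
    parental <- haps[[e]]
    parental_seq <- vapply(parental, haplotype_sequence, character(1),
                           spec = spec)
    for (b in 1:8) {
      injected <- b <= config$injected_blastomeres
      set.seed(derive_seed(config$seed, 101L, e, b))
      for (cp in seq_len(config$ploidy)) {
        seq_cp <- parental_seq[cp]
        converted <- FALSE; has_by <- FALSE; has_indel <- FALSE
        if (injected) {
          for (tp in target_amp) {
            if (substr(seq_cp, tp, tp) == "C" && runif(1) < config$p_convert) {
              seq_cp <- subst_chars(seq_cp, tp, "T")
              converted <- TRUE
            }
          }
          if (runif(1) < config$p_bystander) {
            bp <- sample(bystander_pos, 1L)
            old <- substr(seq_cp, bp, bp)
            seq_cp <- subst_chars(seq_cp, bp, sample(setdiff(BASES, old), 1L))
            has_by <- TRUE
          }
          if (runif(1) < config$p_indel) {
            len <- sample(1:3, 1L)
            start <- sample(window_pos[window_pos + len - 1L <= qw[2]], 1L)
            seq_cp <- paste0(substr(seq_cp, 1L, start - 1L),
                             substr(seq_cp, start + len, nchar(seq_cp)))
            has_indel <- TRUE
          }
        }
        hap_post <- if (has_indel) "indel"
          else if (has_by) "NTS"
          else call_apoe_haplotype(
            substr(seq_cp, spec$apoe_codons$c112, spec$apoe_codons$c112 + 2L),
            substr(seq_cp, spec$apoe_codons$c158, spec$apoe_codons$c158 + 2L))
        rows[[r]] <- data.frame(
          embryo_id = embryo_id,
          blastomere_id = sprintf("%s_B%d", embryo_id, b),
          copy = cp, injected = injected,
          haplotype_pre = parental[cp], haplotype_post = hap_post,
          converted = converted, has_bystander = has_by,
          has_indel = has_indel, seq = seq_cp,
          stringsAsFactors = FALSE
        )
        r <- r + 1L
      }
    }
  }
  alleles <- do.call(rbind, rows)
  blastomeres <- unique(alleles[, c("embryo_id", "blastomere_id", "injected")])
  blastomeres$ploidy <- config$ploidy
  rownames(blastomeres) <- NULL
  list(alleles = alleles, blastomeres = blastomeres, spec = spec,
       config = config)
}

#' Simulate amplicon reads for one blastomere
#'
#' Reads are drawn uniformly from the blastomere's allele copies; per-base
#' substitution errors are injected at rate `seq_error` (no indel sequencing
#' error — indels only arise as true editing outcomes). Base qualities encode
#' the error rate on the Sanger (Phred+33) scale. Deterministic under `seed`.
#'
#' @param allele_seqs character vector of allele copy sequences.
#' @param depth number of reads (>= 1).
#' @param seq_error per-base substitution error rate in `[0, 0.5)`.
#' @param seed integer seed.
#' @return data frame with `read_id`, `seq`, `qual`, `source_allele`.
#' @export
simulate_amplicon_reads <- function(allele_seqs, depth, seq_error, seed) {
  if (length(allele_seqs) == 0) stopf("empty allele set")
  if (depth < 1) stopf("depth must be >= 1")
  if (seq_error < 0 || seq_error >= 0.5) stopf("seq_error must lie in [0, 0.5)")
  set.seed(seed)
  q <- if (seq_error <= 0) 40L else min(40L, as.integer(round(-10 * log10(seq_error))))
  qchar <- rawToChar(as.raw(33L + q))
  src <- sample.int(length(allele_seqs), depth, replace = TRUE)
  seqs <- character(depth)
  for (i in seq_len(depth)) {
    s <- allele_seqs[src[i]]
    L <- nchar(s)
    n_err <- rbinom(1L, L, seq_error)
    if (n_err > 0) {
      pos <- sample.int(L, n_err)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
      s <- paste(chars, collapse = "")
    }
    seqs[i] <- s
  }
  data.frame(
    read_id = sprintf("read_%05d", seq_len(depth)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(L) strrep(qchar, L), character(1)),
    source_allele = src,
    stringsAsFactors = FALSE
  )
}

#' Simulate (and optionally write) reads for a whole cohort
#'
#' @param cohort result of [simulate_embryo_cohort()].
#' @param out_dir optional directory; when given, one FASTQ per blastomere is
#'   written (`<blastomere_id>.fastq`) and paths are returned in the result.
#' @return named list of per-blastomere read data frames (names =
#'   blastomere ids), with attribute `paths` when `out_dir` is used.
#' @export
simulate_cohort_reads <- function(cohort, out_dir = NULL) {
  config <- cohort$config
  ids <- cohort$blastomeres$blastomere_id
  out <- vector("list", length(ids))
  names(out) <- ids
  paths <- character(0)
  for (i in seq_along(ids)) {
    sel <- cohort$alleles$blastomere_id == ids[i]
    eb <- which(unique(cohort$alleles$embryo_id) ==
                  cohort$blastomeres$embryo_id[i])
    b <- as.integer(sub(".*_B", "", ids[i]))
    reads <- simulate_amplicon_reads(
      cohort$alleles$seq[sel], config$read_depth, config$seq_error,
      seed = derive_seed(config$seed, 202L, eb, b)
    )
    out[[i]] <- reads
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fp <- file.path(out_dir, paste0(ids[i], ".fastq"))
      write_fastq(reads, fp)
      paths <- c(paths, fp)
    }
  }
  if (!is.null(out_dir)) attr(out, "paths") <- paths
  out
}

#' Write reads as FASTQ (Sanger quality encoding)
#' @param reads data frame from [simulate_amplicon_reads()].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file as a character vector of sequences
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
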