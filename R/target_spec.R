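#' Define an amplicon target specification
#'
#' Anchors a 20-nt protospacer (plus PAM) on an amplicon reference and fixes
#' the windows used for quantification. Protospacer positions are numbered
#' 1 (PAM-distal, 5') to 20 (PAM-proximal), with the PAM immediately 3' at
#' positions 21-23 — the convention under which the canonical CBE editing
#' window is positions 5-7. Reverse-strand protospacers are handled by
#' reverse-complementing the amplicon once at construction, so all coordinates
#' downstream are in protospacer orientation.
#'
#' @param amplicon_id identifier for the amplicon/locus.
#' @param amplicon_seq amplicon reference sequence (ACGT).
#' @param protospacer_start 1-based offset of protospacer position 1 on the
#'   amplicon (in the given orientation).
#' @param protospacer_strand "+" if the protospacer reads off the amplicon as
#'   given, "-" if off its reverse complement.
#' @param target_positions protospacer positions (1-20) holding target Cs.
#' @param pam 3-nt PAM pattern immediately 3' of the protospacer; "N" matches
#'   any base. Default "NGG".
#' @param onsite_window inclusive protospacer position range regarded as the
#'   editing window (default 5-7).
#' @param quantification_window inclusive amplicon interval (protospacer
#'   orientation) within which substitutions/indels are counted; default
#'   protospacer +/- 10 nt.
#' @param frame_anchor optional 1-based offset of a codon first base on the
#'   coding strand (amplicon orientation when `coding_strand` is "+", reverse
#'   complement orientation when "-"), used for codon-consequence calls.
#' @param coding_strand "+" if the coding sequence reads in amplicon
#'   orientation, "-" otherwise (translation uses the reverse complement).
#' @param apoe_codons optional named list with `c112` and `c158`: 1-based
#'   amplicon offsets of the first bases of APOE codons 112 and 158, enabling
#'   epsilon-haplotype labelling of alleles.
#' @return an object of class `target_spec`.
#' @export
target_spec <- function(amplicon_id, amplicon_seq, protospacer_start,
                        protospacer_strand = "+", target_positions,
                        pam = "NGG", onsite_window = c(5L, 7L),
                        quantification_window = NULL, frame_anchor = NULL,
                        coding_strand = "+", apoe_codons = NULL) {
  amplicon_seq <- toupper(amplicon_seq)
  if (!grepl("^[ACGTN]+$", amplicon_seq)) stopf("amplicon_seq must be ACGTN")
  if (!protospacer_strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (identical(protospacer_strand, "-")) {
    n <- nchar(amplicon_seq)
    amplicon_seq <- reverse_complement(amplicon_seq)
    # protospacer_start was given on the minus strand of the original; after
    # reverse complementing it is the same offset counted from the new 5' end.
  }
  n <- nchar(amplicon_seq)
  if (protospacer_start < 1 || protospacer_start + 22 > n) {
    stopf("protospacer + PAM must map within the amplicon")
  }
  if (any(target_positions < 1 | target_positions > 20)) {
    stopf("target_positions must lie in 1..20")
  }
  if (onsite_window[1] < 1 || onsite_window[2] > 20 ||
      onsite_window[1] > onsite_window[2]) {
    stopf("onsite_window must be an increasing range within 1..20")
  }
  pam_obs <- substr(amplicon_seq, protospacer_start + 20, protospacer_start + 22)
  pam_pat <- strsplit(toupper(pam), "")[[1]]
  pam_ok <- all(pam_pat == "N" | pam_pat == strsplit(pam_obs, "")[[1]])
  if (!pam_ok) {
    stopf("amplicon does not carry PAM '%s' 3' of the protospacer (found '%s')",
          pam, pam_obs)
  }
  if (is.null(quantification_window)) {
    quantification_window <- c(max(1L, protospacer_start - 10L),
                               min(n, protospacer_start + 19L + 10L))
  }
  tc <- substring(amplicon_seq, protospacer_start + target_positions - 1,
                  protospacer_start + target_positions - 1)
  if (!all(tc == "C")) {
    stopf("target_positions must hold C on the protospacer strand")
  }
  structure(list(
    amplicon_id = amplicon_id,
    amplicon_seq = amplicon_seq,
    protospacer_start = as.integer(protospacer_start),
    protospacer_strand = protospacer_strand,
    protospacer_len = 20L,
    pam = pam,
    target_positions = as.integer(sort(target_positions)),
    onsite_window = as.integer(onsite_window),
    quantification_window = as.integer(quantification_window),
    frame_anchor = if (is.null(frame_anchor)) NULL else as.integer(frame_anchor),
    coding_strand = coding_strand,
    apoe_codons = apoe_codons,
    # haplotype-defining positions genotyped alongside the window (e.g. APOE
    # codon 112 lies on the same amplicon but outside the editing window)
    genotype_positions = if (is.null(apoe_codons)) integer() else
      sort(unique(unlist(lapply(apoe_codons, function(p) p:(p + 2L)))))
  ), class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %s: %d nt amplicon, protospacer @%d (%s)\n",
              x$amplicon_id, nchar(x$amplicon_seq), x$protospacer_start,
              x$protospacer_strand))
  cat(sprintf("  protospacer: %s | PAM %s\n",
              substr(x$amplicon_seq, x$protospacer_start, x$protospacer_start + 19),
              substr(x$amplicon_seq, x$protospacer_start + 20, x$protospacer_start + 22)))
  cat(sprintf("  target Cs at protospacer positions: %s; editing window %d-%d\n",
              paste(x$target_positions, collapse = ","),
              x$onsite_window[1], x$onsite_window[2]))
  invisible(x)
}

#' Convert protospacer positions to amplicon coordinates
#' @param spec a [target_spec()].
#' @param positions protospacer positions (1-20).
#' @export
proto_to_amplicon <- function(spec, positions) {
  spec$protospacer_start + as.integer(positions) - 1L
}

#' Convert amplicon coordinates to protospacer positions (NA outside 1-20)
#' @param spec a [target_spec()].
#' @param positions 1-based amplicon coordinates.
#' @export
amplicon_to_proto <- function(spec, positions) {
  p <- as.integer(positions) - spec$protospacer_start + 1L
  p[p < 1L | p > 20L] <- NA_integer_
  p
}

#' Read a target specification from YAML
#'
#' The YAML file holds the fields of [target_spec()] (amplicon_id,
#' amplicon_seq, protospacer_start, protospacer_strand, target_positions,
#' pam, onsite_window, quantification_window, frame_anchor, coding_strand,
#' apoe_codons).
#'
#' @param path YAML file.
#' @return a `target_spec`.
#' @export
read_target_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(target_spec, y)
}

#' Write a target specification to YAML
#' @param spec a [target_spec()].
#' @param path output file.
#' @export
write_target_spec <- function(spec, path) {
  y <- unclass(spec)
  y$protospacer_len <- NULL
  y$genotype_positions <- NULL  # derived field, rebuilt by the constructor
  yaml::write_yaml(y, path)
  invisible(path)
}
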