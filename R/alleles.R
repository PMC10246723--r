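#' Collapse aligned reads into allele calls
#'
#' Reads are aligned to the amplicon, restricted to their difference signature
#' inside the quantification window, and collapsed by identical signature.
#' Signatures supported by fewer than `min_reads` reads or less than
#' `min_fraction` of the blastomere's aligned reads are discarded as
#' sequencing noise, and read fractions are renormalized over the retained
#' alleles. Classification follows the category definitions: `intact` (no
#' window differences), `indel` (any indel overlapping the window; dominates),
#' `targeted_substitution` (C-to-T at one or more target positions and no
#' other window differences), `NTS` (any other substitution pattern).
#' Independently of the category, `edited` flags alleles whose copies carry a
#' targeted C-to-T and no indel — an allele with a targeted conversion plus a
#' bystander substitution is categorized NTS but still counts as converted in
#' allelic accounting.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param spec a [target_spec()].
#' @param min_reads minimum supporting reads per allele signature (default 5).
#' @param min_fraction minimum fraction of aligned reads (default 0.10).
#' @param blastomere_id optional identifier carried into the result.
#' @param min_identity alignment identity floor (see [align_read()]).
#' @return data frame of allele calls: `blastomere_id`, `allele_id`,
#'   `signature`, `allele_seq`, `n_reads`, `fraction`, `classification`,
#'   `edited`, `codon_consequence`, plus list-column `diffs`. Attribute
#'   `n_unalignable` counts rejected reads. Zero-row result (with a warning)
#'   when no read aligns.
#' @export
call_alleles <- function(reads, spec, min_reads = 5L, min_fraction = 0.10,
                         blastomere_id = NA_character_, min_identity = 0.6) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (length(reads) < 1) stopf("at least one read is required")
  ref <- spec$amplicon_seq
  qw <- spec$quantification_window

  uniq <- table(reads)
  useq <- names(uniq)
  ucnt <- as.integer(uniq)

  sigs <- character(length(useq))
  diffs_list <- vector("list", length(useq))
  ok <- logical(length(useq))
  for (k in seq_along(useq)) {
    aln <- align_read(useq[k], spec, min_identity = min_identity)
    ok[k] <- aln$accepted
    if (!aln$accepted) next
    wd <- window_diffs(aln$diffs, qw)
    # haplotype-defining substitutions outside the window (APOE codon 112)
    # are genotyped alongside, but never enter the classification
    gp <- setdiff(spec$genotype_positions, qw[1]:qw[2])
    if (length(gp)) {
      hd <- aln$diffs[aln$diffs$type == "sub" & aln$diffs$pos %in% gp, ,
                      drop = FALSE]
      wd <- rbind(wd, hd)
    }
    diffs_list[[k]] <- wd
    sigs[k] <- diff_signature(wd)
  }

  n_unalignable <- sum(ucnt[!ok])
  n_aligned <- sum(ucnt[ok])
  empty <- allele_call_frame(blastomere_id)
  attr(empty, "n_unalignable") <- n_unalignable
  if (n_aligned == 0) {
    warning("no read aligned to the amplicon reference")
    return(empty)
  }

  counts <- tapply(ucnt[ok], sigs[ok], sum)
  sig_levels <- names(counts)
  keep <- counts >= min_reads & counts / n_aligned >= min_fraction
  if (!any(keep)) {
    warning("all allele signatures fell below support thresholds")
    return(empty)
  }
  counts <- counts[keep]
  sig_levels <- sig_levels[keep]
  # deterministic order: descending support, then signature string
  o <- order(-counts, sig_levels)
  counts <- counts[o]
  sig_levels <- sig_levels[o]

  rows <- vector("list", length(sig_levels))
  for (k in seq_along(sig_levels)) {
    wd <- diffs_list[ok][sigs[ok] == sig_levels[k]][[1]]
    seq_k <- apply_diffs(ref, wd)
    cls <- classify_allele(wd, spec)
    rows[[k]] <- data.frame(
      blastomere_id = blastomere_id,
      allele_id = sprintf("allele_%02d", k),
      signature = sig_levels[k],
      allele_seq = seq_k,
      n_reads = as.integer(counts[k]),
      fraction = as.numeric(counts[k]) / sum(counts),
      classification = cls$classification,
      edited = cls$edited,
      codon_consequence = NA_character_,
      stringsAsFactors = FALSE
    )
    rows[[k]]$diffs <- list(wd)
  }
  calls <- do.call(rbind, rows)
  if (!is.null(spec$frame_anchor)) {
    calls$codon_consequence <-
      vapply(seq_len(nrow(calls)),
             function(i) codon_consequence(calls[i, ], spec),
             character(1))
  }
  attr(calls, "n_unalignable") <- n_unalignable
  calls
}

allele_call_frame <- function(blastomere_id = NA_character_) {
  df <- data.frame(
    blastomere_id = character(), allele_id = character(),
    signature = character(), allele_seq = character(),
    n_reads = integer(), fraction = numeric(), classification = character(),
    edited = logical(), codon_consequence = character(),
    stringsAsFactors = FALSE
  )
  df$diffs <- list()
  df
}

# Diffs restricted to the quantification window; an indel is retained when it
# overlaps any window position.
window_diffs <- function(diffs, qw) {
  if (nrow(diffs) == 0) return(diffs)
  span_start <- diffs$pos
  span_end <- ifelse(diffs$type == "del", diffs$pos + diffs$len - 1L, diffs$pos)
  keep <- span_end >= qw[1] & span_start <= qw[2]
  diffs[keep, , drop = FALSE]
}

diff_signature <- function(diffs) {
  if (nrow(diffs) == 0) return("")
  o <- order(diffs$pos, diffs$type, diffs$alt)
  d <- diffs[o, , drop = FALSE]
  paste(sprintf("%s%d:%s>%s", toupper(substr(d$type, 1, 1)), d$pos, d$ref, d$alt),
        collapse = "|")
}

# Reconstruct the allele sequence by applying window diffs to the reference.
apply_diffs <- function(ref, diffs) {
  if (nrow(diffs) == 0) return(ref)
  o <- order(diffs$pos, decreasing = TRUE)
  d <- diffs[o, , drop = FALSE]
  out <- ref
  for (i in seq_len(nrow(d))) {
    if (d$type[i] == "sub") {
      out <- paste0(substr(out, 1, d$pos[i] - 1L), d$alt[i],
                    substr(out, d$pos[i] + 1L, nchar(out)))
    } else if (d$type[i] == "del") {
      out <- paste0(substr(out, 1, d$pos[i] - 1L),
                    substr(out, d$pos[i] + d$len[i], nchar(out)))
    } else {
      out <- paste0(substr(out, 1, d$pos[i]), d$alt[i],
                    substr(out, d$pos[i] + 1L, nchar(out)))
    }
  }
  out
}

classify_allele <- function(wd, spec) {
  # classification considers quantification-window differences only
  wd <- window_diffs(wd, spec$quantification_window)
  target_amp <- proto_to_amplicon(spec, spec$target_positions)
  if (nrow(wd) == 0) {
    return(list(classification = "intact", edited = FALSE))
  }
  has_indel <- any(wd$type %in% c("ins", "del"))
  subs <- wd[wd$type == "sub", , drop = FALSE]
  targeted <- subs$pos %in% target_amp & subs$ref == "C" & subs$alt == "T"
  has_target_ct <- any(targeted)
  if (has_indel) {
    return(list(classification = "indel", edited = FALSE))
  }
  if (has_target_ct && all(targeted)) {
    return(list(classification = "targeted_substitution", edited = TRUE))
  }
  list(classification = "NTS", edited = has_target_ct)
}

#' Codon consequence of an allele's substitutions
#'
#' Translates the codons touched by an allele's window substitutions against
#' the reference, using the reading-frame anchor of the target specification.
#' When `coding_strand` is "-", translation is performed on the reverse
#' complement (this is how an antisense-strand C-to-T yields TGG-to-TGA stop
#' gains on the coding strand). Indel-bearing alleles return "frameshift"
#' (in-frame length changes are not further interpreted).
#'
#' @param allele one row of a [call_alleles()] result (or a list with
#'   `allele_seq` and `diffs`).
#' @param spec a [target_spec()] with `frame_anchor` set.
#' @param frame_anchor optional override of the target specification's anchor (1-based
#'   amplicon offset of a codon first base, in coding orientation).
#' @return one of "none", "synonymous", "missense", "stop_gain", "frameshift".
#' @export
codon_consequence <- function(allele, spec, frame_anchor = NULL) {
  anchor <- if (!is.null(frame_anchor)) frame_anchor else spec$frame_anchor
  if (is.null(anchor)) stopf("no reading-frame anchor available")
  ref <- spec$amplicon_seq
  alt <- allele$allele_seq
  diffs <- if (is.list(allele$diffs) && !is.data.frame(allele$diffs)) {
    allele$diffs[[1]]
  } else {
    allele$diffs
  }
  if (nrow(diffs) == 0) return("none")
  if (any(diffs$type %in% c("ins", "del"))) return("frameshift")

  n <- nchar(ref)
  if (identical(spec$coding_strand, "-")) {
    # anchor is given in coding orientation, i.e. as an offset into the
    # reverse complement of the stored amplicon.
    ref <- reverse_complement(ref)
    alt <- reverse_complement(alt)
    pos <- n - diffs$pos + 1L
  } else {
    pos <- diffs$pos
  }
  if (anchor < 1L || anchor > n) stopf("frame anchor incompatible with amplicon")

  codon_idx <- sort(unique((pos - anchor) %/% 3L))
  codon_idx <- codon_idx[anchor + codon_idx * 3L >= 1L &
                         anchor + codon_idx * 3L + 2L <= n]
  if (length(codon_idx) == 0) return("none")
  starts <- anchor + codon_idx * 3L
  ref_cod <- substring(ref, starts, starts + 2L)
  alt_cod <- substring(alt, starts, starts + 2L)
  changed <- ref_cod != alt_cod
  if (!any(changed)) return("none")
  stops <- c("TAA", "TAG", "TGA")
  if (any(alt_cod[changed] %in% stops & !(ref_cod[changed] %in% stops))) {
    return("stop_gain")
  }
  aa_ref <- translate_codons(ref_cod[changed])
  aa_alt <- translate_codons(alt_cod[changed])
  if (any(aa_ref != aa_alt)) "missense" else "synonymous"
}

GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE

translate_codons <- function(codons) {
  aa <- unname(GENETIC_CODE_TAB[codons])
  aa[is.na(aa)] <- "X"
  aa
}
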