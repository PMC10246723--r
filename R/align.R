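#' Align an amplicon read to its reference
#'
#' Semi-global pairwise alignment with affine gap penalties: the read is
#' aligned end to end while reference overhangs at either end are free.
#' Scoring is match +2, mismatch -3, gap open -8, gap extend -1 (a gap of
#' length L costs 8 + L); ties are broken deterministically, preferring a
#' mismatch over a gap and the leftmost placement. Reads of the same length
#' as the reference with at most 3 mismatches take a gapless fast path: with
#' this scoring a gapped alignment of equal-length sequences must pay at
#' least two gap openings (cost 18) and can recover at most 5 per rescued
#' mismatch, so the gapless alignment is provably optimal there.
#'
#' @param read read sequence (ACGTN).
#' @param spec a [target_spec()] (or a plain reference string).
#' @param min_identity identity floor below which the read is rejected as
#'   unalignable (default 0.6).
#' @return a list with `score`, `aligned_read`, `aligned_ref`, `ref_start`,
#'   `ref_end`, `identity`, `accepted`, and `diffs` (data frame with columns
#'   type ("sub"/"ins"/"del"), pos (1-based reference coordinate), len, ref,
#'   alt). For insertions `pos` is the reference base after which the
#'   insertion occurs.
#' @export
align_read <- function(read, spec, min_identity = 0.6) {
  ref <- if (inherits(spec, "target_spec")) spec$amplicon_seq else toupper(spec)
  read <- toupper(read)
  if (!nzchar(read)) stopf("empty read")
  if (!grepl("^[ACGTN]+$", read)) stopf("read alphabet must be ACGTN")

  if (nchar(read) == nchar(ref)) {
    rb <- charToRaw(read)
    fb <- charToRaw(ref)
    mm <- which(rb != fb)
    if (length(mm) <= 3L) {
      n <- nchar(ref)
      identity <- (n - length(mm)) / n
      accepted <- identity >= min_identity
      diffs <- if (accepted && length(mm)) {
        data.frame(type = "sub", pos = mm, len = 1L,
                   ref = rawToCharVec(fb[mm]), alt = rawToCharVec(rb[mm]),
                   stringsAsFactors = FALSE)
      } else {
        alignment_diffs(NULL)
      }
      return(list(score = 2L * (n - length(mm)) - 3L * length(mm),
                  aligned_read = read, aligned_ref = ref,
                  ref_start = 1L, ref_end = n, identity = identity,
                  accepted = accepted, diffs = diffs))
    }
  }
  aln <- cpp_align_read(read, ref)
  aln$accepted <- aln$identity >= min_identity
  aln$diffs <- if (aln$accepted) alignment_diffs(aln) else alignment_diffs(NULL)
  aln
}

rawToCharVec <- function(r) vapply(r, rawToChar, character(1))

# Extract substitution/indel records from an alignment.
alignment_diffs <- function(aln) {
  empty <- data.frame(type = character(), pos = integer(), len = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (is.null(aln)) return(empty)
  p <- strsplit(aln$aligned_read, "", fixed = TRUE)[[1]]
  r <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  refpos <- aln$ref_start - 1L
  type <- character(); pos <- integer(); len <- integer()
  refs <- character(); alts <- character()
  i <- 1L
  ncol_ <- length(p)
  while (i <= ncol_) {
    if (r[i] != "-" && p[i] != "-") {
      refpos <- refpos + 1L
      if (r[i] != p[i]) {
        type <- c(type, "sub"); pos <- c(pos, refpos); len <- c(len, 1L)
        refs <- c(refs, r[i]); alts <- c(alts, p[i])
      }
      i <- i + 1L
    } else if (r[i] == "-") {
      j <- i
      while (j <= ncol_ && r[j] == "-") j <- j + 1L
      type <- c(type, "ins"); pos <- c(pos, refpos); len <- c(len, j - i)
      refs <- c(refs, ""); alts <- c(alts, paste(p[i:(j - 1L)], collapse = ""))
      i <- j
    } else {
      j <- i
      while (j <= ncol_ && p[j] == "-") j <- j + 1L
      type <- c(type, "del"); pos <- c(pos, refpos + 1L); len <- c(len, j - i)
      refs <- c(refs, paste(r[i:(j - 1L)], collapse = "")); alts <- c(alts, "")
      refpos <- refpos + (j - i)
      i <- j
    }
  }
  if (length(type) == 0) return(empty)
  data.frame(type = type, pos = pos, len = len, ref = refs, alt = alts,
             stringsAsFactors = FALSE)
}
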