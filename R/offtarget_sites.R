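#' Mismatch-limited protospacer off-target scan
#'
#' Scans both strands of a genome for 20-mers within `max_mm` mismatches of
#' the query protospacer that are immediately followed (3', in protospacer
#' orientation) by an NGG-type PAM. `N` in the genome never matches a
#' protospacer base (it counts as a mismatch, and fails a non-N PAM slot),
#' while the PAM's `N` matches any of A/C/G/T. Sites are ranked by ascending
#' mismatch count, then chromosome, position and strand — a deterministic
#' order; ranking beyond the mismatch count is positional by design since no
#' finer criterion is defined for equal-mismatch sites.
#'
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param protospacer 20-nt query (protospacer only, PAM excluded).
#' @param pam PAM pattern (default "NGG"); `N` matches any base.
#' @param max_mm maximum mismatches over the 20-mer (default 3; PAM excluded
#'   from the count).
#' @param limit optional cap on the number of (ranked) sites returned.
#' @return data frame: `chrom`, `start` (0-based start of the 23-nt
#'   protospacer+PAM span on the genome), `strand`, `site_seq` (23 nt in
#'   protospacer orientation), `mismatch_count`.
#' @export
find_offtarget_sites <- function(genome, protospacer, pam = "NGG",
                                 max_mm = 3, limit = NULL) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20) stopf("protospacer must be 20 nt")
  if (nchar(pam) != 3) stopf("PAM pattern must be 3 nt")
  genome <- as_genome_set(genome)

  hits <- list()
  k <- 1L
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    subject <- genome[[ci]]
    len <- length(subject)

    # plus strand: protospacer 20-mer then PAM
    m <- Biostrings::matchPattern(protospacer, subject,
                                  max.mismatch = max_mm, fixed = TRUE)
    for (s in IRanges::start(m)) {
      if (s + 22L > len) next
      site <- as.character(Biostrings::subseq(subject, s, s + 22L))
      if (!pam_matches(substr(site, 21, 23), pam)) next
      mm <- hamming(substr(site, 1, 20), protospacer)
      if (mm > max_mm) next
      hits[[k]] <- data.frame(chrom = chrom, start = s - 1L, strand = "+",
                              site_seq = site, mismatch_count = mm,
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }

    # minus strand: reverse complement of the protospacer, PAM 5' as CCN
    rc <- reverse_complement(protospacer)
    m <- Biostrings::matchPattern(rc, subject, max.mismatch = max_mm,
                                  fixed = TRUE)
    for (s in IRanges::start(m)) {
      if (s - 3L < 1L) next
      span <- as.character(Biostrings::subseq(subject, s - 3L, s + 19L))
      site <- reverse_complement(span)
      if (!pam_matches(substr(site, 21, 23), pam)) next
      mm <- hamming(substr(site, 1, 20), protospacer)
      if (mm > max_mm) next
      hits[[k]] <- data.frame(chrom = chrom, start = s - 4L, strand = "-",
                              site_seq = site, mismatch_count = mm,
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               site_seq = character(), mismatch_count = integer(),
               stringsAsFactors = FALSE)
  o <- order(out$mismatch_count, out$chrom, out$start, out$strand)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(limit) && nrow(out) > limit) out <- out[seq_len(limit), ]
  out
}

as_genome_set <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  if (methods::is(genome, "DNAStringSet")) return(genome)
  stopf("genome must be a FASTA path, character vector, or DNAStringSet")
}

# Hamming distance between equal-length strings; N never matches.
hamming <- function(a, b) {
  av <- charToRaw(a); bv <- charToRaw(b)
  sum(av != bv | av == charToRaw("N")[1])
}

pam_matches <- function(observed, pattern) {
  obs <- strsplit(observed, "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  all(ifelse(pat == "N", obs %in% BASES, obs == pat))
}

#' Per-site editing-rate comparison between sample groups
#'
#' Joins per-site (mutated_reads, depth) measurements for injected and
#' un-injected samples over a site list (from the scanner or an external
#' assay) and reports per-site editing rates and their difference. A site
#' missing in one group is reported with `NA` (missing, not zero).
#'
#' @param sites data frame with a `site_id` column (plus any annotation).
#' @param injected,uninjected data frames with `site_id`, `mutated_reads`,
#'   `DP`.
#' @return `sites` with `rate_injected`, `rate_uninjected`, `rate_diff`.
#' @export
site_editing_comparison <- function(sites, injected, uninjected) {
  if (nrow(sites) == 0) {
    return(cbind(sites, data.frame(rate_injected = numeric(),
                                   rate_uninjected = numeric(),
                                   rate_diff = numeric())))
  }
  rate_of <- function(tab) {
    idx <- match(sites$site_id, tab$site_id)
    r <- rep(NA_real_, nrow(sites))
    found <- !is.na(idx)
    r[found] <- editing_rate(tab$mutated_reads[idx[found]], tab$DP[idx[found]])
    r
  }
  sites$rate_injected <- rate_of(injected)
  sites$rate_uninjected <- rate_of(uninjected)
  sites$rate_diff <- sites$rate_injected - sites$rate_uninjected
  sites
}
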