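#' Per-position C-to-T editing profile
#'
#' Computes, for each protospacer position 1-20 whose reference base is C, the
#' fraction of alleles carrying a C-to-T conversion there, together with
#' aggregate on-site (editing-window) and bystander rates and NTS/indel
#' category frequencies. Alleles are weighted equally (not by read support),
#' so duplicating reads leaves the profile unchanged; `weights` can supply
#' copy numbers for copy-weighted cohort accounting. Indel alleles are
#' excluded from per-position substitution counting (their category is
#' reported separately).
#'
#' @param calls allele calls from [call_alleles()] (rows may span
#'   blastomeres).
#' @param spec a [target_spec()].
#' @param weights optional non-negative per-allele weights (e.g. copy
#'   numbers); default 1 per allele.
#' @return a list with `by_position` (data frame: position, ref_base,
#'   n_c_alleles, n_converted, rate), `onsite_rate`, `bystander_rate`,
#'   `nts_rate`, `indel_rate`, `n_alleles`.
#' @export
editing_profile <- function(calls, spec, weights = NULL) {
  if (nrow(calls) < 1) stopf("at least one allele call is required")
  if (is.null(weights)) weights <- rep(1, nrow(calls))
  stopifnot(length(weights) == nrow(calls), all(weights >= 0))

  proto_pos <- 1:20
  amp_pos <- proto_to_amplicon(spec, proto_pos)
  ref_base <- substring(spec$amplicon_seq, amp_pos, amp_pos)
  is_c <- ref_base == "C"

  non_indel <- calls$classification != "indel"
  w_sub <- weights[non_indel]
  n_c_alleles <- ifelse(is_c, sum(w_sub), 0)

  n_conv <- numeric(20)
  for (i in which(non_indel)) {
    d <- calls$diffs[[i]]
    if (nrow(d) == 0) next
    ct <- d$type == "sub" & d$ref == "C" & d$alt == "T"
    pp <- amplicon_to_proto(spec, d$pos[ct])
    pp <- pp[!is.na(pp)]
    if (length(pp)) n_conv[pp] <- n_conv[pp] + weights[i]
  }
  rate <- ifelse(n_c_alleles > 0, n_conv / n_c_alleles, NA_real_)

  by_position <- data.frame(
    position = proto_pos, ref_base = ref_base,
    n_c_alleles = n_c_alleles, n_converted = ifelse(is_c, n_conv, 0),
    rate = ifelse(is_c, rate, NA_real_)
  )

  ow <- spec$onsite_window
  onsite <- is_c & proto_pos >= ow[1] & proto_pos <= ow[2]
  offsite <- is_c & !onsite
  agg <- function(sel) {
    if (!any(sel) || sum(by_position$n_c_alleles[sel]) == 0) return(NA_real_)
    sum(by_position$n_converted[sel]) / sum(by_position$n_c_alleles[sel])
  }
  fr <- nts_indel_frequency(calls, weights = weights)

  list(by_position = by_position,
       onsite_rate = agg(onsite),
       bystander_rate = agg(offsite),
       nts_rate = fr[["nts_rate"]],
       indel_rate = fr[["indel_rate"]],
       n_alleles = sum(weights))
}

#' NTS and indel category frequencies
#'
#' Fraction of alleles classified as nontargeted substitution (NTS) and as
#' indel; the categories are disjoint (an indel overlapping the window
#' dominates the classification). Weights default to one per allele type
#' (read-duplication invariant); pass copy numbers for copy-weighted rates.
#'
#' @param calls allele calls from [call_alleles()].
#' @param weights optional non-negative per-allele weights.
#' @return named numeric vector `c(nts_rate=, indel_rate=)`.
#' @export
nts_indel_frequency <- function(calls, weights = NULL) {
  if (nrow(calls) < 1) stopf("at least one allele call is required")
  if (is.null(weights)) weights <- rep(1, nrow(calls))
  total <- sum(weights)
  c(nts_rate = sum(weights[calls$classification == "NTS"]) / total,
    indel_rate = sum(weights[calls$classification == "indel"]) / total)
}
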