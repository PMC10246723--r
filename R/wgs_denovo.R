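#' Candidate regions around primary-caller variants
#'
#' One region per primary-caller variant, spanning `pad` bp upstream and
#' downstream of the site (a 1-based variant at pos maps to the 0-based
#' half-open interval `[pos - 1 - pad, pos + pad)`), with overlapping regions
#' merged.
#'
#' @param primary_callset data frame with `chrom` and `pos` (1-based).
#' @param pad flanking width in bp (default 200).
#' @return a `GenomicRanges::GRanges` of merged candidate regions.
#' @export
candidate_regions <- function(primary_callset, pad = 200) {
  if (pad < 0) stopf("pad must be >= 0")
  if (nrow(primary_callset) == 0) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = primary_callset$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, primary_callset$pos - pad),
                              end = primary_callset$pos + pad)
  )
  GenomicRanges::reduce(gr)
}

#' Three-caller consensus variants with allele-fraction floor
#'
#' Retains variants whose (chrom, pos, ref, alt) key is reported by all three
#' callers, that lie inside a candidate region, and whose allele fraction is
#' strictly greater than `min_af` in every caller reporting one (a variant at
#' exactly the floor is excluded; callers with missing AF fall back to the
#' minimum AF reported by the others).
#'
#' @param callsets list of exactly three variant data frames
#'   (chrom/pos/ref/alt/AF).
#' @param regions `GRanges` from [candidate_regions()]; `NULL` skips the
#'   region restriction.
#' @param min_af allele-fraction floor (default 0.10, strict `>`).
#' @return consensus variant data frame with `AF` set to the minimum reported
#'   fraction across callers.
#' @export
consensus_variants <- function(callsets, regions = NULL, min_af = 0.10) {
  if (!is.list(callsets) || length(callsets) != 3) {
    stopf("exactly three call sets are required")
  }
  if (min_af < 0 || min_af > 1) stopf("min_af must lie in [0, 1]")
  keys <- lapply(callsets, variant_key)
  if (any(vapply(keys, anyDuplicated, numeric(1)) > 0)) {
    stopf("duplicate variant keys within a call set")
  }
  common <- Reduce(intersect, keys)
  if (length(common) == 0) return(empty_variant_table())

  base <- callsets[[1]][match(common, keys[[1]]), , drop = FALSE]
  af <- sapply(seq_along(callsets), function(i) {
    callsets[[i]]$AF[match(common, keys[[i]])]
  })
  af <- matrix(af, nrow = length(common))
  min_reported <- apply(af, 1, function(x) {
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  })
  af_ok <- !is.na(min_reported) & min_reported > min_af
  base$AF <- min_reported

  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(base$chrom,
                                 IRanges::IRanges(base$pos, base$pos))
    in_region <- IRanges::overlapsAny(gr, regions)
  } else {
    in_region <- rep(TRUE, nrow(base))
  }
  out <- base[af_ok & in_region, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trio-based de novo determination
#'
#' A consensus variant is de novo when its mutant allele (chrom, pos, alt)
#' appears in neither parent's call set: if the child carries A where both
#' parents carry the reference G, A is de novo; if either parent also carries
#' A, the variant is inherited and dropped.
#'
#' @param consensus consensus variants from [consensus_variants()].
#' @param father_set,mother_set parental call tables (chrom/pos/alt at
#'   minimum).
#' @return the de novo subset of `consensus`.
#' @export
denovo_call <- function(consensus, father_set, mother_set) {
  if (nrow(consensus) == 0) return(consensus)
  parental <- character()
  if (!is.null(father_set) && nrow(father_set) > 0) {
    parental <- c(parental, variant_key(father_set, with_ref = FALSE))
  }
  if (!is.null(mother_set) && nrow(mother_set) > 0) {
    parental <- c(parental, variant_key(mother_set, with_ref = FALSE))
  }
  keep <- !(variant_key(consensus, with_ref = FALSE) %in% parental)
  out <- consensus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants in repeat regions or known databases
#'
#' Drops variants lying inside any interval of a repeat BED (0-based
#' half-open) or matching a known-site key (chrom, pos, ref, alt). Malformed
#' BED lines raise a hard error naming the line number.
#'
#' @param variants variant data frame.
#' @param repeat_bed path to a BED file, or `NULL`.
#' @param known_sites data frame of known sites, or `NULL`.
#' @return the retained subset of `variants`.
#' @export
exclude_regions <- function(variants, repeat_bed = NULL, known_sites = NULL) {
  out <- variants
  if (!is.null(repeat_bed) && nrow(out) > 0) {
    gr_rep <- read_bed_checked(repeat_bed)
    gr_var <- GenomicRanges::GRanges(out$chrom,
                                     IRanges::IRanges(out$pos, out$pos))
    out <- out[!IRanges::overlapsAny(gr_var, gr_rep), , drop = FALSE]
  }
  if (!is.null(known_sites) && nrow(known_sites) > 0 && nrow(out) > 0) {
    out <- out[!(variant_key(out) %in% variant_key(known_sites)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# BED reader with per-line validation (0-based half-open intervals).
read_bed_checked <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed BED line %d in %s: fewer than 3 fields", i, path)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      stopf("malformed BED line %d in %s: bad interval", i, path)
    }
  }
  rtracklayer::import(path, format = "BED")
}

#' 12-type SNV mutation spectrum
#'
#' Proportions of the 12 ordered single-base substitution types among SNVs,
#' and the pooled C·G-to-T·A share (C-to-T plus G-to-A). Indels are ignored
#' but counted.
#'
#' @param variants variant data frame (ref/alt).
#' @return list with `spectrum` (data frame type/count/proportion over the 12
#'   types), `cg_ta_share`, `n_snv`, `n_indel`. Proportions are `NA` when no
#'   SNV is present.
#' @export
snv_spectrum <- function(variants) {
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% BASES & variants$alt %in% BASES &
    variants$ref != variants$alt
  snvs <- variants[is_snv, , drop = FALSE]
  types <- as.vector(t(outer(BASES, BASES, paste, sep = ">")))
  types <- types[substr(types, 1, 1) != substr(types, 3, 3)]
  obs <- paste(snvs$ref, snvs$alt, sep = ">")
  counts <- table(factor(obs, levels = types))
  n <- nrow(snvs)
  prop <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, length(types))
  spectrum <- data.frame(type = types, count = as.integer(counts),
                         proportion = prop, stringsAsFactors = FALSE)
  share <- if (n > 0) {
    spectrum$proportion[spectrum$type == "C>T"] +
      spectrum$proportion[spectrum$type == "G>A"]
  } else NA_real_
  list(spectrum = spectrum, cg_ta_share = share, n_snv = n,
       n_indel = sum(!is_snv))
}

#' On-target efficiency from a bulk allele table
#'
#' Fraction of alleles carrying the targeted substitution in a bulk sample
#' (e.g. an embryo-derived stem-cell line), read-fraction weighted since bulk
#' reads carry no per-cell copy number.
#'
#' @param calls allele calls from [call_alleles()] on the bulk reads.
#' @return on-target efficiency in `[0, 1]`.
#' @export
ontarget_check <- function(calls) {
  if (nrow(calls) == 0) return(NA_real_)
  sum(calls$fraction[calls$edited])
}
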