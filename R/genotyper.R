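#' APOE epsilon haplotype from codon 112/158 states
#'
#' The epsilon haplotypes are defined by the Arg/Cys states at codons 112 and
#' 158: (Cys, Cys) -> e2, (Cys, Arg) -> e3, (Arg, Cys) -> e3r,
#' (Arg, Arg) -> e4, with Arg encoded CGC and Cys encoded TGC. A single
#' C-to-T conversion at codon 158 therefore maps e4 to e3r and e3 to e2.
#' Codons outside {CGC, TGC} yield the label `unclassified:<c112>/<c158>`.
#'
#' @param codon112,codon158 character vectors of codons (recycled).
#' @return character vector of labels in `c("e2","e3","e3r","e4")` or
#'   `unclassified:` labels.
#' @export
call_apoe_haplotype <- function(codon112, codon158) {
  n <- max(length(codon112), length(codon158))
  codon112 <- rep_len(toupper(codon112), n)
  codon158 <- rep_len(toupper(codon158), n)
  res <- character(n)
  for (i in seq_len(n)) {
    a <- codon112[i]; b <- codon158[i]
    res[i] <- if (a == "TGC" && b == "TGC") "e2"
      else if (a == "TGC" && b == "CGC") "e3"
      else if (a == "CGC" && b == "TGC") "e3r"
      else if (a == "CGC" && b == "CGC") "e4"
      else sprintf("unclassified:%s/%s", a, b)
  }
  res
}

#' Ploidy-aware blastomere genotype call
#'
#' Applies the single-blastomere genotyping rule: one observed allele type is
#' regarded as homozygous (0% or 100% allelic editing efficiency by edit
#' status); two observed types are heterozygous with 50% efficiency in
#' diploid (2PN) blastomeres, while in triploid (3PN) blastomeres the edited
#' type is assigned two of the three copies when its read fraction is at
#' least 0.5 (66.7%) and one copy otherwise (33.3%). Three types in a 3PN
#' blastomere get one copy each. More types than the ploidy flags the
#' blastomere as `excess_alleles` (whole-genome-amplification artifact); it
#' is excluded from allelic statistics but retained in reports.
#'
#' @param calls allele calls for one blastomere ([call_alleles()] rows).
#' @param ploidy 2 (2PN) or 3 (3PN).
#' @param edited_read_fraction optional read fraction of the edited allele
#'   type; defaults to the fraction observed in `calls`. Only consulted for
#'   3PN blastomeres with two allele types.
#' @param spec optional [target_spec()]; when it carries `apoe_codons`,
#'   allele labels are epsilon haplotypes (NTS/indel alleles are labelled by
#'   their category), otherwise generic edited/unedited labels are used.
#' @return a one-row data frame: `blastomere_id`, `ploidy`,
#'   `n_allele_types`, `genotype_class`, `allelic_efficiency` (percent, one
#'   decimal), `edited_copies`, `contains_NTS`, `contains_indel`, `e4_free`,
#'   `excess_alleles`, plus list-column `allele_labels` (one label per copy).
#' @export
genotype_blastomere <- function(calls, ploidy, edited_read_fraction = NULL,
                                spec = NULL) {
  if (!ploidy %in% c(2L, 3L)) stopf("ploidy must be 2 or 3")
  if (nrow(calls) < 1) stopf("at least one allele call is required")
  ploidy <- as.integer(ploidy)
  bid <- calls$blastomere_id[1]
  n_types <- nrow(calls)

  base <- data.frame(
    blastomere_id = bid, ploidy = ploidy, n_allele_types = n_types,
    genotype_class = NA_character_, allelic_efficiency = NA_real_,
    edited_copies = NA_integer_,
    contains_NTS = any(calls$classification == "NTS"),
    contains_indel = any(calls$classification == "indel"),
    e4_free = NA, excess_alleles = FALSE, stringsAsFactors = FALSE
  )

  if (n_types > ploidy) {
    base$excess_alleles <- TRUE
    base$allele_labels <- list(character())
    return(base)
  }

  copies <- integer(n_types)
  if (n_types == 1L) {
    copies <- ploidy
  } else if (n_types == ploidy) {
    copies <- rep(1L, n_types)
  } else {
    # ploidy 3, two observed types: the extra copy goes to the edited type
    # when its read fraction reaches 0.5 (ties -> two copies), mirroring the
    # 33.3%/66.7% efficiency classes; with zero or two edited types the
    # majority-fraction type takes the extra copy.
    edited_idx <- which(calls$edited)
    if (length(edited_idx) == 1L) {
      frac <- if (!is.null(edited_read_fraction)) edited_read_fraction
              else calls$fraction[edited_idx]
      copies[] <- 1L
      copies[edited_idx] <- if (frac >= 0.5) 2L else 1L
      copies[-edited_idx] <- 3L - copies[edited_idx]
    } else {
      major <- which.max(calls$fraction)
      copies[] <- 1L
      copies[major] <- 2L
    }
  }

  edited_copies <- sum(copies[calls$edited])
  eff <- round(100 * edited_copies / ploidy, 1)
  gclass <- if (edited_copies == 0L) "homozygous_wt"
    else if (edited_copies == ploidy) "homozygous_edited"
    else "heterozygous"

  labels <- allele_labels(calls, spec)
  label_per_copy <- rep(labels, times = copies)

  base$genotype_class <- gclass
  base$allelic_efficiency <- eff
  base$edited_copies <- as.integer(edited_copies)
  base$e4_free <- !any(label_per_copy == "e4")
  base$allele_labels <- list(label_per_copy)
  base
}

allele_labels <- function(calls, spec = NULL) {
  n <- nrow(calls)
  labels <- character(n)
  for (i in seq_len(n)) {
    cls <- calls$classification[i]
    if (cls %in% c("NTS", "indel")) {
      labels[i] <- cls
    } else if (!is.null(spec) && !is.null(spec$apoe_codons)) {
      c112 <- substr(calls$allele_seq[i], spec$apoe_codons$c112,
                     spec$apoe_codons$c112 + 2L)
      c158 <- substr(calls$allele_seq[i], spec$apoe_codons$c158,
                     spec$apoe_codons$c158 + 2L)
      labels[i] <- call_apoe_haplotype(c112, c158)
    } else {
      labels[i] <- if (calls$edited[i]) "edited" else "unedited"
    }
  }
  labels
}

#' Embryo-level genotype and allele-frequency summary
#'
#' Aggregates one embryo's blastomere genotype calls into: the fraction of
#' injected blastomeres carrying at least one edited allele copy, the allelic
#' conversion rate (mean allelic editing efficiency over injected
#' blastomeres), the e4-free blastomere fraction, and pre-/post-injection
#' allele-frequency tables over the labels e2/e3/e3r/e4 (plus NTS, indel,
#' other), copy-number weighted. Pre-injection frequencies are the parental
#' haplotype frequencies; post-injection frequencies pool the injected
#' blastomeres' allele copies. Excess-allele blastomeres are excluded from
#' allelic statistics.
#'
#' @param genotypes data frame of [genotype_blastomere()] rows for one
#'   embryo, with a logical `injected` column.
#' @param parental_haplotypes character vector of parental allele labels
#'   (length = ploidy), e.g. `c("e3","e4")`.
#' @param embryo_id optional identifier.
#' @return list with `embryo_id`, `n_injected`, `n_edited_blastomeres`,
#'   `pct_blastomeres_edited`, `allelic_conversion_pct`, `e4_free_pct`,
#'   `frequency_table` (data frame label/pre_pct/post_pct), and
#'   `genotype_composition` (table of genotype classes).
#' @export
embryo_summary <- function(genotypes, parental_haplotypes,
                           embryo_id = NA_character_) {
  if (!"injected" %in% names(genotypes)) {
    stopf("genotypes must carry an 'injected' column")
  }
  inj <- genotypes[genotypes$injected & !genotypes$excess_alleles, , drop = FALSE]
  if (nrow(inj) < 1) stopf("at least one injected genotype call is required")

  n_edited <- sum(inj$edited_copies > 0)
  conv <- mean(inj$allelic_efficiency)
  e4_free_pct <- 100 * mean(inj$e4_free)

  label_levels <- c("e2", "e3", "e3r", "e4", "NTS", "indel", "other")
  bucket <- function(labels) {
    x <- ifelse(labels %in% label_levels, labels, "other")
    tab <- table(factor(x, levels = label_levels))
    100 * as.numeric(tab) / sum(tab)
  }
  pre <- bucket(parental_haplotypes)
  post <- bucket(unlist(inj$allele_labels))
  frequency_table <- data.frame(label = label_levels, pre_pct = pre,
                                post_pct = post, stringsAsFactors = FALSE)

  list(
    embryo_id = embryo_id,
    n_injected = nrow(inj),
    n_edited_blastomeres = n_edited,
    pct_blastomeres_edited = round(100 * n_edited / nrow(inj), 1),
    allelic_conversion_pct = round(conv, 1),
    e4_free_pct = round(e4_free_pct, 1),
    frequency_table = frequency_table,
    genotype_composition = table(inj$genotype_class)
  )
}

#' Cohort-level genotype and frequency report
#'
#' Pools embryo summaries, stratified by parental genotype: blastomere counts,
#' edited-blastomere percentage (plain ratio of counts), mean allelic
#' conversion, and pooled post-injection allele frequencies (whose NTS and
#' indel labels carry the copy-weighted NTS/indel rates).
#'
#' @param summaries list of [embryo_summary()] results.
#' @param parental_genotype character vector (one per summary) used for
#'   stratification, e.g. `"e3/e4"`; defaults to a single stratum.
#' @return list with `by_stratum` (data frame) and `pooled_frequencies`
#'   (label/post_pct data frame). Empty input yields zero-row tables.
#' @export
cohort_table <- function(summaries, parental_genotype = NULL) {
  if (length(summaries) == 0) {
    return(list(
      by_stratum = data.frame(parental_genotype = character(),
                              n_embryos = integer(), n_blastomeres = integer(),
                              n_edited = integer(), pct_edited = numeric(),
                              mean_conversion_pct = numeric()),
      pooled_frequencies = data.frame(label = character(), post_pct = numeric())
    ))
  }
  if (is.null(parental_genotype)) parental_genotype <- rep("all", length(summaries))
  strata <- unique(parental_genotype)
  rows <- lapply(strata, function(s) {
    ss <- summaries[parental_genotype == s]
    nb <- sum(vapply(ss, function(x) x$n_injected, numeric(1)))
    ne <- sum(vapply(ss, function(x) x$n_edited_blastomeres, numeric(1)))
    conv <- vapply(ss, function(x) x$allelic_conversion_pct, numeric(1))
    nw <- vapply(ss, function(x) x$n_injected, numeric(1))
    data.frame(parental_genotype = s, n_embryos = length(ss),
               n_blastomeres = nb, n_edited = ne,
               pct_edited = round(100 * ne / nb, 1),
               mean_conversion_pct = round(sum(conv * nw) / sum(nw), 1),
               stringsAsFactors = FALSE)
  })
  freq <- lapply(summaries, function(x) x$frequency_table)
  nw <- vapply(summaries, function(x) x$n_injected, numeric(1))
  post <- Reduce(`+`, Map(function(f, w) f$post_pct * w, freq, nw)) / sum(nw)
  pooled <- data.frame(label = freq[[1]]$label, post_pct = round(post, 2),
                       stringsAsFactors = FALSE)
  list(by_stratum = do.call(rbind, rows), pooled_frequencies = pooled)
}
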