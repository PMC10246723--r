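#' Simulate trio WGS call sets around planted de novo variants
#'
#' Plants `n_denovo` de novo SNVs and `n_inherited` inherited variants on a
#' synthetic genome. Each of three imperfect child callers reports every true
#' child variant with its sensitivity and adds caller-specific false
#' positives; parental call sets hold the inherited variants (each assigned
#' to the father, the mother, or both). Allele fractions are drawn uniformly
#' from `af_range`, so with the default range some planted variants fall
#' below the 10% consensus floor.
#'
#' @param config a [sim_config()].
#' @return list with `child` (named list of three caller data frames:
#'   `strelka`, `lofreq`, `mutect2`; the first is the primary caller used for
#'   candidate regions), `father`, `mother`, and `truth` (the planted de novo
#'   variants).
#' @export
simulate_wgs_callsets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 404L))
  L <- config$genome_length
  n_d <- config$n_denovo
  n_i <- config$n_inherited
  n_fp_mean <- config$caller_fpr

  n_total <- n_d + n_i + 1000L
  pos_pool <- sample.int(max(L, n_total * 2L), n_total)

  mk_variant <- function(pos) {
    if (length(pos) == 0) return(empty_variant_table())
    ref <- sample(BASES, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
    af <- runif(length(pos), config$af_range[1], config$af_range[2])
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               DP = sample(30:120, length(pos), replace = TRUE),
               AF = round(af, 4), FS = NA_real_, MQ = NA_real_, QD = NA_real_,
               sample = "child", mutated_reads = NA_real_,
               stringsAsFactors = FALSE)
  }

  denovo <- mk_variant(sort(pos_pool[seq_len(n_d)]))
  inherited <- mk_variant(sort(pos_pool[n_d + seq_len(n_i)]))
  fp_pool <- pos_pool[n_d + n_i + seq_len(1000L)]

  child_truth <- rbind(denovo, inherited)
  callers <- c("strelka", "lofreq", "mutect2")
  child <- vector("list", 3L)
  names(child) <- callers
  fp_used <- 0L
  for (k in 1:3) {
    detected <- runif(nrow(child_truth)) < config$caller_sensitivity[k]
    cs <- child_truth[detected, , drop = FALSE]
    n_fp <- if (n_fp_mean > 0) rpois(1L, n_fp_mean) else 0L
    if (n_fp > 0) {
      fp <- mk_variant(sort(fp_pool[fp_used + seq_len(n_fp)]))
      fp_used <- fp_used + n_fp
      cs <- rbind(cs, fp)
    }
    if (nrow(cs)) cs$sample <- paste0("child_", callers[k])
    cs <- cs[order(cs$pos), , drop = FALSE]
    rownames(cs) <- NULL
    child[[k]] <- cs
  }

  side <- sample(c("father", "mother", "both"), n_i, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  father <- inherited[side %in% c("father", "both"), , drop = FALSE]
  mother <- inherited[side %in% c("mother", "both"), , drop = FALSE]
  if (nrow(father)) father$sample <- "father"
  if (nrow(mother)) mother$sample <- "mother"
  rownames(father) <- rownames(mother) <- NULL

  list(child = child, father = father, mother = mother, truth = denovo)
}

#' Run the de novo identification pipeline on a set of call tables
#'
#' Convenience wrapper chaining [candidate_regions()] on the primary caller,
#' [consensus_variants()], [denovo_call()] and [exclude_regions()].
#'
#' @param child list of three caller data frames (first = primary).
#' @param father,mother parental call tables.
#' @param repeat_bed,known_sites optional exclusion inputs.
#' @param pad,min_af pipeline thresholds (defaults 200 bp, 0.10).
#' @return de novo variant data frame.
#' @export
denovo_pipeline <- function(child, father, mother, repeat_bed = NULL,
                            known_sites = NULL, pad = 200, min_af = 0.10) {
  regions <- candidate_regions(child[[1]], pad = pad)
  cons <- consensus_variants(child, regions, min_af = min_af)
  dn <- denovo_call(cons, father, mother)
  exclude_regions(dn, repeat_bed = repeat_bed, known_sites = known_sites)
}
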