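#' Run the full simulate-quantify-genotype-offtarget pipeline
#'
#' Executes the stages in order against a run directory: (1) simulate a
#' mosaic-embryo cohort and per-blastomere FASTQ reads; (2) align reads and
#' call alleles; (3) genotype blastomeres, summarize embryos and assemble the
#' cohort/frequency-change tables; (4) simulate and analyse RNA SNV tables
#' for the three injection conditions; (5) run the trio de novo WGS
#' intersection on simulated call sets; (6) scan a simulated genome for
#' off-target sites and compare per-site editing rates. All outputs are
#' deterministic under the config seed; a manifest records the config and its
#' hash, so re-running an identical config reproduces identical tables.
#'
#' @param config a [sim_config()].
#' @param out_dir run directory (created if needed).
#' @param spec target specification (default [apoe_target_spec()]).
#' @param stages character subset of
#'   `c("simulate","quantify","genotype","rna","wgs","offtargets")`.
#' @return (invisibly) a list with the main in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         spec = apoe_target_spec(),
                         stages = c("simulate", "quantify", "genotype",
                                    "rna", "wgs", "offtargets")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = out_dir)

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "mosaicbe",
    version = as.character(utils::packageVersion("mosaicbe")),
    config_hash = unname(tools::md5sum(cfg_json)),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  cohort <- NULL
  reads <- NULL
  if ("simulate" %in% stages) {
    cohort <- simulate_embryo_cohort(config, spec)
    reads <- simulate_cohort_reads(cohort, out_dir = file.path(out_dir, "fastq"))
    write_target_spec(spec, file.path(out_dir, "target_spec.yaml"))
    write.table(cohort$alleles, file.path(out_dir, "truth_alleles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(embryos = lapply(split(cohort$blastomeres,
                                  cohort$blastomeres$embryo_id),
                            function(df) list(
                              embryo_id = df$embryo_id[1],
                              ploidy = config$ploidy,
                              injected = df$blastomere_id[df$injected]
                            ))),
      file.path(out_dir, "manifest_embryos.yaml"))
    res$cohort <- cohort
  }

  calls_all <- NULL
  if ("quantify" %in% stages) {
    if (is.null(reads)) stopf("quantify stage requires the simulate stage")
    calls_all <- lapply(names(reads), function(bid) {
      call_alleles(reads[[bid]]$seq, spec, blastomere_id = bid)
    })
    names(calls_all) <- names(reads)
    flat <- do.call(rbind, lapply(calls_all, function(df) {
      df$signature <- ifelse(df$signature == "", "ref", df$signature)
      df[, setdiff(names(df), "diffs"), drop = FALSE]
    }))
    write.table(flat, file.path(out_dir, "allele_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prof <- editing_profile(do.call(rbind, calls_all), spec)
    write.table(prof$by_position, file.path(out_dir, "editing_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$calls <- calls_all
    res$profile <- prof
  }

  if ("genotype" %in% stages) {
    if (is.null(calls_all)) stopf("genotype stage requires the quantify stage")
    geno <- genotype_cohort(calls_all, cohort, spec)
    summaries <- geno$summaries
    write.table(geno$genotypes[, setdiff(names(geno$genotypes), "allele_labels")],
                file.path(out_dir, "genotypes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    freq <- do.call(rbind, Map(function(s, id) {
      cbind(embryo_id = id, s$frequency_table)
    }, summaries, names(summaries)))
    write.table(freq, file.path(out_dir, "frequency_change.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ct <- cohort_table(summaries, geno$parental_genotype)
    write.table(ct$by_stratum, file.path(out_dir, "cohort_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cohort = ct$by_stratum, pooled = ct$pooled_frequencies),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    res$genotypes <- geno
    res$cohort_table <- ct
  }

  if ("rna" %in% stages) {
    conds <- c("GFP-only", "YE1-like", "BE3-like")
    tabs <- lapply(conds, function(cc) simulate_rna_snv_tables(config, cc))
    names(tabs) <- conds
    analysed <- lapply(tabs, function(cells) {
      lapply(cells, function(df) filter_rna_snvs(df))
    })
    gc_tab <- group_comparison(unlist(analysed, recursive = FALSE),
                               rep(conds, times = vapply(analysed, length,
                                                         numeric(1))))
    write.table(gc_tab, file.path(out_dir, "rna_offtarget_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$rna <- gc_tab
  }

  if ("wgs" %in% stages) {
    cs <- simulate_wgs_callsets(config)
    dn <- denovo_pipeline(cs$child, cs$father, cs$mother)
    write_variant_tsv(dn, file.path(out_dir, "denovo_variants.tsv"))
    spect <- snv_spectrum(dn)
    write.table(spect$spectrum, file.path(out_dir, "snv_spectrum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$wgs <- list(denovo = dn, spectrum = spect, truth = cs$truth)
  }

  if ("offtargets" %in% stages) {
    proto <- substr(spec$amplicon_seq, spec$protospacer_start,
                    spec$protospacer_start + 19L)
    g <- simulate_genome_with_offtargets(config, proto)
    write_genome_fasta(g$genome, file.path(out_dir, "genome.fasta"))
    sites <- find_offtarget_sites(g$genome, proto, max_mm = 3)
    sites$site_id <- sprintf("OT%02d", seq_len(nrow(sites)))
    # clean-editor scenario: no off-target editing signal in either group
    mk <- function() data.frame(site_id = sites$site_id, mutated_reads = 0,
                                DP = 1000)
    cmp <- site_editing_comparison(sites, mk(), mk())
    write.table(cmp, file.path(out_dir, "offtarget_sites.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$offtargets <- list(sites = cmp, truth = g$truth)
  }

  invisible(res)
}

#' Genotype every blastomere of a simulated cohort
#'
#' Applies [genotype_blastomere()] per blastomere, derives each embryo's
#' parental genotype from its un-injected blastomeres (majority vote across
#' them; a tie excludes the embryo with a warning), and assembles
#' [embryo_summary()] objects.
#'
#' @param calls_all named list of per-blastomere allele-call tables.
#' @param cohort the [simulate_embryo_cohort()] result (blastomere metadata).
#' @param spec the [target_spec()].
#' @return list with `genotypes` (data frame), `summaries` (named list per
#'   embryo), `parental_genotype` (character per embryo).
#' @export
genotype_cohort <- function(calls_all, cohort, spec) {
  meta <- cohort$blastomeres
  geno <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    calls <- calls_all[[meta$blastomere_id[i]]]
    if (is.null(calls) || nrow(calls) == 0) next
    g <- genotype_blastomere(calls, meta$ploidy[i], spec = spec)
    g$embryo_id <- meta$embryo_id[i]
    g$injected <- meta$injected[i]
    geno[[i]] <- g
  }
  genotypes <- do.call(rbind, geno)

  embryos <- unique(genotypes$embryo_id)
  summaries <- list()
  parental <- character()
  for (eid in embryos) {
    ge <- genotypes[genotypes$embryo_id == eid, , drop = FALSE]
    uninj <- ge[!ge$injected & !ge$excess_alleles, , drop = FALSE]
    if (nrow(uninj) > 0) {
      votes <- vapply(uninj$allele_labels,
                      function(x) paste(sort(x), collapse = "/"), character(1))
      tab <- sort(table(votes), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) {
        warning(sprintf("embryo %s: un-injected blastomeres disagree (tie); excluded",
                        eid))
        next
      }
      par_labels <- strsplit(names(tab)[1], "/", fixed = TRUE)[[1]]
    } else {
      par_labels <- rep("e3", unique(ge$ploidy))
    }
    summaries[[eid]] <- embryo_summary(ge, par_labels, embryo_id = eid)
    parental <- c(parental, paste(sort(unique(par_labels)), collapse = "/"))
  }
  list(genotypes = genotypes, summaries = summaries,
       parental_genotype = parental)
}

#' Render a human-readable report for a completed run
#'
#' Reads the stage outputs of a [run_pipeline()] directory and assembles a
#' deterministic plain-text report (genotype composition, pre/post allele
#' frequencies, editing profile, off-target comparison). Numbers are printed
#' exactly as stored in the stage tables.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path optional output file; default `report.txt` inside `run_dir`.
#' @return (invisibly) the report lines.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  if (!dir.exists(run_dir)) stopf("run directory '%s' does not exist", run_dir)
  manifest_fp <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_fp)) stopf("no manifest.json: incomplete run")
  manifest <- jsonlite::read_json(manifest_fp)
  lines <- c(
    "== mosaicbe run report ==",
    sprintf("package version: %s", manifest$version),
    sprintf("config hash: %s", manifest$config_hash),
    ""
  )
  grab <- function(fp, title) {
    if (!file.exists(fp)) {
      return(c(sprintf("[%s: missing — partial run]", title), ""))
    }
    tab <- readLines(fp)
    c(sprintf("-- %s --", title), tab, "")
  }
  lines <- c(lines,
             grab(file.path(run_dir, "cohort_table.tsv"), "cohort genotype table"),
             grab(file.path(run_dir, "frequency_change.tsv"),
                  "allele frequency change (pre/post)"),
             grab(file.path(run_dir, "editing_profile.tsv"),
                  "per-position editing profile"),
             grab(file.path(run_dir, "rna_offtarget_summary.tsv"),
                  "RNA off-target summary"),
             grab(file.path(run_dir, "snv_spectrum.tsv"), "WGS SNV spectrum"),
             grab(file.path(run_dir, "offtarget_sites.tsv"),
                  "off-target site comparison"))
  writeLines(lines, path)
  invisible(lines)
}
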