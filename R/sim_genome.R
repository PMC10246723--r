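#' Simulate a genome with planted off-target sites
#'
#' Generates a random background genome and plants `n_planted_offtargets`
#' sites carrying 0-4 mismatches to the query protospacer (cycling through
#' the mismatch counts, alternating strands), each followed 3' (in
#' protospacer orientation) by an NGG PAM. Planting collisions (overlap with
#' a previously planted site) are re-drawn and logged via `message()`.
#'
#' @param config a [sim_config()] (`genome_length`, `n_planted_offtargets`,
#'   `seed`).
#' @param protospacer 20-nt query.
#' @return list with `genome` (named character vector, one chromosome
#'   `chr1`) and `truth` (data frame: chrom, start `[0-based start of the
#'   23-nt span]`, strand, mismatches, site_seq).
#' @export
simulate_genome_with_offtargets <- function(config, protospacer) {
  stopifnot(inherits(config, "sim_config"))
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20) stopf("protospacer must be 20 nt")
  set.seed(derive_seed(config$seed, 505L))
  L <- config$genome_length
  chars <- sample(BASES, L, replace = TRUE)

  n <- config$n_planted_offtargets
  occupied <- matrix(numeric(0), ncol = 2)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    mm <- (i - 1L) %% 5L
    strand <- if (i %% 2L == 1L) "+" else "-"
    site20 <- protospacer
    if (mm > 0) {
      pos <- sample.int(20L, mm)
      sc <- strsplit(site20, "")[[1]]
      for (p in pos) sc[p] <- sample(setdiff(BASES, sc[p]), 1L)
      site20 <- paste(sc, collapse = "")
    }
    site23 <- paste0(site20, sample(BASES, 1L), "GG")
    insert <- if (strand == "+") site23 else reverse_complement(site23)

    placed <- FALSE
    for (try in 1:200) {
      start1 <- sample.int(L - 23L - 10L, 1L) + 5L  # 1-based start of 23-nt span
      if (nrow(occupied) == 0 ||
          all(start1 + 22L < occupied[, 1] - 5 | start1 > occupied[, 2] + 5)) {
        chars[start1:(start1 + 22L)] <- strsplit(insert, "")[[1]]
        occupied <- rbind(occupied, c(start1, start1 + 22L))
        truth[[i]] <- data.frame(
          chrom = "chr1", start = start1 - 1L, strand = strand,
          mismatches = mm, site_seq = site23, stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      message(sprintf("planting collision for site %d; re-drawing", i))
    }
    if (!placed) stopf("could not place off-target site %d without collision", i)
  }
  genome <- setNames(paste(chars, collapse = ""), "chr1")
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Write a genome as FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
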