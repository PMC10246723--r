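# Independent oracles used to validate the package implementations.

# Brute-force affine-gap DP, score only, written independently of the package
# aligner: full (m+1) x (n+1) matrices, scalar loops, same scoring contract
# (match +2, mismatch -3, gap of length L costs 8 + L, read end-to-end,
# reference overhangs free, N never matches).
oracle_align_score <- function(read, ref) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd); n <- length(rf)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1) # gap in reference
  Y <- matrix(NEG, m + 1, n + 1) # gap in read
  M[1, ] <- 0
  if (m >= 1) for (i in 2:(m + 1)) X[i, 1] <- -(8 + (i - 1))
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (rd[i - 1] == "N" || rf[j - 1] == "N") -3
           else if (rd[i - 1] == rf[j - 1]) 2 else -3
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - 9, Y[i - 1, j] - 9, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 9, X[i, j - 1] - 9, Y[i, j - 1] - 1)
    }
  }
  max(M[m + 1, ], X[m + 1, ], Y[m + 1, ])
}

# Exhaustive position-by-position off-target scan over both strands, using
# plain character comparisons (independent of Biostrings matching).
oracle_offtarget_scan <- function(genome_seq, proto, max_mm = 3) {
  g <- strsplit(genome_seq, "")[[1]]
  p <- strsplit(proto, "")[[1]]
  rc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  prc <- rev(unname(rc[p]))
  L <- length(g)
  out <- list(); k <- 1L
  for (i in seq_len(L - 22L)) {
    w <- g[i:(i + 19L)]
    # plus strand: 20-mer then PAM at i+20..i+22
    mm <- sum(w != p | w == "N")
    if (mm <= max_mm && g[i + 21L] == "G" && g[i + 22L] == "G" &&
        g[i + 20L] %in% c("A", "C", "G", "T")) {
      out[[k]] <- data.frame(chrom = "chr1", start = i - 1L, strand = "+",
                             mismatch_count = mm, stringsAsFactors = FALSE)
      k <- k + 1L
    }
    # minus strand: revcomp(proto) at i..i+19, CCN PAM at i-3..i-1
    if (i > 3L) {
      mm2 <- sum(w != prc | w == "N")
      if (mm2 <= max_mm && g[i - 3L] == "C" && g[i - 2L] == "C" &&
          g[i - 1L] %in% c("A", "C", "G", "T")) {
        out[[k]] <- data.frame(chrom = "chr1", start = i - 4L, strand = "-",
                               mismatch_count = mm2, stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatch_count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$mismatch_count, res$start, res$strand), ]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
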