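# Independent brute-force oracles. These deliberately share no code with the
# package: the affine-gap DP is a plain three-matrix Gotoh recursion in R,
# the codon counter is a simple 3-mer stepper, and the translator is a
# direct table lookup. A gap of length L costs open + L * ext, matching the
# convention of the package's alignment parameters.

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_nuc_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

oracle_align_score <- function(a, b, mat, open, ext, local = FALSE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in B (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in A (horizontal)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
    for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      diag_best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- if (local) s + max(0, diag_best) else s + diag_best
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_codon_counts <- function(seqs) {
  out <- list()
  for (s in seqs) {
    if (nchar(s) %% 3 != 0) next
    i <- 1
    while (i + 2 <= nchar(s)) {
      cod <- substr(s, i, i + 2)
      if (grepl("^[ACGT]{3}$", cod)) {
        out[[cod]] <- (out[[cod]] %||% 0) + 1
      }
      i <- i + 3
    }
  }
  unlist(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_translate <- function(nt) {
  code <- Biostrings::getGeneticCode("11")
  names(code) <- gsub("U", "T", names(code))
  n <- nchar(nt)
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(code[cods], collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_rbs <- function(upstream, window = c(4, 18), consensus = "AGGAGGT") {
  n <- nchar(upstream)
  best <- c(0L, 0L)
  for (len in 3:nchar(consensus)) {
    for (cs in 1:(nchar(consensus) - len + 1)) {
      pat <- substr(consensus, cs, cs + len - 1)
      for (p in seq_len(max(0, n - len + 1))) {
        if (substr(upstream, p, p + len - 1) == pat) {
          spacer <- n - (p + len - 1)
          if (spacer >= window[1] && spacer <= window[2]) {
            if (len > best[1] || (len == best[1] && spacer < best[2])) {
              best <- c(len, spacer)
            }
          }
        }
      }
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# circular distance between two positions on a genome of length L
circ_dist <- function(a, b, L) {
  d <- abs(a - b)
  min(d, L - d)
}
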