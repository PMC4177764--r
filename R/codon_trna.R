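#' Build a codon usage table from a set of coding sequences
#'
#' Codons are counted in reading frame, including the terminal stop codon;
#' codons containing N (or other ambiguity codes) are skipped, as are
#' sequences whose length is not divisible by 3 (both with logged counts).
#'
#' @param cds_seqs Character vector of in-frame coding sequences.
#' @return list of class `CodonUsageTable`: `counts` (named 64-vector, codons
#'   sorted), `total_codons`, `per_aa_fraction` (named list: per amino acid,
#'   each synonymous codon's share), `per_thousand`, `n_skipped_seqs`,
#'   `n_skipped_codons`.
#' @export
codon_usage <- function(cds_seqs) {
  if (length(cds_seqs) == 0L) stop("no coding sequences supplied")
  cds_seqs <- toupper(chartr("U", "T", unlist(cds_seqs, use.names = FALSE)))
  ok <- nchar(cds_seqs) %% 3L == 0L & nchar(cds_seqs) > 0L
  n_skipped_seqs <- sum(!ok)
  cods <- unlist(lapply(cds_seqs[ok], codons_of), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", cods)
  n_skipped_codons <- sum(!clean)
  cods <- cods[clean]
  if (length(cods) == 0L) stop("no countable codons")

  gc11 <- genetic_code_11()
  counts <- integer(length(gc11))
  names(counts) <- sort(names(gc11))
  tab <- table(cods)
  counts[names(tab)] <- as.integer(tab)
  total <- sum(counts)

  aa_of <- gc11[names(counts)]
  per_aa <- lapply(split(counts, aa_of), function(x) {
    if (sum(x) == 0) x * NA_real_ else x / sum(x)
  })
  structure(list(
    counts = counts, total_codons = total,
    per_aa_fraction = per_aa,
    per_thousand = counts * 1000 / total,
    n_skipped_seqs = n_skipped_seqs, n_skipped_codons = n_skipped_codons
  ), class = "CodonUsageTable")
}

#' @export
print.CodonUsageTable <- function(x, ...) {
  cat(sprintf("CodonUsageTable: %s codons (%d seqs skipped, %d codons skipped)\n",
              format(x$total_codons, big.mark = ","), x$n_skipped_seqs,
              x$n_skipped_codons))
  invisible(x)
}

#' Determine the optimal codon for each amino acid
#'
#' The optimal codon is the most frequently used synonymous codon across the
#' gene set; ties are broken lexicographically. Stop codons are excluded, and
#' amino acids absent from the table are omitted.
#'
#' @param table A `CodonUsageTable`.
#' @return Named character vector, single-letter amino acid -> codon.
#' @export
optimal_codons <- function(table) {
  gc11 <- genetic_code_11()
  aa_of <- gc11[names(table$counts)]
  out <- character(0)
  for (aa in setdiff(sort(unique(aa_of)), "*")) {
    cnt <- table$counts[aa_of == aa]
    if (sum(cnt) == 0L) next
    cnt <- cnt[order(names(cnt))]  # lexicographic tie-break via which.max
    out[aa] <- names(cnt)[which.max(cnt)]
  }
  out
}

#' Decode a tRNA anticodon to the codon(s) it reads
#'
#' Anticodons are written 5'->3'; the Watson-Crick decoded codon is the
#' reverse complement. With `wobble = TRUE` the relaxed third-position
#' pairing is added: a 5' G in the anticodon also reads a codon ending in T,
#' and a 5' U (T) also reads a codon ending in G.
#'
#' @param anticodon 3-mer over A/C/G/T (U accepted).
#' @param wobble Expand wobble pairing at the codon third position.
#' @return Character vector of codons (sorted, unique).
#' @export
decode_anticodon <- function(anticodon, wobble = FALSE) {
  anticodon <- toupper(chartr("U", "T", anticodon))
  if (!grepl("^[ACGT]{3}$", anticodon)) {
    stop(sprintf("invalid anticodon '%s'", anticodon))
  }
  codon <- reverse_complement(anticodon)
  codons <- codon
  if (wobble) {
    first <- substr(anticodon, 1L, 1L)
    stem <- substr(codon, 1L, 2L)
    if (first == "G") codons <- c(codons, paste0(stem, "T"))
    if (first == "T") codons <- c(codons, paste0(stem, "G"))
  }
  sort(unique(codons))
}

#' Relate a phage's tRNA set to its optimal codon usage
#'
#' A tRNA is called optimal-related when its Watson-Crick decoded codon (no
#' wobble) equals the optimal codon for its amino acid. Suppressor/Pyl tRNAs
#' decode stop codons and are never optimal-related but count toward the
#' total. `n_a_ending` counts tRNAs whose decoded codon has A in the third
#' position, a hallmark of low-GC genomes.
#'
#' @param trnas data.frame with columns `locus_tag`, `amino_acid` (3-letter,
#'   or `Sup`/`Pyl`), `anticodon`.
#' @param optimal Named map from [optimal_codons()] on the same genome's CDSs.
#' @return list of class `OptimalityReport`: per-tRNA data.frame (`decoded`,
#'   `optimal_codon`, `is_optimal`), `n_optimal_trnas`, `n_trnas`,
#'   `n_a_ending`, `optimal`.
#' @export
trna_optimality <- function(trnas, optimal) {
  gc11 <- genetic_code_11()
  decoded <- vapply(trnas$anticodon, function(a) decode_anticodon(a)[1], character(1))
  aa1 <- unname(AA3_TO_1[trnas$amino_acid])
  is_stop_decoder <- decoded %in% STOP_CODONS | (!is.na(aa1) & aa1 %in% c("*", "O"))
  opt <- ifelse(is.na(aa1) | is_stop_decoder, NA_character_,
                unname(optimal[aa1]))
  per <- data.frame(
    locus_tag = trnas$locus_tag, amino_acid = trnas$amino_acid,
    anticodon = trnas$anticodon, decoded = unname(decoded),
    optimal_codon = opt,
    is_optimal = !is.na(opt) & decoded == opt,
    stringsAsFactors = FALSE
  )
  structure(list(
    per_trna = per,
    n_optimal_trnas = sum(per$is_optimal),
    n_trnas = nrow(per),
    n_a_ending = sum(substr(per$decoded, 3L, 3L) == "A"),
    optimal = optimal
  ), class = "OptimalityReport")
}

#' @export
print.OptimalityReport <- function(x, ...) {
  cat(sprintf("tRNA optimality: %d of %d tRNAs decode the optimal codon; %d decode A-ending codons\n",
              x$n_optimal_trnas, x$n_trnas, x$n_a_ending))
  invisible(x)
}

#' Codon adaptation index of a gene against a reference usage table
#'
#' Geometric mean of the relative adaptiveness w(codon) =
#' count(codon)/count(best synonymous codon). Stop codons and amino acids
#' with a single codon (Met, Trp) are excluded; w is floored at 0.01 for
#' codons unobserved in the reference.
#'
#' @param gene_cds In-frame coding sequence.
#' @param table Reference `CodonUsageTable`.
#' @return CAI value in (0, 1].
#' @export
cai <- function(gene_cds, table) {
  gene_cds <- toupper(chartr("U", "T", gene_cds))
  if (nchar(gene_cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  gc11 <- genetic_code_11()
  aa_of <- gc11[names(table$counts)]
  # w for every codon
  w <- rep(NA_real_, length(table$counts))
  names(w) <- names(table$counts)
  for (aa in unique(aa_of)) {
    idx <- aa_of == aa
    mx <- max(table$counts[idx])
    w[idx] <- if (mx > 0) table$counts[idx] / mx else NA_real_
  }
  w[!is.na(w) & w == 0] <- 0.01
  single <- names(table(aa_of))[table(aa_of) == 1L]
  scorable <- !(aa_of %in% c("*", single))
  cods <- codons_of(gene_cds)
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  use <- cods[scorable[match(cods, names(w))] & !is.na(w[cods])]
  if (length(use) == 0L) stop("no scorable codons in gene")
  exp(mean(log(w[use])))
}

#' Find homologous tRNA genes between two tRNA sets
#'
#' Pairwise local nucleotide alignment (match +2, mismatch -3, gap open 5,
#' extend 2); pairs above both the query-coverage and identity thresholds are
#' reported, mirroring the "(coverage/identities)" style of phage tRNA
#' comparisons.
#'
#' @param set_a,set_b data.frames with columns `locus_tag` and `sequence`.
#' @param min_coverage Minimum percent of the query inside the aligned region.
#' @param min_identity Minimum percent identity over aligned columns.
#' @return data.frame: `query`, `subject`, `coverage`, `identity`, `score`.
#' @export
compare_trnas <- function(set_a, set_b, min_coverage = 50, min_identity = 70) {
  out <- list()
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      al <- align(set_a$sequence[i], set_b$sequence[j],
                  mode = "local", type = "nucleotide")
      if (al$coverage_query >= min_coverage && al$identity_percent >= min_identity) {
        out[[length(out) + 1L]] <- data.frame(
          query = set_a$locus_tag[i], subject = set_b$locus_tag[j],
          coverage = al$coverage_query, identity = al$identity_percent,
          score = al$score, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(query = character(), subject = character(), coverage = numeric(),
               identity = numeric(), score = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, out)
}
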