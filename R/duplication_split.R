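#' Find candidate lineage-specific gene duplications within one genome
#'
#' All unordered CDS pairs are locally aligned at the protein level; pairs
#' whose Karlin-Altschul E-value passes the (deliberately loose) candidate
#' threshold are emitted, each once, without a verdict. Paralog identities in
#' T4-like phages are low (25-30%), hence the 1e-3 default rather than the
#' stricter cross-genome homolog cut-off.
#'
#' @param record Annotated `GenomeRecord` with >= 2 CDSs (or a list as
#'   returned by [cds_sequences()]).
#' @param max_evalue Candidate E-value threshold.
#' @return data.frame of class `DuplicationCalls`: `gene_a`, `gene_b`,
#'   `aa_identity`, `aa_evalue`, `aa_score`, `verdict` (NA until
#'   [classify_duplication()] is applied), plus nt columns filled in by the
#'   classifier.
#' @export
find_duplications <- function(record, max_evalue = 1e-3) {
  seqs <- if (inherits(record, "GenomeRecord")) cds_sequences(record) else record
  prot <- seqs$protein
  stopifnot(length(prot) >= 2L)
  tags <- names(prot)
  rows <- list()
  for (i in seq_len(length(prot) - 1L)) {
    subj <- prot[(i + 1L):length(prot)]
    hits <- .align_one_vs_many(prot[[i]], subj, type = "protein")
    hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = tags[i], gene_b = hits$subject[k],
        aa_identity = hits$identity_percent[k],
        aa_evalue = hits$evalue[k], aa_score = hits$score[k],
        nt_identity = NA_real_, nt_coverage = NA_real_,
        verdict = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               aa_identity = numeric(), aa_evalue = numeric(),
               aa_score = numeric(), nt_identity = numeric(),
               nt_coverage = numeric(), verdict = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("DuplicationCalls", class(out))
  out
}

#' Classify duplication candidates as duplication vs convergent evolution
#'
#' True lineage-specific duplicates diverge by point mutation and therefore
#' retain significant nucleotide identity; pairs that align well at the
#' protein level but not at the DNA level are better explained by convergent
#' evolution. "Significant nucleotide identity" is operationalised as
#' `nt_min_identity` percent identity over at least `nt_min_coverage` percent
#' of the shorter CDS. The verdicts partition every candidate:
#' `duplication` when the nt profile passes, `convergent` when it fails while
#' the protein E-value is significant (<= 1e-3), `ambiguous` otherwise.
#'
#' @param record The same annotated `GenomeRecord` (nucleotide CDSs are
#'   extracted from it), or a [cds_sequences()] list.
#' @param calls Candidate table from [find_duplications()].
#' @param nt_min_identity,nt_min_coverage The nucleotide significance
#'   profile (percent).
#' @return `calls` with `nt_identity`, `nt_coverage` and `verdict` filled in;
#'   the thresholds used are attached as attributes.
#' @export
classify_duplication <- function(record, calls, nt_min_identity = 65,
                                 nt_min_coverage = 50) {
  seqs <- if (inherits(record, "GenomeRecord")) cds_sequences(record) else record
  nt <- seqs$cds
  for (i in seq_len(nrow(calls))) {
    a <- nt[[calls$gene_a[i]]]; b <- nt[[calls$gene_b[i]]]
    al <- align(a, b, mode = "local", type = "nucleotide")
    shorter <- min(nchar(a), nchar(b))
    aligned <- min(al$q_end - al$q_start, al$s_end - al$s_start) + 1
    calls$nt_identity[i] <- al$identity_percent
    calls$nt_coverage[i] <- 100 * aligned / shorter
    nt_ok <- calls$nt_identity[i] >= nt_min_identity &&
      calls$nt_coverage[i] >= nt_min_coverage
    calls$verdict[i] <- if (nt_ok) "duplication"
      else if (calls$aa_evalue[i] <= 1e-3) "convergent"
      else "ambiguous"
  }
  attr(calls, "nt_min_identity") <- nt_min_identity
  attr(calls, "nt_min_coverage") <- nt_min_coverage
  calls
}

#' Detect split genes: two or more fragments tiling one homolog
#'
#' A gene in the fragment proteome may correspond to only a segment of an
#' intact gene in the target proteome; when two or more fragment genes align
#' to near-disjoint segments of the same target (pairwise overlap at most
#' `max_overlap` of the shorter segment) and together cover at least
#' `min_combined_coverage` of it, a split call is emitted. The canonical
#' geometry is an Alt-like gene of ~680 aa represented by fragments covering
#' roughly residues 1-217 and 409-643.
#'
#' @param target_proteome Named character vector: genomes with the intact
#'   genes.
#' @param fragment_proteome Named character vector: genome suspected to carry
#'   the split fragments.
#' @param max_overlap Maximum pairwise segment overlap, as a fraction of the
#'   shorter segment.
#' @param min_combined_coverage Minimum combined coverage of the target, as
#'   a fraction.
#' @param max_evalue E-value threshold for fragment-to-target hits.
#' @return list of `SplitCall`s; each has `target`, `fragments` (data.frame
#'   ordered by segment start: `fragment`, `t_start`, `t_end`, `identity`),
#'   and `combined_coverage` (percent of the target covered).
#' @export
detect_splits <- function(target_proteome, fragment_proteome,
                          max_overlap = 0.2, min_combined_coverage = 0.5,
                          max_evalue = 1e-3) {
  hits <- find_homologs(fragment_proteome, target_proteome,
                        max_evalue = max_evalue)
  out <- list()
  if (nrow(hits) == 0L) return(out)
  for (tgt in unique(hits$subject)) {
    h <- hits[hits$subject == tgt, , drop = FALSE]
    if (nrow(h) < 2L) next
    h <- h[order(h$s_start), , drop = FALSE]
    # pairwise disjointness on the target
    ok <- TRUE
    for (i in seq_len(nrow(h) - 1L)) {
      for (j in (i + 1L):nrow(h)) {
        ov <- min(h$s_end[i], h$s_end[j]) - max(h$s_start[i], h$s_start[j]) + 1L
        shorter <- min(h$s_end[i] - h$s_start[i], h$s_end[j] - h$s_start[j]) + 1L
        if (ov > max_overlap * shorter) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    tlen <- nchar(target_proteome[[tgt]])
    covered <- interval_union_length(h$s_start, h$s_end)
    if (covered / tlen < min_combined_coverage) next
    out[[length(out) + 1L]] <- structure(list(
      target = tgt,
      fragments = data.frame(
        fragment = h$query, t_start = h$s_start, t_end = h$s_end,
        identity = h$identity_percent, stringsAsFactors = FALSE
      ),
      combined_coverage = 100 * covered / tlen
    ), class = "SplitCall")
  }
  out
}

#' @export
print.SplitCall <- function(x, ...) {
  cat(sprintf("SplitCall: %s tiled by %s (segments %s; combined coverage %.1f%%)\n",
              x$target, paste(x$fragments$fragment, collapse = " + "),
              paste(sprintf("%d-%d", x$fragments$t_start, x$fragments$t_end),
                    collapse = ", "),
              x$combined_coverage))
  invisible(x)
}
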