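#' Pairwise sequence alignment with affine gaps
#'
#' Smith-Waterman (local) or Needleman-Wunsch (global) dynamic programming
#' with affine gap penalties, via Biostrings. Proteins are scored with
#' BLOSUM62 and gap open 11 / extend 1; nucleotides with match +2,
#' mismatch -3, gap open 5 / extend 2 (a gap of length L costs
#' open + L * extend). Identity is computed over aligned columns excluding
#' gaps; coverage is the percent of each sequence inside the aligned region.
#' The Karlin-Altschul expect value for the score is attached (see
#' [evalue()]).
#'
#' @param a,b Residue strings (both protein or both nucleotide).
#' @param mode `"local"` (default) or `"global"`.
#' @param type `"protein"` or `"nucleotide"`; guessed from the alphabet when
#'   missing.
#' @param gap_open,gap_extend Affine gap parameters; defaults depend on
#'   `type`.
#' @return list of class `AlignmentResult`: `score`, `identity_percent`,
#'   `coverage_query`, `coverage_subject`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `mode`, `type`.
#' @export
align <- function(a, b, mode = c("local", "global"), type = NULL,
                  gap_open = NULL, gap_extend = NULL) {
  mode <- match.arg(mode)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  a_nt <- grepl("^[ACGTUN]+$", toupper(a))
  b_nt <- grepl("^[ACGTUN]+$", toupper(b))
  if (a_nt != b_nt) stop("mixed alphabet: one sequence looks nucleotide, the other protein")
  if (is.null(type)) type <- .guess_seq_type(a, b)
  prm <- .align_params(type, gap_open, gap_extend)
  qx <- .as_xstring(a, type)
  sx <- .as_xstring(b, type)
  pa <- Biostrings::pairwiseAlignment(
    pattern = qx, subject = sx, type = mode,
    substitutionMatrix = prm$mat,
    gapOpening = prm$gap_open, gapExtension = prm$gap_extend
  )
  .alignment_result(pa, nchar(a), nchar(b), mode, type)
}

.guess_seq_type <- function(a, b) {
  if (grepl("^[ACGTUN]+$", toupper(a)) && grepl("^[ACGTUN]+$", toupper(b)))
    "nucleotide" else "protein"
}

.align_params <- function(type, gap_open = NULL, gap_extend = NULL) {
  if (type == "protein") {
    mat <- .blosum62()
    list(mat = mat, gap_open = gap_open %||% 11, gap_extend = gap_extend %||% 1)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    list(mat = mat, gap_open = gap_open %||% 5, gap_extend = gap_extend %||% 2)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$mat <- e$BLOSUM62
  }
  .blosum62_cache$mat
}

.as_xstring <- function(s, type) {
  if (type == "protein") Biostrings::AAString(toupper(s))
  else Biostrings::DNAString(toupper(chartr("U", "T", s)))
}

.alignment_result <- function(pa, m, n, mode, type) {
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  qr <- pa@pattern@range
  sr <- pa@subject@range
  q_start <- BiocGenerics::start(qr); q_end <- BiocGenerics::end(qr)
  s_start <- BiocGenerics::start(sr); s_end <- BiocGenerics::end(sr)
  sc <- Biostrings::score(pa)
  structure(list(
    score = sc,
    identity_percent = if (nm + nmm == 0) 0 else 100 * nm / (nm + nmm),
    coverage_query = 100 * (q_end - q_start + 1) / m,
    coverage_subject = 100 * (s_end - s_start + 1) / n,
    q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
    evalue = evalue(max(sc, 0), m, n),
    mode = mode, type = type
  ), class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("%s %s alignment: score %.1f, identity %.1f%%, coverage %.0f/%.0f%%, E = %.3g\n",
              x$mode, x$type, x$score, x$identity_percent,
              x$coverage_query, x$coverage_subject, x$evalue))
  invisible(x)
}

#' Karlin-Altschul expect value
#'
#' E = K * m * n * exp(-lambda * S), the expected number of chance local
#' alignments scoring at least S between sequences of lengths m and n.
#' Defaults are the gapped BLOSUM62 parameters (lambda = 0.267, K = 0.041).
#'
#' @param score Alignment score S (raw substitution-matrix units), >= 0.
#' @param m,n Sequence lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @return The expect value (monotone decreasing in S).
#' @export
evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  stopifnot(score >= 0)
  K * m * n * exp(-lambda * score)
}

# Vectorised local protein alignment of one query against a set of subjects.
# Returns a data.frame with one row per subject. Used by the homolog and
# duplication scanners to avoid per-pair call overhead.
.align_one_vs_many <- function(query, subjects, type = "protein",
                               lambda = 0.267, K = 0.041) {
  prm <- .align_params(type)
  sset <- if (type == "protein") Biostrings::AAStringSet(subjects)
          else Biostrings::DNAStringSet(subjects)
  qx <- .as_xstring(query, type)
  pa <- Biostrings::pairwiseAlignment(
    pattern = sset, subject = qx, type = "local",
    substitutionMatrix = prm$mat,
    gapOpening = prm$gap_open, gapExtension = prm$gap_extend
  )
  nm <- Biostrings::nmatch(pa); nmm <- Biostrings::nmismatch(pa)
  # pattern = subject sequences, subject = query
  pr <- pa@pattern@range
  sr <- pa@subject@range
  sc <- Biostrings::score(pa)
  m <- nchar(query); n <- nchar(subjects)
  data.frame(
    subject = names(subjects) %||% as.character(seq_along(subjects)),
    score = sc,
    evalue = K * m * n * exp(-lambda * pmax(sc, 0)),
    identity_percent = ifelse(nm + nmm == 0, 0, 100 * nm / (nm + nmm)),
    coverage_query = 100 * (BiocGenerics::end(sr) - BiocGenerics::start(sr) + 1) / m,
    coverage_subject = 100 * (BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1) / n,
    q_start = BiocGenerics::start(sr), q_end = BiocGenerics::end(sr),
    s_start = BiocGenerics::start(pr), s_end = BiocGenerics::end(pr),
    stringsAsFactors = FALSE
  )
}
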