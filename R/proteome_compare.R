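#' Find homologs between two proteomes by best-hit local alignment
#'
#' Every query protein is locally aligned against every subject protein; for
#' each query the best subject (smallest Karlin-Altschul E-value) with
#' E <= `max_evalue` is reported. An optional stricter profile on identity
#' and query coverage can be layered on top, e.g. the >= 50% identity /
#' >= 80% coverage profile used when annotating conserved phage genes.
#'
#' @param proteome_a,proteome_b Named character vectors of protein sequences
#'   (query and subject proteomes). When the two are identical, self-pairs
#'   are excluded so a proteome can be scanned against itself.
#' @param max_evalue Homolog E-value cut-off (default 1e-6).
#' @param min_identity,min_coverage Optional stricter thresholds (percent).
#' @param exclude_self NULL (default) excludes same-name pairs only when the
#'   two proteomes are one and the same object; TRUE/FALSE forces the
#'   behaviour (e.g. FALSE when comparing distinct genomes that happen to
#'   share gene names).
#' @return data.frame with one row per query that has a qualifying best hit:
#'   `query`, `subject`, `score`, `evalue`, `identity_percent`,
#'   `coverage_query`, `coverage_subject`, aligned-segment bounds.
#' @export
find_homologs <- function(proteome_a, proteome_b, max_evalue = 1e-6,
                          min_identity = 0, min_coverage = 0,
                          exclude_self = NULL) {
  stopifnot(length(proteome_a) > 0L, length(proteome_b) > 0L)
  if (is.null(names(proteome_a))) names(proteome_a) <- paste0("q", seq_along(proteome_a))
  if (is.null(names(proteome_b))) names(proteome_b) <- paste0("s", seq_along(proteome_b))
  self <- exclude_self %||%
    (identical(unname(proteome_a), unname(proteome_b)) &&
       identical(names(proteome_a), names(proteome_b)))
  rows <- list()
  for (q in names(proteome_a)) {
    subjects <- proteome_b
    if (self) subjects <- subjects[names(subjects) != q]
    if (length(subjects) == 0L) next
    hits <- .align_one_vs_many(proteome_a[[q]], subjects, type = "protein")
    hits <- hits[hits$evalue <= max_evalue &
                 hits$identity_percent >= min_identity &
                 hits$coverage_query >= min_coverage, , drop = FALSE]
    if (nrow(hits) == 0L) next
    best <- hits[order(hits$evalue, -hits$score, hits$subject)[1], , drop = FALSE]
    best <- cbind(query = q, best, stringsAsFactors = FALSE)
    rows[[q]] <- best
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(), subject = character(), score = numeric(),
                      evalue = numeric(), identity_percent = numeric(),
                      coverage_query = numeric(), coverage_subject = numeric(),
                      q_start = integer(), q_end = integer(), s_start = integer(),
                      s_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presence/absence core-genome analysis across phage proteomes
#'
#' Homologs of every reference gene are sought in each other genome with
#' [find_homologs()]; a reference gene is core when it has a qualifying
#' homolog in every other genome. Pairwise shared-homolog counts and per-pair
#' maximum identities are reported for all ordered genome pairs.
#'
#' @param proteomes Named list (>= 2) of named character vectors of proteins.
#' @param reference Name of the reference genome (default: first).
#' @param max_evalue,min_identity,min_coverage Passed to [find_homologs()].
#' @return list of class `CoreGenome`: `presence` (logical matrix, reference
#'   gene x genome), `core` (character vector of core reference genes),
#'   `shared_counts` (matrix, `[i, j]` = queries of genome i with a hit in
#'   genome j), `max_identity` (matrix of per-pair maximum identity percent),
#'   `reference`.
#' @export
core_genome <- function(proteomes, reference = names(proteomes)[1],
                        max_evalue = 1e-6, min_identity = 0, min_coverage = 0) {
  if (length(proteomes) < 2L) stop("need at least 2 genomes")
  stopifnot(!is.null(names(proteomes)), reference %in% names(proteomes))
  gn <- names(proteomes)
  ref <- proteomes[[reference]]
  others <- setdiff(gn, reference)

  presence <- matrix(FALSE, nrow = length(ref), ncol = length(gn),
                     dimnames = list(names(ref), gn))
  presence[, reference] <- TRUE
  shared <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  maxid <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))

  for (i in gn) for (j in gn) {
    if (i == j) next
    ht <- find_homologs(proteomes[[i]], proteomes[[j]], max_evalue = max_evalue,
                        min_identity = min_identity, min_coverage = min_coverage,
                        exclude_self = FALSE)
    shared[i, j] <- nrow(ht)
    maxid[i, j] <- if (nrow(ht)) max(ht$identity_percent) else 0
    if (i == reference) presence[ht$query, j] <- TRUE
  }
  core <- rownames(presence)[rowSums(presence) == length(gn)]
  structure(list(presence = presence, core = core, shared_counts = shared,
                 max_identity = maxid, reference = reference),
            class = "CoreGenome")
}

#' @export
print.CoreGenome <- function(x, ...) {
  cat(sprintf("CoreGenome: %d genomes, reference '%s', core set %d of %d genes\n",
              ncol(x$presence), x$reference, length(x$core), nrow(x$presence)))
  invisible(x)
}

#' Chain homolog pairs into synteny blocks
#'
#' Operates on gene-order indices. Pairs sorted by position in genome A are
#' chained greedily into maximal runs that are strictly monotone in both
#' genomes, skip at most `max_gap` intervening genes on either side, and are
#' strand-consistent (colinear blocks pair like strands, inverted blocks
#' pair opposite strands). Pairs in no block of length >= 2 are reported as
#' relocated.
#'
#' @param pairs data.frame with columns `query`, `subject`, `q_index`,
#'   `s_index` (gene-order indices) and `q_strand`, `s_strand` (`+`/`-`).
#' @param max_gap Maximum number of intervening non-homologous genes.
#' @return list of class `SyntenyResult`: `blocks` (list of data.frames with
#'   an `orientation` attribute, `"colinear"` or `"inverted"`) and
#'   `relocated` (data.frame of unchained pairs).
#' @export
synteny_blocks <- function(pairs, max_gap = 3L) {
  need <- c("query", "subject", "q_index", "s_index", "q_strand", "s_strand")
  stopifnot(all(need %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    return(structure(list(blocks = list(), relocated = pairs),
                     class = "SyntenyResult"))
  }
  pairs <- pairs[order(pairs$q_index), , drop = FALSE]
  same <- pairs$q_strand == pairs$s_strand
  blocks <- list()
  cur <- 1L  # row indices of the current chain
  orient <- NA_character_
  flush <- function(chain, orientation) {
    if (length(chain) >= 2L) {
      blk <- pairs[chain, , drop = FALSE]
      attr(blk, "orientation") <- orientation
      blocks[[length(blocks) + 1L]] <<- blk
      integer(0)
    } else chain
  }
  leftovers <- integer(0)
  for (i in seq_len(nrow(pairs))[-1]) {
    last <- cur[length(cur)]
    dq <- pairs$q_index[i] - pairs$q_index[last]
    ds <- pairs$s_index[i] - pairs$s_index[last]
    step_ok <- dq >= 1L && dq <= max_gap + 1L && abs(ds) <= max_gap + 1L && ds != 0L
    dir_ok <- if (is.na(orient)) TRUE
              else if (orient == "colinear") ds > 0L else ds < 0L
    strand_ok <- if (ds > 0L) same[i] && same[last] else !same[i] && !same[last]
    if (step_ok && dir_ok && strand_ok) {
      if (is.na(orient)) orient <- if (ds > 0L) "colinear" else "inverted"
      cur <- c(cur, i)
    } else {
      leftovers <- c(leftovers, flush(cur, orient))
      cur <- i
      orient <- NA_character_
    }
  }
  leftovers <- c(leftovers, flush(cur, orient))
  structure(list(
    blocks = blocks,
    relocated = pairs[leftovers, , drop = FALSE]
  ), class = "SyntenyResult")
}

#' @export
print.SyntenyResult <- function(x, ...) {
  cat(sprintf("SyntenyResult: %d blocks (%s), %d relocated pairs\n",
              length(x$blocks),
              paste(vapply(x$blocks, function(b)
                sprintf("%d %s", nrow(b), attr(b, "orientation")), character(1)),
                collapse = ", "),
              nrow(x$relocated)))
  invisible(x)
}

#' Build homolog pairs with gene-order indices for synteny analysis
#'
#' Convenience bridge from two annotated records to the input of
#' [synteny_blocks()]: homologs are called between the records' proteomes and
#' annotated with each gene's rank along its genome and strand.
#'
#' @param record_a,record_b Annotated `GenomeRecord`s.
#' @param max_evalue Homolog E-value cut-off.
#' @return data.frame suitable for [synteny_blocks()].
#' @export
homolog_pairs_for_synteny <- function(record_a, record_b, max_evalue = 1e-6) {
  pa <- cds_sequences(record_a)$protein
  pb <- cds_sequences(record_b)$protein
  ht <- find_homologs(pa, pb, max_evalue = max_evalue)
  fa <- record_a$features[record_a$features$kind == "CDS", ]
  fb <- record_b$features[record_b$features$kind == "CDS", ]
  fa <- fa[order(fa$start), ]; fb <- fb[order(fb$start), ]
  ht$q_index <- match(ht$query, fa$locus_tag)
  ht$s_index <- match(ht$subject, fb$locus_tag)
  ht$q_strand <- fa$strand[ht$q_index]
  ht$s_strand <- fb$strand[ht$s_index]
  ht[!is.na(ht$q_index) & !is.na(ht$s_index), , drop = FALSE]
}
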