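#' Scan a genome for candidate open reading frames
#'
#' All six reading frames are scanned; on circular genomes frames wrap the
#' junction. A candidate runs from an initiator codon (ATG/GTG/TTG by
#' default) to the next in-frame stop and is emitted when the encoded product
#' has at least `min_aa` amino acids (the stop codon is part of the ORF but
#' not of the product). Each candidate carries a Shine-Dalgarno score from
#' [score_rbs()]; `scan_orfs` itself never filters on it so start-codon and
#' RBS criteria can be studied independently.
#'
#' @param record A `GenomeRecord`.
#' @param min_aa Minimum product length in amino acids (default 30).
#' @param starts Permitted initiator codons.
#' @param longest_per_stop Keep only the most upstream valid start per stop.
#' @param spacer_window RBS spacer window passed to [score_rbs()].
#' @return data.frame of candidates: `start`, `end`, `strand`, `wraps`,
#'   `start_codon`, `length_aa`, `rbs_score`, `rbs_spacer`.
#' @export
scan_orfs <- function(record, min_aa = 30L,
                      starts = c("ATG", "GTG", "TTG"),
                      longest_per_stop = FALSE,
                      spacer_window = c(4L, 18L)) {
  L <- nchar(record$sequence)
  stopifnot(L >= 3L * (min_aa + 2L))
  circ <- record$topology == "circular"
  out <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") record$sequence else reverse_complement(record$sequence)
    work <- if (circ) paste0(s, s) else s
    cands <- .scan_strand(work, min_aa, starts, max_start = L, max_len = L)
    if (nrow(cands) == 0L) next
    # map working coordinates back to the forward strand of the original circle
    b <- cands$begin; e <- cands$stop_end
    wraps <- circ & e > L
    e_mod <- ifelse(e > L, e - L, e)
    if (str == "+") {
      cands$start <- b; cands$end <- e_mod
    } else {
      # position p on the reverse strand is L - p + 1 on the forward strand
      cands$start <- ifelse(wraps, L - (e - L) + 1L, L - e + 1L)
      cands$end <- L - b + 1L
      # a minus-strand ORF wraps iff its reverse-strand span crossed L
    }
    cands$strand <- str
    cands$wraps <- wraps
    out[[str]] <- cands
  }
  cands <- do.call(rbind, out)
  if (is.null(cands) || nrow(cands) == 0L) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      wraps = logical(), start_codon = character(),
                      length_aa = integer(), rbs_score = integer(),
                      rbs_spacer = integer(), stringsAsFactors = FALSE))
  }
  if (longest_per_stop) {
    key <- paste(cands$strand, ifelse(cands$strand == "+", cands$end, cands$start))
    keep <- unlist(lapply(split(seq_len(nrow(cands)), key), function(ix) {
      ix[which.max(cands$length_aa[ix])]
    }), use.names = FALSE)
    cands <- cands[sort(keep), , drop = FALSE]
  }
  rbs <- t(vapply(seq_len(nrow(cands)), function(i) {
    up <- .upstream_sequence(record, cands$start[i], cands$end[i],
                             cands$strand[i], cands$wraps[i], 30L)
    unlist(score_rbs(up, spacer_window = spacer_window))
  }, integer(2)))
  res <- data.frame(
    start = cands$start, end = cands$end, strand = cands$strand,
    wraps = cands$wraps, start_codon = cands$start_codon,
    length_aa = cands$length_aa, rbs_score = rbs[, 1], rbs_spacer = rbs[, 2],
    stringsAsFactors = FALSE
  )
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# Scan one (already oriented) working strand. Returns begin/stop_end in
# working coordinates plus start codon and product length.
.scan_strand <- function(work, min_aa, starts, max_start, max_len) {
  res <- list()
  n <- nchar(work)
  for (off in 0:2) {
    ncod <- (n - off) %/% 3L
    if (ncod < min_aa + 1L) next
    cods <- substring(work, off + seq(1L, by = 3L, length.out = ncod),
                      off + seq(3L, by = 3L, length.out = ncod))
    stop_idx <- which(cods %in% STOP_CODONS)
    start_idx <- which(cods %in% starts)
    if (length(stop_idx) == 0L || length(start_idx) == 0L) next
    nxt <- stop_idx[findInterval(start_idx, stop_idx) + 1L]
    ok <- !is.na(nxt)
    start_idx <- start_idx[ok]; nxt <- nxt[ok]
    len_aa <- nxt - start_idx
    begin <- off + (start_idx - 1L) * 3L + 1L
    stop_end <- off + nxt * 3L
    keep <- len_aa >= min_aa & begin <= max_start & (stop_end - begin + 1L) <= max_len
    if (!any(keep)) next
    res[[off + 1L]] <- data.frame(
      begin = begin[keep], stop_end = stop_end[keep],
      start_codon = cods[start_idx[keep]], length_aa = len_aa[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(begin = integer(), stop_end = integer(),
                               start_codon = character(), length_aa = integer(),
                               stringsAsFactors = FALSE) else out
}

# The `width` nt immediately 5' of the start codon, on the coding strand.
.upstream_sequence <- function(record, start, end, strand, wraps, width = 30L) {
  s <- record$sequence
  L <- nchar(s)
  circ <- record$topology == "circular"
  if (strand == "+") {
    from <- start - width; to <- start - 1L
  } else {
    from <- end + 1L; to <- end + width
  }
  if (circ) {
    pos <- ((seq(from, to) - 1L) %% L) + 1L
    up <- paste(substring(s, pos, pos), collapse = "")
  } else {
    from <- max(1L, from); to <- min(L, to)
    if (from > to) return("")
    up <- substr(s, from, to)
  }
  if (strand == "-") up <- reverse_complement(up)
  up
}

#' Score a putative Shine-Dalgarno ribosome binding site
#'
#' The score is the length of the longest contiguous match to the SD
#' consensus (`AGGAGGT` by default) whose 3' end lies within the spacer
#' window upstream of the start codon; matches shorter than 3 nt score 0.
#' The spacer is the number of nucleotides between the 3' end of the match
#' and the first base of the start codon.
#'
#' @param upstream Sequence immediately 5' of the start codon, coding strand
#'   (typically 30 nt; shorter near the ends of linear genomes).
#' @param spacer_window Inclusive `(min, max)` spacer range in nt.
#' @param consensus SD consensus to match against.
#' @return list with `rbs_score` and `rbs_spacer` (0 and NA-free: spacer is
#'   0 when score is 0).
#' @export
score_rbs <- function(upstream, spacer_window = c(4L, 18L), consensus = "AGGAGGT") {
  upstream <- toupper(upstream)
  n <- nchar(upstream)
  best_len <- 0L; best_spacer <- 0L
  if (n >= 3L) {
    for (len in nchar(consensus):3L) {
      for (cs in 1:(nchar(consensus) - len + 1L)) {
        pat <- substr(consensus, cs, cs + len - 1L)
        hits <- gregexpr(pat, upstream, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        ends <- hits + len - 1L
        spacers <- n - ends
        ok <- spacers >= spacer_window[1] & spacers <= spacer_window[2]
        if (any(ok)) {
          sp <- min(spacers[ok])
          if (len > best_len || (len == best_len && sp < best_spacer)) {
            best_len <- len; best_spacer <- sp
          }
        }
      }
      if (best_len == len) break  # longer lengths already tried first
    }
  }
  list(rbs_score = as.integer(best_len), rbs_spacer = as.integer(best_spacer))
}

#' Genome-wide annotation statistics
#'
#' The Table-1-style summary: size, GC%, CDS count, gene density, percent of
#' the genome covered by at least one CDS (span union, overlaps counted
#' once), product-length summaries and start/stop codon tallies. Malformed
#' CDSs (length not divisible by 3) are excluded from codon tallies and
#' product statistics and counted in `malformed`.
#'
#' @param record A `GenomeRecord` with at least one CDS feature.
#' @return list of class `GenomeStats`.
#' @export
genome_stats <- function(record) {
  ft <- record$features
  cds <- ft[ft$kind == "CDS", , drop = FALSE]
  stopifnot(nrow(cds) >= 1L)
  L <- nchar(record$sequence)
  gc <- sum(strsplit(record$sequence, "")[[1]] %in% c("G", "C")) / L * 100

  # span union, splitting wrapped features at the junction
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(cds))) {
    if (isTRUE(cds$wraps[i])) {
      starts <- c(starts, cds$start[i], 1L); ends <- c(ends, L, cds$end[i])
    } else {
      starts <- c(starts, cds$start[i]); ends <- c(ends, cds$end[i])
    }
  }
  coding <- interval_union_length(starts, ends) / L * 100

  start_tally <- integer(0); stop_tally <- integer(0)
  prod_aa <- integer(0); malformed <- 0L
  for (i in seq_len(nrow(cds))) {
    nt <- feature_sequence(record, cds[i, ])
    if (nchar(nt) %% 3L != 0L) { malformed <- malformed + 1L; next }
    sc <- substr(nt, 1L, 3L)
    ec <- substr(nt, nchar(nt) - 2L, nchar(nt))
    start_tally[sc] <- (if (is.na(start_tally[sc])) 0L else start_tally[sc]) + 1L
    stop_tally[ec] <- (if (is.na(stop_tally[ec])) 0L else stop_tally[ec]) + 1L
    prod_aa <- c(prod_aa, nchar(nt) %/% 3L - 1L)
  }
  structure(list(
    length_bp = L,
    gc_percent = gc,
    n_cds = nrow(cds),
    gene_density = round(nrow(cds) / (L / 1000), 1),
    coding_percent = coding,
    avg_product_aa = if (length(prod_aa)) mean(prod_aa) else NA_real_,
    min_product_aa = if (length(prod_aa)) min(prod_aa) else NA_integer_,
    max_product_aa = if (length(prod_aa)) max(prod_aa) else NA_integer_,
    start_codon_counts = start_tally[order(-start_tally, names(start_tally))],
    stop_codon_counts = stop_tally[order(-stop_tally, names(stop_tally))],
    n_trna = sum(ft$kind == "tRNA"),
    malformed = malformed
  ), class = "GenomeStats")
}

#' @export
print.GenomeStats <- function(x, ...) {
  cat(sprintf("%d bp, GC %.1f%%, %d CDS (%.1f/kbp, %.1f%% coding), %d tRNA\n",
              x$length_bp, x$gc_percent, x$n_cds, x$gene_density,
              x$coding_percent, x$n_trna))
  cat("  products (aa): mean", round(x$avg_product_aa), "range",
      x$min_product_aa, "-", x$max_product_aa, "\n")
  cat("  starts:", paste(names(x$start_codon_counts), x$start_codon_counts,
                         sep = "=", collapse = " "), "\n")
  cat("  stops: ", paste(names(x$stop_codon_counts), x$stop_codon_counts,
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}
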