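#' Specification for a synthetic phage-like genome
#'
#' Defaults emulate a densely coded, low-GC T4-like phage genome: ~1.5 genes
#' per kbp, ~200-aa average products, ~34.5% GC, a planted replication origin
#' near mid-genome with the terminus at nt 1, two-replichore G/C strand
#' asymmetry, and eight planted tRNA genes on the minus strand.
#'
#' @param length_bp Genome length.
#' @param gc_percent Target GC content (percent).
#' @param n_genes Number of CDSs (default: 1.5 per kbp).
#' @param gene_mean_aa,gene_sd_aa,gene_min_aa Product-length distribution.
#' @param skew_bias Per-strand G excess on the leading strand, in (0, 0.2).
#' @param origin_pos,terminus_pos Planted origin/terminus (1-based nt).
#' @param codon_weights Optional named list: per single-letter amino acid, a
#'   named numeric vector of synonymous-codon weights. NULL means GC-matched
#'   neutral weights.
#' @param trnas data.frame with columns `amino_acid` (3-letter or Sup/Pyl)
#'   and `anticodon`; default is an 8-tRNA set typical of a low-GC T4-like
#'   phage.
#' @param trna_len tRNA gene length in nt.
#' @param min_gap Minimum intergenic gap (must leave room for the planted
#'   Shine-Dalgarno motif).
#' @param seed Integer seed fixing all randomness.
#' @return list of class `GenomeSpec`.
#' @export
genome_spec <- function(length_bp = 50000L, gc_percent = 34.5, n_genes = NULL,
                        gene_mean_aa = 200, gene_sd_aa = 40, gene_min_aa = 34,
                        skew_bias = 0.08, origin_pos = NULL, terminus_pos = 1L,
                        codon_weights = NULL, trnas = default_trna_set(),
                        trna_len = 76L, min_gap = 36L, seed = 1L) {
  if (is.null(n_genes)) n_genes <- round(1.5 * length_bp / 1000)
  if (is.null(origin_pos)) origin_pos <- floor(length_bp * 0.486)
  stopifnot(origin_pos != terminus_pos, skew_bias > 0, skew_bias < 0.2,
            gc_percent > 0, gc_percent < 100, min_gap >= 20L)
  structure(list(
    length_bp = as.integer(length_bp), gc_percent = gc_percent,
    n_genes = as.integer(n_genes), gene_mean_aa = gene_mean_aa,
    gene_sd_aa = gene_sd_aa, gene_min_aa = as.integer(gene_min_aa),
    skew_bias = skew_bias, origin_pos = as.integer(origin_pos),
    terminus_pos = as.integer(terminus_pos), codon_weights = codon_weights,
    trnas = trnas, trna_len = as.integer(trna_len),
    min_gap = as.integer(min_gap), seed = seed
  ), class = "GenomeSpec")
}

#' Default planted tRNA set (anticodons typical of a low-GC T4-like phage)
#' @return data.frame with `amino_acid` and `anticodon`.
#' @export
default_trna_set <- function() {
  data.frame(
    amino_acid = c("Trp", "Pro", "Ser", "Thr", "Cys", "Met", "Arg", "Sup"),
    anticodon = c("CCA", "TGG", "TGA", "TGT", "GCA", "CAT", "TCT", "CTA"),
    stringsAsFactors = FALSE
  )
}

# --- internal sampling machinery -------------------------------------------

# sample n values from x without the base-R scalar surprise
sample_from <- function(x, n) x[sample.int(length(x), n)]

# fast reverse complement for short internal strings
.rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Base probabilities at GC fraction `gc` with signed leading-strand bias `b`
# (+b => G-rich forward strand).
.base_probs <- function(gc, b) {
  c(A = (1 - gc) / 2, C = gc / 2 * (1 - b), G = gc / 2 * (1 + b),
    T = (1 - gc) / 2)
}

# Per-amino-acid codon sampling distributions. `img` controls whether the
# skew multiplier applies to the codon itself (+ strand gene) or to its
# reverse complement (the forward-strand image of a - strand gene).
.codon_probs <- function(gc, b = 0, weights = NULL, image_revcomp = FALSE) {
  gc11 <- genetic_code_11()
  codons <- names(gc11)
  probs <- vapply(codons, function(cd) {
    img <- if (image_revcomp) .rc(cd) else cd
    bp <- .base_probs(gc, b)
    prod(bp[strsplit(img, "")[[1]]])
  }, numeric(1))
  out <- list()
  mass <- numeric(0)
  for (aa in unique(gc11)) {
    idx <- gc11 == aa
    p <- probs[idx]
    if (!is.null(weights) && aa %in% names(weights)) {
      w <- weights[[aa]][names(p)]
      w[is.na(w)] <- 1
      p <- p * w
    }
    p <- p[order(names(p))]
    mass[aa] <- sum(p)
    out[[aa]] <- p / sum(p)
  }
  attr(out, "aa_mass") <- mass
  out
}

# expected GC fraction of coding sequence sampled at parameter `gc_eff`
.expected_coding_gc <- function(gc_eff, weights = NULL) {
  cp <- .codon_probs(gc_eff, 0, weights)
  mass <- attr(cp, "aa_mass")
  aas <- setdiff(names(mass), "*")
  m <- mass[aas] / sum(mass[aas])
  sum(vapply(aas, function(aa) {
    p <- cp[[aa]]
    ngc <- vapply(names(p), function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")), numeric(1))
    m[aa] * sum(p * ngc) / 3
  }, numeric(1)))
}

# expected (G - C)/(G + C) of coding sequence when codons are sampled with
# internal bias parameter `beta` applied to the forward-strand image
.expected_coding_skew <- function(beta, gc_eff, weights = NULL) {
  cp <- .codon_probs(gc_eff, beta, weights)
  # proteins are sampled from the unbiased amino-acid marginal, so the
  # expectation must be taken under that composition
  mass <- attr(.codon_probs(gc_eff, 0, weights), "aa_mass")
  aas <- setdiff(names(mass), "*")
  m <- mass[aas] / sum(mass[aas])
  g <- 0; cc <- 0
  for (aa in aas) {
    p <- cp[[aa]]
    ng <- vapply(names(p), function(cd) sum(strsplit(cd, "")[[1]] == "G"), numeric(1))
    nc <- vapply(names(p), function(cd) sum(strsplit(cd, "")[[1]] == "C"), numeric(1))
    g <- g + m[aa] * sum(p * ng)
    cc <- cc + m[aa] * sum(p * nc)
  }
  unname((g - cc) / (g + cc))
}

# argmax codon per amino acid of the unbiased sampling distribution;
# lexicographic tie-break (names are sorted).
.planted_optimal <- function(codon_probs) {
  out <- character(0)
  for (aa in setdiff(names(codon_probs), "*")) {
    p <- codon_probs[[aa]]
    out[aa] <- names(p)[which.max(p)]
  }
  out
}

.sample_protein <- function(len_aa, codon_probs) {
  # amino-acid marginal proportional to the summed codon mass => composition
  # tracks the target base composition
  mass <- attr(codon_probs, "aa_mass")
  mass <- mass[setdiff(names(mass), "*")]
  body <- sample(names(mass), len_aa - 1L, replace = TRUE, prob = mass)
  paste0("M", paste(body, collapse = ""))
}

# Back-translate under biased codon distributions; first codon is ATG.
.back_translate <- function(protein, codon_probs_biased) {
  aas <- strsplit(protein, "")[[1]]
  cods <- character(length(aas))
  cods[1] <- "ATG"
  for (aa in unique(aas[-1])) {
    at <- which(aas == aa); at <- at[at > 1L]
    p <- codon_probs_biased[[aa]]
    cods[at] <- sample(names(p), length(at), replace = TRUE, prob = p)
  }
  stop_p <- codon_probs_biased[["*"]]
  paste0(paste(cods, collapse = ""), sample(names(stop_p), 1L, prob = stop_p))
}

.random_nt <- function(n, gc, b = 0) {
  bp <- .base_probs(gc, b)
  paste(sample(names(bp), n, replace = TRUE, prob = bp), collapse = "")
}

# signed leading-strand bias at forward position p for terminus at 1:
# positions at/after the origin lie on the rightward-replicated arc.
.bias_at <- function(p, origin, bias) if (p >= origin) bias else -bias

# --- layout -----------------------------------------------------------------
# A layout is a list of segments, each
#   list(type = "intergenic"|"CDS"|"tRNA", fwd_seq, locus_tag, family,
#        strand, protein, cds, amino_acid, anticodon)
# and the genome is the concatenation of fwd_seq.

.layout_assemble <- function(id, layout, topology = "circular") {
  widths <- vapply(layout, function(s) nchar(s$fwd_seq), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- list()
  for (i in seq_along(layout)) {
    s <- layout[[i]]
    if (s$type == "intergenic") next
    rows[[length(rows) + 1L]] <- feature_table(
      locus_tag = s$locus_tag, kind = if (s$type == "CDS") "CDS" else "tRNA",
      start = starts[i], end = ends[i], strand = s$strand,
      product = if (s$type == "CDS") "hypothetical protein"
                else paste0("tRNA-", s$amino_acid),
      anticodon = if (s$type == "tRNA") s$anticodon else NA_character_,
      amino_acid = if (s$type == "tRNA") s$amino_acid else NA_character_
    )
  }
  feats <- if (length(rows)) do.call(rbind, rows) else feature_table()
  genome_record(id, paste(vapply(layout, `[[`, character(1), "fwd_seq"),
                          collapse = ""),
                topology = topology, features = feats)
}

.layout_gene_rows <- function(layout) {
  widths <- vapply(layout, function(s) nchar(s$fwd_seq), integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  idx <- which(vapply(layout, function(s) s$type == "CDS", logical(1)))
  data.frame(
    family = vapply(layout[idx], `[[`, character(1), "family"),
    locus_tag = vapply(layout[idx], `[[`, character(1), "locus_tag"),
    start = starts[idx], end = ends[idx],
    strand = vapply(layout[idx], `[[`, character(1), "strand"),
    protein = vapply(layout[idx], `[[`, character(1), "protein"),
    cds = vapply(layout[idx], `[[`, character(1), "cds"),
    stringsAsFactors = FALSE
  )
}

# intergenic segment of width n at bias b, with a Shine-Dalgarno motif
# embedded for an adjacent gene: `rbs_right` plants AGGAGG near the segment
# end (for a following + strand gene), `rbs_left` plants its reverse
# complement near the start (for a preceding - strand gene).
.make_gap <- function(n, gc, b, rbs_right = FALSE, rbs_left = FALSE,
                      spacer = 8L) {
  s <- strsplit(.random_nt(n, gc, b), "")[[1]]
  if (rbs_right && n >= spacer + 6L) {
    s[(n - spacer - 5L):(n - spacer)] <- strsplit("AGGAGG", "")[[1]]
  }
  if (rbs_left && n >= spacer + 6L) {
    s[(spacer + 1L):(spacer + 6L)] <- strsplit("CCTCCT", "")[[1]]
  }
  paste(s, collapse = "")
}

#' Generate a synthetic phage-like genome with known ground truth
#'
#' Genes are synthesised by sampling proteins and back-translating them under
#' per-amino-acid codon preferences; intergenic sequence is sampled at the
#' target GC with replichore-dependent G/C asymmetry (G-rich forward strand
#' on the arc replicated rightward from the planted origin), and the same
#' asymmetry is applied to synonymous codon choice so the cumulative-skew
#' signal survives dense coding. Genes are co-oriented with the leading
#' strand ~85% of the time; a Shine-Dalgarno motif is planted 5-10 nt
#' upstream of every start. Deterministic under the spec seed.
#'
#' @param spec A [genome_spec()].
#' @return list with `record` (a `GenomeRecord`) and `manifest` (class
#'   `SyntheticManifest`: planted `origin`/`terminus`, `genes`, `trnas`,
#'   `codon_probs`, `planted_optimal`, `events`, and the internal `layout`
#'   that [evolve_genome()] operates on).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  with_seed(spec$seed, .generate_genome_impl(spec))
}

.generate_genome_impl <- function(spec) {
  gc <- spec$gc_percent / 100
  L <- spec$length_bp
  n <- spec$n_genes
  ntr <- nrow(spec$trnas)
  # conditioning the codon pool on non-stop codons removes AT-rich mass, so
  # the sampling GC is calibrated so that realised coding GC hits the target
  gc_cod <- stats::uniroot(function(x) .expected_coding_gc(x, spec$codon_weights) - gc,
                           c(0.02, 0.98), tol = 1e-5)$root
  probs0 <- .codon_probs(gc_cod, 0, spec$codon_weights)
  # The codon table has its own baseline strand skew (typically C-rich), and
  # the origin signal lives in the *difference* between the two replichores;
  # the internal codon bias is therefore calibrated so the leading-strand
  # G-excess exceeds that baseline by skew_bias. The common-mode baseline is
  # removed by the detrended cumulative curve during origin prediction.
  base_skew <- .expected_coding_skew(0, gc_cod, spec$codon_weights)
  beta <- stats::uniroot(function(x)
    .expected_coding_skew(x, gc_cod, spec$codon_weights) -
      (base_skew + spec$skew_bias),
    c(0, 0.95), tol = 1e-4, extendInt = "upX")$root

  # draw gene lengths until the packing fits (lengths stay distribution-true,
  # conditioned on feasibility)
  for (try in 1:100) {
    len_aa <- pmax(spec$gene_min_aa,
                   round(stats::rnorm(n, spec$gene_mean_aa, spec$gene_sd_aa)))
    gene_nt <- (len_aa + 1L) * 3L
    spare <- L - sum(gene_nt) - ntr * spec$trna_len
    need <- (n + ntr + 1L) * spec$min_gap
    if (spare >= need) break
    if (try == 100L) stop("infeasible packing: genes do not fit the genome")
  }
  n_items <- n + ntr
  extra <- as.vector(stats::rmultinom(1, spare - (n_items + 1L) * spec$min_gap,
                                      rep(1, n_items + 1L)))
  gaps <- spec$min_gap + extra

  # item order: genes, with the tRNA cluster inserted at a random point
  trna_at <- sample(n + 1L, 1L)
  item_kind <- append(rep("CDS", n), rep("tRNA", ntr), after = trna_at - 1L)

  layout <- list()
  prob_cache <- list()
  pos <- 0L
  gi <- 0L; ti <- 0L
  for (k in seq_len(n_items)) {
    gapw <- gaps[k]
    gap_b <- .bias_at(pos + gapw %/% 2L, spec$origin_pos, spec$skew_bias)
    this_kind <- item_kind[k]
    seg <- NULL
    if (this_kind == "CDS") {
      gi <- gi + 1L
      at <- pos + gapw + 1L
      b <- .bias_at(at, spec$origin_pos, spec$skew_bias)
      leading_strand <- if (b > 0) "+" else "-"
      strand <- if (stats::runif(1) < 0.85) leading_strand
                else setdiff(c("+", "-"), leading_strand)
      # the bias always refers to the forward-strand image of the codon
      key <- paste0(strand, sign(b))
      if (is.null(prob_cache[[key]])) {
        prob_cache[[key]] <- .codon_probs(gc_cod, sign(b) * beta,
                                          spec$codon_weights,
                                          image_revcomp = (strand == "-"))
      }
      probs_b <- prob_cache[[key]]
      prot <- .sample_protein(len_aa[gi], probs0)
      cds <- .back_translate(prot, probs_b)
      fwd <- if (strand == "+") cds else reverse_complement(cds)
      seg <- list(type = "CDS", fwd_seq = fwd,
                  locus_tag = sprintf("g%03d", gi),
                  family = sprintf("fam%03d", gi), strand = strand,
                  protein = prot, cds = cds)
    } else {
      ti <- ti + 1L
      tr <- spec$trnas[ti, ]
      coding <- strsplit(.random_nt(spec$trna_len, gc, 0), "")[[1]]
      coding[33:35] <- strsplit(tr$anticodon, "")[[1]]
      coding <- paste(coding, collapse = "")
      seg <- list(type = "tRNA", fwd_seq = reverse_complement(coding),
                  locus_tag = sprintf("t%03d", ti), family = NA_character_,
                  strand = "-", amino_acid = tr$amino_acid,
                  anticodon = tr$anticodon, trna_coding = coding)
    }
    gap_seg <- list(type = "intergenic",
                    fwd_seq = .make_gap(gapw, gc, gap_b,
                                        rbs_right = this_kind == "CDS" && seg$strand == "+",
                                        rbs_left = length(layout) > 0L &&
                                          layout[[length(layout)]]$type == "CDS" &&
                                          layout[[length(layout)]]$strand == "-",
                                        spacer = sample(5:10, 1L)))
    layout <- c(layout, list(gap_seg), list(seg))
    pos <- pos + gapw + nchar(seg$fwd_seq)
  }
  final_b <- .bias_at(pos + gaps[n_items + 1L] %/% 2L, spec$origin_pos, spec$skew_bias)
  layout <- c(layout, list(list(
    type = "intergenic",
    fwd_seq = .make_gap(gaps[n_items + 1L], gc, final_b,
                        rbs_left = layout[[length(layout)]]$type == "CDS" &&
                          layout[[length(layout)]]$strand == "-",
                        spacer = sample(5:10, 1L))
  )))

  record <- .layout_assemble("synthetic_phage", layout)
  manifest <- structure(list(
    origin = spec$origin_pos, terminus = spec$terminus_pos,
    genes = .layout_gene_rows(layout),
    trnas = cbind(spec$trnas,
                  locus_tag = sprintf("t%03d", seq_len(ntr)),
                  stringsAsFactors = FALSE),
    codon_probs = probs0,
    planted_optimal = .planted_optimal(probs0),
    spec = spec,
    events = list(),
    layout = layout
  ), class = "SyntheticManifest")
  list(record = record, manifest = manifest)
}

#' Specification of evolutionary changes for [evolve_genome()]
#'
#' @param aa_divergence Target per-residue substitution probability applied
#'   to every protein (start Met excluded).
#' @param nt_rate Additional per-site nucleotide substitution probability
#'   (start and stop codons excluded; substitutions creating internal stops
#'   are reverted).
#' @param kappa Transition:transversion ratio for nucleotide substitutions.
#' @param gene_loss Number of genes to delete.
#' @param gene_gain Number of new unrelated genes to insert.
#' @param duplications NULL or list(n =, divergence =): copy n genes and
#'   diverge the copies at the given per-site nucleotide rate.
#' @param splits NULL or list of list(family =, breakpoint_aa =,
#'   deletion_aa = 0): replace a gene by two in-frame fragments covering
#'   residues 1..b and (b + deletion + 1)..end.
#' @param inversions NULL or list of c(from, to) gene ranks: invert the
#'   spanned block.
#' @param seed Seed for the evolution step.
#' @return list of class `EvolutionSpec`.
#' @export
evolution_spec <- function(aa_divergence = 0, nt_rate = 0, kappa = 2,
                           gene_loss = 0L, gene_gain = 0L,
                           duplications = NULL, splits = NULL,
                           inversions = NULL, seed = 1L) {
  structure(list(
    aa_divergence = aa_divergence, nt_rate = nt_rate, kappa = kappa,
    gene_loss = as.integer(gene_loss), gene_gain = as.integer(gene_gain),
    duplications = duplications, splits = splits, inversions = inversions,
    seed = seed
  ), class = "EvolutionSpec")
}

#' Mutate a coding sequence by point substitutions
#'
#' Per-site substitutions at the given rate under a two-parameter model
#' (transition:transversion ratio `kappa`); the start and stop codons are
#' never touched and substitutions that would create an internal stop are
#' reverted, so the reading frame stays intact. Used to derive diverged gene
#' duplicates with a known expected nucleotide identity.
#'
#' @param cds In-frame coding sequence.
#' @param rate Per-site substitution probability.
#' @param kappa Transition:transversion ratio.
#' @param seed Optional seed.
#' @return The mutated coding sequence.
#' @export
mutate_cds <- function(cds, rate, kappa = 2, seed = NULL) {
  with_seed(seed, .mutate_nt(cds, rate, kappa))
}

#' Construct a convergent gene pair
#'
#' Two genes whose proteins share a chosen moderate identity but whose
#' nucleotide sequences are unrelated beyond what the shared residues force:
#' each protein is back-translated under a disjoint codon preference (one
#' GC-rich, one AT-rich third-position regime). Such pairs align at the
#' protein level yet show no significant DNA identity — the signature that
#' separates convergent evolution from lineage-specific duplication.
#'
#' @param len_aa Protein length.
#' @param aa_identity Fraction of shared residues between the two proteins.
#' @param gc_a,gc_b Sampling GC for the two codon regimes.
#' @param seed Optional seed.
#' @return list with `protein_a`, `protein_b`, `cds_a`, `cds_b`.
#' @export
make_convergent_pair <- function(len_aa = 150L, aa_identity = 0.4,
                                 gc_a = 0.65, gc_b = 0.25, seed = NULL) {
  with_seed(seed, {
    probs_a <- .codon_probs(gc_a, 0)
    probs_b <- .codon_probs(gc_b, 0)
    prot_a <- .sample_protein(len_aa, .codon_probs(0.45, 0))
    aas <- strsplit(prot_a, "")[[1]]
    alphabet <- setdiff(unique(unname(genetic_code_11())), "*")
    keep <- stats::runif(len_aa) < aa_identity
    keep[1] <- TRUE
    bas <- vapply(seq_len(len_aa), function(i) {
      if (keep[i]) aas[i] else sample(setdiff(alphabet, aas[i]), 1L)
    }, character(1))
    prot_b <- paste(bas, collapse = "")
    list(protein_a = prot_a, protein_b = prot_b,
         cds_a = .back_translate(prot_a, probs_a),
         cds_b = .back_translate(prot_b, probs_b))
  })
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Mutate a coding sequence at per-site rate, kappa-weighted, never touching
# the first or last codon and reverting substitutions that create stops.
.mutate_nt <- function(cds, rate, kappa) {
  if (rate <= 0) return(cds)
  s <- strsplit(cds, "")[[1]]
  n <- length(s)
  sites <- which(stats::runif(n) < rate)
  sites <- sites[sites > 3L & sites <= n - 3L]
  for (i in sites) {
    old <- s[i]
    ts <- TRANSITION[[old]]
    tv <- setdiff(c("A", "C", "G", "T"), c(old, ts))
    p <- c(kappa, 1, 1) / (kappa + 2)
    s[i] <- sample(c(ts, tv), 1L, prob = p)
    cod_i <- (i - 1L) %/% 3L
    cod <- paste(s[(cod_i * 3L + 1L):(cod_i * 3L + 3L)], collapse = "")
    if (cod %in% STOP_CODONS) s[i] <- old
  }
  paste(s, collapse = "")
}

# Mutate a protein at per-residue probability, resampling codons of changed
# residues; returns list(protein, cds).
.mutate_protein <- function(protein, cds, rate, codon_probs) {
  if (rate <= 0) return(list(protein = protein, cds = cds))
  aas <- strsplit(protein, "")[[1]]
  cods <- codons_of(cds)
  alphabet <- setdiff(names(codon_probs), "*")
  for (i in seq_along(aas)) {
    if (i == 1L) next
    if (stats::runif(1) < rate) {
      new_aa <- sample(setdiff(alphabet, aas[i]), 1L)
      aas[i] <- new_aa
      p <- codon_probs[[new_aa]]
      cods[i] <- sample(names(p), 1L, prob = p)
    }
  }
  list(protein = paste(aas, collapse = ""),
       cds = paste(cods, collapse = ""))
}

#' Evolve a synthetic genome under a set of recorded events
#'
#' Substitutions are applied first, then structural events (loss, gain,
#' duplication, splitting, inversion), so divergence targets refer to
#' pre-event orthologs. Family ids propagate to children; every event is
#' recorded in the returned manifest. With a zero spec the child is
#' byte-identical to the parent.
#'
#' @param parent Output of [generate_genome()] or [evolve_genome()] (list
#'   with `record` and `manifest`).
#' @param espec An [evolution_spec()].
#' @return list with `record` and `manifest` for the child genome.
#' @export
evolve_genome <- function(parent, espec) {
  stopifnot(inherits(espec, "EvolutionSpec"))
  with_seed(espec$seed, .evolve_genome_impl(parent, espec))
}

.evolve_genome_impl <- function(parent, espec) {
  man <- parent$manifest
  layout <- man$layout
  spec <- man$spec
  gc <- spec$gc_percent / 100
  probs0 <- man$codon_probs
  events <- list()

  gene_idx <- function() which(vapply(layout, function(s) s$type == "CDS", logical(1)))

  # 1. substitutions on every gene
  if (espec$aa_divergence > 0 || espec$nt_rate > 0) {
    for (i in gene_idx()) {
      s <- layout[[i]]
      mut <- .mutate_protein(s$protein, s$cds, espec$aa_divergence, probs0)
      cds <- .mutate_nt(mut$cds, espec$nt_rate, espec$kappa)
      s$protein <- mut$protein
      s$cds <- cds
      s$fwd_seq <- if (s$strand == "+") cds else reverse_complement(cds)
      layout[[i]] <- s
    }
  }

  # 2. gene loss
  if (espec$gene_loss > 0L) {
    gi <- gene_idx()
    protected <- vapply(espec$splits %||% list(), `[[`, character(1), "family")
    fams <- vapply(layout[gi], `[[`, character(1), "family")
    victims <- sample_from(gi[!fams %in% protected], espec$gene_loss)
    for (v in victims) {
      events[[length(events) + 1L]] <- list(type = "loss",
                                            family = layout[[v]]$family)
    }
    layout <- layout[-victims]
  }

  gain_counter <- 0L
  insert_gene <- function(layout, seg) {
    # insert [gap-with-RBS, gene] after a random intergenic segment
    ig <- which(vapply(layout, function(s) s$type == "intergenic", logical(1)))
    at <- sample_from(ig, 1L)
    gap <- list(type = "intergenic",
                fwd_seq = .make_gap(spec$min_gap, gc, 0,
                                    rbs_right = seg$strand == "+",
                                    rbs_left = seg$strand == "-",
                                    spacer = sample(5:10, 1L)))
    append(layout, list(gap, seg), after = at)
  }

  # 3. gene gain
  if (espec$gene_gain > 0L) {
    for (k in seq_len(espec$gene_gain)) {
      gain_counter <- gain_counter + 1L
      len <- max(spec$gene_min_aa,
                 round(stats::rnorm(1, spec$gene_mean_aa, spec$gene_sd_aa)))
      prot <- .sample_protein(len, probs0)
      cds <- .back_translate(prot, probs0)
      strand <- sample(c("+", "-"), 1L)
      seg <- list(type = "CDS",
                  fwd_seq = if (strand == "+") cds else reverse_complement(cds),
                  locus_tag = sprintf("gain%03d", gain_counter),
                  family = sprintf("gainfam%03d", gain_counter),
                  strand = strand, protein = prot, cds = cds)
      layout <- insert_gene(layout, seg)
      events[[length(events) + 1L]] <- list(type = "gain", family = seg$family)
    }
  }

  # 4. duplications
  if (!is.null(espec$duplications)) {
    ndup <- espec$duplications$n
    div <- espec$duplications$divergence %||% 0
    gi <- gene_idx()
    src <- sample_from(gi, ndup)
    for (k in seq_along(src)) {
      s <- layout[[src[k]]]
      cds <- .mutate_nt(s$cds, div, espec$kappa)
      prot <- suppressWarnings(as.character(translate_cds(cds)))
      seg <- s
      seg$cds <- cds
      seg$protein <- prot
      seg$locus_tag <- sprintf("%s_dup", s$locus_tag)
      seg$fwd_seq <- if (s$strand == "+") cds else reverse_complement(cds)
      layout <- insert_gene(layout, seg)
      events[[length(events) + 1L]] <- list(
        type = "duplication", family = s$family,
        source = s$locus_tag, copy = seg$locus_tag, divergence = div
      )
    }
  }

  # 5. splits
  for (sp in espec$splits %||% list()) {
    gi <- gene_idx()
    fams <- vapply(layout[gi], `[[`, character(1), "family")
    hit <- gi[fams == sp$family]
    if (length(hit) == 0L) stop(sprintf("split references missing gene family '%s'", sp$family))
    i <- hit[1]
    s <- layout[[i]]
    b <- sp$breakpoint_aa
    del <- sp$deletion_aa %||% 0L
    cods <- codons_of(s$cds)
    n_aa <- length(cods) - 1L  # excl stop
    stopifnot(b >= spec$gene_min_aa, b + del + spec$gene_min_aa <= n_aa)
    cds1 <- paste0(paste(cods[1:b], collapse = ""), "TAA")
    cds2 <- paste0("ATG", paste(cods[(b + del + 1L):length(cods)], collapse = ""))
    f1 <- list(type = "CDS", locus_tag = paste0(s$locus_tag, ".1"),
               family = s$family, strand = s$strand,
               protein = suppressWarnings(as.character(translate_cds(cds1))),
               cds = cds1,
               fwd_seq = if (s$strand == "+") cds1 else reverse_complement(cds1))
    f2 <- list(type = "CDS", locus_tag = paste0(s$locus_tag, ".2"),
               family = s$family, strand = s$strand,
               protein = suppressWarnings(as.character(translate_cds(cds2))),
               cds = cds2,
               fwd_seq = if (s$strand == "+") cds2 else reverse_complement(cds2))
    gapw <- spec$min_gap
    gap <- list(type = "intergenic",
                fwd_seq = .make_gap(gapw, gc, 0,
                                    rbs_right = s$strand == "+",
                                    rbs_left = s$strand == "-",
                                    spacer = sample(5:10, 1L)))
    pieces <- if (s$strand == "+") list(f1, gap, f2) else list(f2, gap, f1)
    layout <- append(layout[-i], pieces, after = i - 1L)
    events[[length(events) + 1L]] <- list(
      type = "split", family = s$family, source = s$locus_tag,
      fragments = c(f1$locus_tag, f2$locus_tag),
      breakpoint_aa = b, deletion_aa = del,
      segments = list(c(1L, b), c(b + del + 1L, n_aa))
    )
  }

  # 6. inversions (ranks refer to gene order along the genome)
  for (inv in espec$inversions %||% list()) {
    gi <- gene_idx()
    stopifnot(inv[1] >= 1L, inv[2] <= length(gi), inv[1] <= inv[2])
    from <- gi[inv[1]]; to <- gi[inv[2]]
    block <- rev(layout[from:to])
    block <- lapply(block, function(s) {
      s$fwd_seq <- reverse_complement(s$fwd_seq)
      if (!is.null(s$strand)) s$strand <- if (s$strand == "+") "-" else "+"
      s
    })
    layout <- append(layout[-(from:to)], block, after = from - 1L)
    events[[length(events) + 1L]] <- list(
      type = "inversion", from_rank = inv[1], to_rank = inv[2],
      families = vapply(block[vapply(block, function(s) s$type == "CDS",
                                     logical(1))], `[[`, character(1), "family")
    )
  }

  record <- .layout_assemble(paste0(parent$record$id, "_child"), layout)
  manifest <- man
  manifest$genes <- .layout_gene_rows(layout)
  manifest$events <- c(man$events, events)
  manifest$layout <- layout
  manifest$origin <- NA_integer_  # indels shift the planted origin
  list(record = record, manifest = manifest)
}
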