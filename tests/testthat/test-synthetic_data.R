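test_that("generation is byte-identical under a fixed seed", {
  spec <- genome_spec(length_bp = 12000, n_genes = 16, seed = 123)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$record$features, b$record$features)
  expect_identical(a$manifest$genes, b$manifest$genes)

  ch1 <- evolve_genome(a, evolution_spec(aa_divergence = 0.1, gene_loss = 2,
                                         seed = 9))
  ch2 <- evolve_genome(b, evolution_spec(aa_divergence = 0.1, gene_loss = 2,
                                         seed = 9))
  expect_identical(ch1$record$sequence, ch2$record$sequence)
})

test_that("construction honours gene count, density and feasibility", {
  g <- generate_genome(genome_spec(length_bp = 10000, n_genes = 15, seed = 1))
  expect_equal(sum(g$record$features$kind == "CDS"), 15L)
  expect_equal(genome_stats(g$record)$gene_density, 1.5)
  expect_error(generate_genome(genome_spec(length_bp = 5000, n_genes = 20,
                                           seed = 1)),
               "infeasible packing")
})

test_that("realised GC tracks the target within one percentage point", {
  for (gc in c(30, 34.5, 40)) {
    g <- generate_genome(genome_spec(length_bp = 15000, n_genes = 22,
                                     gc_percent = gc, seed = 7))
    expect_lt(abs(genome_stats(g$record)$gc_percent - gc), 1)
  }
})

test_that("a zero evolution spec reproduces the parent exactly", {
  g <- generate_genome(genome_spec(length_bp = 10000, n_genes = 14, seed = 2))
  ch <- evolve_genome(g, evolution_spec(seed = 3))
  expect_identical(ch$record$sequence, g$record$sequence)
  expect_identical(ch$manifest$genes$cds, g$manifest$genes$cds)
})

test_that("realised amino-acid divergence is close to the target", {
  g <- generate_genome(genome_spec(length_bp = 20000, n_genes = 30, seed = 5))
  ch <- evolve_genome(g, evolution_spec(aa_divergence = 0.2, seed = 6))
  div <- mapply(function(p, q) {
    a <- strsplit(p, "")[[1]]; b <- strsplit(q, "")[[1]]
    mean(a != b)
  }, g$manifest$genes$protein, ch$manifest$genes$protein)
  expect_lt(abs(median(div) - 0.2), 0.05)
})

test_that("duplication divergence is applied at the requested rate", {
  g <- generate_genome(genome_spec(length_bp = 10000, n_genes = 14, seed = 8))
  ch <- evolve_genome(g, evolution_spec(
    duplications = list(n = 1, divergence = 0.10), seed = 9))
  ev <- Filter(function(e) e$type == "duplication", ch$manifest$events)[[1]]
  m <- ch$manifest$genes
  src <- m$cds[m$locus_tag == ev$source]
  cpy <- m$cds[m$locus_tag == ev$copy]
  expect_equal(nchar(src), nchar(cpy))
  mismatch <- mean(strsplit(src, "")[[1]] != strsplit(cpy, "")[[1]])
  expect_lt(abs(mismatch - 0.10), 0.04)
  # one extra CDS relative to the parent
  expect_equal(nrow(m), nrow(g$manifest$genes) + 1L)
})

test_that("gene gain and loss are recorded and change the gene count", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 16, seed = 10))
  ch <- evolve_genome(g, evolution_spec(gene_loss = 3, gene_gain = 2, seed = 11))
  m <- ch$manifest$genes
  expect_equal(nrow(m), 16L - 3L + 2L)
  types <- vapply(ch$manifest$events, `[[`, character(1), "type")
  expect_equal(sum(types == "loss"), 3L)
  expect_equal(sum(types == "gain"), 2L)
  lost <- vapply(Filter(function(e) e$type == "loss", ch$manifest$events),
                 `[[`, character(1), "family")
  expect_false(any(lost %in% m$family))
})

test_that("split fragments tile the parent protein at the stated breakpoints", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 16, seed = 12))
  ch <- evolve_genome(g, evolution_spec(
    splits = list(list(family = "fam004", breakpoint_aa = 50, deletion_aa = 30)),
    seed = 13))
  ev <- Filter(function(e) e$type == "split", ch$manifest$events)[[1]]
  m <- ch$manifest$genes
  parent_prot <- g$manifest$genes$protein[g$manifest$genes$locus_tag == ev$source]
  f1 <- m$protein[m$locus_tag == ev$fragments[1]]
  f2 <- m$protein[m$locus_tag == ev$fragments[2]]
  expect_identical(f1, substr(parent_prot, 1, 50))
  # fragment 2 = planted Met + the C-terminal segment after the deletion
  expect_identical(substr(f2, 2, nchar(f2)),
                   substr(parent_prot, 81, nchar(parent_prot)))
  expect_error(
    evolve_genome(g, evolution_spec(
      splits = list(list(family = "no_such", breakpoint_aa = 50)), seed = 1)),
    "missing gene family")
})

test_that("inversion reverses gene order and flips strands in the span", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 16, seed = 14))
  ch <- evolve_genome(g, evolution_spec(inversions = list(c(4L, 8L)), seed = 15))
  pa <- g$manifest$genes; pb <- ch$manifest$genes
  span <- pa$family[4:8]
  inv <- pb[pb$family %in% span, ]
  expect_identical(inv$family, rev(span))
  orig <- pa[match(inv$family, pa$family), ]
  expect_true(all(inv$strand != orig$strand))
  expect_identical(inv$protein, rev(pa$protein[4:8]))
  # genes outside the span are untouched
  out <- pb[!pb$family %in% span, ]
  expect_identical(out$cds, pa$cds[match(out$family, pa$family)])
})

test_that("planted codon preferences are recovered as optimal codons", {
  code <- Biostrings::getGeneticCode("11")
  names(code) <- gsub("U", "T", names(code))
  weights <- list()
  set.seed(33)
  for (aa in setdiff(unique(code), "*")) {
    syn <- sort(names(code)[code == aa])
    if (length(syn) == 1L) next
    w <- rep(1, length(syn)); names(w) <- syn
    w[sample.int(length(syn), 1)] <- 8
    weights[[aa]] <- w
  }
  # minimal strand bias: this experiment isolates codon preference recovery
  spec <- genome_spec(length_bp = 40000, n_genes = 60, codon_weights = weights,
                      skew_bias = 0.01, seed = 34)
  g <- generate_genome(spec)
  opt <- optimal_codons(codon_usage(g$manifest$genes$cds))
  planted <- g$manifest$planted_optimal
  shared <- intersect(names(opt), names(planted))
  expect_identical(opt[shared], planted[shared])
})
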