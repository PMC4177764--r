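# small helper: named proteome from a generated genome
proteome_of <- function(g) setNames(g$manifest$genes$protein,
                                    g$manifest$genes$locus_tag)
family_of <- function(g) setNames(g$manifest$genes$family,
                                  g$manifest$genes$locus_tag)

test_that("self-comparison records best non-self hits only", {
  g <- generate_genome(genome_spec(length_bp = 10000, n_genes = 14, seed = 51))
  child <- evolve_genome(g, evolution_spec(
    duplications = list(n = 2, divergence = 0.05), seed = 52))
  p <- proteome_of(child)
  ht <- find_homologs(p, p, max_evalue = 1e-6)
  expect_true(all(ht$query != ht$subject))
  # the two planted duplicate pairs are mutual best hits
  dups <- Filter(function(e) e$type == "duplication", child$manifest$events)
  for (d in dups) {
    expect_equal(ht$subject[ht$query == d$source], d$copy)
    expect_equal(ht$subject[ht$query == d$copy], d$source)
  }
})

test_that("ortholog recall on diverged families meets the recovery targets", {
  recall20 <- c(); recall50 <- c()
  for (seed in 1:3) {
    g <- generate_genome(genome_spec(length_bp = 18000, n_genes = 27, seed = seed))
    pa <- proteome_of(g); fa <- family_of(g)
    for (d in c(0.2, 0.5)) {
      ch <- evolve_genome(g, evolution_spec(aa_divergence = d, seed = seed + 100))
      pb <- proteome_of(ch); fb <- family_of(ch)
      ht <- find_homologs(pa, pb, max_evalue = 1e-6)
      rec <- sum(fa[ht$query] == fb[ht$subject]) / length(pa)
      if (d == 0.2) recall20 <- c(recall20, rec) else recall50 <- c(recall50, rec)
    }
  }
  expect_gte(median(recall20), 0.95)
  expect_gte(median(recall50), 0.80)
})

test_that("unrelated random proteomes yield no homologs at E <= 1e-6", {
  g1 <- generate_genome(genome_spec(length_bp = 15000, n_genes = 22, seed = 61))
  g2 <- generate_genome(genome_spec(length_bp = 15000, n_genes = 22, seed = 62))
  ht <- find_homologs(proteome_of(g1), proteome_of(g2), max_evalue = 1e-6)
  expect_equal(nrow(ht), 0L)
})

test_that("core_genome: identical genomes share everything, cores are planted", {
  g <- generate_genome(genome_spec(length_bp = 8000, n_genes = 10, seed = 71))
  p <- proteome_of(g)
  cg <- core_genome(list(A = p, B = p, C = p))
  expect_setequal(cg$core, names(p))
  expect_true(all(cg$presence))

  # 10 core families everywhere + 3 private genes per genome
  set.seed(72)
  core <- p
  mk <- function(tag) {
    priv <- setNames(vapply(1:3, function(i) random_protein(150), character(1)),
                     paste0(tag, "_priv", 1:3))
    c(core, priv)
  }
  genomes <- list(A = mk("a"), B = mk("b"), C = mk("c"))
  cg <- core_genome(genomes, reference = "A")
  expect_setequal(cg$core, names(core))
  # removing one genome never shrinks the core
  cg2 <- core_genome(genomes[c("A", "B")], reference = "A")
  expect_true(all(cg$core %in% cg2$core))
  # pairwise shared counts are near-symmetric
  expect_lte(abs(cg$shared_counts["A", "B"] - cg$shared_counts["B", "A"]),
             0.1 * min(lengths(genomes)))
})

test_that("core_genome refuses a single genome", {
  expect_error(core_genome(list(A = c(x = "MKT"))), "at least 2")
})

test_that("synteny chaining: colinear set, planted inversion, relocation", {
  mk_pairs <- function(s_index, q_strand, s_strand) {
    n <- length(s_index)
    data.frame(query = paste0("q", 1:n), subject = paste0("s", s_index),
               q_index = 1:n, s_index = s_index,
               q_strand = q_strand, s_strand = s_strand,
               stringsAsFactors = FALSE)
  }
  # perfectly colinear 20 genes
  sb <- synteny_blocks(mk_pairs(1:20, "+", "+"))
  expect_length(sb$blocks, 1L)
  expect_equal(nrow(sb$blocks[[1]]), 20L)
  expect_equal(attr(sb$blocks[[1]], "orientation"), "colinear")
  expect_equal(nrow(sb$relocated), 0L)

  # a 5-gene inversion: s order reversed, strands flipped inside the block
  s_idx <- c(1:7, 12:8, 13:20)
  s_str <- rep("+", 20); s_str[8:12] <- "-"
  sb <- synteny_blocks(mk_pairs(s_idx, "+", s_str))
  orients <- vapply(sb$blocks, attr, character(1), "orientation")
  expect_equal(sum(orients == "inverted"), 1L)
  inv <- sb$blocks[[which(orients == "inverted")]]
  expect_equal(nrow(inv), 5L)
  expect_true(all(diff(inv$s_index) < 0))

  # one gene moved across the genome: reported relocated, rest in <= 2 blocks
  s_idx <- c(1:6, 18, 7:17)  # gene 7 relocated near the end
  pairs <- mk_pairs(s_idx, "+", "+")
  sb <- synteny_blocks(pairs)
  expect_lte(length(sb$blocks), 2L)
  expect_true("q7" %in% sb$relocated$query)
})

test_that("blocks are strictly monotone and strand-consistent in genome data", {
  g <- generate_genome(genome_spec(length_bp = 15000, n_genes = 20, seed = 81))
  ch <- evolve_genome(g, evolution_spec(aa_divergence = 0.1,
                                        inversions = list(c(6L, 10L)),
                                        seed = 82))
  pairs <- homolog_pairs_for_synteny(g$record, ch$record)
  sb <- synteny_blocks(pairs)
  expect_gte(length(sb$blocks), 2L)
  orients <- vapply(sb$blocks, attr, character(1), "orientation")
  expect_true("inverted" %in% orients)
  inv_fams <- unlist(lapply(Filter(function(e) e$type == "inversion",
                                   ch$manifest$events), `[[`, "families"))
  fa <- family_of(g)
  for (b in sb$blocks) {
    d <- diff(b$s_index)
    expect_true(all(d > 0) || all(d < 0))
    if (attr(b, "orientation") == "inverted") {
      expect_true(all(fa[b$query] %in% inv_fams))
    }
  }
})
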