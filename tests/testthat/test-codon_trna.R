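test_that("codon_usage counts in frame, including the stop codon", {
  u <- codon_usage("ATGAAATAA")
  expect_equal(unname(u$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(u$total_codons, 3L)
  expect_equal(sum(u$counts), 3L)

  expect_error(codon_usage(character(0)), "no coding sequences")

  # N-containing codons and out-of-frame sequences are skipped with counts
  u <- codon_usage(c("ATGANATAA", "ATGAA"))
  expect_equal(u$total_codons, 2L)
  expect_equal(u$n_skipped_codons, 1L)
  expect_equal(u$n_skipped_seqs, 1L)
})

test_that("codon_usage equals an independent 3-mer stepping oracle", {
  set.seed(12)
  seqs <- vapply(1:100, function(i) {
    paste0("ATG", random_dna(3 * sample(10:80, 1)), "TAA")
  }, character(1))
  u <- codon_usage(seqs)
  oracle <- oracle_codon_counts(seqs)
  expect_equal(u$counts[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  expect_equal(u$total_codons, sum(oracle))
  expect_equal(sum(u$per_thousand), 1000, tolerance = 1e-9)
  # per-amino-acid fractions are proper distributions
  for (aa in names(u$per_aa_fraction)) {
    f <- u$per_aa_fraction[[aa]]
    if (all(is.na(f))) next
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("optimal_codons takes the per-amino-acid argmax with lexicographic ties", {
  u <- codon_usage(c(strrep("AAA", 10), strrep("AAG", 3), "TAA"))
  expect_equal(optimal_codons(u)[["K"]], "AAA")

  u <- codon_usage(c(strrep("GGA", 5), strrep("GGC", 5)))
  expect_equal(optimal_codons(u)[["G"]], "GGA")

  # absent amino acids are omitted
  expect_false("W" %in% names(optimal_codons(u)))

  # random table agrees with a direct argmax oracle
  set.seed(14)
  seqs <- vapply(1:50, function(i) paste0("ATG", random_dna(150), "TAA"), character(1))
  u <- codon_usage(seqs)
  opt <- optimal_codons(u)
  code <- Biostrings::getGeneticCode("11")
  names(code) <- gsub("U", "T", names(code))
  for (aa in names(opt)) {
    syn <- sort(names(code)[code == aa])
    cnt <- u$counts[syn]
    expect_equal(opt[[aa]], syn[which.max(cnt)])
  }
})

test_that("decode_anticodon reverse-complements and expands wobble", {
  expect_equal(decode_anticodon("CCA"), "TGG")   # Trp
  expect_equal(decode_anticodon("CAT"), "ATG")   # Met
  expect_equal(decode_anticodon("GCA", wobble = TRUE), c("TGC", "TGT"))
  expect_equal(decode_anticodon("TCT", wobble = TRUE), c("AGA", "AGG"))
  expect_error(decode_anticodon("CXA"), "invalid")
  # involution with reverse complement (wobble off)
  set.seed(3)
  for (i in 1:20) {
    a <- random_dna(3)
    expect_equal(reverse_complement(decode_anticodon(a)), a)
  }
})

test_that("trna_optimality handles single-codon amino acids and suppressors", {
  u <- codon_usage(c("ATGAAATAA"))
  opt <- optimal_codons(u)
  met <- data.frame(locus_tag = "t1", amino_acid = "Met", anticodon = "CAT")
  rep <- trna_optimality(met, opt)
  expect_equal(rep$n_optimal_trnas, 1L)
  expect_equal(rep$n_trnas, 1L)

  sup <- data.frame(locus_tag = "t8", amino_acid = "Sup", anticodon = "CTA")
  rep <- trna_optimality(sup, opt)
  expect_equal(rep$per_trna$decoded, "TAG")
  expect_equal(rep$n_optimal_trnas, 0L)
  expect_equal(rep$n_trnas, 1L)
})

test_that("the default low-GC tRNA set decodes 4 of 8 A-ending codons", {
  tr <- default_trna_set()
  tr$locus_tag <- paste0("t", seq_len(nrow(tr)))
  u <- codon_usage(c("ATGAAATAA"))
  rep <- trna_optimality(tr, optimal_codons(u))
  expect_equal(rep$n_trnas, 8L)
  expect_equal(rep$n_a_ending, 4L)
})

test_that("CAI follows the geometric-mean definition", {
  # gene using only optimal codons scores 1
  ref <- c(rep("AAA", 10), rep("AAG", 5), rep("GAA", 8), rep("GAG", 2))
  u <- codon_usage(paste(ref, collapse = ""))
  expect_equal(cai("AAAGAA", u), 1.0)
  # single-codon-type gene with w = 0.5
  expect_equal(cai("AAG", u), 0.5)
  # random gene equals the direct product formula
  set.seed(15)
  seqs <- vapply(1:40, function(i) paste0("ATG", random_dna(120), "TAA"), character(1))
  u <- codon_usage(seqs)
  gene <- paste0("ATG", random_dna(90), "TAA")
  got <- cai(gene, u)
  code <- Biostrings::getGeneticCode("11")
  names(code) <- gsub("U", "T", names(code))
  w <- numeric(0)
  for (aa in unique(code)) {
    syn <- names(code)[code == aa]
    mx <- max(u$counts[syn])
    w[syn] <- if (mx > 0) u$counts[syn] / mx else NA
  }
  w[!is.na(w) & w == 0] <- 0.01
  single <- names(table(code))[table(code) == 1]
  cods <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
  keep <- !(code[cods] %in% c("*", single)) & !is.na(w[cods])
  expect_equal(got, prod(w[cods[keep]])^(1 / sum(keep)), tolerance = 1e-9)
  # scale invariance
  u2 <- u
  u2$counts <- u$counts * 7L
  expect_equal(cai(gene, u2), got, tolerance = 1e-12)
})

test_that("compare_trnas reports coverage/identity above thresholds", {
  set.seed(16)
  t1 <- random_dna(76, gc = 0.5)
  a <- data.frame(locus_tag = "a1", sequence = t1)
  b <- data.frame(locus_tag = "b1", sequence = t1)
  hit <- compare_trnas(a, b)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$coverage, 100)
  expect_equal(hit$identity, 100)

  # ~20% mutated copy: identity near 80%
  mut <- strsplit(t1, "")[[1]]
  at <- sample(76, 15)
  mut[at] <- vapply(mut[at], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
  b2 <- data.frame(locus_tag = "b2", sequence = paste(mut, collapse = ""))
  hit <- compare_trnas(a, b2)
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$identity, 70)
  expect_lt(hit$identity, 92)

  # unrelated random 76-mers: nothing above both thresholds
  hits <- 0L
  for (i in 1:30) {
    x <- data.frame(locus_tag = "x", sequence = random_dna(76))
    y <- data.frame(locus_tag = "y", sequence = random_dna(76))
    hits <- hits + nrow(compare_trnas(x, y))
  }
  expect_equal(hits, 0L)
})

test_that("tRNA genes planted by the generator carry their anticodons", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 15, seed = 18))
  ft <- g$record$features
  tr <- ft[ft$kind == "tRNA", ]
  expect_equal(nrow(tr), 8L)
  expect_true(all(tr$strand == "-"))
  for (i in seq_len(nrow(tr))) {
    coding <- feature_sequence(g$record, tr[i, ])
    expect_equal(substr(coding, 33, 35), tr$anticodon[i])
  }
})
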