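test_that("read_fasta normalises case and RNA and preserves entry order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(nchar(recs[[1]]$sequence), 4L)

  writeLines(c(">g1", "acgu"), f)
  expect_equal(read_fasta(f)[[1]]$sequence, "ACGT")

  writeLines(c(">a", "ACGT", ">b", "GGCC", "TTAA"), f)
  recs <- read_fasta(f)
  expect_equal(names(recs), c("a", "b"))
  expect_equal(recs$b$sequence, "GGCCTTAA")
})

test_that("read_fasta rejects empty files and names offending positions", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">g1", "ACGJGT"), f)
  expect_error(read_fasta(f), "position 4")
})

test_that("FASTA write/read round trip is exact", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 15, seed = 11))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g$record, f)
  back <- read_fasta(f)[[1]]
  expect_identical(back$sequence, g$record$sequence)
  expect_identical(back$id, g$record$id)
})

test_that("feature_sequence handles strand, wrap and the circular junction", {
  rec <- genome_record("t", "AACGTT")
  plus <- list(start = 2L, end = 4L, strand = "+", wraps = FALSE)
  minus <- list(start = 2L, end = 4L, strand = "-", wraps = FALSE)
  expect_equal(feature_sequence(rec, plus), "ACG")
  expect_equal(feature_sequence(rec, minus), "CGT")

  # wrap oracle: rotating the genome so the feature becomes contiguous
  s <- "ACGTACGTAC"  # length 10
  circ <- genome_record("c", s)
  wrapped <- list(start = 9L, end = 2L, strand = "+", wraps = TRUE)
  got <- feature_sequence(circ, wrapped)
  rot <- paste0(substr(s, 9, 10), substr(s, 1, 8))  # rotation oracle
  expect_equal(got, substr(rot, 1, 4))
  expect_equal(nchar(got), 4L)

  lin <- genome_record("l", s, topology = "linear")
  expect_error(feature_sequence(lin, wrapped), "linear")
})

test_that("non-wrapped feature sequences have length end - start + 1", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 15, seed = 4))
  ft <- g$record$features
  for (i in seq_len(nrow(ft))) {
    if (ft$wraps[i]) next
    expect_equal(nchar(feature_sequence(g$record, ft[i, ])),
                 ft$end[i] - ft$start[i] + 1L)
  }
})

test_that("reverse_complement is an involution", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("translate_cds follows table 11 with start recoding and stop handling", {
  expect_equal(as.character(translate_cds("ATGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("GTGAAATAA")), "MK")
  expect_equal(as.character(translate_cds("TTGAAATAA")), "MK")
  expect_error(translate_cds("ATGAAAT"), "divisible")
  expect_warning(translate_cds("ATGTAAAAATAA"), "internal stop")
  val <- suppressWarnings(translate_cds("ATGTAAAAATAA"))
  expect_true(attr(val, "internal_stop"))
  expect_equal(as.character(val), "M*K")

  # random in-frame CDS against an independent table-lookup oracle
  set.seed(42)
  for (i in 1:10) {
    body <- random_dna(297)
    cds <- paste0("ATG", body)
    got <- suppressWarnings(as.character(translate_cds(cds)))
    exp <- oracle_translate(cds)
    exp <- sub("\\*$", "", exp)
    substr(exp, 1, 1) <- "M"
    expect_identical(got, exp)
  }
})

test_that("GenBank write/read round trip preserves sequence and features", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 15, seed = 9))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, f)
  back <- read_annotations(f, "genbank")
  expect_identical(back$sequence, g$record$sequence)
  expect_identical(back$topology, "circular")
  cols <- c("locus_tag", "kind", "start", "end", "strand")
  expect_identical(back$features[, cols], g$record$features[, cols])
  expect_identical(back$features$anticodon, g$record$features$anticodon)
})

test_that("a join location wrapping the circular junction becomes one wrapped feature", {
  s <- paste(rep("ACGTACGTGG", 30), collapse = "")  # 300 nt
  ft <- feature_table(locus_tag = "w1", kind = "CDS", start = 271L, end = 60L,
                      strand = "+", wraps = TRUE)
  rec <- genome_record("wrapped", s, features = ft)
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, f)
  back <- read_annotations(f, "genbank")
  expect_equal(nrow(back$features), 1L)
  expect_true(back$features$wraps[1])
  expect_equal(back$features$start[1], 271L)
  expect_equal(back$features$end[1], 60L)
  expect_equal(nchar(feature_sequence(back, back$features[1, ])), 90L)
})

test_that("GFF3 + FASTA yields the same feature set as the equivalent GenBank", {
  g <- generate_genome(genome_spec(length_bp = 12000, n_genes = 15, seed = 13))
  fgb <- withr::local_tempfile(fileext = ".gb")
  fgff <- withr::local_tempfile(fileext = ".gff3")
  write_genbank(g$record, fgb)
  write_gff3(g$record, fgff)
  a <- read_annotations(fgb, "genbank")
  b <- read_annotations(fgff, "gff3")
  cols <- c("locus_tag", "kind", "start", "end", "strand", "anticodon")
  fa <- a$features[, cols]
  fb <- b$features[, cols]
  rownames(fa) <- rownames(fb) <- NULL
  expect_identical(fa, fb)
  expect_identical(a$sequence, b$sequence)
})

test_that("malformed CDSs are kept but flagged", {
  s <- strrep("ACGTACGTGG", 40)
  ft <- feature_table(locus_tag = c("ok", "bad"), kind = "CDS",
                      start = c(1L, 101L), end = c(90L, 200L),
                      strand = "+", wraps = FALSE)
  rec <- genome_record("m", s, features = ft)
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, f)
  back <- read_annotations(f, "genbank")
  expect_identical(back$features$malformed, c(FALSE, TRUE))
})
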