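#' Genome records and feature tables
#'
#' A `GenomeRecord` is the unit every analysis stage consumes: a nucleotide
#' sequence (circular by default, as for phage genomes deposited as a single
#' closed sequence), plus a feature table of CDS and tRNA annotations with
#' 1-based inclusive coordinates.
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide string over A/C/G/T/N (IUPAC codes tolerated).
#' @param topology `"circular"` or `"linear"`.
#' @param features Feature table as built by [feature_table()].
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear"),
                          features = feature_table()) {
  topology <- match.arg(topology)
  sequence <- chartr("U", "T", toupper(sequence))
  stopifnot(nchar(sequence) >= 1L)
  .validate_nt(sequence, id)
  rec <- structure(
    list(id = id, sequence = sequence, topology = topology, features = features),
    class = "GenomeRecord"
  )
  .validate_features(rec)
  rec
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %s bp (%s), %d CDS, %d tRNA\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology,
              sum(x$features$kind == "CDS"), sum(x$features$kind == "tRNA")))
  invisible(x)
}

#' Construct an empty or populated feature table
#'
#' Columns follow GenBank conventions: 1-based inclusive `start`/`end`,
#' `strand` in `+`/`-`. `wraps = TRUE` marks a feature crossing the circular
#' junction (its `start` > `end`). `malformed` flags CDSs whose length is not
#' divisible by 3.
#'
#' @param locus_tag,kind,start,end,strand,product,category,anticodon,amino_acid,wraps,malformed
#'   Per-feature vectors, recycled to a common length.
#' @return A data.frame with one row per feature.
#' @export
feature_table <- function(locus_tag = character(), kind = character(),
                          start = integer(), end = integer(),
                          strand = character(), product = NA_character_,
                          category = NA_character_, anticodon = NA_character_,
                          amino_acid = NA_character_, wraps = FALSE,
                          malformed = FALSE) {
  n <- length(locus_tag)
  data.frame(
    locus_tag = as.character(locus_tag), kind = as.character(kind),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    product = rep_len(as.character(product), n),
    category = rep_len(as.character(category), n),
    anticodon = rep_len(as.character(anticodon), n),
    amino_acid = rep_len(as.character(amino_acid), n),
    wraps = rep_len(as.logical(wraps), n),
    malformed = rep_len(as.logical(malformed), n),
    stringsAsFactors = FALSE
  )
}

.validate_nt <- function(seq, id = "?") {
  bad <- regexpr("[^ACGTNRYSWKMBDHV]", seq)
  if (bad > 0L) {
    stop(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                 id, substr(seq, bad, bad), bad))
  }
  invisible(TRUE)
}

.validate_features <- function(rec) {
  ft <- rec$features
  if (nrow(ft) == 0L) return(invisible(TRUE))
  L <- nchar(rec$sequence)
  if (any(ft$start < 1L | ft$start > L | ft$end < 1L | ft$end > L)) {
    stop(sprintf("record '%s': feature coordinates outside [1, %d]", rec$id, L))
  }
  if (any(ft$start > ft$end & !ft$wraps)) {
    stop(sprintf("record '%s': start > end for non-wrapping feature", rec$id))
  }
  if (any(ft$wraps) && rec$topology == "linear") {
    stop(sprintf("record '%s': wrapped feature on a linear genome", rec$id))
  }
  invisible(TRUE)
}

# Feature length in nt, accounting for circular wrap.
feature_length <- function(record, feature) {
  if (isTRUE(feature$wraps)) {
    nchar(record$sequence) - feature$start + 1L + feature$end
  } else {
    feature$end - feature$start + 1L
  }
}

#' Read a (multi-)FASTA file into GenomeRecords
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`. Characters outside
#' the IUPAC nucleotide alphabet raise an error naming the offending position.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (phage default: circular).
#' @return A list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path, topology = "circular") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("'%s': empty FASTA file", path))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop(sprintf("'%s': not a FASTA file (no leading '>')", path))
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  recs <- lapply(seq_along(ids), function(i) {
    seq <- paste(lines[grp == i & !hdr], collapse = "")
    if (nchar(seq) == 0L) stop(sprintf("'%s': entry '%s' has no sequence", path, ids[i]))
    genome_record(ids[i], seq, topology = topology)
  })
  names(recs) <- ids
  recs
}

#' Write GenomeRecords to a FASTA file
#'
#' @param records A `GenomeRecord` or list of them.
#' @param path Output path.
#' @param width Line width for the sequence.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    n <- nchar(rec$sequence)
    starts <- seq(1L, n, by = width)
    writeLines(substring(rec$sequence, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Extract the nucleotide sequence of a feature
#'
#' Minus-strand features are reverse-complemented; features wrapping the
#' circular junction are concatenated across it.
#'
#' @param record A `GenomeRecord`.
#' @param feature One row of the record's feature table (or any list with
#'   `start`, `end`, `strand`, `wraps`).
#' @return Nucleotide string on the coding strand.
#' @export
feature_sequence <- function(record, feature) {
  s <- record$sequence
  if (isTRUE(feature$wraps)) {
    if (record$topology != "circular")
      stop("wrapped feature on a linear genome")
    nt <- paste0(substr(s, feature$start, nchar(s)), substr(s, 1L, feature$end))
  } else {
    nt <- substr(s, feature$start, feature$end)
  }
  if (identical(feature$strand, "-")) nt <- reverse_complement(nt)
  nt
}

#' Translate a coding sequence
#'
#' Uses the bacterial/plastid genetic code (table 11). Alternative initiators
#' GTG/TTG are rendered as Met at position 1, the trailing stop codon is
#' stripped, and an internal stop is flagged via the `internal_stop` attribute
#' (with a warning) rather than silently dropped. Codons containing N
#' translate to `X`.
#'
#' @param cds_nt In-frame coding sequence, length >= 6 and divisible by 3.
#' @param table Genetic code id (NCBI numbering, default `"11"`).
#' @return Protein string; attribute `internal_stop` is TRUE if one was seen.
#' @export
translate_cds <- function(cds_nt, table = "11") {
  cds_nt <- toupper(chartr("U", "T", cds_nt))
  n <- nchar(cds_nt)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  if (n < 6L) stop("CDS shorter than 6 nt")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_nt),
    genetic.code = Biostrings::getGeneticCode(table),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  # start-codon recoding: initiator GTG/TTG (and ATG) read as fMet
  if (substr(cds_nt, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    substr(aa, 1L, 1L) <- "M"
  if (substr(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  internal <- grepl("*", aa, fixed = TRUE)
  if (internal) warning("internal stop codon in CDS")
  attr(aa, "internal_stop") <- internal
  aa
}

#' Read genome annotations (GenBank flat file or GFF3+FASTA)
#'
#' Populates CDS and tRNA features; all other feature kinds are skipped and
#' counted in the `skipped_kinds` attribute. CDSs whose length is not
#' divisible by 3 are kept but flagged `malformed`.
#'
#' @param path Path to a GenBank flat file or a GFF3 file with a `##FASTA`
#'   section.
#' @param fmt `"genbank"` or `"gff3"`.
#' @return A [genome_record()].
#' @export
read_annotations <- function(path, fmt = c("genbank", "gff3")) {
  fmt <- match.arg(fmt)
  rec <- if (fmt == "genbank") .read_genbank(path) else .read_gff3(path)
  # flag malformed CDSs and check coordinates
  ft <- rec$features
  if (nrow(ft) > 0L) {
    lens <- vapply(seq_len(nrow(ft)), function(i) feature_length(rec, ft[i, ]), integer(1))
    ft$malformed <- ft$kind == "CDS" & (lens %% 3L != 0L)
    rec$features <- ft
  }
  .validate_features(rec)
  rec
}

# --- GenBank flat file ------------------------------------------------------
# Minimal parser: LOCUS (length + topology), FEATURES (CDS/tRNA with
# complement()/join() locations and /locus_tag /product /anticodon /note
# qualifiers), ORIGIN sequence. Other feature kinds are counted and skipped.

.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop(sprintf("'%s': no LOCUS line", path))
  topo <- if (grepl("circular", locus[1], ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop(sprintf("'%s': no ORIGIN section", path))
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seq <- paste(gsub("[^A-Za-z]", "", lines[(ostart[1] + 1L):(oend - 1L)]), collapse = "")

  feats <- feature_table()
  skipped <- integer(0)
  if (length(fstart) > 0L) {
    flines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # a new feature starts with a key in column 6 (5 leading spaces, non-space)
    is_key <- grepl("^ {5}\\S", flines)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L else length(flines))]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (!key %in% c("CDS", "tRNA")) {
        skipped[key] <- (if (is.na(skipped[key])) 0L else skipped[key]) + 1L
        names(skipped)[is.na(names(skipped))] <- key
        next
      }
      # location may continue over lines until the first qualifier line
      body <- c(sub("^\\s*\\S+\\s*", "", block[1]), trimws(block[-1]))
      qual_at <- grep("^/", body)
      loc_str <- paste(body[seq_len(if (length(qual_at)) qual_at[1] - 1L else length(body))],
                       collapse = "")
      loc <- .parse_gb_location(loc_str, nchar(seq))
      q <- .parse_gb_qualifiers(body[if (length(qual_at)) qual_at[1]:length(body) else integer(0)])
      aa3 <- NA_character_
      if (key == "tRNA" && !is.na(q["product"]) && grepl("^tRNA-", q["product"]))
        aa3 <- sub("^tRNA-", "", q["product"])
      anticodon <- if (key == "tRNA") .parse_anticodon(q) else NA_character_
      feats <- rbind(feats, feature_table(
        locus_tag = if (!is.na(q["locus_tag"])) q["locus_tag"] else sprintf("feat%03d", k),
        kind = key, start = loc$start, end = loc$end, strand = loc$strand,
        product = unname(q["product"]), anticodon = anticodon, amino_acid = aa3,
        wraps = loc$wraps
      ))
    }
  }
  rec <- genome_record(id, seq, topology = topo, features = feats)
  attr(rec, "skipped_kinds") <- skipped
  rec
}

.parse_gb_location <- function(loc, genome_len) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  segs <- strsplit(loc, ",")[[1]]
  pos <- lapply(segs, function(s) {
    m <- regmatches(s, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", s))[[1]]
    if (length(m) == 0L) {
      m1 <- regmatches(s, regexec("^[<>]?(\\d+)$", s))[[1]]
      if (length(m1) == 0L) stop(sprintf("unparseable location segment '%s'", s))
      as.integer(c(m1[2], m1[2]))
    } else as.integer(c(m[2], m[3]))
  })
  starts <- vapply(pos, `[`, integer(1), 1L)
  ends <- vapply(pos, `[`, integer(1), 2L)
  if (any(starts > genome_len | ends > genome_len | starts < 1L))
    stop("feature coordinates outside sequence")
  wraps <- length(segs) > 1L && starts[length(starts)] < starts[1]
  if (wraps) {
    list(start = starts[1], end = ends[length(ends)], strand = strand, wraps = TRUE)
  } else {
    list(start = min(starts), end = max(ends), strand = strand, wraps = FALSE)
  }
}

.parse_gb_qualifiers <- function(qlines) {
  out <- c(locus_tag = NA_character_, product = NA_character_,
           anticodon = NA_character_, note = NA_character_)
  if (length(qlines) == 0L) return(out)
  # re-join continuation lines onto their qualifier
  joined <- character(0)
  for (ln in qlines) {
    if (grepl("^/", ln) || length(joined) == 0L) joined <- c(joined, ln)
    else joined[length(joined)] <- paste(joined[length(joined)], ln)
  }
  for (ln in joined) {
    m <- regmatches(ln, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(out)) out[m[2]] <- m[3]
  }
  out
}

.parse_anticodon <- function(q) {
  # /anticodon=(pos:...,aa:Trp,seq:cca) or a bare 3-mer in /anticodon or /note
  for (field in c("anticodon", "note")) {
    v <- q[field]
    if (is.na(v)) next
    m <- regmatches(v, regexec("seq:([acgtuACGTU]{3})", v))[[1]]
    if (length(m) == 2L) return(toupper(chartr("Uu", "Tt", m[2])))
    m <- regmatches(v, regexec("^([ACGTUacgtu]{3})$", v))[[1]]
    if (length(m) == 2L) return(toupper(chartr("Uu", "Tt", m[2])))
  }
  NA_character_
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Minimal LOCUS/FEATURES/ORIGIN writer sufficient for round-tripping the
#' package's own records (wrapped features are emitted as
#' `join(start..L,1..end)`).
#'
#' @param record A `GenomeRecord`.
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- nchar(record$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   PHG",
                     record$id, L, record$topology), con)
  writeLines(sprintf("DEFINITION  %s.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    loc <- if (isTRUE(f$wraps)) sprintf("join(%d..%d,1..%d)", f$start, L, f$end)
           else sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", f$kind, loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', f$locus_tag), con)
    if (!is.na(f$product))
      writeLines(sprintf('                     /product="%s"', f$product), con)
    if (f$kind == "tRNA" && !is.na(f$anticodon))
      writeLines(sprintf('                     /anticodon="(aa:%s,seq:%s)"',
                         if (is.na(f$amino_acid)) "Xaa" else f$amino_acid,
                         tolower(f$anticodon)), con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substring(record$sequence, off + seq(0L, 50L, by = 10L),
                       pmin(off + seq(9L, 59L, by = 10L), L))
    chunk <- chunk[nzchar(chunk)]
    writeLines(sprintf("%9d %s", off, tolower(paste(chunk, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# --- GFF3 + ##FASTA ---------------------------------------------------------

.read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fa_at <- grep("^##FASTA", lines)
  if (length(fa_at) == 0L) stop(sprintf("'%s': GFF3 lacks a ##FASTA section", path))
  gff_tmp <- tempfile(fileext = ".gff3")
  fa_tmp <- tempfile(fileext = ".fa")
  writeLines(lines[seq_len(fa_at[1] - 1L)], gff_tmp)
  writeLines(lines[(fa_at[1] + 1L):length(lines)], fa_tmp)
  on.exit(unlink(c(gff_tmp, fa_tmp)))
  recs <- read_fasta(fa_tmp)
  gr <- rtracklayer::import(gff_tmp, format = "gff3")
  topo <- "circular"
  if (any(grepl("Is_circular=false", lines, ignore.case = TRUE))) topo <- "linear"
  keep <- as.character(gr$type) %in% c("CDS", "tRNA")
  skipped <- table(as.character(gr$type)[!keep])
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  getcol <- function(nm) if (nm %in% colnames(md)) as.character(md[[nm]]) else rep(NA_character_, length(gr))
  feats <- feature_table(
    locus_tag = {
      lt <- getcol("locus_tag")
      ifelse(is.na(lt), getcol("ID"), lt)
    },
    kind = as.character(gr$type),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    product = getcol("product"),
    anticodon = toupper(chartr("Uu", "Tt", getcol("anticodon"))),
    amino_acid = getcol("amino_acid")
  )
  rec <- recs[[1]]
  rec$topology <- topo
  rec$features <- feats
  attr(rec, "skipped_kinds") <- skipped
  .validate_features(rec)
  rec
}

#' Write a GenomeRecord as GFF3 with an embedded FASTA section
#'
#' @param record A `GenomeRecord`.
#' @param path Output path.
#' @export
write_gff3 <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", record$id, nchar(record$sequence)), con)
  ft <- record$features
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    if (isTRUE(f$wraps)) stop("GFF3 output does not support junction-wrapping features")
    attrs <- sprintf("ID=%s;locus_tag=%s", f$locus_tag, f$locus_tag)
    if (!is.na(f$product)) attrs <- paste0(attrs, ";product=", f$product)
    if (!is.na(f$anticodon)) attrs <- paste0(attrs, ";anticodon=", f$anticodon)
    if (!is.na(f$amino_acid)) attrs <- paste0(attrs, ";amino_acid=", f$amino_acid)
    writeLines(paste(record$id, "phagecomp", f$kind, f$start, f$end, ".",
                     f$strand, if (f$kind == "CDS") "0" else ".", attrs,
                     sep = "\t"), con)
  }
  writeLines("##FASTA", con)
  writeLines(paste0(">", record$id), con)
  n <- nchar(record$sequence)
  starts <- seq(1L, n, by = 70L)
  writeLines(substring(record$sequence, starts, pmin(starts + 69L, n)), con)
  invisible(path)
}

#' Extract all CDS coding sequences (and translations) from a record
#'
#' Convenience accessor used throughout the comparative stages. Malformed
#' CDSs (length not divisible by 3) are dropped with a count attribute.
#'
#' @param record A `GenomeRecord`.
#' @return Named list with `cds` (named character vector of nt sequences) and
#'   `protein` (named character vector of translations, stops stripped).
#' @export
cds_sequences <- function(record) {
  ft <- record$features[record$features$kind == "CDS", , drop = FALSE]
  nt <- character(0); aa <- character(0); dropped <- 0L
  for (i in seq_len(nrow(ft))) {
    s <- feature_sequence(record, ft[i, ])
    if (nchar(s) %% 3L != 0L || nchar(s) < 6L) { dropped <- dropped + 1L; next }
    nt[ft$locus_tag[i]] <- s
    aa[ft$locus_tag[i]] <- suppressWarnings(as.character(translate_cds(s)))
  }
  out <- list(cds = nt, protein = aa)
  attr(out, "dropped") <- dropped
  out
}
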