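#' Reverse-complement a nucleotide string
#'
#' Plain-character wrapper around the usual complement table; accepts IUPAC
#' ambiguity codes.
#'
#' @param x Single nucleotide string (A/C/G/T/N and IUPAC codes).
#' @return The reverse complement, same case-insensitive alphabet, upper-cased.
#' @export
#' @examples
#' reverse_complement("AACGTT")
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# Run code with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Split a string into its in-frame codons. No validation beyond length.
codons_of <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, by = 3L), pmin(seq(3L, n + 2L, by = 3L), n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Genetic code table 11 as a named character vector codon -> single-letter aa
# ('*' for stops). Bacterial/plastid code shares codon assignments with the
# standard table; the difference is in permitted initiators, handled separately.
genetic_code_11 <- function() {
  gc <- Biostrings::getGeneticCode("11")
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

# 3-letter (plus Sup/Pyl) to 1-letter amino-acid codes as used in tRNA tables.
AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q", Glu = "E",
  Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K", Met = "M", Phe = "F",
  Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Sup = "*", Pyl = "O", Sec = "U"
)

# Length of the union of 1-based inclusive intervals, clipping duplicates.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  sum(IRanges::width(ir))
}
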