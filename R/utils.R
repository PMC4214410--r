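#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Generate a random DNA sequence
#'
#' @param length sequence length in bp.
#' @return a single character string over A/C/G/T.
#' @keywords internal
random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

## run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Derive a per-stage seed from a global seed
#'
#' A fixed integer derivation (documented so runs are reproducible): the global
#' seed is combined with a stage index via a multiplicative hash and reduced
#' modulo 2^31 - 1. Changing the global seed changes every stage seed; two
#' stages never share a seed for the same global seed.
#'
#' @param seed global integer seed.
#' @param stage stage name (character) or index (integer).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, merge = 2L, scaffold = 3L, profile = 4L,
              selection = 5L, mite = 6L, reads = 7L, bac = 8L,
              expression = 9L, divergence = 10L, diploid = 11L,
              genome = 12L, mites = 13L, fragment = 14L)
  idx <- if (is.character(stage)) {
    if (!stage %in% names(stages)) {
      # fall back to a stable hash of the name
      sum(utf8ToInt(stage)) %% 1000L + 100L
    } else stages[[stage]]
  } else as.integer(stage)
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + idx * 69621) %% (m - 1) + 1)
}

## simple assertion helper
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

## split a genome string at 1-based positions into substrings [start, end]
substr_vec <- function(x, start, end) {
  substring(x, start, end)
}

## translate DNA (length divisible by 3) to amino acids; ambiguous codons -> X
translate_cds <- function(cds) {
  gc <- genetic_code()
  vapply(cds, function(x) {
    n <- nchar(x)
    cods <- substring(x, seq(1, n, 3), seq(3, n, 3))
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## the standard genetic code as a named vector codon -> one-letter amino acid
genetic_code <- function() Biostrings::GENETIC_CODE

## BLOSUM62 substitution matrix from Biostrings, loaded once
blosum62 <- function() {
  if (is.null(.domestigen_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .domestigen_env$blosum62 <- get("BLOSUM62", envir = e)
  }
  .domestigen_env$blosum62
}

## all 61 sense codons
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}
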