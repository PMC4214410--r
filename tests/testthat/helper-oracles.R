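# Independent oracles used by the tests. These re-derive expected values by
# brute force (recursive enumeration, direct dynamic programming) and stay
# independent of the implementation paths they check.

ORACLE_GC <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")

## synonymous site count of one codon (mutations to stop count nonsynonymous)
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(ORACLE_BASES, ch[p])) {
      alt <- ch
      alt[p] <- b
      ac <- paste(alt, collapse = "")
      if (ORACLE_GC[[ac]] != "*" && ORACLE_GC[[ac]] == ORACLE_GC[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

## recursive enumeration of all mutational pathways between two codons;
## returns pathway-averaged (syn, nonsyn) counts, excluding pathways through
## stop codons when any stop-free pathway exists
oracle_path_counts <- function(c1, c2) {
  walk <- function(cur) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(d) == 0) return(list(list(s = 0, n = 0, ok = TRUE)))
    out <- list()
    for (p in d) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      syn <- ORACLE_GC[[cur]] == ORACLE_GC[[nxt]]
      for (tailpath in walk(nxt)) {
        out[[length(out) + 1]] <- list(
          s = tailpath$s + as.numeric(syn),
          n = tailpath$n + as.numeric(!syn),
          ok = tailpath$ok && (ORACLE_GC[[nxt]] != "*" || nxt == c2))
      }
    }
    out
  }
  paths <- walk(c1)
  ok <- vapply(paths, `[[`, logical(1), "ok")
  use <- if (any(ok)) paths[ok] else paths
  c(s = mean(vapply(use, `[[`, numeric(1), "s")),
    n = mean(vapply(use, `[[`, numeric(1), "n")))
}

## full NG86 Ka/Ks on two aligned codon vectors, by enumeration
oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  sd <- nd <- 0
  for (i in seq_along(codons_a)) {
    if (codons_a[i] == codons_b[i]) next
    pc <- oracle_path_counts(codons_a[i], codons_b[i])
    sd <- sd + pc[["s"]]
    nd <- nd + pc[["n"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(ka = jc(nd / N), ks = jc(sd / S), sd = sd, nd = nd,
       s_sites = S, n_sites = N)
}

## affine-gap global protein alignment score (maximisation), same penalties as
## Biostrings::pairwiseAlignment: a gap of length L costs opening + L * ext
oracle_nw_score <- function(a, b, mat, opening = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -opening - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -opening - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - opening - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - opening - ext)
      Y[i, j] <- max(M[i, j - 1] - opening - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - opening - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## random DNA convenience for tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## random valid ORF of m codons
rand_orf <- function(m) {
  sense <- setdiff(names(ORACLE_GC)[ORACLE_GC != "*"], character(0))
  paste(c("ATG", sample(sense, m - 2, replace = TRUE), "TAA"), collapse = "")
}

## dinucleotide shuffle of a sequence (simple pairwise-swap shuffle preserving
## dinucleotide composition approximately; adequate as an empirical null)
dinucleotide_shuffle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch) - (length(ch) %% 2)
  pairs <- vapply(seq(1, n, 2), function(i) paste0(ch[i], ch[i + 1]),
                  character(1))
  paste(sample(pairs), collapse = "")
}

## run code under a fixed seed without disturbing the test RNG stream
with_seed_for_tests <- function(seed, code) withr::with_seed(seed, code)
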