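# Differential expression between the two genotype groups and the association
# of cultivar-specific upstream MITE insertions with expression suppression.

#' Median-of-ratios library size factors
#'
#' @param counts genes x samples count matrix.
#' @return numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  check_that(any(pos), "no gene is expressed in every sample")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2, function(col) exp(median(col - geo)))
}

#' Two-group differential expression on log counts
#'
#' Library sizes are normalised by median-of-ratios factors; a two-sided Welch
#' t-test is applied per gene on log2(normalised count + 1), with
#' Benjamini-Hochberg adjustment across genes. The call is "lower" or "higher"
#' (second group versus first) by sign at adjusted p <= alpha.
#'
#' @param counts genes x samples count matrix.
#' @param groups factor of length ncol(counts) with two levels; the first level
#'   is the baseline (wild) group.
#' @param alpha adjusted-p threshold.
#' @return data.frame gene, log2fc, t, p, padj, call.
#' @export
diff_expression <- function(counts, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  check_that(nlevels(groups) == 2, "need exactly two groups")
  check_that(all(table(groups) >= 2), "need >= 2 replicates per group")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  x <- log2(norm + 1)
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, g2, drop = FALSE], 1, var)
  se <- sqrt(v1 / n1 + v2 / n2)
  tstat <- (m2 - m1) / se
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  padj <- p.adjust(p, method = "BH")
  call <- rep("none", nrow(counts))
  sig <- !is.na(padj) & padj <= alpha
  call[sig & m2 < m1] <- "lower"
  call[sig & m2 > m1] <- "higher"
  data.frame(gene = rownames(counts), log2fc = m2 - m1, t = tstat, p = p,
             padj = padj, call = call, stringsAsFactors = FALSE)
}

#' Associate lineage-specific MITE insertions with expression differences
#'
#' Restricted to cultivar-specific insertions: tallies how many of their genes
#' are called significantly lower / higher in the cultivar group.
#'
#' @param presence presence table from [compare_presence()].
#' @param de differential-expression table from [diff_expression()].
#' @param specific_label which status counts as lineage-specific.
#' @param alpha the threshold used by the DE step (recorded in the summary).
#' @return list with counts and fractions over the restricted set.
#' @export
associate <- function(presence, de, specific_label = "cultivar-specific",
                      alpha = 0.05) {
  spec <- unique(presence$gene[presence$status == specific_label])
  calls <- setNames(de$call, de$gene)[spec]
  n_lower <- sum(calls == "lower", na.rm = TRUE)
  n_higher <- sum(calls == "higher", na.rm = TRUE)
  n <- length(spec)
  list(n_specific = n, n_lower = n_lower, n_higher = n_higher,
       n_none = n - n_lower - n_higher,
       frac_lower = if (n > 0) n_lower / n else 0,
       frac_higher = if (n > 0) n_higher / n else 0,
       alpha = alpha)
}

#' Permutation test for MITE-expression association
#'
#' Tests whether the fraction of genes called "lower" among MITE-bearing genes
#' exceeds what random gene sets of the same size show.
#'
#' @param de differential-expression table from [diff_expression()].
#' @param mite_genes gene ids carrying a cultivar-specific upstream insertion.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with observed fraction, permutation p-value (one-sided,
#'   enrichment) and the null fractions.
#' @export
permutation_association <- function(de, mite_genes, n_perm = 1000, seed = 1L) {
  genes <- de$gene
  m <- sum(genes %in% mite_genes)
  if (m == 0) return(list(observed = 0, p = 1, null = numeric(0)))
  lower <- de$call == "lower"
  obs <- sum(lower[genes %in% mite_genes]) / m
  with_seed(derive_seed(seed, "expression"), {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(genes), m)
      sum(lower[idx]) / m
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(observed = obs, p = p, null = null)
}
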