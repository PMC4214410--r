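#' Simulate negative-binomial expression counts for two groups
#'
#' Genes carrying a cultivar-specific upstream MITE have their cultivar group
#' mean shifted by `suppression_log2fc`; all other genes have equal means in
#' both groups. Counts are negative-binomial with the stated dispersion
#' (variance = mu + dispersion * mu^2).
#'
#' @param gene_ids character vector of gene identifiers.
#' @param mite_genes ids of genes with a cultivar-specific upstream insertion.
#' @param suppression_log2fc log2 fold change applied to the cultivar mean of
#'   `mite_genes` (negative = suppression).
#' @param nb_dispersion negative-binomial dispersion.
#' @param n_replicates replicates per group (>= 2).
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   means.
#' @return list with `counts` (genes x samples matrix), `groups` (factor), and
#'   `truth` (gene, mu_wild, mu_cultivar, log2fc).
#' @export
simulate_expression <- function(gene_ids, mite_genes = character(0),
                                suppression_log2fc = -2, nb_dispersion = 0.05,
                                n_replicates = 5, seed = 1L,
                                baseline_meanlog = log(200),
                                baseline_sdlog = 0.8) {
  check_that(n_replicates >= 2, "need >= 2 replicates per group")
  n <- length(gene_ids)
  with_seed(derive_seed(seed, "expression"), {
    mu <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    mu_w <- mu
    mu_c <- mu
    hit <- gene_ids %in% mite_genes
    mu_c[hit] <- mu[hit] * 2^suppression_log2fc
    size <- 1 / nb_dispersion
    counts <- matrix(0L, n, 2 * n_replicates)
    for (r in seq_len(n_replicates)) {
      counts[, r] <- rnbinom(n, mu = mu_w, size = size)
      counts[, n_replicates + r] <- rnbinom(n, mu = mu_c, size = size)
    }
  })
  rownames(counts) <- gene_ids
  colnames(counts) <- c(paste0("wild_", seq_len(n_replicates)),
                        paste0("cultivar_", seq_len(n_replicates)))
  groups <- factor(rep(c("wild", "cultivar"), each = n_replicates),
                   levels = c("wild", "cultivar"))
  truth <- data.frame(gene = gene_ids, mu_wild = mu_w, mu_cultivar = mu_c,
                      log2fc = ifelse(hit, suppression_log2fc, 0),
                      stringsAsFactors = FALSE)
  list(counts = counts, groups = groups, truth = truth)
}
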