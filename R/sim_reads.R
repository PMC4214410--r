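# Read simulation: tiered paired-end / mate-pair libraries drawn from one or
# two haplotypes in inward (FR) orientation with uniform substitution errors,
# and BAC clones with end reads plus the FPC clone-order map.

#' Simulate tiered paired reads
#'
#' Pairs are drawn uniformly from the given haplotypes in inward orientation.
#' The number of pairs is set so realized coverage equals the requested
#' coverage; errors are uniform substitutions. A fraction of pairs can be made
#' chimeric (mate drawn from an unrelated position) to emulate library noise.
#'
#' @param haplotypes character vector of 1 or 2 sequences.
#' @param insert_tiers data.frame with columns mean, sd, coverage.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param chimera_rate fraction of pairs whose mate is drawn at random.
#' @return list of tiers; each tier has `read1`, `read2` (character vectors),
#'   `insert_mean`, `insert_sd`, `coverage`, and a `truth` data.frame (hap,
#'   start, insert, chimeric).
#' @export
simulate_reads <- function(haplotypes, insert_tiers, read_length = 100,
                           error_rate = 0, seed = 1L, chimera_rate = 0) {
  rl <- as.integer(read_length)
  check_that(all(insert_tiers$mean > 2 * rl), "insert mean must exceed 2x read length")
  Ls <- nchar(haplotypes)
  check_that(all(insert_tiers$mean < min(Ls)), "insert exceeds genome length")
  G <- mean(Ls)
  out <- vector("list", nrow(insert_tiers))
  with_seed(derive_seed(seed, "reads"), {
    for (t in seq_len(nrow(insert_tiers))) {
      mu <- insert_tiers$mean[t]; sdv <- insert_tiers$sd[t]
      cov <- insert_tiers$coverage[t]
      n <- as.integer(round(cov * G / (2 * rl)))
      hap <- sample.int(length(haplotypes), n, replace = TRUE)
      ins <- pmax(2L * rl + 2L, as.integer(round(rnorm(n, mu, sdv))))
      ins <- pmin(ins, Ls[hap])
      start <- floor(runif(n) * (Ls[hap] - ins + 1)) + 1L
      r1 <- character(n); r2 <- character(n)
      for (h in seq_along(haplotypes)) {
        sel <- hap == h
        if (!any(sel)) next
        r1[sel] <- cpp_extract_subseqs(haplotypes[h], start[sel],
                                       rep(rl, sum(sel)), rep(FALSE, sum(sel)))
        r2[sel] <- cpp_extract_subseqs(haplotypes[h],
                                       start[sel] + ins[sel] - rl,
                                       rep(rl, sum(sel)), rep(TRUE, sum(sel)))
      }
      chim <- rep(FALSE, n)
      if (chimera_rate > 0) {
        chim <- runif(n) < chimera_rate
        nc <- sum(chim)
        if (nc > 0) {
          h2 <- sample.int(length(haplotypes), nc, replace = TRUE)
          s2 <- floor(runif(nc) * (Ls[h2] - rl + 1)) + 1L
          rc2 <- sample(c(TRUE, FALSE), nc, replace = TRUE)
          r2[chim] <- unlist(lapply(seq_len(nc), function(i)
            cpp_extract_subseqs(haplotypes[h2[i]], s2[i], rl, rc2[i])))
        }
      }
      if (error_rate > 0) {
        for (which_read in 1:2) {
          rr <- if (which_read == 1) r1 else r2
          nerr <- rbinom(n, rl, error_rate)
          tot <- sum(nerr)
          if (tot > 0) {
            idx <- rep.int(seq_len(n), nerr)
            pos <- sample.int(rl, tot, replace = TRUE)
            shift <- sample.int(3L, tot, replace = TRUE)
            rr <- cpp_apply_errors(rr, idx, pos, shift)
          }
          if (which_read == 1) r1 <- rr else r2 <- rr
        }
      }
      out[[t]] <- list(read1 = r1, read2 = r2, insert_mean = mu,
                       insert_sd = sdv, coverage = cov, read_length = rl,
                       truth = data.frame(hap = hap, start = start,
                                          insert = ins, chimeric = chim))
    }
  })
  out
}

#' Simulate a BAC library with end reads and an FPC clone-order map
#'
#' Clone start positions are uniform; insert sizes normal around the configured
#' mean. End reads are taken from the two insert ends (the 3' end read is
#' reported on the minus strand, i.e. reading outward provenance is recorded).
#' The FPC map lists clones grouped into map contigs (split at clone-coverage
#' gaps) and ordered by true insert midpoint; fingerprinting chemistry is
#' abstracted away, only clone order is produced.
#'
#' @param genome character scalar.
#' @param n_clones number of BAC clones.
#' @param insert_mean,insert_sd clone insert size in bp.
#' @param end_read_length end read length in bp.
#' @param seed integer seed.
#' @return list with `end_reads` (data.frame clone_id, end, seq), `fpc_map`
#'   (data.frame clone_id, map_contig, order_index), and `truth` (clone
#'   coordinates).
#' @export
simulate_bac_and_fpc <- function(genome, n_clones, insert_mean = 115000,
                                 insert_sd = 10000, end_read_length = 500,
                                 seed = 1L) {
  L <- nchar(genome)
  check_that(insert_mean < L, "BAC insert must be shorter than the genome")
  erl <- as.integer(end_read_length)
  with_seed(derive_seed(seed, "bac"), {
    ins <- pmax(4L * erl, pmin(as.integer(round(rnorm(n_clones, insert_mean,
                                                      insert_sd))), L))
    start <- floor(runif(n_clones) * (L - ins + 1)) + 1L
    end <- start + ins - 1L
  })
  clone_id <- sprintf("BAC%05d", seq_len(n_clones))
  e1 <- cpp_extract_subseqs(genome, start, rep(erl, n_clones),
                            rep(FALSE, n_clones))
  e2 <- cpp_extract_subseqs(genome, end - erl + 1L, rep(erl, n_clones),
                            rep(TRUE, n_clones))
  end_reads <- data.frame(clone_id = rep(clone_id, 2),
                          end = rep(c(1L, 2L), each = n_clones),
                          seq = c(e1, e2), stringsAsFactors = FALSE)
  # FPC: order by midpoint, break map contigs at coverage gaps
  mid <- (start + end) / 2
  ord <- order(mid)
  s_o <- start[ord]; e_o <- end[ord]
  map_contig <- integer(n_clones)
  mc <- 1L; reach <- e_o[1]
  map_contig[1] <- 1L
  for (i in seq_len(n_clones)[-1]) {
    if (s_o[i] > reach) mc <- mc + 1L
    map_contig[i] <- mc
    reach <- max(reach, e_o[i])
  }
  order_index <- stats::ave(seq_len(n_clones), map_contig, FUN = seq_along)
  fpc_map <- data.frame(clone_id = clone_id[ord],
                        map_contig = sprintf("FPC%03d", map_contig),
                        order_index = as.integer(order_index),
                        stringsAsFactors = FALSE)
  truth <- data.frame(clone_id = clone_id, start = start, end = end,
                      stringsAsFactors = FALSE)
  list(end_reads = end_reads, fpc_map = fpc_map, truth = truth)
}
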