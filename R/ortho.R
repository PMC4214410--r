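# Orthologue matching across 2-3 genomes: reciprocal best protein hits with
# single-linkage clustering, plus secondary assignment of within-genome extra
# copies. Replaces Markov clustering with a deterministic, self-contained
# scheme that preserves the shared / unique / copy-number labels.

## protein k-mer prefilter: candidate cross-genome pairs sharing >= min_shared
## k-mers (keeps all-vs-all alignment desk-fast)
protein_kmer_candidates <- function(prot, genome, k = 5, min_shared = 4) {
  kmers <- lapply(prot, function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    unique(substring(p, 1:(n - k + 1), k:n))
  })
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(kmers)) {
    for (km in kmers[[i]]) {
      assign(km, c(get0(km, envir = idx, ifnotfound = integer(0)), i),
             envir = idx)
    }
  }
  pair_counts <- new.env(parent = emptyenv())
  for (km in ls(idx)) {
    hits <- get(km, envir = idx)
    if (length(hits) < 2 || length(hits) > 50) next
    for (a in seq_along(hits)) {
      for (b in seq_along(hits)) {
        if (a >= b) next
        i <- hits[a]; j <- hits[b]
        if (genome[i] == genome[j]) next
        key <- paste0(i, "_", j)
        assign(key, get0(key, envir = pair_counts, ifnotfound = 0L) + 1L,
               envir = pair_counts)
      }
    }
  }
  keys <- ls(pair_counts)
  counts <- vapply(keys, function(k2) get(k2, envir = pair_counts), integer(1))
  keys <- keys[counts >= min_shared]
  if (length(keys) == 0) return(data.frame(i = integer(0), j = integer(0)))
  ij <- do.call(rbind, strsplit(keys, "_"))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

#' Match gene models across genomes into orthologue clusters
#'
#' Reciprocal best protein matches (global alignment, BLOSUM62) with identity
#' and coverage thresholds define orthologue links; links are clustered by
#' single linkage. Genes without a reciprocal best link join the cluster of
#' their best qualifying hit (capturing duplicated copies); remaining genes
#' become single-genome clusters.
#'
#' @param gene_sets named list (2-3 genomes) of data.frames with columns `id`
#'   and `cds`.
#' @param min_identity minimum fraction identical amino acids over aligned
#'   columns.
#' @param min_coverage minimum fraction of the shorter protein aligned.
#' @return list with `cluster` (ids), `status` (shared / `<genome>`-unique),
#'   `copies` (data.frame of per-genome copy numbers) and `members` (per-genome
#'   list of member-id vectors, aligned with `cluster`).
#' @export
find_orthologues <- function(gene_sets, min_identity = 0.5, min_coverage = 0.5) {
  genomes <- names(gene_sets)
  check_that(length(genomes) >= 2 && length(genomes) <= 3,
             "gene_sets must cover 2-3 genomes")
  ids <- unlist(lapply(gene_sets, function(g) g$id), use.names = FALSE)
  check_that(!any(duplicated(ids)), "duplicate gene ids across gene sets")
  genome <- rep(genomes, vapply(gene_sets, nrow, integer(1)))
  cds <- unlist(lapply(gene_sets, function(g) g$cds), use.names = FALSE)
  prot <- vapply(cds, function(x) {
    x2 <- if (nchar(x) %% 3 == 0) x else substr(x, 1, nchar(x) - nchar(x) %% 3)
    sub("\\*$", "", translate_cds(x2))
  }, character(1), USE.NAMES = FALSE)
  n <- length(ids)

  cand <- protein_kmer_candidates(prot, genome)
  # score candidates
  hits <- NULL
  if (nrow(cand) > 0) {
    B62 <- blosum62()
    res <- lapply(seq_len(nrow(cand)), function(r) {
      i <- cand$i[r]; j <- cand$j[r]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(prot[i]), Biostrings::AAString(prot[j]),
        type = "global", substitutionMatrix = B62,
        gapOpening = 10, gapExtension = 0.5)
      sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      both <- sa != "-" & sb != "-"
      shorter <- min(nchar(prot[i]), nchar(prot[j]))
      ident <- if (sum(both) > 0) sum(sa == sb & both) / sum(both) else 0
      cover <- sum(both) / shorter
      data.frame(i = i, j = j, score = Biostrings::score(aln),
                 identity = ident, coverage = cover)
    })
    hits <- do.call(rbind, res)
    hits <- hits[hits$identity >= min_identity & hits$coverage >= min_coverage, ,
                 drop = FALSE]
  }
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- data.frame(i = integer(0), j = integer(0), score = numeric(0),
                       identity = numeric(0), coverage = numeric(0))
  }

  # reciprocal best: for each gene, its best-scoring hit per partner genome
  best_of <- function(gi, gj) {
    sub <- hits[(hits$i == gi & genome[hits$j] == genome[gj]) |
                  (hits$j == gi & genome[hits$i] == genome[gj]), , drop = FALSE]
    if (nrow(sub) == 0) return(NA_integer_)
    partner <- ifelse(sub$i == gi, sub$j, sub$i)
    partner[order(-sub$score, partner)][1]
  }
  # precompute best partner per (gene, other genome)
  best <- matrix(NA_integer_, n, length(genomes), dimnames = list(NULL, genomes))
  for (r in seq_len(nrow(hits))) {
    for (d in 1:2) {
      gi <- if (d == 1) hits$i[r] else hits$j[r]
      gj <- if (d == 1) hits$j[r] else hits$i[r]
      gset <- genome[gj]
      cur <- best[gi, gset]
      if (is.na(cur)) best[gi, gset] <- gj
      else {
        sc_cur <- max(hits$score[(hits$i == gi & hits$j == cur) |
                                   (hits$j == gi & hits$i == cur)])
        sc_new <- hits$score[r]
        if (sc_new > sc_cur || (sc_new == sc_cur && gj < cur))
          best[gi, gset] <- gj
      }
    }
  }
  rb_edges <- NULL
  for (i in seq_len(n)) {
    for (g in genomes) {
      j <- best[i, g]
      if (!is.na(j) && i < j && !is.na(best[j, genome[i]]) &&
          best[j, genome[i]] == i) {
        rb_edges <- rbind(rb_edges, c(i, j))
      }
    }
  }

  # single-linkage components over reciprocal-best edges
  comp <- seq_len(n)
  if (!is.null(rb_edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = rb_edges[, 1], to = rb_edges[, 2]),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  }
  # secondary assignment: genes alone in their component but with a qualifying
  # best hit join that hit's component (duplicated copies)
  sizes <- table(comp)
  for (i in seq_len(n)) {
    if (sizes[as.character(comp[i])] > 1) next
    js <- best[i, ]
    js <- js[!is.na(js)]
    if (length(js) > 0) {
      j <- js[1]
      if (sizes[as.character(comp[j])] >= 1 && comp[j] != comp[i])
        comp[i] <- comp[j]
    }
  }

  comp_ids <- sort(unique(comp))
  cluster <- sprintf("OC%05d", seq_along(comp_ids))
  members <- setNames(lapply(genomes, function(g) {
    lapply(comp_ids, function(cid) ids[comp == cid & genome == g])
  }), genomes)
  copies <- as.data.frame(setNames(lapply(genomes, function(g)
    vapply(comp_ids, function(cid) sum(comp == cid & genome == g), integer(1))),
    genomes))
  present <- copies > 0
  status <- apply(present, 1, function(p) {
    if (sum(p) == 1) paste0(genomes[which(p)], "-unique") else "shared"
  })
  list(cluster = cluster, status = status, copies = copies, members = members,
       genomes = genomes)
}
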