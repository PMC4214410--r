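# Mate-pair scaffolding: link-evidence collection from uniquely placed read
# pairs, a support-ranked scaffold graph, and tier-by-tier (smallest insert
# first) scaffold construction.

## placement of a read on a contig -> (end linked, distance from read start to
## that contig end). A forward read points at the contig tail, a reverse read
## at the head.
link_geometry <- function(pos, strand, read_length, contig_len) {
  end <- ifelse(strand == 1, "tail", "head")
  dist <- ifelse(strand == 1, contig_len - pos + 1, pos + read_length - 1)
  list(end = end, dist = dist)
}

#' Collect inter-contig link evidence from one read tier
#'
#' Reads are placed by unique-seed ungapped alignment; pairs with both mates
#' uniquely placed on different contigs contribute to one bundle per oriented
#' end pair. The gap estimate is the mean over pairs of
#' (insert mean - distance to end a - distance to end b).
#'
#' @param contigs named character vector.
#' @param tier one tier from [simulate_reads()] (read1, read2, insert_mean,
#'   read_length).
#' @param seed_k,max_mm placement parameters (31-mer unique seeds by default).
#' @param placements optional precomputed placements (internal reuse).
#' @return data.frame contig_a, end_a, contig_b, end_b, support, gap_estimate.
#' @export
collect_link_evidence <- function(contigs, tier, seed_k = 31, max_mm = 3,
                                  placements = NULL) {
  rl <- tier$read_length
  if (is.null(placements)) {
    p1 <- cpp_map_placements(unname(contigs), tier$read1, seed_k, max_mm)
    p2 <- cpp_map_placements(unname(contigs), tier$read2, seed_k, max_mm)
  } else {
    p1 <- placements$p1; p2 <- placements$p2
  }
  lens <- nchar(contigs)
  ok <- !is.na(p1$ref) & !is.na(p2$ref) & p1$ref != p2$ref
  if (!any(ok)) {
    warning("tier produced no inter-contig links")
    return(data.frame(contig_a = character(0), end_a = character(0),
                      contig_b = character(0), end_b = character(0),
                      support = integer(0), gap_estimate = numeric(0)))
  }
  g1 <- link_geometry(p1$pos[ok], p1$strand[ok], rl, lens[p1$ref[ok]])
  g2 <- link_geometry(p2$pos[ok], p2$strand[ok], rl, lens[p2$ref[ok]])
  ids <- names(contigs)
  a <- ids[p1$ref[ok]]; b <- ids[p2$ref[ok]]
  ea <- g1$end; eb <- g2$end
  gap <- tier$insert_mean - g1$dist - g2$dist
  # canonical order within each pair
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  key <- paste(a, ea, b, eb, sep = "\r")
  supp <- table(key)
  gapm <- tapply(gap, key, mean)
  parts <- do.call(rbind, strsplit(names(supp), "\r", fixed = TRUE))
  data.frame(contig_a = parts[, 1], end_a = parts[, 2],
             contig_b = parts[, 3], end_b = parts[, 4],
             support = as.integer(supp), gap_estimate = as.numeric(gapm[names(supp)]),
             stringsAsFactors = FALSE)
}

#' Build a scaffold graph from link bundles
#'
#' Nodes are oriented contig ends; only bundles with support >= `min_support`
#' become edges. Conflicting edges at one end are retained but ranked by
#' support (descending); path construction later applies the majority rule.
#'
#' @param bundles data.frame from [collect_link_evidence()].
#' @param min_support minimum read-pair support per edge.
#' @return the filtered, support-ranked bundle table (class `scaffold_graph`).
#' @export
build_scaffold_graph <- function(bundles, min_support = 3) {
  check_that(min_support >= 1, "min_support must be >= 1")
  g <- bundles[bundles$support >= min_support, , drop = FALSE]
  g <- g[order(-g$support), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("scaffold_graph", class(g))
  g
}

## keep at most one edge per end. Orientation conflicts between the same two
## contigs are settled by support (majority rule); among edges to different
## partners the nearest neighbour (smallest gap estimate) wins, since a long
## insert tier also links non-adjacent contigs across short ones. An edge is
## used only when chosen reciprocally at both of its ends.
resolve_edges <- function(g, support_ratio = 0.3) {
  if (nrow(g) == 0) return(g)
  # majority rule for duplicate contig pairs
  pair_key <- paste(g$contig_a, g$contig_b)
  g <- g[order(pair_key, -g$support), , drop = FALSE]
  g <- g[!duplicated(paste(g$contig_a, g$contig_b)), , drop = FALSE]
  # drop weakly supported edges at each end before the nearest-gap choice
  # (spurious chimeric bundles carry a small fraction of the real support)
  keyA <- paste(g$contig_a, g$end_a); keyB <- paste(g$contig_b, g$end_b)
  best_at <- tapply(c(g$support, g$support), c(keyA, keyB), max)
  keep_s <- g$support >= support_ratio * pmax(best_at[keyA], best_at[keyB])
  g <- g[keep_s, , drop = FALSE]
  keyA <- paste(g$contig_a, g$end_a); keyB <- paste(g$contig_b, g$end_b)
  ord <- order(g$gap_estimate, -g$support, g$contig_a, g$contig_b)
  chosen <- new.env(parent = emptyenv())
  for (r in ord) {
    for (k in c(keyA[r], keyB[r])) {
      if (is.null(get0(k, envir = chosen, ifnotfound = NULL))) {
        assign(k, r, envir = chosen)
      }
    }
  }
  keep <- vapply(seq_len(nrow(g)), function(r) {
    identical(get0(keyA[r], envir = chosen), r) &&
      identical(get0(keyB[r], envir = chosen), r)
  }, logical(1))
  g[keep, , drop = FALSE]
}

## generic chain construction over (id, end) edges; returns list of chains,
## each a data.frame(id, orient, gap_before); cycles broken at lowest support
build_chains <- function(ids, edges, log = character(0)) {
  ekey <- function(id, end) paste(id, end, sep = "|")
  adj <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      assign(ekey(edges$contig_a[r], edges$end_a[r]), r, envir = adj)
      assign(ekey(edges$contig_b[r], edges$end_b[r]), r, envir = adj)
    }
  }
  edge_at <- function(id, end) get0(ekey(id, end), envir = adj,
                                    ifnotfound = NA_integer_)
  removed <- logical(nrow(edges))
  visited <- setNames(rep(FALSE, length(ids)), ids)
  chains <- list()
  walk <- function(start, orient) {
    rows <- list(data.frame(id = start, orient = orient, gap_before = NA_real_,
                            stringsAsFactors = FALSE))
    cur <- start; o <- orient
    repeat {
      exit_end <- if (o == "+") "tail" else "head"
      er <- edge_at(cur, exit_end)
      if (is.na(er) || removed[er]) break
      e <- edges[er, ]
      if (e$contig_a == cur && e$end_a == exit_end) {
        nxt <- e$contig_b; nin <- e$end_b
      } else {
        nxt <- e$contig_a; nin <- e$end_a
      }
      if (visited[nxt]) break
      no <- if (nin == "head") "+" else "-"
      rows[[length(rows) + 1]] <- data.frame(id = nxt, orient = no,
                                             gap_before = e$gap_estimate,
                                             stringsAsFactors = FALSE)
      visited[nxt] <<- TRUE
      cur <- nxt; o <- no
    }
    do.call(rbind, rows)
  }
  for (id in ids) {
    if (visited[id]) next
    h <- !is.na(edge_at(id, "head")); t <- !is.na(edge_at(id, "tail"))
    if (h && t) next
    visited[id] <- TRUE
    if (!h && !t) {
      chains[[length(chains) + 1]] <- data.frame(id = id, orient = "+",
                                                 gap_before = NA_real_,
                                                 stringsAsFactors = FALSE)
      next
    }
    chains[[length(chains) + 1]] <- walk(id, if (t) "+" else "-")
  }
  for (id in ids) { # remaining = cycles
    if (visited[id]) next
    cyc <- integer(0)
    cur <- id; o <- "+"
    repeat {
      exit_end <- if (o == "+") "tail" else "head"
      er <- edge_at(cur, exit_end)
      if (is.na(er) || er %in% cyc) break
      cyc <- c(cyc, er)
      e <- edges[er, ]
      if (e$contig_a == cur && e$end_a == exit_end) { cur <- e$contig_b; nin <- e$end_b }
      else { cur <- e$contig_a; nin <- e$end_a }
      o <- if (nin == "head") "+" else "-"
      if (cur == id) break
    }
    if (length(cyc) > 0) {
      worst <- cyc[which.min(edges$support[cyc])]
      removed[worst] <- TRUE
      log <- c(log, sprintf("cyclic chain broken at %s-%s (support %d)",
                            edges$contig_a[worst], edges$contig_b[worst],
                            edges$support[worst]))
      sid <- edges$contig_a[worst]
      sor <- if (edges$end_a[worst] == "tail") "-" else "+"
      visited[sid] <- TRUE
      chains[[length(chains) + 1]] <- walk(sid, sor)
    }
    visited[id] <- TRUE
  }
  list(chains = chains, log = log)
}

## layout bookkeeping: data.frame(scaffold, member, orientation, offset,
## length, gap_after); offsets are 1-based within the scaffold sequence
## (estimated gaps included, clamped to >= min_gap)
layout_from_chains <- function(chains, lens, min_gap = 1) {
  out <- list()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    sc <- sprintf("scf%05d", ci)
    gap_after <- c(pmax(min_gap, round(ch$gap_before[-1])), 0L)
    offset <- integer(nrow(ch))
    pos <- 1L
    for (i in seq_len(nrow(ch))) {
      offset[i] <- pos
      pos <- pos + lens[[ch$id[i]]] + as.integer(gap_after[i])
    }
    out[[ci]] <- data.frame(scaffold = sc, member = ch$id,
                            orientation = ch$orient, offset = offset,
                            length = unname(lens[ch$id]),
                            gap_after = as.integer(gap_after),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Hierarchical scaffolding over insert tiers
#'
#' Tiers are applied smallest insert first. Each tier maps its reads to the
#' contigs, translates placements into current scaffold coordinates, bundles
#' scaffold-end links, and joins scaffolds along unambiguous, non-conflicting
#' chains. A later tier never breaks an earlier join; every contig ends up in
#' exactly one scaffold (singletons allowed).
#'
#' @param contigs named character vector.
#' @param tiers list of tiers from [simulate_reads()], ascending insert size.
#' @param min_support minimum bundle support per tier.
#' @param seed_k,max_mm read placement parameters.
#' @return list with `layout` (contig-level layout data.frame), `log`, and
#'   per-tier link tables.
#' @export
hierarchical_scaffold <- function(contigs, tiers, min_support = 5,
                                  seed_k = 31, max_mm = 3) {
  means <- vapply(tiers, function(t) t$insert_mean, numeric(1))
  check_that(!is.unsorted(means), "tiers must be sorted by ascending insert size")
  ids <- names(contigs)
  lens <- setNames(nchar(contigs), ids)
  # initial: each contig a singleton scaffold
  layout <- data.frame(scaffold = ids, member = ids, orientation = "+",
                       offset = 1L, length = unname(lens), gap_after = 0L,
                       stringsAsFactors = FALSE)
  log <- character(0)
  tier_links <- list()
  for (ti in seq_along(tiers)) {
    tier <- tiers[[ti]]
    rl <- tier$read_length
    p1 <- cpp_map_placements(unname(contigs), tier$read1, seed_k, max_mm)
    p2 <- cpp_map_placements(unname(contigs), tier$read2, seed_k, max_mm)
    # translate contig placements into scaffold coordinates
    scf_of <- setNames(layout$scaffold, layout$member)
    ori_of <- setNames(layout$orientation, layout$member)
    off_of <- setNames(layout$offset, layout$member)
    scf_len <- tapply(layout$offset + layout$length - 1, layout$scaffold, max)
    to_scaffold <- function(p) {
      mapped <- !is.na(p$ref)
      member <- ids[p$ref]
      spos <- ifelse(ori_of[member] == "+",
                     off_of[member] + p$pos - 1,
                     off_of[member] + (lens[member] - (p$pos + rl - 1)))
      sstr <- ifelse(ori_of[member] == "+", p$strand, -p$strand)
      list(ref = ifelse(mapped, scf_of[member], NA_character_),
           pos = as.integer(spos), strand = as.integer(sstr))
    }
    s1 <- to_scaffold(p1); s2 <- to_scaffold(p2)
    ok <- !is.na(s1$ref) & !is.na(s2$ref) & s1$ref != s2$ref
    if (!any(ok)) {
      warning(sprintf("tier %d (insert %g) produced no inter-scaffold links",
                      ti, tier$insert_mean))
      next
    }
    g1 <- link_geometry(s1$pos[ok], s1$strand[ok], rl, scf_len[s1$ref[ok]])
    g2 <- link_geometry(s2$pos[ok], s2$strand[ok], rl, scf_len[s2$ref[ok]])
    a <- s1$ref[ok]; b <- s2$ref[ok]; ea <- g1$end; eb <- g2$end
    gap <- tier$insert_mean - g1$dist - g2$dist
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
    key <- paste(a, ea, b, eb, sep = "\r")
    supp <- table(key)
    gapm <- tapply(gap, key, mean)
    parts <- do.call(rbind, strsplit(names(supp), "\r", fixed = TRUE))
    bundles <- data.frame(contig_a = parts[, 1], end_a = parts[, 2],
                          contig_b = parts[, 3], end_b = parts[, 4],
                          support = as.integer(supp),
                          gap_estimate = as.numeric(gapm[names(supp)]),
                          stringsAsFactors = FALSE)
    tier_links[[ti]] <- bundles
    graph <- build_scaffold_graph(bundles, min_support)
    edges <- resolve_edges(graph)
    # negative gap estimates beyond overlap plausibility are contradictions
    bad <- edges$gap_estimate < -2 * tier$insert_sd - 100
    if (any(bad)) {
      log <- c(log, sprintf("tier %d: rejected %d edges with implausible gaps",
                            ti, sum(bad)))
      edges <- edges[!bad, , drop = FALSE]
    }
    scf_ids <- unique(layout$scaffold)
    res <- build_chains(scf_ids, edges, log)
    log <- res$log
    # merge scaffold-level chains into a new contig-level layout
    new_layout <- list()
    for (ci in seq_along(res$chains)) {
      ch <- res$chains[[ci]]
      sc <- sprintf("t%02d_scf%05d", ti, ci)
      pos <- 1L
      for (i in seq_len(nrow(ch))) {
        mem <- layout[layout$scaffold == ch$id[i], , drop = FALSE]
        mem <- mem[order(mem$offset), , drop = FALSE]
        if (!is.na(ch$gap_before[i]) && i > 1) {
          gp <- max(1L, as.integer(round(ch$gap_before[i])))
          # assign the junction gap to the previous member
          last <- length(new_layout)
          new_layout[[last]]$gap_after[nrow(new_layout[[last]])] <- gp
          pos <- pos + gp
        }
        if (ch$orient[i] == "-") {
          # flip the scaffold: reverse member order, flip orientations,
          # shift gaps (gap_after of member i becomes gap_after of i-1)
          sl <- max(mem$offset + mem$length - 1)
          mem2 <- mem[rev(seq_len(nrow(mem))), , drop = FALSE]
          mem2$orientation <- ifelse(mem2$orientation == "+", "-", "+")
          mem2$offset <- sl - (mem2$offset + mem2$length - 1) + 1
          mem2$gap_after <- c(rev(mem$gap_after[-nrow(mem)]), 0L)
          mem <- mem2
        }
        mem$scaffold <- sc
        mem$offset <- mem$offset - min(mem$offset) + pos
        pos <- max(mem$offset + mem$length - 1) + mem$gap_after[nrow(mem)] + 1L
        pos <- as.integer(pos)
        new_layout[[length(new_layout) + 1]] <- mem
      }
      # last member of a chain has no trailing gap
      new_layout[[length(new_layout)]]$gap_after[
        nrow(new_layout[[length(new_layout)]])] <- 0L
    }
    layout <- do.call(rbind, new_layout)
    rownames(layout) <- NULL
  }
  list(layout = layout, log = log, tier_links = tier_links)
}

#' Emit scaffold sequences from a contig layout
#'
#' Gaps between members are written as runs of N at their estimated (clamped)
#' lengths.
#'
#' @param contigs named character vector.
#' @param layout layout data.frame from [hierarchical_scaffold()].
#' @return named character vector of scaffold sequences.
#' @export
emit_scaffold_seqs <- function(contigs, layout) {
  scaffolds <- unique(layout$scaffold)
  out <- setNames(character(length(scaffolds)), scaffolds)
  for (sc in scaffolds) {
    mem <- layout[layout$scaffold == sc, , drop = FALSE]
    mem <- mem[order(mem$offset), , drop = FALSE]
    pieces <- character(2 * nrow(mem) - 1)
    for (i in seq_len(nrow(mem))) {
      s <- contigs[[mem$member[i]]]
      if (mem$orientation[i] == "-") s <- revcomp(s)
      pieces[2 * i - 1] <- s
      if (i < nrow(mem))
        pieces[2 * i] <- strrep("N", max(1L, mem$gap_after[i]))
    }
    out[sc] <- paste(pieces, collapse = "")
  }
  out
}
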