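# Mega-scaffolding: scaffolds are assigned to FPC map contigs by their BAC
# clone hits, ordered by median clone order index (the physical map is the
# ordering backbone), oriented by the within-scaffold trend of clone order
# versus hit position, and checked against BAC-end links. Pseudomolecules are
# emitted with fixed 500-N gaps plus an AGP that reconstructs them exactly.

#' Order and orient scaffolds into mega-scaffolds using BAC ends and an FPC map
#'
#' BAC end reads are placed on the scaffolds; each scaffold is assigned to the
#' map contig hit by the majority of its clones and ordered by the median FPC
#' order index of supporting clones. Orientation follows the sign of the
#' association between clone order index and hit position within the scaffold.
#' BAC-end links consistent with the FPC order are accepted; inconsistent ones
#' are rejected and logged. Unplaced scaffolds pass through unchanged.
#'
#' @param scaffold_seqs named character vector of scaffold sequences.
#' @param end_reads data.frame (clone_id, end, seq) from
#'   [simulate_bac_and_fpc()] or equivalent.
#' @param fpc_map data.frame (clone_id, map_contig, order_index).
#' @param seed_k,max_mm read placement parameters.
#' @return list with `mega` (data.frame mega, scaffold, orientation, rank),
#'   `links` (accepted/rejected BAC links) and `log`.
#' @export
mega_scaffold <- function(scaffold_seqs, end_reads, fpc_map,
                          seed_k = 31, max_mm = 3) {
  ids <- names(scaffold_seqs)
  pl <- cpp_map_placements(unname(scaffold_seqs), end_reads$seq, seed_k, max_mm)
  hits <- data.frame(clone_id = end_reads$clone_id, end = end_reads$end,
                     scaffold = ids[pl$ref], pos = pl$pos, strand = pl$strand,
                     stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$scaffold), , drop = FALSE]
  hits <- merge(hits, fpc_map, by = "clone_id")
  log <- character(0)

  # scaffold -> map contig (majority), order (median index), orientation
  assign_rows <- list()
  for (sc in ids) {
    h <- hits[hits$scaffold == sc, , drop = FALSE]
    if (nrow(h) == 0) {
      assign_rows[[sc]] <- data.frame(scaffold = sc, map_contig = NA_character_,
                                      rank = NA_real_, orientation = "+",
                                      n_clones = 0L, stringsAsFactors = FALSE)
      next
    }
    tab <- sort(table(h$map_contig), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      log <- c(log, sprintf("scaffold %s hits two map contigs equally: unplaced", sc))
      assign_rows[[sc]] <- data.frame(scaffold = sc, map_contig = NA_character_,
                                      rank = NA_real_, orientation = "+",
                                      n_clones = 0L, stringsAsFactors = FALSE)
      next
    }
    mc <- names(tab)[1]
    hm <- h[h$map_contig == mc, , drop = FALSE]
    rank <- median(hm$order_index)
    ori <- "+"
    if (length(unique(hm$order_index)) >= 2) {
      ct <- stats::cor(hm$order_index, hm$pos, method = "spearman")
      if (!is.na(ct) && ct < 0) ori <- "-"
      if (is.na(ct) || ct == 0)
        log <- c(log, sprintf("scaffold %s: ambiguous orientation, kept +", sc))
    } else {
      log <- c(log, sprintf("scaffold %s: single clone index, orientation kept +", sc))
    }
    assign_rows[[sc]] <- data.frame(scaffold = sc, map_contig = mc, rank = rank,
                                    orientation = ori,
                                    n_clones = length(unique(hm$clone_id)),
                                    stringsAsFactors = FALSE)
  }
  assign_df <- do.call(rbind, assign_rows)

  # BAC-end links between scaffolds, judged against the FPC order
  lk <- merge(hits[hits$end == 1, c("clone_id", "scaffold")],
              hits[hits$end == 2, c("clone_id", "scaffold")],
              by = "clone_id", suffixes = c("_1", "_2"))
  lk <- lk[lk$scaffold_1 != lk$scaffold_2, , drop = FALSE]
  if (nrow(lk) > 0) {
    r1 <- assign_df$rank[match(lk$scaffold_1, assign_df$scaffold)]
    r2 <- assign_df$rank[match(lk$scaffold_2, assign_df$scaffold)]
    m1 <- assign_df$map_contig[match(lk$scaffold_1, assign_df$scaffold)]
    m2 <- assign_df$map_contig[match(lk$scaffold_2, assign_df$scaffold)]
    # consistent: same map contig and adjacent-ish ranks
    ranks_by_mc <- split(assign_df$rank[!is.na(assign_df$map_contig)],
                         assign_df$map_contig[!is.na(assign_df$map_contig)])
    adjacent <- function(mc, a, b) {
      if (is.na(mc) || is.na(a) || is.na(b)) return(FALSE)
      rs <- sort(unique(ranks_by_mc[[mc]]))
      ia <- match(a, rs); ib <- match(b, rs)
      !is.na(ia) && !is.na(ib) && abs(ia - ib) == 1
    }
    lk$consistent <- vapply(seq_len(nrow(lk)), function(i) {
      !is.na(m1[i]) && !is.na(m2[i]) && m1[i] == m2[i] &&
        adjacent(m1[i], r1[i], r2[i])
    }, logical(1))
    nrej <- sum(!lk$consistent)
    if (nrej > 0) log <- c(log, sprintf("rejected %d BAC links inconsistent with FPC order", nrej))
  } else {
    lk$consistent <- logical(0)
  }

  placed <- assign_df[!is.na(assign_df$map_contig), , drop = FALSE]
  unplaced <- assign_df[is.na(assign_df$map_contig), , drop = FALSE]
  mega_rows <- list()
  for (mc in sort(unique(placed$map_contig))) {
    p <- placed[placed$map_contig == mc, , drop = FALSE]
    p <- p[order(p$rank, p$scaffold), , drop = FALSE]
    mega_rows[[mc]] <- data.frame(mega = paste0("mega_", mc),
                                  scaffold = p$scaffold,
                                  orientation = p$orientation,
                                  rank = seq_len(nrow(p)),
                                  stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(unplaced))) {
    sc <- unplaced$scaffold[i]
    mega_rows[[paste0("un_", sc)]] <- data.frame(
      mega = paste0("mega_unplaced_", sc), scaffold = sc, orientation = "+",
      rank = 1L, stringsAsFactors = FALSE)
  }
  mega <- do.call(rbind, mega_rows)
  rownames(mega) <- NULL
  list(mega = mega, links = lk, assignments = assign_df, log = log)
}

#' Emit a pseudomolecule with fixed N gaps and its AGP
#'
#' Consecutive scaffolds are joined by exactly `gap_len` N characters; the AGP
#' (v2.1) alternates component and gap rows and reconstructs the sequence
#' exactly.
#'
#' @param mega_members data.frame (scaffold, orientation) in output order.
#' @param scaffold_seqs named character vector.
#' @param object_name name of the emitted pseudomolecule.
#' @param gap_len gap length between scaffolds (500 N by convention).
#' @return list with `seq` and `agp` (data.frame, AGP v2.1 columns).
#' @export
emit_pseudomolecule <- function(mega_members, scaffold_seqs,
                                object_name = "pseudo1", gap_len = 500) {
  check_that(nrow(mega_members) >= 1, "pseudomolecule needs >= 1 component")
  n <- nrow(mega_members)
  pieces <- character(2 * n - 1)
  agp <- list()
  pos <- 1L; part <- 1L
  for (i in seq_len(n)) {
    s <- scaffold_seqs[[mega_members$scaffold[i]]]
    if (mega_members$orientation[i] == "-") s <- revcomp(s)
    pieces[2 * i - 1] <- s
    agp[[length(agp) + 1]] <- data.frame(
      object = object_name, object_beg = pos, object_end = pos + nchar(s) - 1L,
      part_number = part, component_type = "W",
      component_id = mega_members$scaffold[i], component_beg = "1",
      component_end = as.character(nchar(s)),
      orientation = mega_members$orientation[i], stringsAsFactors = FALSE)
    pos <- pos + nchar(s); part <- part + 1L
    if (i < n) {
      pieces[2 * i] <- strrep("N", gap_len)
      agp[[length(agp) + 1]] <- data.frame(
        object = object_name, object_beg = pos, object_end = pos + gap_len - 1L,
        part_number = part, component_type = "N",
        component_id = as.character(gap_len), component_beg = "scaffold",
        component_end = "yes", orientation = "na", stringsAsFactors = FALSE)
      pos <- pos + gap_len; part <- part + 1L
    }
  }
  list(seq = paste(pieces, collapse = ""), agp = do.call(rbind, agp))
}

#' Reconstruct a pseudomolecule sequence from its AGP
#'
#' @param agp AGP data.frame from [emit_pseudomolecule()] (or read back from
#'   file).
#' @param scaffold_seqs named character vector of components.
#' @return the reconstructed sequence (character scalar).
#' @export
agp_to_sequence <- function(agp, scaffold_seqs) {
  pieces <- character(nrow(agp))
  for (i in seq_len(nrow(agp))) {
    if (agp$component_type[i] == "N") {
      pieces[i] <- strrep("N", as.integer(agp$component_id[i]))
    } else {
      s <- scaffold_seqs[[agp$component_id[i]]]
      s <- substr(s, as.integer(agp$component_beg[i]),
                  as.integer(agp$component_end[i]))
      if (agp$orientation[i] == "-") s <- revcomp(s)
      pieces[i] <- s
    }
  }
  paste(pieces, collapse = "")
}

#' Assembly summary statistics
#'
#' N50 is the length of the shortest sequence in the minimal set of longest
#' sequences covering at least half the total; the non-gapped fraction is the
#' share of non-N bases.
#'
#' @param seqs character vector of sequences.
#' @return list with total_bp, contig_count, n50, non_gapped_fraction.
#' @export
assembly_stats <- function(seqs) {
  check_that(length(seqs) > 0, "empty sequence set")
  lens <- nchar(seqs)
  sorted <- sort(lens, decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(sorted))
  n50 <- sorted[which(cum >= total / 2)[1]]
  nn <- sum(vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
  }, numeric(1)))
  list(total_bp = total, contig_count = length(seqs), n50 = n50,
       non_gapped_fraction = 1 - nn / total)
}

#' Adjacency and orientation accuracy against a truth layout
#'
#' For every pair of members adjacent in the assembled layout, checks whether
#' the pair is adjacent in the source genome with consistent relative
#' orientation (whole-object flips count as correct).
#'
#' @param layout data.frame with scaffold (or mega) grouping column `group`,
#'   ordered members `member` and `orientation`.
#' @param truth truth data.frame from [fragment_genome()] (id, strand, order).
#' @return list with `correct`, `total`, `accuracy`.
#' @export
adjacency_accuracy <- function(layout, truth) {
  idx <- setNames(truth$order, truth$id)
  tstr <- setNames(truth$strand, truth$id)
  gdir <- function(member, orient) {
    ifelse((orient == "+") == (tstr[member] == "+"), 1L, -1L)
  }
  correct <- 0L; total <- 0L
  for (g in unique(layout$group)) {
    mem <- layout[layout$group == g, , drop = FALSE]
    if (nrow(mem) < 2) next
    for (i in seq_len(nrow(mem) - 1)) {
      a <- mem$member[i]; b <- mem$member[i + 1]
      da <- gdir(a, mem$orientation[i]); db <- gdir(b, mem$orientation[i + 1])
      total <- total + 1L
      ok <- (idx[b] == idx[a] + 1 && da == 1 && db == 1) ||
        (idx[b] == idx[a] - 1 && da == -1 && db == -1)
      if (isTRUE(ok)) correct <- correct + 1L
    }
  }
  list(correct = correct, total = total,
       accuracy = if (total > 0) correct / total else NA_real_)
}
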