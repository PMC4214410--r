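# Hybrid contig-set integration: redundancy filtering of a secondary contig
# set against a primary set, dovetail overlap discovery, and
# overlap-layout-consensus merging of unambiguous chains.

#' Filter redundant secondary contigs against a primary set
#'
#' A secondary contig is removed iff at least `min_containment` of its length
#' aligns to some primary contig (either strand) at identity >=
#' `min_identity`. Removal decisions are logged with the best hit.
#'
#' @param primary_set,secondary_set named character vectors of contig
#'   sequences.
#' @param min_identity,min_containment thresholds in (0, 1].
#' @param seed_len seed k-mer length for alignment anchoring.
#' @return list with `retained` (named character vector) and `log` (data.frame
#'   id, removed, best_target, coverage, identity).
#' @export
filter_redundant_contigs <- function(primary_set, secondary_set,
                                     min_identity = 0.95,
                                     min_containment = 0.90, seed_len = 15) {
  check_that(min_identity > 0 && min_identity <= 1 &&
               min_containment > 0 && min_containment <= 1,
             "thresholds must be in (0, 1]")
  if (length(primary_set) == 0) {
    message("empty primary set: retaining all secondary contigs")
    return(list(retained = secondary_set,
                log = data.frame(id = names(secondary_set), removed = FALSE,
                                 best_target = NA_character_, coverage = 0,
                                 identity = 0, stringsAsFactors = FALSE)))
  }
  ids <- names(secondary_set)
  logs <- lapply(seq_along(secondary_set), function(i) {
    res <- cpp_containment(secondary_set[[i]], unname(primary_set), seed_len,
                           1 - min_identity)
    best <- which.max(res$coverage)
    data.frame(id = ids[i],
               removed = res$coverage[best] >= min_containment &&
                 res$identity[best] >= min_identity,
               best_target = if (res$coverage[best] > 0)
                 names(primary_set)[best] else NA_character_,
               coverage = res$coverage[best], identity = res$identity[best],
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, logs)
  list(retained = secondary_set[!log$removed], log = log)
}

#' Discover dovetail overlaps between contigs
#'
#' Finds every suffix-prefix overlap (both strands) of length >=
#' `min_overlap_len` with Hamming error rate <= `max_error_rate`, via seed
#' k-mer matching followed by direct verification. Symmetric records are stored
#' once, canonically ordered by contig index.
#'
#' @param contigs named character vector.
#' @param min_overlap_len minimum overlap length in bp.
#' @param max_error_rate maximum mismatch fraction within the overlap.
#' @param seed_len seed k-mer length (must be <= min_overlap_len).
#' @return data.frame with a, b, a_end, b_end ("head"/"tail"), orientation
#'   ("same"/"reverse"), length, identity.
#' @export
compute_overlaps <- function(contigs, min_overlap_len = 50,
                             max_error_rate = 0.02, seed_len = 15) {
  check_that(min_overlap_len >= seed_len, "min_overlap_len must be >= seed size")
  ov <- cpp_find_overlaps(unname(contigs), as.integer(min_overlap_len),
                          max_error_rate, as.integer(seed_len))
  ids <- names(contigs)
  ends <- c("head", "tail")
  df <- data.frame(a = ids[ov$a], b = ids[ov$b],
                   a_end = ends[ov$a_end], b_end = ends[ov$b_end],
                   orientation = ifelse((ov$a_end == 2 & ov$b_end == 1) |
                                          (ov$a_end == 1 & ov$b_end == 2),
                                        "same", "reverse"),
                   length = ov$length, identity = ov$identity,
                   stringsAsFactors = FALSE)
  df[order(df$a, df$b), , drop = FALSE]
}

## per-column consensus of two equal-length strings; ties broken toward the
## sequence with higher depth, then lexicographically
consensus2 <- function(x, y, depth_x = NA, depth_y = NA) {
  if (x == y) return(x)
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  diff <- which(cx != cy)
  pick_x <- if (!is.na(depth_x) && !is.na(depth_y) && depth_x != depth_y)
    depth_x > depth_y else NA
  for (i in diff) {
    cx[i] <- if (isTRUE(pick_x)) cx[i]
    else if (isFALSE(pick_x)) cy[i]
    else min(cx[i], cy[i])
  }
  paste(cx, collapse = "")
}

#' Merge contigs along unambiguous overlap chains (overlap-layout-consensus)
#'
#' Edges at ends involved in more than one overlap are dropped (branch points
#' are never merged); the remaining edges form chains that are merged with
#' per-column consensus over overlap regions. Cyclic chains are broken at the
#' lowest-identity overlap.
#'
#' @param contigs named character vector.
#' @param overlaps data.frame from [compute_overlaps()] on the same contigs.
#' @param depth optional named numeric of contig mean depths used for consensus
#'   tie-breaking (off by default).
#' @return list with `contigs` (merged + passthrough, named), `layout`
#'   (data.frame merged id, member, orientation, position) and `log` (character
#'   vector of notes).
#' @export
olc_merge <- function(contigs, overlaps, depth = NULL) {
  ids <- names(contigs)
  log <- character(0)
  if (is.null(depth)) depth <- setNames(rep(NA_real_, length(ids)), ids)
  ekey <- function(id, end) paste(id, end, sep = "|")
  if (nrow(overlaps) > 0) {
    keys <- c(ekey(overlaps$a, overlaps$a_end), ekey(overlaps$b, overlaps$b_end))
    tab <- table(keys)
    ambig <- names(tab)[tab > 1]
    drop <- ekey(overlaps$a, overlaps$a_end) %in% ambig |
      ekey(overlaps$b, overlaps$b_end) %in% ambig
    if (any(drop)) log <- c(log, sprintf("dropped %d edges at ambiguous ends",
                                         sum(drop)))
    edges <- overlaps[!drop, , drop = FALSE]
  } else edges <- overlaps
  # adjacency: end key -> edge row
  adj <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      assign(ekey(edges$a[r], edges$a_end[r]), r, envir = adj)
      assign(ekey(edges$b[r], edges$b_end[r]), r, envir = adj)
    }
  }
  edge_at <- function(id, end) get0(ekey(id, end), envir = adj,
                                    ifnotfound = NA_integer_)
  has_edge <- function(id, end) !is.na(edge_at(id, end))

  visited <- setNames(rep(FALSE, length(ids)), ids)
  removed_edges <- logical(nrow(edges))
  merged <- list(); layout <- list()
  mcount <- 0

  walk_chain <- function(start_id, start_orient) {
    chain <- list(list(id = start_id, orient = start_orient))
    cur <- start_id; orient <- start_orient
    repeat {
      exit_end <- if (orient == "+") "tail" else "head"
      er <- edge_at(cur, exit_end)
      if (is.na(er) || removed_edges[er]) break
      e <- edges[er, ]
      if (e$a == cur && e$a_end == exit_end) {
        nxt <- e$b; nxt_in <- e$b_end
      } else {
        nxt <- e$a; nxt_in <- e$a_end
      }
      if (visited[nxt]) break
      nxt_orient <- if (nxt_in == "head") "+" else "-"
      chain[[length(chain) + 1]] <- list(id = nxt, orient = nxt_orient,
                                         olen = e$length, ident = e$identity)
      visited[nxt] <<- TRUE
      cur <- nxt; orient <- nxt_orient
    }
    chain
  }

  emit_chain <- function(chain) {
    if (length(chain) == 1) {
      return(NULL)
    }
    mcount <<- mcount + 1
    mid <- sprintf("merged%04d", mcount)
    first <- chain[[1]]
    seqm <- if (first$orient == "+") contigs[[first$id]] else
      revcomp(contigs[[first$id]])
    lay <- data.frame(merged = mid, member = first$id, orientation = first$orient,
                      position = 1L, stringsAsFactors = FALSE)
    prev_id <- first$id
    for (k in 2:length(chain)) {
      el <- chain[[k]]
      nseq <- if (el$orient == "+") contigs[[el$id]] else revcomp(contigs[[el$id]])
      olen <- el$olen
      ov_a <- substr(seqm, nchar(seqm) - olen + 1, nchar(seqm))
      ov_b <- substr(nseq, 1, olen)
      cons <- consensus2(ov_a, ov_b, depth[[prev_id]], depth[[el$id]])
      seqm <- paste0(substr(seqm, 1, nchar(seqm) - olen), cons,
                     substr(nseq, olen + 1, nchar(nseq)))
      lay <- rbind(lay, data.frame(merged = mid, member = el$id,
                                   orientation = el$orient, position = k,
                                   stringsAsFactors = FALSE))
      prev_id <- el$id
    }
    merged[[mid]] <<- seqm
    layout[[mid]] <<- lay
    NULL
  }

  # path chains: start from contigs with exactly one used end
  for (id in ids) {
    if (visited[id]) next
    h <- has_edge(id, "head"); t <- has_edge(id, "tail")
    if (h && t) next # cycle candidate, handled below
    if (!h && !t) { visited[id] <- TRUE; next } # singleton
    visited[id] <- TRUE
    orient <- if (t) "+" else "-" # leave via tail when oriented +
    emit_chain(walk_chain(id, orient))
  }
  # cycles: break at lowest identity edge
  for (id in ids) {
    if (visited[id]) next
    # find the cycle through id, collect its edges
    cyc_edges <- integer(0)
    cur <- id; orient <- "+"
    repeat {
      exit_end <- if (orient == "+") "tail" else "head"
      er <- edge_at(cur, exit_end)
      if (is.na(er) || er %in% cyc_edges) break
      cyc_edges <- c(cyc_edges, er)
      e <- edges[er, ]
      if (e$a == cur && e$a_end == exit_end) { cur <- e$b; nin <- e$b_end }
      else { cur <- e$a; nin <- e$a_end }
      orient <- if (nin == "head") "+" else "-"
      if (cur == id) break
    }
    if (length(cyc_edges) > 0) {
      worst <- cyc_edges[which.min(edges$identity[cyc_edges])]
      removed_edges[worst] <- TRUE
      log <- c(log, sprintf("broke cyclic chain at overlap %s-%s (identity %.3f)",
                            edges$a[worst], edges$b[worst],
                            edges$identity[worst]))
      # restart walk from one side of the removed edge
      sid <- edges$a[worst]
      sorient <- if (edges$a_end[worst] == "tail") "-" else "+"
      visited[sid] <- TRUE
      emit_chain(walk_chain(sid, sorient))
      visited[id] <- TRUE
    } else visited[id] <- TRUE
  }

  used <- unlist(lapply(layout, function(l) l$member))
  passthrough <- contigs[setdiff(ids, used)]
  out <- c(unlist(merged), passthrough)
  layout_df <- if (length(layout)) do.call(rbind, layout) else
    data.frame(merged = character(0), member = character(0),
               orientation = character(0), position = integer(0))
  rownames(layout_df) <- NULL
  list(contigs = out, layout = layout_df, log = log)
}
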