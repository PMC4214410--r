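# MITE detection in upstream windows and cross-genome presence comparison.
# A candidate element must show terminal inverted repeats (TIRs) and a
# duplicated flanking target-site motif (TSD). Mismatches in the TIR are
# admitted only when compensated by TIR length (>= min_tir + 5 bp per
# mismatch), which keeps the false-call rate on random sequence low while
# leaving recall on canonical perfect-TIR elements unaffected.

#' Extract upstream regions of genes
#'
#' The window is taken 5' of the annotated gene start on the gene's strand;
#' minus-strand regions are reverse complemented (5'->3' toward the gene
#' start). Regions truncated at the sequence edge are flagged.
#'
#' @param genes data.frame with id, start, end, strand.
#' @param genome character scalar.
#' @param window window length in bp.
#' @return data.frame with gene, start, end (genomic, 1-based), strand, seq,
#'   truncated.
#' @export
extract_upstream <- function(genes, genome, window = 1000) {
  L <- nchar(genome)
  check_that(all(genes$start >= 1 & genes$end <= L),
             "gene coordinates out of genome bounds")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(1L, genes$start - window), genes$end + 1L)
  end <- ifelse(plus, genes$start - 1L, pmin(L, genes$end + window))
  ok <- start <= end
  seq <- character(nrow(genes))
  seq[ok] <- cpp_extract_subseqs(genome, as.integer(start[ok]),
                                 as.integer(end[ok] - start[ok] + 1L),
                                 !plus[ok])
  data.frame(gene = genes$id, start = as.integer(start), end = as.integer(end),
             strand = genes$strand, seq = seq,
             truncated = (end - start + 1L) < window,
             stringsAsFactors = FALSE)
}

#' Detect MITEs in a sequence window
#'
#' Scans for elements with terminal inverted repeats of at least `min_tir` bp
#' (mismatches allowed only when compensated: m mismatches require a TIR of at
#' least `min_tir + mm_step * m`), element length within `len_range`, and an
#' exact duplicated flanking motif of length within `tsd_range`. Overlapping
#' candidates are resolved longest-TIR-first, then leftmost.
#'
#' @param seq character scalar (one window).
#' @param min_tir minimum TIR length in bp.
#' @param max_tir_mismatch maximum TIR mismatches.
#' @param mm_step extra TIR length required per mismatch.
#' @param len_range element length range in bp.
#' @param tsd_range TSD length range in bp.
#' @return data.frame start, end (1-based inclusive within the window),
#'   tir_len, tir_mm, tsd_len.
#' @export
detect_mites <- function(seq, min_tir = 10, max_tir_mismatch = 2, mm_step = 5,
                         len_range = c(50, 800), tsd_range = c(2, 10)) {
  if (nchar(seq) < len_range[1] + 2 * tsd_range[1]) {
    return(data.frame(start = integer(0), end = integer(0),
                      tir_len = integer(0), tir_mm = integer(0),
                      tsd_len = integer(0)))
  }
  cand <- cpp_scan_mites(seq, as.integer(min_tir), as.integer(max_tir_mismatch),
                         as.integer(mm_step), as.integer(len_range[1]),
                         as.integer(len_range[2]), as.integer(tsd_range[1]),
                         as.integer(tsd_range[2]))
  df <- data.frame(start = cand$start, end = cand$end, tir_len = cand$tir_len,
                   tir_mm = cand$tir_mm, tsd_len = cand$tsd_len)
  if (nrow(df) == 0) return(df)
  df <- df[order(-df$tir_len, df$start), , drop = FALSE]
  taken <- logical(nchar(seq))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    span <- df$start[i]:df$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect MITEs across a set of upstream regions
#'
#' @param regions data.frame from [extract_upstream()].
#' @param ... passed to [detect_mites()].
#' @return data.frame with gene plus the per-window detection columns.
#' @export
detect_mites_regions <- function(regions, ...) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    d <- detect_mites(regions$seq[i], ...)
    if (nrow(d) == 0) return(NULL)
    cbind(data.frame(gene = regions$gene[i], stringsAsFactors = FALSE), d)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene = character(0), start = integer(0),
                                      end = integer(0), tir_len = integer(0),
                                      tir_mm = integer(0), tsd_len = integer(0))
  res
}

## Hamming distance between two strings over their common length
hamming <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(Inf)
  sum(strsplit(substr(a, 1, n), "")[[1]] != strsplit(substr(b, 1, n), "")[[1]])
}

#' Compare MITE presence across orthologous upstream windows
#'
#' Insertions in orthologous windows of two genomes are matched by their
#' flanking sequence anchors (`flank_match` bp on each side, approximate
#' matching); each insertion is labelled shared or genome-specific.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (orthologous gene
#'   ids of genome A and B) and `gene` (cluster key used downstream).
#' @param regions_a,regions_b upstream regions per genome
#'   ([extract_upstream()]).
#' @param mites_a,mites_b detections per genome ([detect_mites_regions()]).
#' @param labels character(2), genome labels (e.g. c("wild", "cultivar")).
#' @param flank_match flank anchor length in bp.
#' @param max_flank_mm maximum mismatches per flank anchor.
#' @return data.frame gene, genome, start, end, status
#'   ("shared"/"<label>-specific").
#' @export
compare_presence <- function(pairs, regions_a, regions_b, mites_a, mites_b,
                             labels = c("wild", "cultivar"),
                             flank_match = 20, max_flank_mm = 3) {
  flanks <- function(regions, mites) {
    seqs <- setNames(regions$seq, regions$gene)
    data.frame(gene = mites$gene, start = mites$start, end = mites$end,
               fl = substr(seqs[mites$gene],
                           pmax(1, mites$start - flank_match), mites$start - 1),
               fr = substr(seqs[mites$gene], mites$end + 1,
                           mites$end + flank_match),
               stringsAsFactors = FALSE)
  }
  fa <- flanks(regions_a, mites_a)
  fb <- flanks(regions_b, mites_b)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    xa <- fa[fa$gene == pairs$gene_a[i], , drop = FALSE]
    xb <- fb[fb$gene == pairs$gene_b[i], , drop = FALSE]
    used_b <- logical(nrow(xb))
    for (j in seq_len(nrow(xa))) {
      match_j <- 0L
      for (k in seq_len(nrow(xb))) {
        if (used_b[k]) next
        if (hamming(xa$fl[j], xb$fl[k]) <= max_flank_mm &&
            hamming(xa$fr[j], xb$fr[k]) <= max_flank_mm) { match_j <- k; break }
      }
      if (match_j > 0) {
        used_b[match_j] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          gene = pairs$gene[i], genome = labels[1], start = xa$start[j],
          end = xa$end[j], status = "shared", stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          gene = pairs$gene[i], genome = labels[2], start = xb$start[match_j],
          end = xb$end[match_j], status = "shared", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          gene = pairs$gene[i], genome = labels[1], start = xa$start[j],
          end = xa$end[j], status = paste0(labels[1], "-specific"),
          stringsAsFactors = FALSE)
      }
    }
    if (any(!used_b)) {
      for (k in which(!used_b)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = pairs$gene[i], genome = labels[2], start = xb$start[k],
          end = xb$end[k], status = paste0(labels[2], "-specific"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(gene = character(0), genome = character(0),
                                      start = integer(0), end = integer(0),
                                      status = character(0))
  res
}
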