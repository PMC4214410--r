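# Planting of MITEs (miniature inverted-repeat transposable elements) into
# upstream windows: perfect terminal inverted repeats (TIRs), a duplicated
# target-site motif (TSD), element length within the canonical range.

## build one element: TIR + random core + revcomp(TIR); total length len
make_mite_element <- function(len, tir_len) {
  tir <- random_dna(tir_len)
  core <- random_dna(len - 2L * tir_len)
  paste0(tir, core, revcomp(tir))
}

#' Plant MITE insertions into upstream windows of one genome
#'
#' Each window receives an insertion with probability `insertion_prob`. The
#' target site is a TA dinucleotide inside the window when available (the
#' canonical Stowaway-like target), otherwise a random position; the host motif
#' is duplicated to flank the element. Windows shorter than the element are
#' skipped with a truth note.
#'
#' @param genome character scalar.
#' @param windows data.frame with gene, start, end (1-based inclusive windows
#'   on the genome).
#' @param insertion_prob per-window insertion probability.
#' @param seed integer seed.
#' @param tir_range,len_range element structure ranges in bp.
#' @param tsd_len target-site duplication length.
#' @return list with `genome` (modified), `truth` (gene, start, end on the new
#'   genome, tir_len, tsd, skipped flag), and `lift` (coordinate liftover).
#' @export
plant_mites <- function(genome, windows, insertion_prob, seed = 1L,
                        tir_range = c(10, 30), len_range = c(50, 800),
                        tsd_len = 2L) {
  check_that(tir_range[1] >= 10, "TIR length must be >= 10 bp")
  check_that(len_range[1] >= 50 && len_range[2] <= 800,
             "element length must be within [50, 800] bp")
  with_seed(derive_seed(seed, "mites"), {
    dec <- plan_mite_insertions(genome, windows, insertion_prob,
                                tir_range, len_range, tsd_len)
  })
  ev <- dec$events
  applied <- apply_events(genome, ev)
  truth <- dec$truth
  if (nrow(truth) > 0 && any(!truth$skipped)) {
    ins <- !truth$skipped
    # element start on the new genome: insertion before source position pos
    newpos <- lift_positions(applied$lift, truth$src_pos[ins])
    truth$start[ins] <- newpos - truth$elem_len[ins] - truth$tsd_nchar[ins]
    truth$end[ins] <- newpos - 1L - truth$tsd_nchar[ins]
  }
  list(genome = applied$seq, truth = truth, lift = applied$lift)
}

## decide insertions for a set of windows on one genome; separated so the
## two-lineage study can reuse identical elements at homologous positions
plan_mite_insertions <- function(genome, windows, insertion_prob,
                                 tir_range, len_range, tsd_len) {
  n <- nrow(windows)
  hit <- runif(n) < insertion_prob
  events <- empty_events()
  rows <- list()
  for (i in seq_len(n)) {
    if (!hit[i]) next
    wstart <- windows$start[i]; wend <- windows$end[i]
    wlen <- wend - wstart + 1
    len <- sample(len_range[1]:len_range[2], 1)
    tir <- sample(tir_range[1]:tir_range[2], 1)
    if (len <= 2 * tir + 10) len <- 2 * tir + 10 + sample.int(40, 1)
    if (wlen < len + 2 * tsd_len + 6) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = windows$gene[i], start = NA_integer_, end = NA_integer_,
        tir_len = tir, tsd = NA_character_, elem_len = len,
        src_pos = NA_integer_, tsd_nchar = 0L, skipped = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    wseq <- substring(genome, wstart, wend)
    ta <- gregexpr("TA", wseq, fixed = TRUE)[[1]]
    # the insertion shifts higher coordinates by the element length; keep the
    # element inside the final window, whose gene-side anchor is at high
    # coordinates for + genes (default) and low ones for - genes
    plus <- is.null(windows$strand) || windows$strand[i] == "+"
    ta <- if (plus) ta[ta > len + tsd_len + 2 & ta < wlen - tsd_len - 2] else
      ta[ta > tsd_len & ta < wlen - len - tsd_len - 2]
    if (length(ta) >= 1 && ta[1] != -1 && tsd_len == 2L) {
      p_local <- ta[sample.int(length(ta), 1)]
      tsd <- "TA"
    } else {
      p_local <- if (plus) sample(seq(len + tsd_len + 3, wlen - tsd_len - 2), 1)
        else sample(seq(tsd_len + 1, wlen - len - tsd_len - 2), 1)
      tsd <- substring(wseq, p_local, p_local + tsd_len - 1)
    }
    elem <- make_mite_element(len, tir)
    # host: ...tsd | elem + tsd | rest...  insertion before src position
    src_pos <- wstart + p_local - 1L + tsd_len
    events <- rbind(events, data.frame(
      pos = as.integer(src_pos), ref_len = 0L, alt = paste0(elem, tsd),
      type = "mite_insertion", lineage = NA_character_,
      stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      gene = windows$gene[i], start = NA_integer_, end = NA_integer_,
      tir_len = tir, tsd = tsd, elem_len = len,
      src_pos = as.integer(src_pos), tsd_nchar = as.integer(tsd_len),
      skipped = FALSE, stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               tir_len = integer(0), tsd = character(0), elem_len = integer(0),
               src_pos = integer(0), tsd_nchar = integer(0),
               skipped = logical(0))
  list(events = events, truth = truth)
}
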