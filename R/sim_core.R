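# Event machinery shared by the simulators. An event edits a source sequence
# at a 1-based position: `ref_len` source bases starting at `pos` are replaced
# by the string `alt`. SNV: ref_len 1, alt one base. Deletion: ref_len > 0,
# alt "". Insertion: ref_len 0, alt inserted *before* `pos`.

empty_events <- function() {
  data.frame(pos = integer(), ref_len = integer(), alt = character(),
             type = character(), lineage = character(),
             stringsAsFactors = FALSE)
}

## validate and sort an event table; drop overlapping events (keep first)
normalise_events <- function(events, L) {
  if (nrow(events) == 0) return(events)
  events <- events[order(events$pos, events$ref_len), , drop = FALSE]
  end_excl <- events$pos + events$ref_len
  keep <- logical(nrow(events))
  last_end <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$pos[i] > last_end) {
      keep[i] <- TRUE
      last_end <- max(last_end, end_excl[i] - 1L)
    }
  }
  events <- events[keep, , drop = FALSE]
  events <- events[events$pos >= 1 & end_excl[keep] - 1 <= L, , drop = FALSE]
  rownames(events) <- NULL
  events
}

## apply a normalised event table to a sequence; returns the edited sequence
## and a liftover table mapping source coordinates to edited coordinates
apply_events <- function(seq, events) {
  L <- nchar(seq)
  events <- normalise_events(events, L)
  if (nrow(events) == 0) {
    return(list(seq = seq, events = events,
                lift = list(end_excl = numeric(0), cumdelta = numeric(0))))
  }
  starts <- events$pos
  ends_excl <- events$pos + events$ref_len
  # source pieces between events
  piece_start <- c(1L, ends_excl)
  piece_end <- c(starts - 1L, L)
  pieces <- character(2L * nrow(events) + 1L)
  pieces[seq(1, length(pieces), by = 2)] <-
    ifelse(piece_start <= piece_end, substring(seq, piece_start, piece_end), "")
  pieces[seq(2, length(pieces), by = 2)] <- events$alt
  out <- paste(pieces, collapse = "")
  delta <- nchar(events$alt) - events$ref_len
  lift <- list(end_excl = ends_excl, cumdelta = cumsum(delta))
  list(seq = out, events = events, lift = lift)
}

## map source positions through a liftover produced by apply_events
lift_positions <- function(lift, pos) {
  if (length(lift$end_excl) == 0) return(pos)
  idx <- findInterval(pos, lift$end_excl)
  shift <- c(0, lift$cumdelta)[idx + 1L]
  as.integer(pos + shift)
}
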