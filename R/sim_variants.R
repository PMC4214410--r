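# Variant planting: within-individual heterozygosity (diploid second
# haplotype) and wild/cultivar lineage divergence with selection-regime-biased
# coding changes, presence/absence and copy-number variation.

## draw SNV events at `rate` per kb over positions allowed by `allowed_ranges`
## (data.frame start/end, 1-based inclusive); returns an event table
draw_snv_events <- function(seq, rate, ranges, alt_sampler = NULL) {
  total <- sum(ranges$end - ranges$start + 1)
  n <- rpois(1, rate * total / 1000)
  if (n == 0) return(empty_events())
  n <- min(n, total)
  offsets <- sort(sample.int(total, n))
  cum <- cumsum(ranges$end - ranges$start + 1)
  ridx <- findInterval(offsets - 1, c(0, cum), rightmost.closed = FALSE)
  pos <- ranges$start[ridx] + (offsets - c(0, cum)[ridx] - 1L)
  ref <- substring(seq, pos, pos)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  data.frame(pos = as.integer(pos), ref_len = 1L, alt = alt, type = "SNV",
             lineage = NA_character_, stringsAsFactors = FALSE)
}

## draw InDel events (insertions and deletions 50/50, truncated-geometric
## lengths 1..max_len) within allowed ranges, spaced >= min_gap apart
draw_indel_events <- function(seq, rate, ranges, max_len = 10, min_gap = 25) {
  total <- sum(ranges$end - ranges$start + 1)
  n <- rpois(1, rate * total / 1000)
  if (n == 0) return(empty_events())
  offsets <- sort(sample.int(total, min(n, total)))
  cum <- cumsum(ranges$end - ranges$start + 1)
  ridx <- findInterval(offsets - 1, c(0, cum))
  pos <- as.integer(ranges$start[ridx] + (offsets - c(0, cum)[ridx] - 1L))
  keep <- c(TRUE, diff(pos) >= min_gap)
  pos <- pos[keep]
  m <- length(pos)
  len <- pmin(max_len, rgeom(m, 0.45) + 1L)
  is_del <- runif(m) < 0.5
  L <- nchar(seq)
  ev <- vector("list", m)
  for (i in seq_len(m)) {
    if (is_del[i] && pos[i] + len[i] - 1 <= L - 1) {
      ev[[i]] <- data.frame(pos = pos[i], ref_len = as.integer(len[i]),
                            alt = "", type = "deletion",
                            lineage = NA_character_, stringsAsFactors = FALSE)
    } else {
      ev[[i]] <- data.frame(pos = pos[i], ref_len = 0L,
                            alt = random_dna(len[i]), type = "insertion",
                            lineage = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, ev)
}

#' Create a second haplotype at stated heterozygosity rates
#'
#' Plants SNVs and short InDels along the haplotype as Poisson processes at the
#' given per-kb rates and applies them to obtain the partner haplotype. Every
#' planted event is recorded in the truth table on the coordinates of the input
#' haplotype.
#'
#' @param haplotype character scalar (the assembly haplotype).
#' @param het_snv_rate,het_indel_rate events per kb.
#' @param seed integer seed.
#' @return list with `haplotype2` and `truth` (pos, ref, alt, type).
#' @export
make_diploid <- function(haplotype, het_snv_rate = 3.8, het_indel_rate = 0.5,
                         seed = 1L) {
  check_that(het_snv_rate >= 0 && het_indel_rate >= 0, "rates must be >= 0")
  L <- nchar(haplotype)
  ranges <- data.frame(start = 2L, end = L - 12L)
  with_seed(derive_seed(seed, "diploid"), {
    snv <- draw_snv_events(haplotype, het_snv_rate, ranges)
    ind <- draw_indel_events(haplotype, het_indel_rate, ranges)
  })
  events <- normalise_events(rbind(snv, ind), L)
  applied <- apply_events(haplotype, events)
  truth <- applied$events
  truth$ref <- ifelse(truth$type == "insertion", "",
                      substring(haplotype, truth$pos,
                                truth$pos + truth$ref_len - 1L))
  truth <- truth[, c("pos", "ref", "alt", "type")]
  list(haplotype2 = applied$seq, truth = truth)
}

## plant `n_sub` coding substitutions in one CDS targeting Ka/Ks ~ ratio;
## returns data.frame(codon_idx, pos_in_codon, ref, alt, syn)
plant_coding_changes <- function(cds, n_sub, ratio) {
  tb <- ng86_tables()
  m <- nchar(cds) / 3
  if (n_sub == 0 || m <= 3) {
    return(data.frame(codon_idx = integer(0), pos_in_codon = integer(0),
                      ref = character(0), alt = character(0),
                      syn = logical(0)))
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  internal <- 2:(m - 1)
  n_sub <- min(n_sub, length(internal))
  S <- sum(tb$syn_sites[codons[internal]], na.rm = TRUE)
  N <- 3 * length(internal) - S
  na <- round(n_sub * ratio * N / (ratio * N + S))
  ns <- n_sub - na
  picks <- sample(internal, n_sub)
  out <- vector("list", n_sub)
  want_syn <- c(rep(FALSE, na), rep(TRUE, ns))
  unused <- setdiff(internal, picks)
  for (i in seq_len(n_sub)) {
    ci <- picks[i]
    ch <- tb$changes[[codons[ci]]]
    if (is.null(ch)) next
    cand <- ch[ch$syn == want_syn[i] & !ch$to_stop, , drop = FALSE]
    tries <- 0
    while (nrow(cand) == 0 && length(unused) > 0 && tries < 20) {
      # rejection sampling: this codon offers no change of the wanted kind
      ci <- unused[sample.int(length(unused), 1)]
      unused <- setdiff(unused, ci)
      ch <- tb$changes[[codons[ci]]]
      cand <- ch[ch$syn == want_syn[i] & !ch$to_stop, , drop = FALSE]
      tries <- tries + 1
    }
    if (nrow(cand) == 0) next
    sel <- cand[sample.int(nrow(cand), 1), ]
    out[[i]] <- data.frame(codon_idx = ci, pos_in_codon = sel$pos,
                           ref = substr(codons[ci], sel$pos, sel$pos),
                           alt = sel$alt, syn = sel$syn,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(codon_idx = integer(0),
                                      pos_in_codon = integer(0),
                                      ref = character(0), alt = character(0),
                                      syn = logical(0))
  res
}

## intergenic ranges (1-based inclusive) of a genome given gene coordinates
intergenic_ranges <- function(L, genes, margin = 0L) {
  if (nrow(genes) == 0) return(data.frame(start = 1L, end = L))
  g <- genes[order(genes$start), ]
  starts <- c(1L, g$end + 1L + margin)
  ends <- c(g$start - 1L - margin, L)
  ok <- starts <= ends
  data.frame(start = as.integer(starts[ok]), end = as.integer(ends[ok]))
}

#' Diverge an ancestral genome into wild and cultivar lineages
#'
#' Intergenic SNVs and short InDels are planted as Poisson processes at the
#' configured per-kb pairwise rates, each event assigned to one lineage.
#' Coding substitutions are planted per gene according to its selection regime
#' (nonsynonymous-biased for positive, synonymous-biased for negative,
#' site-proportional for neutral) at the coding per-kb rate. A configurable
#' fraction of genes is deleted per lineage (presence/absence truth) and
#' duplicated (copy-number truth).
#'
#' @param ancestor list with `genome` and `genes` from
#'   [generate_ancestral_genome()].
#' @param config a [simulation_config()].
#' @return list with `wild`, `cultivar` (each: genome, genes, lift), and
#'   `truth` (variants, gene regimes, pav, cnv).
#' @export
diverge_lineages <- function(ancestor, config) {
  genome <- ancestor$genome
  genes <- ancestor$genes
  L <- nchar(genome)
  profile <- config$selection_profile
  check_that(sum(profile) <= 1 + 1e-9, "selection_profile fractions sum > 1")
  with_seed(derive_seed(config$seed, "divergence"), {
    inter <- intergenic_ranges(L, genes)
    snv <- draw_snv_events(genome, config$divergence_snv_rate, inter)
    ind <- draw_indel_events(genome, config$divergence_indel_rate, inter)
    inter_ev <- rbind(snv, ind)
    if (nrow(inter_ev) > 0) {
      inter_ev$lineage <- sample(c("wild", "cultivar"), nrow(inter_ev),
                                 replace = TRUE)
    }
    # selection regimes
    n <- nrow(genes)
    regimes <- character(n)
    if (n > 0) {
      pool <- c(names(profile), "neutral")
      probs <- c(unname(profile), max(0, 1 - sum(profile)))
      regimes <- sample(pool, n, replace = TRUE, prob = probs)
    }
    coding_ev <- vector("list", n)
    gene_truth <- genes[, c("id", "start", "end", "strand")]
    gene_truth$regime <- regimes
    gene_truth$n_nonsyn <- 0L
    gene_truth$n_syn <- 0L
    skipped <- character(0)
    for (i in seq_len(n)) {
      glen <- genes$end[i] - genes$start[i] + 1
      n_sub <- rpois(1, config$coding_snv_rate * glen / 1000)
      if (n_sub == 0) next
      if (glen / 3 <= 4) { skipped <- c(skipped, genes$id[i]); next }
      ratio <- config$regime_ratios[[regimes[i]]]
      ch <- plant_coding_changes(genes$cds[i], n_sub, ratio)
      if (nrow(ch) == 0) next
      gene_truth$n_nonsyn[i] <- sum(!ch$syn)
      gene_truth$n_syn[i] <- sum(ch$syn)
      # map CDS changes to genome coordinates
      cpos <- (ch$codon_idx - 1L) * 3L + ch$pos_in_codon
      if (genes$strand[i] == "+") {
        gpos <- genes$start[i] + cpos - 1L
        galt <- ch$alt
      } else {
        gpos <- genes$end[i] - cpos + 1L
        galt <- revcomp(ch$alt)
      }
      coding_ev[[i]] <- data.frame(
        pos = as.integer(gpos), ref_len = 1L, alt = galt, type = "SNV",
        lineage = sample(c("wild", "cultivar"), nrow(ch), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    coding_ev <- do.call(rbind, coding_ev)
    # PAV deletions and CNV duplications
    pav <- data.frame(gene = character(0), lineage = character(0))
    cnv <- data.frame(gene = character(0), lineage = character(0))
    sv_ev <- list()
    for (lin in c("wild", "cultivar")) {
      if (n > 0) {
        del <- runif(n) < config$pav_fraction
        dup <- runif(n) < config$cnv_fraction & !del
        if (any(del)) {
          pav <- rbind(pav, data.frame(gene = genes$id[del], lineage = lin))
          sv_ev[[length(sv_ev) + 1]] <- data.frame(
            pos = genes$start[del], ref_len = genes$end[del] - genes$start[del] + 1L,
            alt = "", type = "pav_deletion", lineage = lin,
            stringsAsFactors = FALSE)
        }
        if (any(dup)) {
          cnv <- rbind(cnv, data.frame(gene = genes$id[dup], lineage = lin))
          for (gi in which(dup)) {
            gseq <- substring(genome, genes$start[gi], genes$end[gi])
            sv_ev[[length(sv_ev) + 1]] <- data.frame(
              pos = genes$end[gi] + 150L,
              ref_len = 0L, alt = gseq, type = "cnv_insertion", lineage = lin,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    sv_ev <- if (length(sv_ev)) do.call(rbind, sv_ev) else empty_events()
  })
  all_ev <- rbind(inter_ev, coding_ev, sv_ev)
  lineages <- lapply(c(wild = "wild", cultivar = "cultivar"), function(lin) {
    ev <- all_ev[!is.na(all_ev$lineage) & all_ev$lineage == lin, , drop = FALSE]
    applied <- apply_events(genome, ev)
    gset <- genes
    if (nrow(gset) > 0) {
      deleted <- pav$gene[pav$lineage == lin]
      gset <- gset[!gset$id %in% deleted, , drop = FALSE]
      gset$start <- lift_positions(applied$lift, gset$start)
      gset$end <- lift_positions(applied$lift, gset$end)
      gset$cds <- cpp_extract_subseqs(applied$seq, gset$start,
                                      gset$end - gset$start + 1L,
                                      gset$strand == "-")
    }
    dup_ids <- cnv$gene[cnv$lineage == lin]
    list(genome = applied$seq, genes = gset, lift = applied$lift,
         applied_events = applied$events, duplicated_genes = dup_ids)
  })
  truth <- list(variants = all_ev, genes = gene_truth, pav = pav, cnv = cnv,
                regime_skipped = if (exists("skipped")) skipped else character(0))
  list(wild = lineages$wild, cultivar = lineages$cultivar, truth = truth)
}
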