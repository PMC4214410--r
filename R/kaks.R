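# NG86 Ka/Ks: per-codon synonymous/nonsynonymous site fractions, pathway-
# averaged substitution counting for codon pairs, Jukes-Cantor correction,
# and the selection classification used for the wild-vs-cultivar scan.
#
# Conventions (stated once, used consistently here and when planting
# substitutions in the simulator): a mutation producing a stop codon counts as
# nonsynonymous when computing site fractions; mutational pathways passing
# through a stop codon are excluded from pathway averaging, unless every
# pathway does, in which case all pathways are used.

ng86_tables <- function() {
  if (!is.null(.domestigen_env$ng86)) return(.domestigen_env$ng86)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  sense <- codons[gc != "*"]

  # per-codon synonymous site fraction and the list of possible single-base
  # changes (for the simulator's rejection sampling)
  syn_sites <- setNames(numeric(length(sense)), sense)
  changes <- setNames(vector("list", length(sense)), sense)
  for (cd in sense) {
    chars <- strsplit(cd, "")[[1]]
    s <- 0
    ch <- list()
    for (p in 1:3) {
      for (b in setdiff(bases, chars[p])) {
        alt <- chars
        alt[p] <- b
        altc <- paste(alt, collapse = "")
        syn <- !is.na(gc[altc]) && gc[altc] != "*" && gc[altc] == gc[cd]
        if (syn) s <- s + 1 / 3
        ch[[length(ch) + 1]] <- data.frame(pos = p, alt = b, syn = syn,
                                           to_stop = gc[altc] == "*",
                                           stringsAsFactors = FALSE)
      }
    }
    syn_sites[cd] <- s
    changes[[cd]] <- do.call(rbind, ch)
  }

  # pathway-averaged (sd, nd) for every ordered sense-codon pair
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  step_counts <- function(from, to) {
    # single-base step from codon `from` to codon `to`
    if (gc[from] == gc[to]) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(n)) {
    ci <- strsplit(sense[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(sense[j], "")[[1]]
      diffpos <- which(ci != cj)
      m <- length(diffpos)
      if (m == 1) {
        sc <- step_counts(sense[i], sense[j])
        sd_mat[i, j] <- sc[1]; nd_mat[i, j] <- sc[2]
        next
      }
      paths <- perms[[as.character(m)]]
      path_sd <- numeric(0); path_nd <- numeric(0); path_ok <- logical(0)
      for (p in paths) {
        cur <- ci
        s <- 0; d <- 0; ok <- TRUE
        for (step in p) {
          nxt <- cur
          nxt[diffpos[step]] <- cj[diffpos[step]]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (gc[to] == "*" && to != sense[j]) ok <- FALSE
          sc <- step_counts(from, to)
          s <- s + sc[1]; d <- d + sc[2]
          cur <- nxt
        }
        path_sd <- c(path_sd, s); path_nd <- c(path_nd, d); path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(paths))
      sd_mat[i, j] <- mean(path_sd[use])
      nd_mat[i, j] <- mean(path_nd[use])
    }
  }
  .domestigen_env$ng86 <- list(syn_sites = syn_sites, changes = changes,
                               sd = sd_mat, nd = nd_mat, sense = sense)
  .domestigen_env$ng86
}

#' Align two coding sequences codon-wise
#'
#' Global protein alignment (BLOSUM62, affine gaps) back-translated to codons.
#' Terminal stop codons are trimmed before alignment. Codon columns containing
#' a gap or an ambiguous base are excluded.
#'
#' @param cds_a,cds_b coding sequences (character scalars, length divisible by 3).
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return list with `codons_a`, `codons_b` (equal-length codon vectors over
#'   unambiguous columns), the protein alignment `score`, and `identity`
#'   (fraction identical amino acids over aligned columns).
#' @export
align_codons <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 0.5) {
  check_that(nchar(cds_a) %% 3 == 0 && nchar(cds_b) %% 3 == 0,
             "CDS length must be divisible by 3")
  trim_stop <- function(x) {
    last <- substr(x, nchar(x) - 2, nchar(x))
    if (genetic_code()[last] %in% "*") substr(x, 1, nchar(x) - 3) else x
  }
  cds_a <- trim_stop(cds_a); cds_b <- trim_stop(cds_b)
  pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  ia <- ib <- 0L
  cod_a <- cod_b <- character(length(sa))
  for (k in seq_along(sa)) {
    cod_a[k] <- if (sa[k] == "-") "---" else { ia <- ia + 1L; ca[ia] }
    cod_b[k] <- if (sb[k] == "-") "---" else { ib <- ib + 1L; cb[ib] }
  }
  keep <- !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b)
  ident <- sum(sa == sb & sa != "-") / sum(sa != "-" & sb != "-")
  list(codons_a = cod_a[keep], codons_b = cod_b[keep],
       score = Biostrings::score(aln), identity = ident)
}

#' NG86 Ka and Ks from a codon alignment
#'
#' Nei-Gojobori counting: per-codon synonymous site fractions averaged over the
#' two sequences; substitution counts averaged over all minimal mutational
#' pathways between differing codons (stop-passing pathways excluded when
#' possible); Jukes-Cantor correction applied to the proportions.
#'
#' @param alignment list with `codons_a` and `codons_b` as produced by
#'   [align_codons()] (gap-free codon columns).
#' @param min_codons minimum ungapped codon columns required.
#' @return list with `ka`, `ks`, `ratio`, raw counts (`sd`, `nd`), site totals
#'   (`s_sites`, `n_sites`), proportions (`ps`, `pn`) and `saturated` flag.
#' @export
compute_ka_ks <- function(alignment, min_codons = 10) {
  tb <- ng86_tables()
  a <- alignment$codons_a; b <- alignment$codons_b
  ok <- a %in% tb$sense & b %in% tb$sense
  a <- a[ok]; b <- b[ok]
  check_that(length(a) >= min_codons,
             sprintf("need >= %d ungapped codon columns", min_codons))
  s_sites <- (sum(tb$syn_sites[a]) + sum(tb$syn_sites[b])) / 2
  n_sites <- 3 * length(a) - s_sites
  idx <- cbind(match(a, tb$sense), match(b, tb$sense))
  sdv <- tb$sd[idx]; ndv <- tb$nd[idx]
  Sd <- sum(sdv); Nd <- sum(ndv)
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ps <- if (s_sites > 0) Sd / s_sites else NA_real_
  pn <- if (n_sites > 0) Nd / n_sites else NA_real_
  ks <- if (is.na(ps)) NA_real_ else jc(ps)
  ka <- if (is.na(pn)) NA_real_ else jc(pn)
  saturated <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, sd = Sd, nd = Nd,
       s_sites = s_sites, n_sites = n_sites, ps = ps, pn = pn,
       saturated = saturated)
}

#' Classify selection from Ka and Ks
#'
#' `Ka = Ks = 0` is reported as `no-divergence`; `Ka = 0, Ks > 0` as `Ks-only`;
#' `Ka > 0, Ks = 0` as `Ka-only`. Otherwise the ratio is compared to 1 within a
#' relative tolerance: above is `positive`, below `negative`, within `neutral`.
#'
#' @param ka,ks nonsynonymous / synonymous substitution rates (>= 0).
#' @param tolerance relative half-width of the neutral band around Ka/Ks = 1.
#' @return one of "no-divergence", "Ks-only", "Ka-only", "positive",
#'   "negative", "neutral" (or "undefined" for missing input).
#' @export
classify_selection <- function(ka, ks, tolerance = 0.1) {
  if (is.na(ka) || is.na(ks)) return("undefined")
  check_that(ka >= 0 && ks >= 0, "Ka and Ks must be >= 0")
  if (ka == 0 && ks == 0) return("no-divergence")
  if (ka == 0) return("Ks-only")
  if (ks == 0) return("Ka-only")
  r <- ka / ks
  if (abs(r - 1) <= tolerance) "neutral" else if (r > 1) "positive" else "negative"
}

#' Ka/Ks selection scan over orthologue clusters
#'
#' Restricted to clusters with exactly one member in each genome of the pair
#' (high-confidence orthologues); multi-copy clusters are excluded and counted
#' separately.
#'
#' @param clusters cluster table from [find_orthologues()].
#' @param cds named character vector: gene id -> CDS, covering both genomes.
#' @param genome_pair character(2), the genome labels to compare.
#' @param neutral_tol tolerance passed to [classify_selection()].
#' @param min_codons minimum ungapped codon columns per pair.
#' @return list with `records` (per-cluster Ka, Ks, ratio, class) and `counts`
#'   (class tally plus `multi_copy_excluded`).
#' @export
selection_scan <- function(clusters, cds, genome_pair = c("wild", "cultivar"),
                           neutral_tol = 0.1, min_codons = 10) {
  g1 <- genome_pair[1]; g2 <- genome_pair[2]
  eligible <- clusters$copies[[g1]] == 1 & clusters$copies[[g2]] == 1
  multi <- sum(clusters$copies[[g1]] > 1 | clusters$copies[[g2]] > 1)
  rows <- which(eligible)
  recs <- lapply(rows, function(i) {
    id1 <- clusters$members[[g1]][[i]]; id2 <- clusters$members[[g2]][[i]]
    aln <- align_codons(cds[[id1]], cds[[id2]])
    if (aln$identity < 0.3 || length(aln$codons_a) < min_codons) return(NULL)
    kk <- compute_ka_ks(aln, min_codons = min_codons)
    data.frame(cluster = clusters$cluster[i], gene_a = id1, gene_b = id2,
               ka = kk$ka, ks = kk$ks, ratio = kk$ratio,
               class = classify_selection(kk$ka, kk$ks, neutral_tol),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  if (is.null(records)) records <- data.frame(cluster = character(),
                                              gene_a = character(),
                                              gene_b = character(),
                                              ka = numeric(), ks = numeric(),
                                              ratio = numeric(),
                                              class = character())
  classes <- c("positive", "negative", "neutral", "no-divergence",
               "Ka-only", "Ks-only", "undefined")
  counts <- setNames(vapply(classes, function(cl) sum(records$class == cl),
                            numeric(1)), classes)
  list(records = records, counts = counts, multi_copy_excluded = multi)
}
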