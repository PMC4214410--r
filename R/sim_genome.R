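#' Simulation configuration
#'
#' Bundles all generator parameters with validation. Defaults encode the study
#' conditions: 3.8 heterozygous SNVs per kb in the wild genotype (3.4 in the
#' cultivar), 6.9 SNVs and 0.8 InDels per kb of wild-vs-cultivar divergence,
#' BAC clones with ~115 kb inserts at roughly ten genome equivalents, and a
#' 20/10/70 split of positively / negatively / neutrally selected genes.
#'
#' @param genome_length ancestral genome length in bp.
#' @param n_genes number of protein-coding genes to plant.
#' @param gene_length CDS length in bp (divisible by 3).
#' @param het_snv_rate,het_indel_rate within-individual heterozygosity of the
#'   wild genotype, events/kb.
#' @param het_snv_rate_cultivar heterozygous SNV rate of the cultivar, events/kb.
#' @param divergence_snv_rate,divergence_indel_rate wild-vs-cultivar divergence,
#'   events/kb (intergenic; the coding rate defaults to the SNV rate).
#' @param coding_snv_rate substitutions/kb planted inside CDS by selection
#'   regime; defaults to `divergence_snv_rate`.
#' @param selection_profile named numeric: fractions of genes under the
#'   `positive`, `negative` and `neutral` regimes (sum <= 1; remainder neutral).
#' @param regime_ratios target Ka/Ks per regime used when planting coding
#'   changes.
#' @param pav_fraction per-lineage probability a gene is deleted (presence /
#'   absence variation).
#' @param cnv_fraction per-lineage probability a gene is duplicated.
#' @param mite_insertion_prob per-window, per-lineage probability of a MITE
#'   insertion in the 1-kb upstream window.
#' @param suppression_log2fc expression shift applied to genes with a
#'   cultivar-specific upstream MITE.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param n_replicates expression replicates per group.
#' @param read_length sequencing read length in bp.
#' @param insert_tiers data.frame with columns `mean`, `sd`, `coverage`
#'   describing the paired-end/mate-pair libraries, smallest insert first.
#' @param error_rate per-base sequencing error rate.
#' @param bac_insert_mean,bac_insert_sd BAC clone insert size in bp.
#' @param bac_equivalents genome equivalents of BAC clones (sets `n_bac_clones`).
#' @param bac_end_read_length BAC end read length in bp.
#' @param upstream_window upstream window length in bp.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e6,
                              n_genes = 100,
                              gene_length = 600,
                              het_snv_rate = 3.8,
                              het_snv_rate_cultivar = 3.4,
                              het_indel_rate = 0.5,
                              divergence_snv_rate = 6.9,
                              divergence_indel_rate = 0.8,
                              coding_snv_rate = divergence_snv_rate,
                              selection_profile = c(positive = 0.2,
                                                    negative = 0.1,
                                                    neutral = 0.7),
                              regime_ratios = c(positive = 3, negative = 0.2,
                                                neutral = 1),
                              pav_fraction = 0.05,
                              cnv_fraction = 0.02,
                              mite_insertion_prob = 0.15,
                              suppression_log2fc = -2,
                              nb_dispersion = 0.05,
                              n_replicates = 5,
                              read_length = 100,
                              insert_tiers = data.frame(
                                mean = c(300, 3000, 8000),
                                sd = c(30, 300, 800),
                                coverage = c(20, 10, 5)),
                              error_rate = 0.001,
                              bac_insert_mean = 115000,
                              bac_insert_sd = 10000,
                              bac_equivalents = 10,
                              bac_end_read_length = 500,
                              upstream_window = 1000,
                              seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              het_snv_rate = het_snv_rate,
              het_snv_rate_cultivar = het_snv_rate_cultivar,
              het_indel_rate = het_indel_rate,
              divergence_snv_rate = divergence_snv_rate,
              divergence_indel_rate = divergence_indel_rate,
              coding_snv_rate = coding_snv_rate,
              selection_profile = selection_profile,
              regime_ratios = regime_ratios,
              pav_fraction = pav_fraction, cnv_fraction = cnv_fraction,
              mite_insertion_prob = mite_insertion_prob,
              suppression_log2fc = suppression_log2fc,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              read_length = as.integer(read_length),
              insert_tiers = insert_tiers, error_rate = error_rate,
              bac_insert_mean = bac_insert_mean, bac_insert_sd = bac_insert_sd,
              n_bac_clones = as.integer(round(bac_equivalents * genome_length /
                                                bac_insert_mean)),
              bac_end_read_length = as.integer(bac_end_read_length),
              upstream_window = as.integer(upstream_window),
              seed = as.integer(seed))
  rates <- c(cfg$het_snv_rate, cfg$het_indel_rate, cfg$divergence_snv_rate,
             cfg$divergence_indel_rate, cfg$coding_snv_rate)
  check_that(all(rates >= 0), "all rates must be >= 0")
  check_that(sum(selection_profile) <= 1 + 1e-9 && all(selection_profile >= 0),
             "selection_profile fractions must be in [0,1] and sum <= 1")
  check_that(all(insert_tiers$coverage > 0), "coverage must be > 0")
  check_that(pav_fraction >= 0 && pav_fraction <= 1 &&
               cnv_fraction >= 0 && cnv_fraction <= 1 &&
               mite_insertion_prob >= 0 && mite_insertion_prob <= 1,
             "fractions must be in [0,1]")
  check_that(cfg$gene_length %% 3 == 0, "gene_length must be divisible by 3")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate the ancestral genome with planted gene models
#'
#' Genes are placed non-overlapping, each with at least the configured upstream
#' window of clearance on its own strand; every CDS is a valid open reading
#' frame (ATG start, sense codons, single terminal stop).
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (character scalar) and `genes` (data.frame with
#'   id, start, end, strand, cds).
#' @export
generate_ancestral_genome <- function(config) {
  L <- config$genome_length
  n <- config$n_genes
  glen <- config$gene_length
  U <- config$upstream_window
  slot <- glen + 2L * U + 400L
  if (n > 0 && as.numeric(n) * slot > L) {
    stop("cannot pack ", n, " genes of ", glen, " bp with ", U,
         " bp clearance into ", L, " bp", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "genome"), {
    if (n > 0) {
      slot_starts <- floor((seq_len(n) - 1) * (L / n)) + 1L
      jitter <- sample.int(200L, n, replace = TRUE)
      gstart <- as.integer(slot_starts + U + jitter)
      gend <- gstart + glen - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      stops <- c("TAA", "TAG", "TGA")
      sense <- sense_codons()
      cds <- vapply(seq_len(n), function(i) {
        m <- glen / 3L
        paste(c("ATG", sample(sense, m - 2L, replace = TRUE),
                sample(stops, 1L)), collapse = "")
      }, character(1))
    } else {
      gstart <- gend <- integer(0)
      strand <- cds <- character(0)
    }
    # build genome: random intergenic stretches with CDS written in
    pieces <- character(2L * n + 1L)
    prev <- 1L
    for (i in seq_len(n)) {
      pieces[2L * i - 1L] <- random_dna(gstart[i] - prev)
      pieces[2L * i] <- if (strand[i] == "+") cds[i] else revcomp(cds[i])
      prev <- gend[i] + 1L
    }
    pieces[2L * n + 1L] <- random_dna(L - prev + 1L)
    genome <- paste(pieces, collapse = "")
  })
  genes <- data.frame(id = sprintf("gene%04d", seq_len(n)),
                      start = gstart, end = gend, strand = strand,
                      cds = cds, stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

#' Fragment a genome into contigs with truth layout
#'
#' Cuts the genome into non-overlapping contigs separated by unassembled gaps,
#' then shuffles contig order and randomly flips orientations, recording the
#' truth layout. Used to emulate an assembly whose scaffolding is then tested
#' against the known source.
#'
#' @param genome character scalar.
#' @param contig_mean,contig_min target and minimum contig length in bp.
#' @param gap_sampler function(n) returning n gap lengths; the default draws a
#'   mixture of short (tier-1 spannable), medium and long (BAC-only) gaps.
#' @param seed integer seed.
#' @param shuffle,flip randomise output order / orientation.
#' @return list with `contigs` (named character vector) and `truth` (data.frame
#'   id, start, end, strand, order giving the source layout).
#' @export
fragment_genome <- function(genome, contig_mean = 12000, contig_min = 2000,
                            gap_sampler = NULL, seed = 1L,
                            shuffle = TRUE, flip = TRUE) {
  L <- nchar(genome)
  if (is.null(gap_sampler)) {
    gap_sampler <- function(n) {
      cls <- sample.int(4L, n, replace = TRUE, prob = c(0.70, 0.20, 0.08, 0.02))
      len <- numeric(n)
      len[cls == 1] <- runif(sum(cls == 1), 50, 250)
      len[cls == 2] <- runif(sum(cls == 2), 400, 2000)
      len[cls == 3] <- runif(sum(cls == 3), 3000, 6000)
      len[cls == 4] <- runif(sum(cls == 4), 15000, 40000)
      round(len)
    }
  }
  with_seed(derive_seed(seed, "fragment"), {
    starts <- integer(0); ends <- integer(0)
    pos <- 1L
    while (pos + contig_min <= L) {
      clen <- max(contig_min, round(rnorm(1, contig_mean, contig_mean / 4)))
      cend <- min(L, pos + clen - 1L)
      starts <- c(starts, pos); ends <- c(ends, as.integer(cend))
      gap <- gap_sampler(1L)
      pos <- as.integer(cend + 1L + gap)
    }
    n <- length(starts)
    strand <- if (flip) sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
    seqs <- cpp_extract_subseqs(genome, starts, ends - starts + 1L,
                                strand == "-")
    ord <- if (shuffle) sample.int(n) else seq_len(n)
  })
  ids <- sprintf("ctg%04d", seq_len(n))
  truth <- data.frame(id = ids, start = starts, end = ends, strand = strand,
                      order = seq_len(n), stringsAsFactors = FALSE)
  contigs <- setNames(seqs, ids)[ord]
  list(contigs = contigs, truth = truth)
}

#' Shred a sequence into overlapping pieces
#'
#' Produces error-free fragments with a fixed pairwise overlap, shuffled and
#' optionally reverse-complemented; used to exercise overlap-layout-consensus
#' merging against the known source string.
#'
#' @param genome character scalar.
#' @param piece_len,overlap fragment length and suffix-prefix overlap, bp.
#' @param seed integer seed.
#' @param flip randomly reverse-complement pieces.
#' @return named character vector of fragments (shuffled).
#' @export
shred_overlapping <- function(genome, piece_len = 2000, overlap = 500,
                              seed = 1L, flip = TRUE) {
  L <- nchar(genome)
  step <- piece_len - overlap
  starts <- seq(1L, max(1L, L - overlap), by = step)
  ends <- pmin(L, starts + piece_len - 1L)
  # merge a trailing runt into the last full piece
  if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < overlap * 2) {
    starts <- starts[-length(starts)]
    ends[length(ends) - 1] <- L
    ends <- ends[-length(ends)]
  }
  with_seed(derive_seed(seed, "fragment"), {
    n <- length(starts)
    rc <- if (flip) sample(c(TRUE, FALSE), n, replace = TRUE) else rep(FALSE, n)
    seqs <- cpp_extract_subseqs(genome, starts, ends - starts + 1L, rc)
    ord <- sample.int(n)
  })
  setNames(seqs, sprintf("frag%04d", seq_len(length(starts))))[ord]
}
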