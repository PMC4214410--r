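# Generators: ancestral genome, diploid haplotypes, lineage divergence,
# MITE planting, reads, BAC/FPC and expression counts.

test_that("ancestral genomes are deterministic and pack valid ORFs", {
  cfg <- simulation_config(genome_length = 2e6, n_genes = 500,
                           gene_length = 600, seed = 3)
  a1 <- generate_ancestral_genome(cfg)
  a2 <- generate_ancestral_genome(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$genes, a2$genes)
  expect_equal(nchar(a1$genome), 2e6)
  expect_equal(nrow(a1$genes), 500)
  # non-overlapping with >= 1 kb clearance
  g <- a1$genes[order(a1$genes$start), ]
  expect_true(all(diff(g$start) > 0))
  expect_true(all(g$start[-1] - g$end[-nrow(g)] > 1000))
  # translate-and-scan oracle: no internal stop, ATG start, terminal stop
  aa <- vapply(g$cds, function(x) {
    paste(ORACLE_GC[substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))],
          collapse = "")
  }, character(1))
  expect_true(all(substr(g$cds, 1, 3) == "ATG"))
  expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
  expect_false(any(grepl("\\*", substr(aa, 1, nchar(aa) - 1))))
  # genes are really embedded in the genome on their strand
  for (i in sample(nrow(g), 20)) {
    emb <- substring(a1$genome, g$start[i], g$end[i])
    if (g$strand[i] == "-") emb <- revcomp(emb)
    expect_identical(emb, g$cds[i])
  }
})

test_that("infeasible gene packing raises a capacity error", {
  cfg <- simulation_config(genome_length = 10000, n_genes = 10,
                           gene_length = 300, seed = 1)
  expect_error(generate_ancestral_genome(cfg), "cannot pack")
})

test_that("make_diploid plants events at the configured Poisson rates", {
  g <- with_seed_for_tests(1, rand_dna(1e6))
  # zero rate: identical haplotypes
  d0 <- make_diploid(g, 0, 0, seed = 2)
  expect_identical(d0$haplotype2, g)
  expect_equal(nrow(d0$truth), 0)
  # 3.8 SNVs/kb: realized count within 3 Poisson SDs
  d <- make_diploid(g, 3.8, 0.5, seed = 2)
  n_snv <- sum(d$truth$type == "SNV")
  expect_lt(abs(n_snv - 3800), 3 * sqrt(3800))
  n_ind <- sum(d$truth$type != "SNV")
  expect_lt(abs(n_ind - 500), 3.5 * sqrt(500))
  # determinism
  d2 <- make_diploid(g, 3.8, 0.5, seed = 2)
  expect_identical(d$haplotype2, d2$haplotype2)
})

test_that("diploid truth matches a position-wise comparison oracle", {
  g <- with_seed_for_tests(4, rand_dna(30000))
  d <- make_diploid(g, 4, 0, seed = 7) # SNVs only: haplotypes stay aligned
  h2 <- d$haplotype2
  expect_equal(nchar(h2), nchar(g))
  c1 <- strsplit(g, "")[[1]]
  c2 <- strsplit(h2, "")[[1]]
  diff_pos <- which(c1 != c2)
  expect_setequal(diff_pos, d$truth$pos)
  expect_identical(c2[d$truth$pos], d$truth$alt)
  expect_identical(c1[d$truth$pos], d$truth$ref)
})

test_that("diverge_lineages with zero rates returns the ancestor unchanged", {
  cfg <- simulation_config(genome_length = 1e5, n_genes = 10,
                           divergence_snv_rate = 0, divergence_indel_rate = 0,
                           coding_snv_rate = 0, pav_fraction = 0,
                           cnv_fraction = 0, seed = 5)
  anc <- generate_ancestral_genome(cfg)
  div <- diverge_lineages(anc, cfg)
  expect_identical(div$wild$genome, anc$genome)
  expect_identical(div$cultivar$genome, anc$genome)
})

test_that("PAV deletions follow the binomial expectation and are recorded once", {
  cfg <- simulation_config(genome_length = 1e6, n_genes = 200,
                           gene_length = 300, pav_fraction = 0.1,
                           cnv_fraction = 0, seed = 9)
  anc <- generate_ancestral_genome(cfg)
  div <- diverge_lineages(anc, cfg)
  for (lin in c("wild", "cultivar")) {
    n_del <- sum(div$truth$pav$lineage == lin)
    expect_lt(abs(n_del - 20), 3 * sqrt(200 * 0.1 * 0.9) + 1)
    # deleted genes absent from the lineage gene table
    expect_false(any(div$truth$pav$gene[div$truth$pav$lineage == lin] %in%
                       div[[lin]]$genes$id))
  }
  expect_false(any(duplicated(paste(div$truth$pav$gene, div$truth$pav$lineage))))
})

test_that("positive-regime genes carry planted Ka/Ks > 1 by NG86 counting", {
  cfg <- simulation_config(genome_length = 4e5, n_genes = 60,
                           gene_length = 900, coding_snv_rate = 25,
                           selection_profile = c(positive = 1),
                           regime_ratios = c(positive = 3),
                           pav_fraction = 0, cnv_fraction = 0, seed = 21)
  anc <- generate_ancestral_genome(cfg)
  div <- diverge_lineages(anc, cfg)
  shared <- intersect(div$wild$genes$id, div$cultivar$genes$id)
  checked <- 0
  for (id in shared[1:20]) {
    ca <- div$wild$genes$cds[div$wild$genes$id == id]
    cb <- div$cultivar$genes$cds[div$cultivar$genes$id == id]
    tr <- div$truth$genes[div$truth$genes$id == id, ]
    if (tr$n_nonsyn + tr$n_syn < 10) next
    cod_a <- substring(ca, seq(1, nchar(ca), 3), seq(3, nchar(ca), 3))
    cod_b <- substring(cb, seq(1, nchar(cb), 3), seq(3, nchar(cb), 3))
    ora <- oracle_ng86(cod_a, cod_b)
    expect_gt(ora$ka / ora$ks, 1)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("plant_mites builds canonical elements at the planted probability", {
  g <- with_seed_for_tests(2, rand_dna(150000))
  windows <- data.frame(gene = sprintf("g%03d", 1:100),
                        start = seq(1, by = 1500, length.out = 100),
                        end = seq(1000, by = 1500, length.out = 100),
                        strand = "+")
  # probability 0: genome unchanged
  p0 <- plant_mites(g, windows, 0, seed = 3)
  expect_identical(p0$genome, g)
  # probability 0.3 over 100 windows: ~30 insertions, binomial oracle
  p <- plant_mites(g, windows, 0.3, seed = 3)
  planted <- p$truth[!p$truth$skipped, ]
  expect_lt(abs(nrow(planted) - 30), 3 * sqrt(100 * 0.3 * 0.7) + 1)
  # structure: 5' TIR equals reverse complement of 3' TIR; TSD flanks both ends
  for (r in seq_len(nrow(planted))) {
    elem <- substring(p$genome, planted$start[r], planted$end[r])
    t <- planted$tir_len[r]
    expect_identical(substr(elem, 1, t),
                     revcomp(substring(elem, nchar(elem) - t + 1, nchar(elem))))
    tl <- substring(p$genome, planted$start[r] - 2, planted$start[r] - 1)
    tr <- substring(p$genome, planted$end[r] + 1, planted$end[r] + 2)
    expect_identical(tl, planted$tsd[r])
    expect_identical(tr, planted$tsd[r])
    expect_true(planted$elem_len[r] >= 50 && planted$elem_len[r] <= 800)
  }
})

test_that("simulate_reads hits requested coverage, orientation and determinism", {
  g <- with_seed_for_tests(3, rand_dna(1e6))
  tiers <- data.frame(mean = 400, sd = 40, coverage = 30)
  rd <- simulate_reads(g, tiers, 100, error_rate = 0, seed = 6)
  n_reads <- length(rd[[1]]$read1) + length(rd[[1]]$read2)
  expect_lt(abs(n_reads - 300000), 0.05 * 300000)
  # error rate 0: every read an exact substring of the genome (or its rc)
  rcg <- revcomp(g)
  idx <- with_seed_for_tests(8, sample(length(rd[[1]]$read1), 25))
  for (i in idx) {
    expect_true(grepl(rd[[1]]$read1[i], g, fixed = TRUE))
    r2 <- rd[[1]]$read2[i]
    expect_true(grepl(r2, rcg, fixed = TRUE) || grepl(r2, g, fixed = TRUE))
  }
  # byte-identical determinism
  rd2 <- simulate_reads(g, tiers, 100, error_rate = 0, seed = 6)
  expect_identical(rd[[1]]$read1, rd2[[1]]$read1)
  expect_identical(rd[[1]]$read2, rd2[[1]]$read2)
  # insert precondition
  expect_error(simulate_reads(g, data.frame(mean = 150, sd = 1, coverage = 1),
                              100, seed = 1), "insert mean")
})

test_that("BAC library matches the ten-genome-equivalent arithmetic and FPC order", {
  g <- with_seed_for_tests(5, rand_dna(1e6))
  cfg <- simulation_config(genome_length = 1e6, bac_equivalents = 10,
                           bac_insert_mean = 115000, seed = 2)
  expect_equal(cfg$n_bac_clones, round(10 * 1e6 / 115000)) # ~87 clones
  bac <- simulate_bac_and_fpc(g, cfg$n_bac_clones, 115000, 10000, 500, seed = 4)
  expect_equal(nrow(bac$truth), 87)
  # FPC order monotone in true insert midpoint
  m <- merge(bac$fpc_map, bac$truth, by = "clone_id")
  m <- m[order(m$map_contig, m$order_index), ]
  mid <- (m$start + m$end) / 2
  for (mc in unique(m$map_contig)) {
    expect_false(is.unsorted(mid[m$map_contig == mc]))
  }
  # end reads sit ~ insert apart on the genome (mapping oracle by exact search)
  for (cl in bac$truth$clone_id[1:5]) {
    e1 <- bac$end_reads$seq[bac$end_reads$clone_id == cl & bac$end_reads$end == 1]
    e2 <- bac$end_reads$seq[bac$end_reads$clone_id == cl & bac$end_reads$end == 2]
    p1 <- regexpr(e1, g, fixed = TRUE)
    p2 <- regexpr(revcomp(e2), g, fixed = TRUE)
    ins <- bac$truth$end[bac$truth$clone_id == cl] -
      bac$truth$start[bac$truth$clone_id == cl] + 1
    expect_equal(as.integer(p2) + 500 - as.integer(p1), ins)
  }
})

test_that("expression counts follow the negative-binomial model", {
  ids <- sprintf("g%04d", 1:1000)
  sim <- simulate_expression(ids, mite_genes = ids[1:50],
                             suppression_log2fc = -2, nb_dispersion = 0.05,
                             n_replicates = 5, seed = 12)
  # log2fc arithmetic: cultivar mean parameter is a quarter of baseline
  expect_equal(sim$truth$mu_cultivar[1:50], sim$truth$mu_wild[1:50] / 4)
  expect_equal(sim$truth$mu_cultivar[51:1000], sim$truth$mu_wild[51:1000])
  # moment matching on many replicates of null genes at fixed mean
  sim2 <- simulate_expression(sprintf("n%04d", 1:2000), character(0), 0,
                              nb_dispersion = 0.05, n_replicates = 5,
                              seed = 13, baseline_meanlog = log(400),
                              baseline_sdlog = 0)
  x <- as.vector(sim2$counts)
  expect_lt(abs(mean(x) - 400) / 400, 0.02)
  expect_lt(abs(var(x) - (400 + 0.05 * 400^2)) / (400 + 0.05 * 400^2), 0.1)
  # zero suppression: group means differ only by sampling noise
  de_means <- abs(rowMeans(sim2$counts[, 1:5]) - rowMeans(sim2$counts[, 6:10]))
  expect_lt(median(de_means) / 400, 0.25)
})
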