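# Link evidence, scaffold graph, hierarchical scaffolding, mega-scaffolding,
# pseudomolecule emission and assembly statistics.

test_that("link gap estimates follow the insert-minus-distances arithmetic", {
  set.seed(41)
  g <- rand_dna(12000)
  contigs <- c(A = substr(g, 1, 5000), B = substr(g, 6001, 11000))
  # one pair: read1 forward on A starting 1200 bp from A's tail, read2 on B
  # reverse-strand with its 5' base 800 bp from B's head
  r1 <- substr(contigs[["A"]], 5000 - 1200 + 1, 5000 - 1200 + 100)
  r2 <- revcomp(substr(contigs[["B"]], 800 - 100 + 1, 800))
  tier <- list(read1 = r1, read2 = r2, insert_mean = 3000, read_length = 100)
  b <- collect_link_evidence(contigs, tier)
  expect_equal(nrow(b), 1)
  expect_equal(b$support, 1)
  expect_equal(b$gap_estimate, 3000 - 1200 - 800)
  expect_setequal(c(b$end_a, b$end_b), c("tail", "head"))
  # bundle gap is the arithmetic mean over pairs (recomputation oracle)
  offs <- c(1200, 1300, 1500)
  r1s <- vapply(offs, function(d) substr(contigs[["A"]], 5000 - d + 1,
                                         5000 - d + 100), character(1))
  r2s <- rep(r2, 3)
  tier2 <- list(read1 = r1s, read2 = r2s, insert_mean = 3000, read_length = 100)
  b2 <- collect_link_evidence(contigs, tier2)
  expect_equal(b2$support, 3)
  expect_equal(b2$gap_estimate, mean(3000 - offs - 800))
  # both reads on one contig: no link
  tier3 <- list(read1 = substr(contigs[["A"]], 101, 200),
                read2 = revcomp(substr(contigs[["A"]], 2001, 2100)),
                insert_mean = 3000, read_length = 100)
  expect_warning(b3 <- collect_link_evidence(contigs, tier3), "no inter-contig")
  expect_equal(nrow(b3), 0)
})

test_that("scaffold graph thresholds and ranks bundles by support", {
  bundles <- data.frame(
    contig_a = c("A", "A"), end_a = c("tail", "tail"),
    contig_b = c("B", "B"), end_b = c("head", "tail"),
    support = c(10L, 2L), gap_estimate = c(100, 50),
    stringsAsFactors = FALSE)
  g <- build_scaffold_graph(bundles, min_support = 3)
  expect_equal(nrow(g), 1) # the support-2 bundle is below the threshold
  g2 <- build_scaffold_graph(bundles, min_support = 1)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$support, c(10L, 2L)) # ranked by support
  # majority rule: conflicting lower-support edge is dropped at resolution
  edges <- domestigen:::resolve_edges(g2)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$support, 10L)
  expect_true(nrow(g2) <= nrow(bundles)) # edge count <= bundle count
})

test_that("hierarchical scaffolding recovers order and orientation tier by tier", {
  set.seed(42)
  g <- rand_dna(3e5)
  frag <- fragment_genome(g, contig_mean = 8000, seed = 6,
                          gap_sampler = function(n)
                            round(runif(n, 80, 150) +
                                    (runif(n) < 0.3) * runif(n, 2000, 5000)))
  tiers <- simulate_reads(g, data.frame(mean = c(300, 8000), sd = c(30, 800),
                                        coverage = c(20, 8)),
                          100, error_rate = 0, seed = 7)
  hs <- hierarchical_scaffold(frag$contigs, tiers, min_support = 3)
  # partition: every contig in exactly one scaffold
  expect_setequal(hs$layout$member, names(frag$contigs))
  expect_false(any(duplicated(hs$layout$member)))
  # adjacency + orientation against the source layout
  acc <- adjacency_accuracy(
    data.frame(group = hs$layout$scaffold, member = hs$layout$member,
               orientation = hs$layout$orientation), frag$truth)
  expect_equal(acc$accuracy, 1)
  expect_gt(acc$total, length(frag$contigs) * 0.7)
  # a linear 5-contig chain collapses into one scaffold with one tier
  sub <- frag$truth[order(frag$truth$order), ][1:5, ]
  # monotonicity: raising min_support never increases the number of joins
  n_joins <- function(ms) {
    h <- hierarchical_scaffold(frag$contigs, tiers, min_support = ms)
    length(unique(h$layout$member)) - length(unique(h$layout$scaffold))
  }
  j3 <- n_joins(3); j6 <- n_joins(6); j12 <- n_joins(12)
  expect_true(j6 <= j3 && j12 <= j6)
})

test_that("mega-scaffolding orders scaffolds by FPC clone evidence", {
  set.seed(43)
  # two scaffolds; clones with order indices {3,4} hit S1, {8,9} hit S2
  s1 <- rand_dna(40000); s2 <- rand_dna(40000)
  scf <- c(S1 = s1, S2 = s2)
  mk_read <- function(s, at) substr(s, at, at + 499)
  end_reads <- data.frame(
    clone_id = c("c3", "c3", "c4", "c4", "c8", "c8", "c9", "c9"),
    end = rep(c(1L, 2L), 4),
    seq = c(mk_read(s1, 1000), mk_read(s1, 20000),
            mk_read(s1, 15000), mk_read(s1, 35000),
            mk_read(s2, 2000), mk_read(s2, 22000),
            mk_read(s2, 18000), mk_read(s2, 38000)),
    stringsAsFactors = FALSE)
  fpc <- data.frame(clone_id = c("c3", "c4", "c8", "c9"),
                    map_contig = "FPC001", order_index = c(3L, 4L, 8L, 9L),
                    stringsAsFactors = FALSE)
  mg <- mega_scaffold(scf, end_reads, fpc)
  ord <- mg$mega[order(mg$mega$rank), ]
  expect_equal(ord$scaffold, c("S1", "S2"))
  expect_equal(ord$orientation, c("+", "+"))
  # a clone linking the two scaffolds against the FPC order is rejected
  end_reads2 <- rbind(end_reads, data.frame(
    clone_id = c("cx", "cx"), end = c(1L, 2L),
    seq = c(mk_read(s2, 1000), mk_read(s1, 30000)), stringsAsFactors = FALSE))
  fpc2 <- rbind(fpc, data.frame(clone_id = "cx", map_contig = "FPC001",
                                order_index = 1L))
  mg2 <- mega_scaffold(scf, end_reads2, fpc2)
  expect_true(nrow(mg2$links) >= 1)
  # scaffold order is still driven by the map, not the contradicting link
  ord2 <- mg2$mega[order(mg2$mega$rank), ]
  expect_equal(ord2$scaffold, c("S1", "S2"))
})

test_that("pseudomolecules carry exactly one 500-N run per junction", {
  set.seed(44)
  scf <- c(S1 = rand_dna(10000), S2 = rand_dna(8000))
  mem <- data.frame(scaffold = c("S1", "S2"), orientation = c("+", "+"))
  ps <- emit_pseudomolecule(mem, scf, gap_len = 500)
  expect_equal(nchar(ps$seq), 18500)
  gap <- substring(ps$seq, 10001, 10500)
  expect_identical(gap, strrep("N", 500))
  expect_false(grepl("N", substring(ps$seq, 1, 10000)))
  expect_false(grepl("N", substring(ps$seq, 10501, 18500)))
  # single scaffold: no Ns added
  ps1 <- emit_pseudomolecule(mem[1, , drop = FALSE], scf)
  expect_identical(ps1$seq, unname(scf[["S1"]]))
  # AGP round-trip reconstructs the sequence byte-identically
  expect_identical(agp_to_sequence(ps$agp, scf), ps$seq)
  tmp <- tempfile(fileext = ".agp")
  write_agp(ps$agp, tmp)
  agp2 <- read_agp(tmp)
  expect_identical(agp_to_sequence(agp2, scf), ps$seq)
  # AGP rows alternate component / gap
  expect_identical(ps$agp$component_type, c("W", "N", "W"))
})

test_that("assembly statistics match the sort-and-accumulate oracle", {
  seqs <- vapply(c(10, 8, 6, 4, 2) * 1000, function(n) strrep("A", n),
                 character(1))
  st <- assembly_stats(seqs)
  expect_equal(st$n50, 8000) # 10+8 = 18 >= 15
  expect_equal(st$total_bp, 30000)
  expect_equal(st$non_gapped_fraction, 1.0)
  st1 <- assembly_stats("ACGTACGT")
  expect_equal(st1$n50, 8)
  st2 <- assembly_stats(c(paste0(strrep("A", 900), strrep("N", 100))))
  expect_equal(st2$non_gapped_fraction, 0.9)
  expect_error(assembly_stats(character(0)), "empty")
})
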