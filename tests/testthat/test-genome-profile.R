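# k-mer spectrum profiling, heterozygous variant calling, assembly comparison
# and Venn partitions.

test_that("k-mer spectra count canonical k-mers and scale with duplication", {
  set.seed(51)
  read <- rand_dna(150)
  sp <- kmer_spectrum(read, k = 17)
  expect_equal(sum(sp$histogram$count), 150 - 17 + 1)
  # canonical counting: a read and its reverse complement give one set
  sp_rc <- kmer_spectrum(c(read, revcomp(read)), k = 17)
  expect_equal(sp_rc$histogram$depth, 2)
  expect_equal(sp_rc$histogram$count, 134)
  # duplicating every read doubles every depth
  reads <- vapply(1:50, function(i) rand_dna(100), character(1))
  h1 <- kmer_spectrum(reads, 17)$histogram
  h2 <- kmer_spectrum(c(reads, reads), 17)$histogram
  expect_equal(h2$depth, 2 * h1$depth)
  expect_equal(h2$count, h1$count)
  # k-mers containing N are skipped: 4 (identical) A-run k-mers on each side
  spn <- kmer_spectrum(paste0(strrep("A", 20), "N", strrep("C", 20)), 17)
  expect_equal(spn$histogram$depth, 4)
  expect_equal(spn$histogram$count, 2)
})

test_that("modal depth of error-free reads matches the expectation formula", {
  set.seed(52)
  g <- rand_dna(3e5)
  rd <- simulate_reads(g, data.frame(mean = 400, sd = 40, coverage = 30),
                       100, error_rate = 0, seed = 2)
  sp <- kmer_spectrum(c(rd[[1]]$read1, rd[[1]]$read2), k = 17)
  expected_mode <- 30 * (100 - 17 + 1) / 100
  expect_lt(abs(sp$peak_depth - expected_mode) / expected_mode, 0.1)
})

test_that("genome size follows mass over peak and recovers simulated sizes", {
  # arithmetic case: constructed spectrum, peak 30, mass 1.5e8 above cutoff
  h <- data.frame(depth = c(1, 29, 30, 31), count = c(10, 1e6, 3e6, 1e6))
  sp <- structure(list(k = 17, histogram = h, error_cutoff = 2L,
                       peak_depth = 30L), class = "kmer_spectrum")
  est <- estimate_genome_size(sp)
  mass <- sum(h$depth[h$depth >= 2] * h$count[h$depth >= 2])
  expect_equal(est$size_bp, mass / est$peak_depth)
  expect_lt(abs(est$size_bp - 5e6) / 5e6, 0.05)
  # truth recovery on a simulated 1-Mb genome at 30x, and coverage invariance
  set.seed(53)
  g <- rand_dna(1e6)
  est_at <- function(cov, seed) {
    rd <- simulate_reads(g, data.frame(mean = 400, sd = 40, coverage = cov),
                         100, error_rate = 0, seed = seed)
    estimate_genome_size(kmer_spectrum(c(rd[[1]]$read1, rd[[1]]$read2), 17))
  }
  e30 <- est_at(30, 3)
  expect_lt(abs(e30$size_bp - 1e6) / 1e6, 0.05)
  e60 <- est_at(60, 4)
  expect_lt(abs(e60$size_bp - e30$size_bp) / e30$size_bp, 0.05)
  # estimation failure is explicit
  flat <- structure(list(k = 17,
                         histogram = data.frame(depth = 1, count = 100),
                         error_cutoff = 1L, peak_depth = 1L),
                    class = "kmer_spectrum")
  expect_error(estimate_genome_size(flat), "failed")
})

test_that("heterozygous calling is silent on homozygous input and recovers rates", {
  set.seed(54)
  g <- rand_dna(4e5)
  # homozygous: error-free reads from one haplotype, zero calls
  rd0 <- simulate_reads(g, data.frame(mean = 400, sd = 40, coverage = 30),
                        100, error_rate = 0, seed = 5)
  r0 <- call_het_variants(g, c(rd0[[1]]$read1, rd0[[1]]$read2))
  expect_equal(nrow(r0$calls), 0)
  expect_equal(r0$rates$snv_per_kb, 0)
  # diploid at 3.8 SNVs/kb, 40x, 0.1% error: rate within 10%, P/R >= 0.95
  dip <- make_diploid(g, 3.8, 0.5, seed = 6)
  rd <- simulate_reads(c(g, dip$haplotype2),
                       data.frame(mean = 400, sd = 40, coverage = 40),
                       100, error_rate = 0.001, seed = 7)
  res <- call_het_variants(g, c(rd[[1]]$read1, rd[[1]]$read2))
  planted_rate <- sum(dip$truth$type == "SNV") / (nchar(g) / 1000)
  expect_lt(abs(res$rates$snv_per_kb - planted_rate) / planted_rate, 0.1)
  truth_keys <- paste(dip$truth$pos[dip$truth$type == "SNV"],
                      dip$truth$alt[dip$truth$type == "SNV"])
  call_keys <- paste(res$calls$pos[res$calls$type == "SNV"],
                     res$calls$alt[res$calls$type == "SNV"])
  expect_gte(mean(call_keys %in% truth_keys), 0.95) # precision
  expect_gte(mean(truth_keys %in% call_keys), 0.95) # recall
  # InDel observations are reported as het events at plausible rates
  expect_gt(res$rates$indel_per_kb, 0)
  expect_lt(res$rates$indel_per_kb, 0.5 * 1.2)
})

test_that("assembly comparison recovers divergence rates and is symmetric", {
  set.seed(55)
  g <- rand_dna(4e5)
  # identical genomes: zero variants
  cmp0 <- compare_assemblies(g, g)
  expect_equal(nrow(cmp0$calls), 0)
  expect_equal(cmp0$rates$snv_per_kb, 0)
  # divergence at 6.9 SNVs + 0.8 InDels per kb: rates recovered within 10%
  d <- make_diploid(g, 6.9, 0.8, seed = 8) # reuse the event planter
  cmp <- compare_assemblies(d$haplotype2, g)
  exp_snv <- sum(d$truth$type == "SNV") / (nchar(g) / 1000)
  exp_ind <- sum(d$truth$type != "SNV") / (nchar(g) / 1000)
  expect_lt(abs(cmp$rates$snv_per_kb - exp_snv) / exp_snv, 0.1)
  expect_lt(abs(cmp$rates$indel_per_kb - exp_ind) / exp_ind, 0.1)
  # symmetry oracle on an SNV-only pair: positions map one-to-one with
  # alleles exchanged
  d2 <- make_diploid(g, 3, 0, seed = 9)
  fw <- compare_assemblies(d2$haplotype2, g)$calls
  bw <- compare_assemblies(g, d2$haplotype2)$calls
  expect_equal(nrow(fw), nrow(bw))
  expect_setequal(paste(fw$pos, fw$ref, fw$alt), paste(bw$pos, bw$alt, bw$ref))
})

test_that("Venn partitions are exact, disjoint and exhaustive", {
  mkset <- function(pos) data.frame(seqid = "r", pos = pos, ref = "A",
                                    alt = "T", stringsAsFactors = FALSE)
  A <- mkset(c(1, 2, 3, 4, 10, 11))
  B <- mkset(c(3, 4, 5, 6, 10))
  C <- mkset(c(4, 6, 7, 10))
  v <- variant_venn(list(A = A, B = B, C = C))
  # brute-force set-operation oracle
  expect_equal(unname(v$regions["A"]), length(setdiff(c(1,2,3,4,10,11),
                                                      union(B$pos, C$pos))))
  expect_equal(unname(v$regions["A&B"]), 1)  # {3}
  expect_equal(unname(v$regions["A&B&C"]), 2) # {4, 10}
  expect_equal(unname(v$regions["B&C"]), 1)  # {6}
  expect_equal(sum(v$regions), v$union_size)
  expect_equal(v$union_size, length(union(union(A$pos, B$pos), C$pos)))
  # disjoint sets: all intersections zero
  v2 <- variant_venn(list(X = mkset(1:3), Y = mkset(5:7)))
  expect_equal(unname(v2$regions["X&Y"]), 0)
  expect_equal(sum(v2$regions), 6)
})
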