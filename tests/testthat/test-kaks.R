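# NG86 Ka/Ks counting against an independent pathway-enumeration oracle,
# codon alignment, and the selection classification rules.

test_that("identical sequences give Ka = Ks = 0 and class no-divergence", {
  set.seed(61)
  cds <- rand_orf(40)
  aln <- align_codons(cds, cds)
  expect_equal(length(aln$codons_a), 39) # terminal stop trimmed
  kk <- compute_ka_ks(aln)
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_equal(classify_selection(kk$ka, kk$ks), "no-divergence")
})

test_that("single synonymous and nonsynonymous differences have the right sign", {
  set.seed(62)
  base <- rand_orf(30)
  # TTT -> TTC (Phe -> Phe): Ka = 0, Ks > 0, exact value from the oracle
  a <- paste0(substr(base, 1, 45), "TTT", substring(base, 49))
  b <- paste0(substr(base, 1, 45), "TTC", substring(base, 49))
  aln <- align_codons(a, b)
  kk <- compute_ka_ks(aln)
  expect_equal(kk$ka, 0)
  expect_gt(kk$ks, 0)
  ora <- oracle_ng86(aln$codons_a, aln$codons_b)
  expect_equal(kk$ks, ora$ks, tolerance = 1e-12)
  expect_equal(kk$sd, 1)
  expect_equal(kk$nd, 0)
  # GCT -> GTT (Ala -> Val): Ks = 0, Ka > 0
  a2 <- paste0(substr(base, 1, 45), "GCT", substring(base, 49))
  b2 <- paste0(substr(base, 1, 45), "GTT", substring(base, 49))
  kk2 <- compute_ka_ks(align_codons(a2, b2))
  expect_equal(kk2$ks, 0)
  expect_gt(kk2$ka, 0)
})

test_that("Ka and Ks are symmetric in sequence order", {
  set.seed(63)
  for (i in 1:5) {
    a <- rand_orf(60)
    d <- make_diploid(a, 20, 0, seed = i)
    b <- d$haplotype2
    # repair any broken stop/frame issues by construction: SNVs keep frame
    ka_ab <- try(compute_ka_ks(align_codons(a, b)), silent = TRUE)
    ka_ba <- try(compute_ka_ks(align_codons(b, a)), silent = TRUE)
    if (inherits(ka_ab, "try-error")) next
    expect_equal(ka_ab$ka, ka_ba$ka, tolerance = 1e-9)
    expect_equal(ka_ab$ks, ka_ba$ks, tolerance = 1e-9)
  }
})

test_that("classification reproduces the ratio partition rules", {
  expect_equal(classify_selection(0.3, 0.1), "positive")
  expect_equal(classify_selection(0.1, 0.3), "negative")
  expect_equal(classify_selection(0, 0), "no-divergence")
  expect_equal(classify_selection(0, 0.2), "Ks-only")
  expect_equal(classify_selection(0.2, 0), "Ka-only")
  expect_equal(classify_selection(0.105, 0.1), "neutral") # within tolerance
  expect_equal(classify_selection(0.2, 0.1, tolerance = 0), "positive")
  # scale-free: classify(c*Ka, c*Ks) == classify(Ka, Ks) for c > 0
  set.seed(64)
  for (i in 1:20) {
    ka <- runif(1, 0.01, 0.5); ks <- runif(1, 0.01, 0.5)
    cc <- runif(1, 0.1, 10)
    expect_equal(classify_selection(ka, ks), classify_selection(cc * ka, cc * ks))
  }
})

test_that("codon alignment handles gaps and matches a brute-force DP score", {
  set.seed(65)
  a <- rand_orf(25)
  # one codon inserted in b -> exactly one 3-base (1-codon) gap in a
  b <- paste0(substr(a, 1, 30), "GCA", substring(a, 31))
  aln <- align_codons(a, b)
  expect_equal(length(aln$codons_a), 24) # gap column excluded from counting
  # count gap columns via re-alignment bookkeeping: lengths differ by one codon
  expect_equal(nchar(b) - nchar(a), 3)
  # DP oracle: alignment score equals an independent affine NW on <= 30 codons
  b62 <- domestigen:::blosum62()
  for (i in 1:4) {
    x <- rand_orf(sample(15:30, 1))
    y_src <- make_diploid(x, 30, 0, seed = i + 100)$haplotype2
    px <- sub("\\*$", "", domestigen:::translate_cds(x))
    py <- sub("\\*$", "", domestigen:::translate_cds(y_src))
    if (grepl("\\*", py)) next # internal stop introduced, skip this draw
    got <- align_codons(x, y_src)$score
    want <- oracle_nw_score(px, py, b62)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("selection scan tallies classes conservatively", {
  # empty cluster set: all counts zero
  empty <- list(cluster = character(0), status = character(0),
                copies = data.frame(wild = integer(0), cultivar = integer(0)),
                members = list(wild = list(), cultivar = list()))
  sc0 <- selection_scan(empty, character(0))
  expect_true(all(sc0$counts == 0))
  # constructed cohort: sum of class counts equals eligible clusters
  set.seed(66)
  n <- 12
  cds_w <- vapply(1:n, function(i) rand_orf(50), character(1))
  cds_c <- vapply(cds_w, function(x) make_diploid(x, 15, 0, seed = 7)$haplotype2,
                  character(1))
  ids_w <- paste0("w", 1:n); ids_c <- paste0("c", 1:n)
  ortho <- list(cluster = sprintf("OC%03d", 1:n), status = rep("shared", n),
                copies = data.frame(wild = rep(1L, n), cultivar = rep(1L, n)),
                members = list(wild = as.list(ids_w), cultivar = as.list(ids_c)))
  cds <- setNames(c(cds_w, cds_c), c(ids_w, ids_c))
  sc <- selection_scan(ortho, cds)
  expect_equal(sum(sc$counts), nrow(sc$records))
  expect_lte(nrow(sc$records), n)
  expect_true(all(sc$records$ka >= 0 & sc$records$ks >= 0))
})
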