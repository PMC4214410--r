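# Upstream window extraction, structural MITE detection, and cross-genome
# presence comparison.

test_that("upstream windows follow strand and truncation rules", {
  set.seed(81)
  g <- rand_dna(20000)
  genes <- data.frame(id = c("gA", "gB", "gC"),
                      start = c(5001, 12000, 201), end = c(5600, 12600, 800),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  reg <- extract_upstream(genes, g, window = 1000)
  # plus-strand gene at 5,001: window covers 4,001-5,000
  expect_equal(reg$start[1], 4001)
  expect_equal(reg$end[1], 5000)
  expect_identical(reg$seq[1], substring(g, 4001, 5000))
  expect_false(reg$truncated[1])
  # minus-strand region is the reverse complement of the forward window
  expect_equal(reg$start[2], 12601)
  expect_equal(reg$end[2], 13600)
  expect_identical(reg$seq[2], revcomp(substring(g, 12601, 13600)))
  # gene 200 bp from the contig edge: truncated 200 bp region
  expect_equal(reg$start[3], 1)
  expect_equal(reg$end[3], 200)
  expect_true(reg$truncated[3])
  expect_error(extract_upstream(data.frame(id = "x", start = 0, end = 10,
                                           strand = "+"), g),
               "out of genome bounds")
})

test_that("the detector finds planted elements and rejects TSD-less repeats", {
  set.seed(82)
  tir <- rand_dna(15)
  core <- rand_dna(120)
  elem <- paste0(tir, core, revcomp(tir))
  win <- paste0(rand_dna(300), "TA", elem, "TA", rand_dna(400))
  d <- detect_mites(win)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 303)
  expect_equal(d$end, 302 + nchar(elem))
  expect_gte(d$tir_len, 15)
  expect_equal(d$tsd_len, 2)
  # same element without a duplicated target site: rejected at its boundaries
  win2 <- paste0(rand_dna(300), "TA", elem, "GG", rand_dna(400))
  d2 <- detect_mites(win2)
  expect_false(any(d2$start == 303 & d2$end == 302 + nchar(elem)))
  # element length bounds respected
  short <- paste0(rand_dna(100), "TA", tir, revcomp(tir), "TA", rand_dna(100))
  expect_false(any(detect_mites(short)$end - detect_mites(short)$start + 1 < 50))
})

test_that("false-call rate on dinucleotide-shuffled windows stays below 0.05/kb", {
  set.seed(83)
  n_win <- 250
  calls <- 0
  for (i in 1:n_win) {
    w <- dinucleotide_shuffle(rand_dna(1000))
    calls <- calls + nrow(detect_mites(w))
  }
  expect_lt(calls / n_win, 0.05) # calls per kb
})

test_that("presence comparison labels shared and specific insertions exactly", {
  set.seed(84)
  n <- 50
  wins <- vapply(1:n, function(i) rand_dna(1000), character(1))
  genes_a <- sprintf("a%03d", 1:n)
  genes_b <- sprintf("b%03d", 1:n)
  # plant 20 shared (same element, same window), 30 cultivar-specific
  elems <- vapply(1:n, function(i) {
    t <- rand_dna(sample(12:20, 1))
    paste0(t, rand_dna(sample(60:200, 1)), revcomp(t))
  }, character(1))
  # host TA at [at, at+1] duplicated around the element
  insert_at <- function(w, e, at) paste0(substr(w, 1, at - 1), "TA", e, "TA",
                                         substring(w, at + 2))
  wa <- wins; wb <- wins
  pos <- sample(200:600, n, replace = TRUE)
  ins_a <- ins_b <- list()
  for (i in 1:20) { # shared
    wa[i] <- insert_at(wa[i], elems[i], pos[i])
    wb[i] <- insert_at(wb[i], elems[i], pos[i])
    ins_a[[length(ins_a) + 1]] <- data.frame(
      gene = genes_a[i], start = pos[i] + 2, end = pos[i] + 1 + nchar(elems[i]))
    ins_b[[length(ins_b) + 1]] <- data.frame(
      gene = genes_b[i], start = pos[i] + 2, end = pos[i] + 1 + nchar(elems[i]))
  }
  for (i in 21:50) { # cultivar only
    wb[i] <- insert_at(wb[i], elems[i], pos[i])
    ins_b[[length(ins_b) + 1]] <- data.frame(
      gene = genes_b[i], start = pos[i] + 2, end = pos[i] + 1 + nchar(elems[i]))
  }
  fake_regions <- function(gn, ws) data.frame(gene = gn, start = 1,
                                              end = nchar(ws), strand = "+",
                                              seq = ws, truncated = FALSE,
                                              stringsAsFactors = FALSE)
  ra <- fake_regions(genes_a, wa); rb <- fake_regions(genes_b, wb)
  ma <- do.call(rbind, ins_a); mb <- do.call(rbind, ins_b)
  pairs <- data.frame(gene_a = genes_a, gene_b = genes_b,
                      gene = sprintf("cl%03d", 1:n), stringsAsFactors = FALSE)
  pres <- compare_presence(pairs, ra, rb, ma, mb)
  tab <- table(pres$status)
  # truth-table oracle: exact label counts (shared rows appear once per genome)
  expect_equal(unname(tab["shared"]), 40)
  expect_equal(unname(tab["cultivar-specific"]), 30)
  expect_true(!"wild-specific" %in% names(tab))
  # the detector also recovers the planted elements in these windows
  det_b <- detect_mites_regions(rb)
  hit <- vapply(seq_len(nrow(mb)), function(i) {
    d <- det_b[det_b$gene == mb$gene[i], , drop = FALSE]
    any(abs(d$start - mb$start[i]) <= 10 & abs(d$end - mb$end[i]) <= 10)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("planting probability zero leaves the genome untouched", {
  set.seed(85)
  g <- rand_dna(30000)
  wins <- data.frame(gene = c("g1", "g2"), start = c(1000, 9000),
                     end = c(1999, 9999), strand = "+")
  p <- plant_mites(g, wins, 0, seed = 2)
  expect_identical(p$genome, g)
  expect_equal(sum(!p$truth$skipped), 0)
})
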