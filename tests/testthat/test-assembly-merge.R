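# Redundancy filtering, dovetail overlap discovery and OLC merging.

test_that("redundant secondary contigs are removed by containment", {
  set.seed(31)
  primary <- setNames(vapply(1:5, function(i) rand_dna(5000), character(1)),
                      paste0("P", 1:5))
  secondary <- setNames(vapply(1:10, function(i) rand_dna(1000), character(1)),
                        paste0("S", 1:10))
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    k <- rbinom(1, length(ch), rate)
    for (p in sample(length(ch), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  # exact substring, two 1%-mutated copies (one reverse strand)
  secondary["S1"] <- substr(primary["P1"], 1001, 2000)
  secondary["S2"] <- mutate(substr(primary["P2"], 2001, 3000), 0.01)
  secondary["S3"] <- mutate(revcomp(substr(primary["P3"], 501, 1500)), 0.01)
  res <- filter_redundant_contigs(primary, secondary, 0.95, 0.90)
  expect_setequal(res$log$id[res$log$removed], c("S1", "S2", "S3"))
  expect_setequal(names(res$retained), paste0("S", 4:10))
  # alignment oracle: removed contigs really are contained at the thresholds
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (id in c("S1", "S2", "S3")) {
    best <- res$log[res$log$id == id, ]
    target <- primary[[best$best_target]]
    ident <- max(vapply(c(target, revcomp(target)), function(tg) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(secondary[[id]]), Biostrings::DNAString(tg),
        type = "local", substitutionMatrix = submat,
        gapOpening = 5, gapExtension = 2)
      Biostrings::nmatch(aln) / nchar(secondary[[id]])
    }, numeric(1)))
    expect_gte(ident, 0.95 * 0.90)
  }
  # empty primary set: all retained
  expect_message(r0 <- filter_redundant_contigs(character(0), secondary),
                 "empty primary")
  expect_identical(r0$retained, secondary)
})

test_that("dovetail overlaps are found on both strands", {
  set.seed(32)
  g <- rand_dna(3000)
  a <- substr(g, 1, 1200)
  b <- substr(g, 1081, 2400)   # 120 bp exact suffix-prefix overlap
  ov <- compute_overlaps(c(A = a, B = b), min_overlap_len = 50)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 120)
  expect_equal(ov$orientation, "same")
  expect_equal(ov$identity, 1)
  # reverse-complement-only overlap flagged reverse
  ov2 <- compute_overlaps(c(A = a, B = revcomp(b)), min_overlap_len = 50)
  expect_equal(nrow(ov2), 1)
  expect_equal(ov2$orientation, "reverse")
  expect_equal(ov2$length, 120)
  # exhaustive oracle: the overlap really is a suffix-prefix match
  expect_identical(substr(a, nchar(a) - 119, nchar(a)), substr(b, 1, 120))
  # no shared region: empty set
  ov3 <- compute_overlaps(c(A = rand_dna(800), B = rand_dna(800)),
                          min_overlap_len = 50)
  expect_equal(nrow(ov3), 0)
})

test_that("olc_merge joins unambiguous chains and respects branch points", {
  set.seed(33)
  g <- rand_dna(2600)
  a <- substr(g, 1, 1000)
  b <- substr(g, 801, 1800)
  c_ <- substr(g, 1601, 2600)
  ctg <- c(A = a, B = b, C = c_)
  ov <- compute_overlaps(ctg, min_overlap_len = 100)
  m <- olc_merge(ctg, ov)
  expect_equal(length(m$contigs), 1)
  expect_equal(nchar(m$contigs[[1]]), 2600) # sum lengths - used overlaps
  expect_true(m$contigs[[1]] == g || m$contigs[[1]] == revcomp(g))
  # ambiguity: A overlaps both B and C at its tail -> A unmerged at that end
  b2 <- paste0(substr(g, 801, 1000), rand_dna(800))
  ctg2 <- c(A = a, B = b2, C = substr(g, 801, 1800))
  ov2 <- compute_overlaps(ctg2, min_overlap_len = 100)
  expect_gte(nrow(ov2), 2)
  m2 <- olc_merge(ctg2, ov2)
  expect_true("A" %in% names(m2$contigs)) # A passed through unmerged
})

test_that("error-free fragmentation re-merges to the exact source string", {
  set.seed(34)
  src <- rand_dna(30000)
  pieces <- shred_overlapping(src, 2000, 500, seed = 5)
  ov <- compute_overlaps(pieces, min_overlap_len = 100)
  m <- olc_merge(pieces, ov)
  expect_equal(length(m$contigs), 1)
  expect_true(m$contigs[[1]] == src || m$contigs[[1]] == revcomp(src))
  # idempotence: re-merging the output changes nothing
  ov2 <- compute_overlaps(m$contigs, min_overlap_len = 100)
  m3 <- olc_merge(m$contigs, ov2)
  expect_equal(length(m3$contigs), 1)
  expect_identical(unname(m3$contigs[[1]]), unname(m$contigs[[1]]))
  # no sequence invention: every 31-mer of the merged contig occurs in an input
  merged <- m$contigs[[1]]
  input_kmers <- unique(unlist(lapply(c(pieces, revcomp(pieces)), function(p) {
    substring(p, 1:(nchar(p) - 30), 31:nchar(p))
  })))
  merged_kmers <- unique(substring(merged, 1:(nchar(merged) - 30),
                                   31:nchar(merged)))
  expect_true(all(merged_kmers %in% input_kmers))
})

test_that("merge layout equals the brute-force chain enumeration on small sets", {
  set.seed(35)
  src <- rand_dna(2360)
  # 8 pieces of 400 bp with 120 bp overlaps
  starts <- seq(1, by = 280, length.out = 8)
  pieces <- setNames(substring(src, starts, starts + 399), paste0("p", 1:8))
  flip <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  pieces[flip] <- revcomp(pieces[flip])
  ord <- sample(8)
  shuffled <- pieces[ord]
  # brute force: all exact suffix-prefix overlaps >= 100 over all orientations
  oriented <- c(shuffled, setNames(revcomp(shuffled),
                                   paste0(names(shuffled), "_rc")))
  edges <- list()
  for (x in names(oriented)) {
    for (y in names(oriented)) {
      if (sub("_rc$", "", x) == sub("_rc$", "", y)) next
      for (olen in 100:400) {
        sx <- oriented[[x]]; sy <- oriented[[y]]
        if (olen > nchar(sx) || olen > nchar(sy)) break
        if (substr(sx, nchar(sx) - olen + 1, nchar(sx)) ==
            substr(sy, 1, olen)) {
          edges[[length(edges) + 1]] <- c(x, y, olen)
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  # each oriented piece has at most one successor: follow the chain from a
  # piece with no incoming edge
  succ <- setNames(edges[, 2], edges[, 1])
  start_node <- setdiff(edges[, 1], edges[, 2])[1]
  chain_bf <- start_node
  while (chain_bf[length(chain_bf)] %in% names(succ)) {
    chain_bf <- c(chain_bf, succ[[chain_bf[length(chain_bf)]]])
  }
  expect_equal(length(chain_bf), 8)
  # the implementation must produce the same member order (up to reversal)
  ov <- compute_overlaps(shuffled, min_overlap_len = 100)
  m <- olc_merge(shuffled, ov)
  expect_equal(length(m$contigs), 1)
  expect_true(m$contigs[[1]] == src || m$contigs[[1]] == revcomp(src))
  got <- m$layout$member
  want <- sub("_rc$", "", chain_bf)
  expect_true(identical(got, want) || identical(got, rev(want)))
})
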