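# Orthologue clustering: shared / unique / copy-number labels.

test_that("orthologue clusters capture shared, unique and duplicated genes", {
  set.seed(71)
  base <- vapply(1:6, function(i) rand_orf(80), character(1))
  mut <- function(x, seed) make_diploid(x, 8, 0, seed = seed)$haplotype2
  wild <- data.frame(id = paste0("w", 1:6), cds = base,
                     stringsAsFactors = FALSE)
  # cultivar: orthologues of 1..5 (slightly diverged), gene 6 missing,
  # gene 2 duplicated
  cult <- data.frame(
    id = c(paste0("c", 1:5), "c2dup"),
    cds = c(vapply(seq_len(5), function(i) mut(base[i], i), character(1)),
            mut(base[2], 99)),
    stringsAsFactors = FALSE)
  # reference genome carries identical copies of genes 1..6
  ref <- data.frame(id = paste0("r", 1:6), cds = base, stringsAsFactors = FALSE)
  ortho <- find_orthologues(list(wild = wild, cultivar = cult,
                                 reference = ref))
  df <- data.frame(cluster = ortho$cluster, status = ortho$status,
                   ortho$copies)
  # identical gene in all three genomes: one shared cluster, copy number 1
  # (genes 1, 3, 4, 5)
  full <- df[df$wild == 1 & df$reference == 1 & df$cultivar == 1, ]
  expect_gte(nrow(full), 3)
  expect_true(all(full$status == "shared"))
  # wild gene 6 has a reference partner but no cultivar copy
  c6 <- which(vapply(seq_along(ortho$cluster), function(i)
    "w6" %in% ortho$members$wild[[i]], logical(1)))
  expect_equal(ortho$copies$cultivar[c6], 0)
  expect_equal(ortho$copies$reference[c6], 1)
  # duplicated cultivar gene: copy number 2 in its cluster
  c2 <- which(vapply(seq_along(ortho$cluster), function(i)
    "w2" %in% ortho$members$wild[[i]], logical(1)))
  expect_equal(ortho$copies$cultivar[c2], 2)
  # a gene present in only one genome forms a unique cluster
  lone <- data.frame(id = "w_only", cds = rand_orf(80), stringsAsFactors = FALSE)
  o2 <- find_orthologues(list(wild = rbind(wild, lone), cultivar = cult))
  i_lone <- which(vapply(seq_along(o2$cluster), function(i)
    "w_only" %in% o2$members$wild[[i]], logical(1)))
  expect_equal(o2$status[i_lone], "wild-unique")
  # duplicate ids are rejected
  expect_error(find_orthologues(list(a = wild, b = wild)), "duplicate")
})
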