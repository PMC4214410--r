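# Differential expression, association tallies and the permutation control.

test_that("identical count columns yield no significant calls", {
  set.seed(91)
  base <- matrix(rnbinom(200 * 5, mu = 300, size = 20), 200, 5)
  counts <- cbind(base, base)
  rownames(counts) <- sprintf("g%03d", 1:200)
  groups <- factor(rep(c("wild", "cultivar"), each = 5),
                   levels = c("wild", "cultivar"))
  de <- diff_expression(counts, groups)
  expect_true(all(de$call == "none"))
  expect_equal(de$log2fc, rep(0, 200))
})

test_that("planted suppression is called lower with adequate power", {
  ids <- sprintf("g%04d", 1:400)
  sim <- simulate_expression(ids, mite_genes = ids[1:30],
                             suppression_log2fc = -2, nb_dispersion = 0.05,
                             n_replicates = 5, seed = 92,
                             baseline_meanlog = log(400), baseline_sdlog = 0.3)
  de <- diff_expression(sim$counts, sim$groups)
  expect_gte(mean(de$call[de$gene %in% ids[1:30]] == "lower"), 0.9)
  # BH controls the FDR, so a small number of null calls is admissible
  expect_lte(sum(de$call[!de$gene %in% ids[1:30]] != "none"), 4)
})

test_that("type-I error over null genes stays within the alpha bound", {
  ids <- sprintf("g%04d", 1:2000)
  sim <- simulate_expression(ids, character(0), 0, 0.05, 5, seed = 93)
  de <- diff_expression(sim$counts, sim$groups, alpha = 0.05)
  frac_sig <- mean(de$call != "none")
  expect_lte(frac_sig, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  # raw p-values are roughly uniform: fraction below 0.05 near alpha
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.03)
})

test_that("association summaries are conservative tallies", {
  de <- data.frame(gene = paste0("g", 1:10),
                   call = c("lower", "lower", "higher", rep("none", 7)),
                   stringsAsFactors = FALSE)
  pres <- data.frame(gene = paste0("g", 1:5),
                     status = c(rep("cultivar-specific", 4), "shared"),
                     stringsAsFactors = FALSE)
  a <- associate(pres, de)
  expect_equal(a$n_specific, 4)
  expect_equal(a$n_lower, 2)
  expect_equal(a$n_higher, 1)
  expect_equal(a$n_lower + a$n_higher + a$n_none, a$n_specific)
  expect_equal(a$frac_lower, 0.5)
  # no cultivar-specific insertions: all-zero summary
  a0 <- associate(pres[pres$status == "shared", , drop = FALSE], de)
  expect_equal(a0$n_specific, 0)
  expect_equal(a0$frac_lower, 0)
})

test_that("the permutation test detects planted suppression and not noise", {
  ids <- sprintf("g%04d", 1:400)
  sim <- simulate_expression(ids, ids[1:30], -2, 0.05, 5, seed = 94)
  de <- diff_expression(sim$counts, sim$groups)
  p_hit <- permutation_association(de, ids[1:30], n_perm = 999, seed = 5)
  expect_lte(p_hit$p, 0.05)
  sim0 <- simulate_expression(ids, ids[1:30], 0, 0.05, 5, seed = 95)
  de0 <- diff_expression(sim0$counts, sim0$groups)
  p_null <- permutation_association(de0, ids[1:30], n_perm = 999, seed = 6)
  expect_gt(p_null$p, 0.05)
})
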