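#' Simulate a complete wild/cultivar study
#'
#' Orchestrates the generators: ancestral genome with gene models, lineage
#' divergence (intergenic SNVs/InDels, regime-biased coding changes, PAV/CNV),
#' MITE insertions into 1-kb upstream windows (planted after divergence, so
#' shared insertions sit at homologous positions with identical elements),
#' diploid second haplotypes per lineage, tiered read libraries, BAC/FPC
#' resources and negative-binomial expression counts with MITE-linked
#' suppression. Returns all data plus machine-readable truth tables.
#'
#' @param config a [simulation_config()].
#' @param with_reads simulate read libraries (can be switched off when only
#'   genomes are needed).
#' @return a list bundling genomes, genes, reads, BAC/FPC data, expression and
#'   `truth`.
#' @export
simulate_study <- function(config, with_reads = TRUE) {
  anc <- generate_ancestral_genome(config)
  div <- diverge_lineages(anc, config)

  # MITE planting (after divergence; ancestor window coordinates decide
  # homologous insertion points)
  anc_windows <- extract_upstream(anc$genes, anc$genome,
                                  config$upstream_window)
  n <- nrow(anc$genes)
  mite_truth <- list()
  events_by_lineage <- list(wild = empty_events(), cultivar = empty_events())
  with_seed(derive_seed(config$seed, "mites"), {
    present_w <- runif(n) < config$mite_insertion_prob
    present_c <- runif(n) < config$mite_insertion_prob
    for (i in seq_len(n)) {
      if (!present_w[i] && !present_c[i]) next
      gid <- anc$genes$id[i]
      w <- anc_windows[i, ]
      wlen <- w$end - w$start + 1
      len <- sample(50:800, 1)
      tir <- sample(10:30, 1)
      if (len <= 2 * tir + 10) len <- 2 * tir + 10 + sample.int(40, 1)
      if (wlen < len + 60) next # window too short, skip
      wseq <- substring(anc$genome, w$start, w$end)
      # the insertion shifts higher coordinates by the element length; the
      # element must stay within the final 1-kb window, whose gene-side
      # anchor is at high coordinates for + genes and low ones for - genes
      ta <- gregexpr("TA", wseq, fixed = TRUE)[[1]]
      ta <- if (anc$genes$strand[i] == "+") {
        ta[ta > len + 40 & ta < wlen - 10]
      } else {
        ta[ta > 10 & ta < wlen - len - 40]
      }
      if (length(ta) >= 1 && ta[1] != -1) {
        p_local <- ta[sample.int(length(ta), 1)]
        tsd <- "TA"
      } else {
        p_local <- if (anc$genes$strand[i] == "+")
          sample(seq(len + 41, wlen - 10), 1) else
            sample(seq(11, wlen - len - 40), 1)
        tsd <- substring(wseq, p_local, p_local + 1)
      }
      elem <- make_mite_element(len, tir)
      anc_pos <- w$start + p_local - 1L + 2L # insertion point after host TSD
      for (lin in c("wild", "cultivar")) {
        if ((lin == "wild" && !present_w[i]) ||
            (lin == "cultivar" && !present_c[i])) next
        deleted <- gid %in% div$truth$pav$gene[div$truth$pav$lineage == lin]
        if (deleted) next
        lin_pos <- lift_positions(div[[lin]]$lift, anc_pos)
        events_by_lineage[[lin]] <- rbind(events_by_lineage[[lin]], data.frame(
          pos = lin_pos, ref_len = 0L, alt = paste0(elem, tsd),
          type = "mite_insertion", lineage = lin, stringsAsFactors = FALSE))
        mite_truth[[length(mite_truth) + 1]] <- data.frame(
          gene = gid, lineage = lin, anc_pos = anc_pos, elem_len = len,
          tir_len = tir, tsd = tsd, stringsAsFactors = FALSE)
      }
    }
  })
  mite_truth <- if (length(mite_truth)) do.call(rbind, mite_truth) else
    data.frame(gene = character(0), lineage = character(0),
               anc_pos = integer(0), elem_len = integer(0),
               tir_len = integer(0), tsd = character(0))

  lineages <- lapply(c(wild = "wild", cultivar = "cultivar"), function(lin) {
    base <- div[[lin]]
    applied <- apply_events(base$genome, events_by_lineage[[lin]])
    genes <- base$genes
    if (nrow(genes) > 0) {
      genes$start <- lift_positions(applied$lift, genes$start)
      genes$end <- lift_positions(applied$lift, genes$end)
    }
    list(genome = applied$seq, genes = genes, mite_lift = applied$lift)
  })

  # MITE element coordinates on the final lineage genomes
  if (nrow(mite_truth) > 0) {
    mite_truth$start <- NA_integer_; mite_truth$end <- NA_integer_
    for (r in seq_len(nrow(mite_truth))) {
      lin <- mite_truth$lineage[r]
      p_div <- lift_positions(div[[lin]]$lift, mite_truth$anc_pos[r])
      p_fin <- lift_positions(lineages[[lin]]$mite_lift, p_div)
      mite_truth$start[r] <- p_fin - mite_truth$elem_len[r] - 2L
      mite_truth$end[r] <- p_fin - 3L
    }
    pres <- table(mite_truth$gene, mite_truth$lineage)
    status <- vapply(rownames(pres), function(g) {
      if (pres[g, "wild"] > 0 && pres[g, "cultivar"] > 0) "shared"
      else if (pres[g, "cultivar"] > 0) "cultivar-specific"
      else "wild-specific"
    }, character(1))
    mite_truth$status <- status[mite_truth$gene]
  } else mite_truth$status <- character(0)

  # diploid haplotypes
  het <- list(
    wild = make_diploid(lineages$wild$genome, config$het_snv_rate,
                        config$het_indel_rate,
                        seed = derive_seed(config$seed, "diploid") + 1L),
    cultivar = make_diploid(lineages$cultivar$genome,
                            config$het_snv_rate_cultivar %||% 3.4,
                            config$het_indel_rate,
                            seed = derive_seed(config$seed, "diploid") + 2L))

  reads <- NULL
  bac <- NULL
  if (with_reads) {
    reads <- list(
      wild = simulate_reads(c(lineages$wild$genome, het$wild$haplotype2),
                            config$insert_tiers, config$read_length,
                            config$error_rate,
                            seed = derive_seed(config$seed, "reads") + 1L),
      cultivar = simulate_reads(c(lineages$cultivar$genome,
                                  het$cultivar$haplotype2),
                                config$insert_tiers, config$read_length,
                                config$error_rate,
                                seed = derive_seed(config$seed, "reads") + 2L))
    bac <- simulate_bac_and_fpc(lineages$wild$genome, config$n_bac_clones,
                                config$bac_insert_mean, config$bac_insert_sd,
                                config$bac_end_read_length,
                                seed = config$seed)
  }

  # expression: suppression applies to genes with a cultivar-specific MITE
  spec_genes <- unique(mite_truth$gene[mite_truth$status == "cultivar-specific"])
  both <- intersect(lineages$wild$genes$id, lineages$cultivar$genes$id)
  expr <- simulate_expression(both, spec_genes, config$suppression_log2fc,
                              config$nb_dispersion, config$n_replicates,
                              seed = config$seed)

  list(ancestor = anc, wild = lineages$wild, cultivar = lineages$cultivar,
       het = het, reads = reads, bac = bac, expression = expr,
       truth = c(div$truth, list(mites = mite_truth,
                                 het_wild = het$wild$truth,
                                 het_cultivar = het$cultivar$truth,
                                 expression = expr$truth)),
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
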