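# End-to-end orchestration: simulate -> merge -> scaffold -> profile ->
# selection -> mite, with a run manifest (config echo, per-stage seeds, output
# checksums). Rerunning with identical config and seed reproduces identical
# output checksums.

stage_order <- c("simulate", "merge", "scaffold", "profile", "selection", "mite")

#' Run the full analysis pipeline on a simulated study
#'
#' Stages execute in dependency order; every stage writes its outputs under
#' `outdir/<stage>/` and is recorded in the manifest. Disabling a stage omits
#' exactly its outputs; a stage whose upstream outputs are missing raises a
#' dependency error naming the stage.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created).
#' @param stages subset of the six stages to run.
#' @param min_support scaffold-graph support threshold.
#' @return the manifest (invisibly also written to `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, outdir,
                         stages = stage_order, min_support = 5) {
  check_that(all(stages %in% stage_order), "unknown stage name")
  stages <- stage_order[stage_order %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "domestigen",
                   version = as.character(utils::packageVersion("domestigen")),
                   seed = config$seed,
                   config_hash = substr(digest_string(paste(
                     deparse(unclass(config)), collapse = "")), 1, 16),
                   config = unclass(config),
                   stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, deps, fun) {
    if (!name %in% stages) return(invisible(NULL))
    for (d in deps) {
      if (!d %in% stages) {
        stop(sprintf("stage '%s' requires stage '%s' which is not enabled",
                     name, d), call. = FALSE)
      }
    }
    t0 <- proc.time()[["elapsed"]]
    dir.create(file.path(outdir, name), showWarnings = FALSE)
    fun(file.path(outdir, name))
    files <- list.files(file.path(outdir, name), recursive = TRUE,
                        full.names = TRUE)
    manifest$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name),
      outputs = setNames(as.list(unname(tools::md5sum(files))),
                         basename(files)),
      wallclock_s = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  run_stage("simulate", character(0), function(dir) {
    study <- simulate_study(config)
    state$study <- study
    write_fasta(c(wild = study$wild$genome, cultivar = study$cultivar$genome,
                  wild_hap2 = study$het$wild$haplotype2,
                  cultivar_hap2 = study$het$cultivar$haplotype2),
                file.path(dir, "genomes.fasta"))
    write_gff3(study$wild$genes, file.path(dir, "wild_genes.gff3"),
               seqid = "wild")
    write_gff3(study$cultivar$genes, file.path(dir, "cultivar_genes.gff3"),
               seqid = "cultivar")
    write_vcf(vcf_normalise(
      data.frame(seqid = "wild", pos = study$truth$het_wild$pos,
                 ref = study$truth$het_wild$ref,
                 alt = study$truth$het_wild$alt,
                 type = study$truth$het_wild$type),
      study$wild$genome), file.path(dir, "het_wild_truth.vcf"),
      contigs = c(wild = nchar(study$wild$genome)))
    write_tsv(study$truth$mites, file.path(dir, "mite_truth.tsv"))
    write_tsv(study$bac$fpc_map, file.path(dir, "fpc_map.tsv"))
    write_tsv(as.data.frame(study$expression$counts),
              file.path(dir, "expression_counts.tsv"))
    tier1 <- study$reads$wild[[1]]
    write_fastq(tier1$read1, file.path(dir, "wild_tier1_R1.fastq"))
    write_fastq(tier1$read2, file.path(dir, "wild_tier1_R2.fastq"))
  })

  run_stage("merge", "simulate", function(dir) {
    study <- state$study
    g <- study$wild$genome
    L <- nchar(g)
    # emulate two input assemblies: a long-fragment primary set covering the
    # first 60% and a short-fragment secondary set covering everything
    primary <- shred_overlapping(substr(g, 1, floor(0.6 * L)), 6000, 500,
                                 seed = derive_seed(config$seed, "merge"),
                                 flip = FALSE)
    names(primary) <- paste0("A_", names(primary))
    secondary <- shred_overlapping(g, 2500, 400,
                                   seed = derive_seed(config$seed, "merge") + 1L)
    names(secondary) <- paste0("B_", names(secondary))
    filt <- filter_redundant_contigs(primary, secondary)
    pool <- c(primary, filt$retained)
    ov <- compute_overlaps(pool, min_overlap_len = 100)
    merged <- olc_merge(pool, ov)
    state$merged <- merged
    write_fasta(merged$contigs, file.path(dir, "merged_contigs.fasta"))
    write_tsv(filt$log, file.path(dir, "redundancy_log.tsv"))
    write_tsv(ov, file.path(dir, "overlaps.tsv"))
  })

  run_stage("scaffold", "simulate", function(dir) {
    study <- state$study
    frag <- fragment_genome(study$wild$genome, contig_mean = 12000,
                            seed = derive_seed(config$seed, "scaffold"))
    tiers <- simulate_reads(study$wild$genome, config$insert_tiers,
                            config$read_length, error_rate = 0,
                            seed = derive_seed(config$seed, "scaffold") + 1L)
    hs <- hierarchical_scaffold(frag$contigs, tiers, min_support = min_support)
    scf <- emit_scaffold_seqs(frag$contigs, hs$layout)
    mg <- mega_scaffold(scf, study$bac$end_reads, study$bac$fpc_map)
    state$scaffolds <- list(frag = frag, layout = hs$layout, seqs = scf,
                            mega = mg)
    pseudos <- list()
    for (m in unique(mg$mega$mega)) {
      mem <- mg$mega[mg$mega$mega == m, , drop = FALSE]
      ps <- emit_pseudomolecule(mem, scf, object_name = m)
      pseudos[[m]] <- ps$seq
      write_agp(ps$agp, file.path(dir, paste0(m, ".agp")))
    }
    write_fasta(unlist(pseudos), file.path(dir, "pseudomolecules.fasta"))
    st <- assembly_stats(unlist(pseudos))
    write_tsv(as.data.frame(st), file.path(dir, "assembly_stats.tsv"))
  })

  run_stage("profile", "simulate", function(dir) {
    study <- state$study
    tier1 <- study$reads$wild[[1]]
    reads <- c(tier1$read1, tier1$read2)
    sp <- kmer_spectrum(reads, k = 17)
    gs <- estimate_genome_size(sp)
    write_tsv(sp$histogram, file.path(dir, "kmer_spectrum.tsv"))
    het <- call_het_variants(study$wild$genome, reads)
    write_vcf(vcf_normalise(het$calls, study$wild$genome),
              file.path(dir, "het_calls.vcf"),
              contigs = c(assembly = nchar(study$wild$genome)))
    cmp <- compare_assemblies(study$cultivar$genome, study$wild$genome)
    wv <- compare_assemblies(study$wild$genome, study$ancestor$genome)
    cv <- compare_assemblies(study$cultivar$genome, study$ancestor$genome)
    venn <- variant_venn(list(wild = wv$calls, cultivar = cv$calls))
    summary <- data.frame(
      metric = c("genome_size_bp", "het_snv_per_kb", "het_indel_per_kb",
                 "divergence_snv_per_kb", "divergence_indel_per_kb",
                 paste0("venn_", names(venn$regions))),
      value = c(gs$size_bp, het$rates$snv_per_kb, het$rates$indel_per_kb,
                cmp$rates$snv_per_kb, cmp$rates$indel_per_kb,
                as.numeric(venn$regions)))
    write_tsv(summary, file.path(dir, "profile_summary.tsv"))
    state$profile <- summary
  })

  run_stage("selection", "simulate", function(dir) {
    study <- state$study
    wg <- study$wild$genes; cg <- study$cultivar$genes
    wg$id <- paste0("w_", wg$id); cg$id <- paste0("c_", cg$id)
    ortho <- find_orthologues(list(wild = wg[, c("id", "cds")],
                                   cultivar = cg[, c("id", "cds")]))
    cds <- setNames(c(wg$cds, cg$cds), c(wg$id, cg$id))
    scan <- selection_scan(ortho, cds)
    state$ortho <- ortho
    state$selection <- scan
    write_tsv(scan$records, file.path(dir, "selection_records.tsv"))
    write_tsv(data.frame(class = names(scan$counts),
                         count = as.integer(scan$counts)),
              file.path(dir, "selection_counts.tsv"))
    write_tsv(data.frame(cluster = ortho$cluster, status = ortho$status,
                         ortho$copies), file.path(dir, "clusters.tsv"))
  })

  run_stage("mite", c("simulate", "selection"), function(dir) {
    study <- state$study
    ortho <- state$ortho
    one2one <- ortho$copies$wild == 1 & ortho$copies$cultivar == 1
    pairs <- data.frame(
      gene_a = vapply(ortho$members$wild[one2one], `[`, character(1), 1),
      gene_b = vapply(ortho$members$cultivar[one2one], `[`, character(1), 1),
      stringsAsFactors = FALSE)
    pairs$gene <- sub("^w_", "", pairs$gene_a)
    wg <- study$wild$genes; cg <- study$cultivar$genes
    wg$id <- paste0("w_", wg$id); cg$id <- paste0("c_", cg$id)
    reg_w <- extract_upstream(wg, study$wild$genome, config$upstream_window)
    reg_c <- extract_upstream(cg, study$cultivar$genome, config$upstream_window)
    mi_w <- detect_mites_regions(reg_w)
    mi_c <- detect_mites_regions(reg_c)
    pres <- compare_presence(pairs, reg_w, reg_c, mi_w, mi_c)
    de <- diff_expression(study$expression$counts, study$expression$groups)
    assoc <- associate(pres, de)
    perm <- permutation_association(
      de, unique(pres$gene[pres$status == "cultivar-specific"]),
      seed = derive_seed(config$seed, "mite"))
    write_tsv(pres, file.path(dir, "mite_presence.tsv"))
    write_tsv(de, file.path(dir, "diff_expression.tsv"))
    write_tsv(data.frame(metric = c("n_cultivar_specific", "n_lower",
                                    "n_higher", "frac_lower", "frac_higher",
                                    "perm_p"),
                         value = c(assoc$n_specific, assoc$n_lower,
                                   assoc$n_higher, assoc$frac_lower,
                                   assoc$frac_higher, perm$p)),
              file.path(dir, "association_summary.tsv"))
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

## stable content hash without extra dependencies: md5 of a temp file
digest_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
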