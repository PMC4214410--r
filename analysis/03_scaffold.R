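# Hierarchical scaffolding of the wild genome's contigs with three insert
# tiers, BAC-end + FPC mega-scaffolding, 500-N pseudomolecule emission, and
# order/orientation accuracy against the known source layout.

source("analysis/00_config.R")

study <- get_study(with_reads = FALSE)
cfg <- study$config

frag <- fragment_genome(study$wild$genome, contig_mean = 12000,
                        seed = STUDY_SEED + 3)
message(sprintf("fragmented the wild genome into %d contigs", length(frag$contigs)))

tiers <- simulate_reads(study$wild$genome, cfg$insert_tiers, cfg$read_length,
                        error_rate = 0, seed = STUDY_SEED + 4)
hs <- hierarchical_scaffold(frag$contigs, tiers)
message(sprintf("hierarchical scaffolding: %d scaffolds from %d contigs",
                length(unique(hs$layout$scaffold)), length(frag$contigs)))

scf <- emit_scaffold_seqs(frag$contigs, hs$layout)
bac <- simulate_bac_and_fpc(study$wild$genome, cfg$n_bac_clones,
                            cfg$bac_insert_mean, cfg$bac_insert_sd,
                            cfg$bac_end_read_length, seed = STUDY_SEED + 5)
mg <- mega_scaffold(scf, bac$end_reads, bac$fpc_map)

pseudos <- list()
for (m in unique(mg$mega$mega)) {
  mem <- mg$mega[mg$mega$mega == m, , drop = FALSE]
  ps <- emit_pseudomolecule(mem, scf, object_name = m)
  pseudos[[m]] <- ps$seq
  write_agp(ps$agp, file.path(RESULTS_DIR, paste0(m, ".agp")))
}
write_fasta(unlist(pseudos), file.path(RESULTS_DIR, "pseudomolecules.fasta"))

st <- assembly_stats(unlist(pseudos))
acc <- adjacency_accuracy(
  data.frame(group = hs$layout$scaffold, member = hs$layout$member,
             orientation = hs$layout$orientation), frag$truth)
message(sprintf("pseudomolecules: %d, N50 %d bp, non-gapped fraction %.3f",
                st$contig_count, st$n50, st$non_gapped_fraction))
message(sprintf("scaffold adjacency accuracy vs the source genome: %d/%d = %.3f",
                acc$correct, acc$total, acc$accuracy))
write_tsv(data.frame(metric = c("pseudomolecules", "n50_bp",
                                "non_gapped_fraction", "adjacency_correct",
                                "adjacency_total"),
                     value = c(st$contig_count, st$n50, st$non_gapped_fraction,
                               acc$correct, acc$total)),
          file.path(RESULTS_DIR, "scaffold_summary.tsv"))
write_tsv(hs$layout, file.path(RESULTS_DIR, "scaffold_layout.tsv"))
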