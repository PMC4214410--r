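# MITE detection in the 1-kb upstream windows of orthologous genes, shared vs
# lineage-specific presence, differential expression between the genotype
# groups, and the association of cultivar-specific insertions with suppressed
# expression (with a permutation control).

source("analysis/00_config.R")

study <- get_study(with_reads = FALSE)
cfg <- study$config

wg <- study$wild$genes; cg <- study$cultivar$genes
shared_ids <- intersect(wg$id, cg$id)
pairs <- data.frame(gene_a = shared_ids, gene_b = shared_ids,
                    gene = shared_ids, stringsAsFactors = FALSE)

reg_w <- extract_upstream(wg[match(shared_ids, wg$id), ], study$wild$genome,
                          cfg$upstream_window)
reg_c <- extract_upstream(cg[match(shared_ids, cg$id), ],
                          study$cultivar$genome, cfg$upstream_window)
mi_w <- detect_mites_regions(reg_w)
mi_c <- detect_mites_regions(reg_c)
message(sprintf("detected MITEs: %d in wild windows, %d in cultivar windows",
                nrow(mi_w), nrow(mi_c)))

pres <- compare_presence(pairs, reg_w, reg_c, mi_w, mi_c)
message(sprintf("presence: %s",
                paste(names(table(pres$status)), table(pres$status),
                      collapse = ", ")))
truth_counts <- table(study$truth$mites$status)
message(sprintf("planted truth: %s",
                paste(names(truth_counts), truth_counts, collapse = ", ")))

de <- diff_expression(study$expression$counts, study$expression$groups)
assoc <- associate(pres, de)
spec_genes <- unique(pres$gene[pres$status == "cultivar-specific"])
perm <- permutation_association(de, spec_genes, seed = STUDY_SEED + 6)
message(sprintf(
  "of %d cultivar-specific insertions: %d (%.1f%%) lower, %d (%.1f%%) higher expression; permutation p = %.4g",
  assoc$n_specific, assoc$n_lower, 100 * assoc$frac_lower, assoc$n_higher,
  100 * assoc$frac_higher, perm$p))

write_tsv(pres, file.path(RESULTS_DIR, "mite_presence.tsv"))
write_tsv(de, file.path(RESULTS_DIR, "diff_expression.tsv"))
write_tsv(data.frame(metric = c("n_cultivar_specific", "n_lower", "n_higher",
                                "frac_lower", "frac_higher", "perm_p"),
                     value = c(assoc$n_specific, assoc$n_lower, assoc$n_higher,
                               assoc$frac_lower, assoc$frac_higher, perm$p)),
          file.path(RESULTS_DIR, "association_summary.tsv"))
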