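# Generate the simulated wild/cultivar study and write its inputs and truth
# tables. The pair is a 1-Mb ancestor diverged at 6.9 SNVs and 0.8 InDels per
# kb, with heterozygosity of 3.8 (wild) and 3.4 (cultivar) SNVs per kb, MITEs
# planted into 1-kb upstream windows, tiered paired reads, a ten-equivalent
# BAC library with an FPC clone map, and negative-binomial expression counts.

source("analysis/00_config.R")

study <- get_study()

write_fasta(c(wild = study$wild$genome, cultivar = study$cultivar$genome),
            file.path(RESULTS_DIR, "genomes.fasta"))
write_gff3(study$wild$genes, file.path(RESULTS_DIR, "wild_genes.gff3"),
           seqid = "wild")
write_gff3(study$cultivar$genes, file.path(RESULTS_DIR, "cultivar_genes.gff3"),
           seqid = "cultivar")
write_tsv(study$truth$genes, file.path(RESULTS_DIR, "gene_regimes_truth.tsv"))
write_tsv(study$truth$mites, file.path(RESULTS_DIR, "mite_truth.tsv"))
write_tsv(study$bac$fpc_map, file.path(RESULTS_DIR, "fpc_map.tsv"))
write_tsv(as.data.frame(study$expression$counts),
          file.path(RESULTS_DIR, "expression_counts.tsv"))

v <- study$truth$variants
message(sprintf("planted divergence: %d SNVs (%.2f/kb), %d InDels (%.2f/kb)",
                sum(v$type == "SNV"), sum(v$type == "SNV") / 1000,
                sum(v$type %in% c("insertion", "deletion")),
                sum(v$type %in% c("insertion", "deletion")) / 1000))
message(sprintf("planted heterozygosity: wild %d events, cultivar %d events",
                nrow(study$truth$het_wild), nrow(study$truth$het_cultivar)))
message(sprintf("MITE insertions: %s",
                paste(names(table(study$truth$mites$status)),
                      table(study$truth$mites$status), collapse = ", ")))
message(sprintf("PAV: %d gene deletions; CNV: %d duplications",
                nrow(study$truth$pav), nrow(study$truth$cnv)))
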