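# Genome profiling: k-mer spectrum genome size, heterozygosity from read
# pileups against each genotype's own assembly, wild-vs-cultivar divergence by
# whole-genome comparison, and the Venn partition of variant sets against the
# common ancestor.

source("analysis/00_config.R")

study <- get_study()

# k-mer spectrum and genome size from the short-insert wild library
tier1 <- study$reads$wild[[1]]
reads <- c(tier1$read1, tier1$read2)
sp <- kmer_spectrum(reads, k = 17)
gs <- estimate_genome_size(sp)
message(sprintf("k-mer spectrum: error cutoff %d, peak depth %.1f, genome size %.0f bp (true %d)",
                gs$error_cutoff, gs$peak_depth, gs$size_bp,
                nchar(study$wild$genome)))
write_tsv(sp$histogram, file.path(RESULTS_DIR, "kmer_spectrum.tsv"))

# heterozygosity per genotype
rates <- list()
for (lin in c("wild", "cultivar")) {
  t1 <- study$reads[[lin]][[1]]
  het <- call_het_variants(study[[lin]]$genome, c(t1$read1, t1$read2))
  rates[[lin]] <- het$rates
  planted <- nrow(study$truth[[paste0("het_", lin)]][
    study$truth[[paste0("het_", lin)]]$type == "SNV", ])
  message(sprintf("%s heterozygosity: %.2f SNVs/kb called (planted %.2f/kb)",
                  lin, het$rates$snv_per_kb,
                  planted / (nchar(study[[lin]]$genome) / 1000)))
  write_vcf(vcf_normalise(het$calls, study[[lin]]$genome),
            file.path(RESULTS_DIR, paste0("het_calls_", lin, ".vcf")),
            contigs = setNames(nchar(study[[lin]]$genome), lin))
}

# wild vs cultivar divergence
cmp <- compare_assemblies(study$wild$genome, study$cultivar$genome)
message(sprintf("divergence: %.2f SNVs/kb, %.2f InDels/kb over %.0f aligned bp",
                cmp$rates$snv_per_kb, cmp$rates$indel_per_kb,
                cmp$rates$aligned_bp))

# Venn partition of lineage variant sets against the ancestor
wv <- compare_assemblies(study$wild$genome, study$ancestor$genome)
cv <- compare_assemblies(study$cultivar$genome, study$ancestor$genome)
venn <- variant_venn(list(wild = wv$calls, cultivar = cv$calls))
message(sprintf("variant Venn vs ancestor: %s (union %d)",
                paste(names(venn$regions), venn$regions, collapse = ", "),
                venn$union_size))

write_tsv(data.frame(
  metric = c("genome_size_bp", "wild_het_snv_per_kb", "cultivar_het_snv_per_kb",
             "divergence_snv_per_kb", "divergence_indel_per_kb",
             paste0("venn_", names(venn$regions))),
  value = c(gs$size_bp, rates$wild$snv_per_kb, rates$cultivar$snv_per_kb,
            cmp$rates$snv_per_kb, cmp$rates$indel_per_kb,
            as.numeric(venn$regions))),
  file.path(RESULTS_DIR, "profile_summary.tsv"))
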