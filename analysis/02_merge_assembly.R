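# Integrate two emulated contig sets (a long-fragment and a short-fragment
# assembly of the wild genome): redundancy filtering of the secondary set,
# dovetail overlap discovery, and overlap-layout-consensus merging.

source("analysis/00_config.R")

study <- get_study(with_reads = FALSE)
g <- study$wild$genome
L <- nchar(g)

primary <- shred_overlapping(substr(g, 1, floor(0.6 * L)), 6000, 500,
                             seed = STUDY_SEED + 1, flip = FALSE)
names(primary) <- paste0("A_", names(primary))
secondary <- shred_overlapping(g, 2500, 400, seed = STUDY_SEED + 2)
names(secondary) <- paste0("B_", names(secondary))
message(sprintf("primary set: %d contigs; secondary: %d contigs",
                length(primary), length(secondary)))

filt <- filter_redundant_contigs(primary, secondary)
message(sprintf("redundancy filter removed %d secondary contigs (covered by the primary set)",
                sum(filt$log$removed)))

pool <- c(primary, filt$retained)
ov <- compute_overlaps(pool, min_overlap_len = 100)
merged <- olc_merge(pool, ov)
st <- assembly_stats(merged$contigs)
message(sprintf("OLC merge: %d contigs in -> %d out; N50 %d bp; total %.0f bp",
                length(pool), length(merged$contigs), st$n50, st$total_bp))

write_fasta(merged$contigs, file.path(RESULTS_DIR, "merged_contigs.fasta"))
write_tsv(filt$log, file.path(RESULTS_DIR, "redundancy_log.tsv"))
write_tsv(ov, file.path(RESULTS_DIR, "overlaps.tsv"))
write_tsv(merged$layout, file.path(RESULTS_DIR, "merge_layout.tsv"))
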