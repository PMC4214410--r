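# Shared configuration for the analysis scripts. Every script regenerates the
# simulated study deterministically from this config, so the scripts can be
# run independently or in sequence; all tables land under results/.

library(domestigen)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 20240 # fixed study seed; change to redraw the whole simulation

study_config <- function() {
  simulation_config(
    genome_length = 1e6,   # 1-Mb desk-scale genome pair
    n_genes = 150,
    gene_length = 600,
    het_snv_rate = 3.8,    # wild heterozygosity, SNVs/kb
    het_snv_rate_cultivar = 3.4,
    divergence_snv_rate = 6.9,
    divergence_indel_rate = 0.8,
    mite_insertion_prob = 0.15,
    suppression_log2fc = -2,
    seed = STUDY_SEED)
}

get_study <- function(with_reads = TRUE) {
  message("regenerating the simulated wild/cultivar study (seed ",
          STUDY_SEED, ") ...")
  simulate_study(study_config(), with_reads = with_reads)
}
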