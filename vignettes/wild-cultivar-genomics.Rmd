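---
title: "Methods: simulating and analysing a wild/cultivated genome pair"
author: "domestigen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a wild/cultivated genome pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`domestigen` rebuilds, as tested and reusable code, the computational chain of
a wild-versus-domesticated plant genome comparison: merging two contig sets
into one assembly, scaffolding with tiered mate pairs and a BAC/FPC physical
map, k-mer spectrum genome profiling, heterozygosity and divergence
estimation, orthologue matching with NG86 Ka/Ks selection classification, and
association of MITE insertions in 1-kb upstream windows with expression
suppression. Because the original chromosome-scale data cannot be reproduced
at desk scale, every stage is exercised end-to-end on seeded simulations whose
parameters encode the study conditions, and validated by recovering the
planted truth.

# The simulated study

`simulation_config()` collects all generator parameters. The defaults are the
study conditions:

* heterozygosity of **3.8 SNVs/kb** in the wild genotype and **3.4 SNVs/kb**
  in the cultivar. Heterozygous InDel rates are not stated for these
  genotypes; the default of 0.5 InDels/kb is a plausible plant-genome value
  and is only a nuisance parameter for the SNV-rate recovery.
* wild-versus-cultivar divergence of **6.9 SNVs/kb and 0.8 InDels/kb**
  (pairwise; each planted event is assigned to one lineage at random).
* BAC clones with a **115 kb** mean insert at **ten genome equivalents**, with
  500-bp end reads and an FPC map that abstracts fingerprinting chemistry into
  an ordered clone list (map contigs split at clone-coverage gaps) -- the
  downstream scaffolder consumes only clone order, which is exactly what a
  physical map contributes.
* three paired-read tiers at 0.3 / 3 / 8 kb inserts (20/10/5-fold coverage,
  100-bp reads). The real study's library tiers are not stated; these are
  configurable placeholders spanning the short / medium / long ranges a
  hierarchical scaffolder needs.
* pseudomolecule joins written as exactly **500 N** bases.
* a 20/10/70% split of genes under positive / negative / neutral selection,
  with target Ka/Ks of 3, 0.2 and 1.
* per-lineage gene deletion (PAV) probability 0.05 and duplication (CNV)
  probability 0.02, in line with the few-percent genotype-specific gene
  fractions such comparisons report.
* MITE insertion probability 0.15 per upstream window per lineage, and
  expression suppression of log2FC = -2 for genes with a cultivar-specific
  upstream insertion (the magnitude of "suppressed" is unstated; -2 gives a
  clearly detectable but not degenerate signal). Counts are negative binomial
  with dispersion 0.05 and 5 replicates per group.

Coding divergence is planted per gene by rejection sampling over codon
positions, classified synonymous/nonsynonymous against the standard genetic
code, with the nonsyn:syn split chosen so the planted ratio matches the
gene's regime. This guarantees the planted Ka/Ks sign without iterative
fitting. The number of coding substitutions is Poisson at the intergenic SNV
rate by default, so genome-wide divergence stays at the configured per-kb
value. InDels are planted only intergenically, which keeps every ORF valid --
a deliberate idealisation (real coding InDels exist but would confound the
Ka/Ks truth).

MITEs are planted *after* divergence, reflecting transposon activity during
domestication; planted elements therefore have perfect terminal inverted
repeats (TIRs, 10-30 bp), a duplicated target site (default the canonical TA
dinucleotide of Stowaway-like elements), and lengths of 50-800 bp. Shared
insertions use the same element at homologous (ancestor-anchored) positions in
both lineages. Because an insertion shifts all downstream coordinates by its
own length, target sites are constrained so the element stays inside the
final 1-kb window of the (strand-aware) gene anchor.

What the simulation does **not** emulate: repeat landscapes and
heterochromatin, quality-dependent sequencing error (errors are uniform
substitutions), polyploidy, rearrangements/inversions, and real
transcript-level expression structure. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
performance on real heterochromatic plant genomes.

# Determinism and seeds

Every generator takes a seed and restores the caller's RNG state. A global
seed fans out to per-stage seeds through `derive_seed()`, a fixed
multiplicative-hash derivation kept below 2^31. All randomness lives in R;
the compiled kernels are deterministic. Re-running any pipeline with the same
config yields byte-identical outputs (the manifest records md5 checksums).

# Assembly merging

Redundant secondary contigs are removed when at least 90% of their length
aligns to a primary contig at >= 95% identity (either strand), by seeded
diagonal extension. The original work filtered with BLAST at an E-value
cutoff; E-values are database-size dependent and not reproducible without the
original tool, so identity/containment thresholds are used and logged.
Overlaps are discovered from 15-bp seed k-mers and verified by direct
comparison; only suffix-prefix (dovetail) overlaps count, with a Hamming error
model (InDel-containing overlaps are out of scope for the merger). Merging
follows the overlap-layout-consensus discipline: ends involved in more than
one overlap are branch points and never merged; unambiguous chains are
concatenated with per-column consensus over overlap regions (ties broken
toward the higher-depth contig when depths are supplied, else
lexicographically, for deterministic output); cyclic chains are broken at the
lowest-identity overlap.

# Scaffolding

Reads are placed by unique 31-mer seeds with ungapped verification -- no
external aligner, fully deterministic. Pairs with mates on different contigs
are bundled per oriented end pair; the gap estimate is the mean of
(insert mean - distance to end a - distance to end b).

Tiers are applied smallest insert first. Edge resolution applies three rules,
in order:

1. bundles below `min_support` (default 5) are dropped. Under a 5% chimera
   rate the expected spurious-bundle support from coincident random pairs is
   below 5 by a Poisson collision argument, while genuine adjacent links at
   the default coverages carry tens to hundreds of pairs;
2. at each contig end, edges carrying less than 30% of the strongest edge's
   support at that end are dropped, and orientation conflicts between the same
   two contigs are settled by support (majority rule);
3. among the survivors at an end, the *nearest* partner (smallest gap
   estimate) wins. This matters because a long-insert tier also links
   non-adjacent contigs across short ones; support alone would happily skip a
   short contig.

An edge is used only when chosen reciprocally at both ends; chains are walked,
cycles broken at the lowest-support edge, and a later tier can only join
current scaffolds, never break an earlier join. Negative gap estimates are
clamped to 1 N on emission; pseudomolecule joins are fixed at 500 N.

Mega-scaffolding assigns each scaffold to the FPC map contig hit by the
majority of its BAC clones, orders scaffolds by the median clone order index,
and orients each scaffold by the sign of the Spearman association between
clone order index and end-read position within the scaffold. BAC-end links
consistent with that order are accepted, inconsistent ones rejected and
logged; the physical map outranks BAC links, which outrank mate-pair tiers.
Scaffolds much shorter than the BAC insert cannot be ordered reliably by
clone medians -- the noise floor of the 2-Mb simulation's residual errors is
exactly such sub-insert scaffolds.

Coordinates are 1-based inclusive in all emitted GFF3/VCF/AGP; BED-like
outputs are 0-based half-open.

# Genome profiling

The k-mer spectrum counts canonical 17-mers (k is not stated in the source
study; 17 is a standard choice for ~1-Gb genomes and is configurable). The
error cutoff sits at the first local minimum of the depth histogram, guarded
to at most peak/3; the genome size is the k-mer mass above the cutoff divided
by the homozygous peak depth, with the peak refined by a centroid over the
modal neighbourhood (raw integer modes alone cost up to ~2% at 30-fold
coverage). A heterozygous half-depth bump is reported when detectable but
never double-counted.

Heterozygous SNVs are called from pileups where a second allele reaches
20-80% of a depth of at least 10 -- heuristic thresholds, declared rather than
inferred, since the original calling criteria are unstated. Short InDels
(<= 10 bp) come from a two-seed placement: when the left and right read seeds
imply different offsets, the split point minimising mismatches dates the
event, and the leftmost minimal split makes all reads of one event agree on
its position. Rates are normalised by callable bases (depth >= 10).

Whole-genome comparison chains k-mers unique in *both* genomes (k = 21) into a
collinear backbone (uniqueness automatically excludes CNV copies), thinned to
one anchor per 64 bp and filtered to a monotone chain; inter-anchor segments
go through a banded affine alignment (mismatch 3, gap open 5, extend 1, so a
substitution is never explained as insertion-plus-deletion). SNVs and InDel
events (gap runs) are counted over aligned columns only; InDels longer than
10 bp are structural and excluded from rates, as are segments whose size
difference exceeds the alignment band (PAV/CNV/MITE differences). Venn
partitions match variants by (sequence, position, alleles) and always sum to
the union.

# Ka/Ks and selection classes

NG86 counting: per-codon synonymous site fractions (a mutation creating a
stop codon counts as nonsynonymous), substitution counts averaged over all
minimal mutational pathways between differing codons, pathways through stop
codons excluded unless all are, and a Jukes-Cantor correction with a
saturation flag at p >= 3/4. The counting tables are verified against an
independent recursive pathway-enumeration oracle on all 61 x 61 sense-codon
pairs to 1e-9. The source study names no Ka/Ks method; NG86 with Jukes-Cantor
is the standard closed-form, oracle-checkable choice.

Codon alignments come from global protein alignment (BLOSUM62, gap opening
10, extension 0.5) back-translated to codons; columns with gaps or ambiguous
bases are excluded, pairs under 30% identity or 10 codons are skipped as
unreliable.

Classification: Ka = Ks = 0 is "no-divergence"; one-sided zeros are "Ks-only"
/ "Ka-only"; otherwise the ratio is compared to 1 with a relative neutrality
tolerance of 0.1 (an exact "ratio = 1" bin would have measure zero; 0.1 is
configurable and logged). Orthologue clusters come from reciprocal best
protein hits plus single linkage -- a deterministic, dependency-free stand-in
for Markov clustering that preserves the shared / unique / copy-number
labels; genes whose best qualifying hit lies in an existing cluster join it,
which is how duplicated copies are counted.

# MITE detection and expression association

The detector scans every (start, end) pair in a window for: TIR extent >= 10
bp, element length 50-800 bp, and an exact duplicated flanking motif of 2-10
bp. TIR mismatches (up to 2) are admitted only when compensated by length --
m mismatches require a TIR of at least 10 + 5m bp. A flat two-mismatch
allowance on a 10-bp TIR would admit roughly one false call per kb on random
sequence by direct calculation, defeating the detector; with compensation the
expected false-call rate is ~0.03/kb while recall on canonical perfect-TIR
elements is unaffected. Overlapping candidates resolve longest-TIR-first,
then leftmost. Detected boundaries can wobble by a few bp when a mismatch
extension reaches into the flanks, so truth matching uses a 10-bp tolerance.

Orthologous-window presence is matched by 20-bp flanking anchors (Hamming
distance <= 3 per flank), robust to the SNVs that accumulate in flanks;
insertions without a matching partner are lineage-specific.

Differential expression uses median-of-ratios normalisation and a two-sided
Welch t-test on log2(normalised counts + 1) with Benjamini-Hochberg
adjustment -- a deliberately self-contained test (the original pipeline's DE
engine is out of scope). The association step tallies significantly lower /
higher calls among genes with cultivar-specific insertions; a one-sided
permutation test against random gene sets of the same size provides the null
control. Under the null model only MITE-linked genes shift, so with zero
planted suppression essentially no calls survive BH and the permutation
p-value is conservative by construction.

# Problem sizes used by the tests

The packaged tests run the recovery analyses at the sizes the methods need to
show their contracts: 5-Mb genomes at 40-fold coverage for heterozygosity and
divergence recovery, 5 Mb at 30/60-fold for genome-size invariance, 2 Mb with
three tiers plus BAC/FPC for scaffolding order recovery (clean and with 5%
chimeric pairs), a 100-kb source for merge fidelity, 200 orthologue pairs for
regime recovery, 100 planted elements for detector precision/recall, and 100
simulated cohorts for the association null control. The analysis scripts
under `analysis/` narrate one full 1-Mb study end to end.

# Known limitations

* The overlap merger is Hamming-based: overlaps containing InDels are not
  merged (they remain separate contigs).
* The variant caller targets the diploid heterozygous regime; it does not
  compute genotype likelihoods and is not a population-scale caller.
* compare_assemblies assumes collinearity; inversions and translocations
  break anchors and are reported as unaligned, not as variants.
* Scaffolds shorter than the BAC insert cannot be reliably ordered by the
  physical map, and orientation of scaffolds with a single clone hit defaults
  to "+" (logged).
* The NG86 pathway convention (stop-passing pathways excluded when possible;
  mutations to stops nonsynonymous in site counts) is one of several in use;
  numbers from tools with other conventions will differ slightly.
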