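---
title: "Benchmarking single-cell small RNA sequencing pipelines with scmirna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single-cell small RNA sequencing pipelines with scmirna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmirna)
```

## The problem

Single cells contain on the order of femtograms of miRNA. At that input,
ligation-based small RNA library preparation is dominated by its failure
modes: adapter dimers (5'+3' adapter ligation products with no insert) can
make up most of a library, sequence-dependent ligation efficiency distorts
an equimolar pool across several orders of magnitude, and heavy PCR
amplification duplicates each captured molecule many times. Protocol
comparisons therefore hinge on a small set of statistics: how much of a
library is adapter dimer, how many reference sequences are detected, how
far an equimolar spike-in deviates from uniformity (coefficient of
variation), how close replicates are to each other (Euclidean distances on
log2 expression), and — once unique molecular identifiers (UMIs) are in
play — how many molecules stand behind the reads.

`scmirna` implements that evaluation framework as reusable, tested R
code: a synthetic library generator with per-read ground truth, read
preprocessing with adapter-dimer accounting, identity-thresholded mapping
to a short RNA reference, hierarchical RNA-class assignment, UMI adjacency
deduplication, and the protocol-comparison and single-cell statistics,
orchestrated by a config-driven pipeline (`validate_config()` /
`run_stage()`).

## The synthetic library model

`simulate_library()` emits reads laid out as

```
[UMI | umi_len] [5' 4N flank] [insert] [3' 4N flank] [3' adapter] [PCR primer] [polyA pad]
```

truncated to the 75-bp single-end read length. The mixture of read
origins is explicit: a fraction `frac_dimer` of adapter dimers (empty
insert), `frac_other_rna` of 30–70-nt fragments drawn from annotated
features of a synthetic genome (the competitors class assignment must
beat), `frac_junk` of reads designed to fail QC (either <18 nt after
trimming or carrying ≥3 N bases), and the remainder miRNA inserts from a
reference pool.

Capture bias follows a single-covariate model: feature `i` with G-content
`g_i` is captured with probability proportional to
`exp(beta_g * g_i + eps_i)`, `eps_i ~ N(0, sigma^2)`, normalized to sum
to one. `beta_g` encodes the observed direction of ligation bias (G-richer
sequences are seen more often); `sigma` encodes everything the covariate
does not explain. PCR duplication is a shifted negative binomial: each
molecule yields `1 + NB(mu = m - 1, size = k)` reads, with the default
mean `m = 4.74` reads per molecule matching the duplication depth
measured in single-cell libraries, and `k = 2` giving a realistic spread.
Base-call errors are uniform substitutions (default 0.002/base) and a
fraction of reads (default 5%) receives a sub-Q20 3' quality tail.

Default mixture fractions (30% dimers, 15% other RNA, 5% junk) sit in the
middle of what single-cell equivalents of the benchmarked protocols
produce; all are configuration, not constants. One RNG is seeded once per
library and consumed in a fixed order (mixture, bias, molecules,
duplication, assembly, errors, qualities), so identical configurations
give byte-identical FASTQ and ground truth.

The reference generator (`generate_reference()`) emulates an equimolar
pool of ~1006 sequences of 20–25 nt. Per-sequence G-content is drawn from
a Beta distribution (default mean 0.25, sd 0.08) so the pool spans a
realistic bias range. The pool is substring-free — no member is contained
in (or even shares a ≥20-mer with) another — because an equimolar pool is
only usable as quantification truth if every member is identifiable under
end-gap-tolerant mapping.

What the generator does *not* model: instrument-specific quality-score
profiles, indel sequencing errors, ligation thermodynamics / secondary
structure (the simulator's bias is a statistical stand-in, not a
mechanistic one), homopolymer-tail artifacts, and the dimer-formation
mechanism itself (`frac_dimer` is an input, not an emergent property).
Passing tests on simulated data therefore demonstrate that the *pipeline
logic* recovers known truth under controlled noise — not that any given
wet-lab protocol behaves well.

## Preprocessing rules

Trimming follows the benchmarked pipeline: one 3' quality trim at Q20
(BWA running-sum rule), then up to three rounds of 3' artifact removal
(3' adapter, PCR primer, optionally polyA/polyG homopolymers), each round
removing the earliest-starting acceptable occurrence at a 10% error rate
(substitutions and indels each cost one). Reads are then classified with
precedence:

* `adapter_dimer` — fewer than 4 bases remain,
* `too_short` — fewer than 18 bases remain,
* `quality_fail` — more than 2 N bases (or a read shorter than its UMI),
* `kept` — everything else (4N-family flanks are clipped afterwards).

Two numerical choices deserve explanation:

**Minimum overlap for partial 3' matches.** A full adapter occurrence may
match anywhere, but a *partial* match at the read's 3' end is only
removed if at least `min_overlap` adapter bases are matched
(`trim_config()` default 10). With the common default of 3, any read
whose genuine 3' end coincides with the first three bases of an adapter
or with a 3-base A/G run is clipped in later trimming rounds; across an
equimolar pool this deterministically destroys the ~2–3% of members whose
ends collide, which is fatal for accuracy statistics. Ten bases of
evidence make random coincidences negligible while leaving genuine
read-through trimming untouched.

**Homopolymer trimming vs G-rich references.** polyA/polyG tails are
modelled as 10-nt homopolymer adapters under the same error rule. A
reference sequence containing a ~10-nt G run (a handful per thousand
under the default G-content profile) is then annihilated wholesale — a
genuine bias of homopolymer trimming on G-rich small RNAs, not a bug.
Because the generator does not simulate homopolymer artifacts at all, the
calibration and acceptance runs configure the trimmer with the artifact
set the generator actually produces (`trim_config_for(arch, polyA =
FALSE, polyG = FALSE)`); pipelines for real data keep both on.

Even so, over-trimming cannot be made impossible: an insert whose 3' end
happens to lie within the 10% error tolerance of a ≥10-base adapter
prefix is truncated below the length floor and lost. The per-feature
probability is about `6e-5`, so roughly one pool in sixteen loses a
single member; this is an intrinsic property of error-tolerant trimming
and the reason the equimolar CV floor is quoted as "sampling-limited up
to rare coincidence losses".

Subsampling (`subsample_reads()`, benchmark setting 300,000 reads at
seed 42) is uniform without replacement and deterministic within this
package; it is *not* bit-compatible with external subsampling tools,
whose RNGs differ.

## Mapping and class assignment

`map_to_reference()` aligns each kept read end-to-end against every
reference with unit-cost edit distance and free end gaps on the reference
only, accepting hits at `identity = 1 - errors/read_length >= 0.80`.
Counting uses exactly one best hit per read, identity ties resolving to
the lexicographically smallest feature id — deterministic, and matching
best-hit usage of short-read mappers. The default path uses an
exact-sequence hash plus a banded, early-abandoning scan for inexact
reads; `best_only = FALSE` computes every qualifying pair (used by the
test oracles). Genome-scale spliced alignment is deliberately out of
scope: for class assignment on real data, externally produced per-read
alignment intervals are imported instead.

`assign_class()` implements the hierarchical rule: every annotation
interval covering at least 90% of the read — across *all* the read's
alignment loci — nominates its class, and the highest-priority class
wins, in the order miRNA, miRNA primary transcript, GtRNAdb, Mt tRNA,
rRNA, Mt rRNA, snoRNA, snRNA, sRNA, scaRNA, scRNA, piRBase, misc RNA,
ribozyme, coding exons, lncRNA, ncRNA, protein-coding; no qualifying
overlap means "intergenic". Coordinates are 0-based half-open internally
(GFF3 is converted on read/write); strand is carried but ignored, since
counting in the benchmarked pipeline was unstranded.

## UMI deduplication

Reads are grouped per (sample, feature, read length — the length stratum
can be disabled) into UMI read-count tables; UMIs containing N are
dropped with a logged count. `adjacency_dedup()` builds the network with
edges between UMIs at Hamming distance exactly 1 and resolves it
greedily: repeatedly take the unassigned UMI with the highest read count
(ties to the lexicographically smallest UMI — a determinism improvement
over arbitrary tie-breaking) together with all its unassigned direct
neighbors. The number of groups is the molecule count; reads per UMI
(total reads / distinct UMIs) measures duplication depth.

## Benchmarking statistics

* **Accuracy** — `coefficient_of_variation()`: sample (n−1) SD over mean
  of one sample's RPMM expression across *all* reference features, zeros
  included (the equimolar truth expects every member present; a
  detected-only mode is provided because the two conventions differ
  substantially in absolute value).
* **Reproducibility** — `reproducibility_distances()`: Euclidean
  distances on `log2(RPMM + 1)` for every unordered sample pair, split
  into within- and between-protocol sets. RPMM (reads per million
  mapped) scales each sample to 1e6 over mapped features; the pseudocount
  of 1 and the RPMM layer choice are documented knobs.
* **Bias association** — `gcontent_detection_association()`: Spearman
  correlation between per-feature detection rates (count ≥ 1, the
  benchmark's detection rule) and G-content.
* **Cell QC** — `filter_cells()`: at least 50 detected miRNA molecules,
  the threshold that separates real cells from empty negative controls.
* **Single-cell processing** — `lognormalize()` (`ln(1 + 1e4·x/libsize)`,
  natural log), `variable_features()` (vst: local regression of log10
  variance on log10 mean, span 0.3, standardized counts clipped at
  `sqrt(n_samples)`, ranked by standardized variance; degenerate inputs
  below 10 usable features fall back to a log-linear trend),
  `embed_and_cluster()` (PCA on scaled variable features, Jaccard-weighted
  shared-nearest-neighbor graph, Louvain at the configured resolution,
  UMAP on the same PCs; deterministic given the seed), and
  `adjusted_mutual_information()` (exact hypergeometric expected-MI
  correction, arithmetic-mean normalization — variants differ in the
  second decimal, hence the explicit choice).

Stage-specific cluster settings mirror the benchmark: 15 or 20 PCs, UMAP
neighborhoods of 9/12/12/15 across stages, Louvain resolution 1.4 (1.05
for patient subsets), SNN `k` defaulting to 20 and shrunk to `n − 1` when
samples are few. One practical caveat the tests encode: in a small
replicate design (e.g. 2 protocols × 3 replicates) the SNN neighborhood
must stay below the group size, otherwise every sample neighbors every
other and the graph is structureless.

## Design decisions on open points

* The UMI occupies the first `umi_len` read bases (a UMI-in-5'-adapter
  design read from the insert side); the read-relative position is
  configurable.
* 4N flanks are clipped from kept reads *after* adapter removal and
  *after* status classification; consequently a 4N adapter dimer retains
  its 4-base 5' flank and classifies as `too_short` rather than
  `adapter_dimer` — the dimer rule is defined on post-trim length alone.
* The ≤2-N rule is evaluated after trimming.
* Status precedence is dimer > too short > quality fail (a 2-nt read
  with an N is a dimer).
* Multi-best-hit reads are counted once, not fractionally.
* The RPMM denominator is "reads with any accepted hit, per sample".
* Dedup strata include read length by default (`group_by_length`),
  mirroring length-aware deduplication; the flag exists because the
  effect on 20–25-nt miRNAs is small and untested.
* One file per sample; multi-lane merging is upstream of this package.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen so the full suite completes in a few minutes on one
core: 50k-read libraries for dimer-load recovery, one 500k-read library
for the CV noise floor (the multinomial floor at 1006 features is
`sqrt(1006/5e5) ≈ 0.045`), 30k-read libraries for CV/bias orderings and
the 2×3 protocol design, 2k-read libraries × 12 samples for
detection-rate association, and 200 random UMI fixtures plus 1000 random
reads for the exhaustive dedup and adapter oracles. Every stochastic step
takes an explicit seed, and a pipeline configuration without a top-level
seed is rejected.

## Known limitations

* The simplified mapper targets short reference sets (spike-in pools,
  mature miRNA catalogs), not genomes; class assignment on real data
  expects externally produced alignments.
* Homopolymer trimming and error-tolerant adapter matching can destroy
  G-run-containing or prefix-coincident reference members (quantified
  above); the package reports what it measures and does not attempt to
  rescue such features.
* The bias model is statistical: it reproduces the detection–G-content
  association and CV inflation, not the underlying ligation chemistry.
* Subsampling determinism holds within this package only.
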