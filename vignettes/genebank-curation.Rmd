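---
title: "Genotype-based gene bank curation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based gene bank curation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genocurate)
```

`genocurate` turns sparse GBS SNP calls on a gene bank collection into
curation decisions: which accessions are redundant seed lots, which
passport labels disagree with the genotype, how diversity is distributed
over taxa and races, where selection has acted, and which small core set
preserves the collection's alleles. This vignette explains the models
behind each stage, the parameters that matter, and the choices made where
the design was genuinely open. The package targets predominantly selfing
diploids: residual heterozygosity is low, so most statistics are built on
homozygous calls and treat heterozygotes as either rare biology or
genotyping noise.

## Data model

Genotypes are stored as an accessions × sites matrix of alternate-allele
dosages: 0 (hom-ref), 1 (het), 2 (hom-alt), `NA` (missing). Phase is
ignored — `0|1` and `0/1` are the same call — because selfing species
genotyped by GBS yield unphased, sparse data. Positions are 1-based and
region reports use 1-based inclusive intervals (BED export converts to
0-based half-open). Ref/alt orientation follows the input file; no
re-polarisation by frequency is done, since every frequency-based
statistic used here is orientation-invariant.

## Variant and accession QC

**Fisher disassociation filter.** In an inbred collection a true
biallelic SNP appears as two mutually exclusive homozygote classes. For
each site we form the per-accession allele-presence 2×2 table — both
alleles present (heterozygotes), ref only (hom-ref), alt only (hom-alt),
neither (missing) — and compute the one-sided Fisher exact P-value for
*under*-representation of co-occurrence (odds ratio < 1), which is the
lower hypergeometric tail of the heterozygote count given the margins.
Sites with P < 0.001 are kept. Missing calls sit in the "neither" cell:
they carry no evidence about co-occurrence but preserve the margins.
Artifact sites — e.g. collapsed paralogs, where both "alleles" are
actually different loci and co-occur freely — have P near 1 and are
removed.

**Threshold semantics.** The site filters are strict inequalities
(MAF > `maf_min`, missing < `missing_max`, het < `het_max`; defaults
0.01 / 0.30 / 0.10), and the accession filter removes accessions with
missing fraction strictly greater than 0.55. Boundary values therefore
pass or fail exactly as the operators read. Accession filtering is
applied once, before the collection is split by taxon.

**Single-heterozygote fixed loci.** In a group of more than
`min_population = 100` accessions, a locus whose only variation is one
heterozygous call on a fixed background is overwhelmingly likely a
sequencing error; such loci are dropped from that group's analyses and
excluded from its segregating-locus counts. Below the gate the rule is a
no-op — in small groups one heterozygote may be real.

**Imputation.** The smoothed F\_ST scan needs complete data. Missing
calls are replaced by the site's most frequent non-missing code, ties
breaking toward the lower code, which is deterministic and conservative:
it shrinks per-site frequency contrasts slightly rather than inventing
them. LD-aware imputation would be more faithful to real haplotype
structure; this affects only the scan stage and is a documented fidelity
limitation.

## Duplicate detection

Identity-by-state between two accessions is the fraction of matching
calls among sites where *both* are homozygous and non-missing;
heterozygous or missing calls drop out of numerator and denominator
alike. Sites are pre-filtered more permissively than the main QC
(MAF > 0.05, missing < 50%, het < 10%) to keep only informative loci.
A pair with fewer than `min_compared = 500` jointly homozygous loci is
*undefined*, never "identical" — high identity over a tiny overlap is
noise, and typical GBS collections compare thousands of loci per pair.

The identity threshold separating clones from relatives is auto-detected
from the histogram (bin width 0.25 percentage points) of all pairwise
identities: clones differ only by genotyping error, so they form a mode
just below 100%, and the threshold is placed in the minimum-density
valley between that mode and the bulk. Two refinements matter in
practice. First, the bulk itself is usually multimodal (within-group
pairs sit well above between-group pairs), so the valley is searched
directly below the duplicate mode, not between arbitrary bulk modes.
Second, when the valley is a wide run of empty bins the cut is placed at
the run's *upper* quarter: a threshold set too low merges genuinely
distinct accessions, which for a curator is the costlier error (a missed
clone pair costs storage; a false merge loses an accession). Without a
populated, separated mode above 95% identity the detector falls back to
0.99 — the operational threshold commonly used for "genetically
identical" — and says so. Identical sets are connected components of the
pairs-over-threshold graph, since curators treat identity as transitive
within a set, and each set is cross-validated against glume colour
(0 white – 9 black): a set showing more than one distinct score is
flagged for review rather than silently accepted.

## Structure and misclassification

The default genetic distance is 1 − IBS, which is robust to missing data;
a scaled Euclidean distance over shared sites
(√(Σ(xᵢ−yᵢ)² · L/L_shared)) is available for comparison with
default-parameter clustering in other tools. Trees are Saitou–Nei
neighbour joining (via \pkg{ape}); NJ's occasional negative branch
estimates are clamped to zero with a count kept in the tree's `clamped`
attribute. PCA operates on the additive relationship matrix: each site
centred by twice its alternate-allele frequency (missing → site mean,
i.e. zero after centring), cross-product scaled by 2Σp(1−p), coordinates
= eigenvectors × √eigenvalues, variance explained = eigenvalue / trace.

Misclassification flagging is a deliberately simple proxy for the joint
model-based/phylogenetic/morphological review a curator would perform:
each accession's `k = 10` nearest non-self neighbours vote with their
passport labels, and an accession is flagged only when the majority label
differs from its own *and* the majority is strong (≥ 0.8). Duplicates
must be collapsed to single representatives first, so a clone cluster
cannot out-vote a neighbourhood. The parameters were chosen so that
well-separated simulated groups produce zero false flags; the output is a
list of *proposals*, never applied automatically, because real
collections contain genuine admixture that no vote can adjudicate.

## Diversity and differentiation

Nei gene diversity is the unweighted mean over sites of expected
heterozygosity 2p(1−p), with frequencies over non-missing alleles; for
biallelic loci it lies in [0, 0.5]. No small-sample correction is applied
by default — at gene bank sample sizes the n/(n−1) correction is below
1% — but `correct = TRUE` enables it for comparison with estimators that
use it.

Two fixation indices are provided because they estimate different
things. The G\_ST-style index, 1 − ΣH_S/ΣH_T (sample-size-weighted
within-group expected heterozygosity against the pooled-frequency
expectation, ratio of sums for stability at low-diversity loci), treats
the two sampled groups as the whole universe; with r = 2 groups it
converges to F/(2−F) when each group has drifted F from a common
ancestor. The Weir–Cockerham (1984) estimator θ̂ = a/(a+b+c) corrects
for the finite number of sampled demes and converges to F itself. Both
are reported; the multi-locus W–C summary is Σa/Σ(a+b+c) (never the mean
of per-site ratios, which is Jensen-biased downward), while the
selection scan consumes the per-site values. Per-site estimates are kept
unclamped — negative values are legitimate finite-sample outcomes, and
clamping would bias the scan's genome-wide mean and standard deviation.
Sites where either group has fewer than two non-missing calls, or where
a+b+c = 0, are undefined and skipped.

## The selection scan

The scan compares a domesticated and a wild group: the larger group is
subsampled (seeded, without replacement) to the smaller one's size so
that sample-size asymmetry cannot masquerade as differentiation. Per-site
θ̂ values are Lowess-smoothed per chromosome — never across chromosome
ends — with span `f = 0.1` of the chromosome's sites, and regions are
maximal runs of consecutive sites whose *smoothed* value exceeds a
genome-wide threshold of mean + 3σ computed on the *raw* defined values
(`threshold_on = "smoothed"` switches the basis; both readings of
"outliers over the genome-wide average" are defensible, and raw is the
default because σ of the smoothed profile shrinks with f, which would
make the threshold an artefact of the smoothing span). A region's peak is
its maximal smoothed site, ties to the lowest position.

The smoother runs **zero robustifying iterations** by default. Classic
Lowess applies bisquare reweighting to resist outliers, but in a
selection scan the "outliers" *are* the signal: with a 25-site sweep
inside a ~70-site span, the robust passes assign the sweep sites
near-zero weight and erase the very peak the scan exists to find, leaving
only spacing artefacts near the threshold. Non-robust local regression
recovers planted sweeps cleanly and, because the calling threshold comes
from the raw values, does not inflate the false-positive rate on
sweep-free simulations. `lowess_smooth()` itself keeps the conventional
3-pass default for general profile smoothing; only the scan
configuration overrides it.

## Core selection

Heterozygous calls are masked to missing first, so the coverage target is
purely allelic: T = all (site, homozygous class) pairs observed at least
once in the collection, and coverage of a subset is the fraction of T it
contains. This presence-based unit is a simplification of
frequency-weighted coverage scores; it makes coverage a monotone
submodular set function, so the greedy algorithm — repeatedly add the
accession with the largest marginal gain, ties to the lowest input index
for determinism — carries the usual (1 − 1/e) guarantee relative to any
equal-size selection. Selection stops at coverage ≥ `cv = 0.99`, when the
best marginal gain falls below `d = 0.0001` (0.01%), or when accessions
run out. The report states, per group, the core's Nei diversity, the
percentage of the group's segregating loci still segregating in the core,
and the passport countries represented; geographic and phenotypic
representativeness are *reported*, not optimised — they remain manual
curation criteria.

## The simulator

`simulate_collection()` generates the kind of collection the pipeline is
built for, with every planted feature recorded as ground truth:

* **Structure.** Ancestral frequencies p₀ ~ U(0.05, 0.95); subpopulation
  frequencies Beta(p₀(1−F)/F, (1−p₀)(1−F)/F), the Balding–Nichols model,
  giving E[p_k] = p₀ and Var[p_k] = F·p₀(1−p₀). With one common ancestor,
  the expected pairwise (ancestral-referenced) F_ST between pops i and j
  is approximately (Fᵢ+Fⱼ)/2. The default configuration has K = 4 groups
  (a strongly diverged sister species, a domesticated group, two wild
  races; F = 0.6/0.4/0.3/0.35, 400 accessions, 5,000 SNPs on seven
  chromosomes) — magnitudes chosen to resemble a diploid wheat
  collection, though a single-ancestor model cannot reproduce a real
  hierarchical topology exactly.
* **Selfing.** Genotypes follow inbreeding-adjusted Hardy–Weinberg:
  het with probability 2pq(1−F_IS), hom-alt p² + F_IS·pq, with
  F_IS = 0.97 — the residual heterozygosity of a natural selfer.
* **Artifacts.** Each call is set missing independently (default 10%,
  typical of GBS), and each remaining homozygote is miscalled het with
  probability 0.005.
* **Duplicates.** Clones copy a source accession with an independent
  per-site discordance ε = 0.002 (flips between homozygote classes) and
  receive fresh missingness — mimicking re-genotyped duplicate seed lots
  whose IBS is 1 − ε over compared loci.
* **Sweep.** An optional window of consecutive sites where the two named
  groups' frequencies are overwritten with p_high/p_low (default
  0.98/0.02) before genotypes are drawn — a localized region of extreme
  differentiation like a domestication locus.
* **Mislabels.** A fraction of non-clone accessions gets a wrong passport
  taxon, with the truth recorded.

Positions are uniform per chromosome then sorted, so the smoother sees
realistically irregular spacing. What the simulator does *not* model —
linkage disequilibrium and recombination, admixed individuals, allele
surfing, heterogeneity within a seed lot — bounds what passing tests
mean: they validate the estimators and detectors under the stated model,
not the pipeline's behaviour under admixture or tight linkage. All
randomness derives from one seed via fixed sub-streams; the same config
yields byte-identical output files.

## Numerical and testing notes

Degenerate inputs are flagged, not fatal, wherever a curator could still
proceed: all-missing sites get undefined statistics, G_ST is `NA` with a
warning when both groups are identically fixed everywhere, and the
identity threshold falls back to 0.99 with a note. Hard errors are
reserved for unusable inputs (duplicate accession ids, glume scores
outside 0–9, an all-missing site given to the imputer, windows exceeding
a chromosome).

The test suite validates against independent oracles at sizes chosen to
run comfortably on one CPU: Fisher P-values against exhaustive
hypergeometric enumeration for all 2×2 tables with margins ≤ 30;
neighbour joining against all 123 additive trees with ≤ 6 leaves (exact
topology and branch-length recovery); Weir–Cockerham against an
independently coded evaluation at 10⁻¹² agreement; coverage
monotonicity/submodularity by exhaustive subset enumeration on ≤ 10
accessions; and full parameter-recovery loops on simulated collections —
two populations of 50 at F = 0.10 with 5,000 loci for F_ST recovery, 20
planted clone pairs among 200 accessions for duplicate detection, a
25-site sweep on a 7 × 700-site genome (plus 50 sweep-free replicates)
for the scan, three populations of 100 for core selection, and 5%
planted mislabels for flagging. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the resulting numbers as JSON.
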