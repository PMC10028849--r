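---
title: "Methods: 3D mutation clusters, local background rates, and insulated heat diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D mutation clusters, local background rates, and insulated heat diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutnet3d)
```

This vignette is the package's own account of its model, the choices
behind every tunable parameter, what the synthetic-data generator does
and does not emulate, and the numerical and design decisions a
maintainer would want written down.

## The model

### Inputs and preprocessing

The unit of analysis is a somatic protein-altering mutation, pre-mapped
to a UniProt accession and 1-based protein residue coordinates and
annotated with a VEP-style consequence term. Terms are partitioned into
`in_frame` (missense, in-frame insertion/deletion — the spatial-
clustering substrate), `lof` (frameshift, nonsense, start/stop-loss,
splice-disrupting — the truncation substrate), `background`
(silent/noncoding — the rate-estimation substrate) and `excluded`.
Records with a non-zero population allele frequency are treated as
germline and removed; an absent frequency means "not seen in the
population resource" and is kept, because most true somatic calls have
no population record. A gene is considered expressed in a cancer type
when it reaches ≥ 1 FPKM in ≥ 80% of that type's tumor samples;
mutations in unexpressed genes are dropped, except for 18 well-known
cancer genes with poor transcript detection (`expression_exempt_genes()`)
and, for samples of unknown type, genes expressed in ≥ 80% of the
cancer types on file. All coordinates are 1-based inclusive; cancer-type
strings are taken verbatim.

### Contact graphs

Two residues are in contact when the euclidean distance between their
closest atoms is below a cutoff: 6 Å within a chain, 9 Å across chains,
the minimum taken over every structure (and every NMR model) covering
the pair. Defaults follow common practice for side-chain-mediated
contacts and are config-exposed (`cutoff` arguments). Atom selection is
all non-hydrogen, non-water polymer atoms; alternate locations resolve
to the highest-occupancy conformer (ties: first in file order); residues
with no resolved atoms are simply absent. Distance computation is an
exact all-pairs minimum; a centroid-radius prefilter skips residue pairs
that provably cannot be within the cutoff, and tests verify exact
agreement with a brute-force oracle. Inter-chain contacts between two
chains of the same protein (homomers) are retained. Predicted
single-protein models contribute a third graph with no confidence
filtering: low-confidence regions are kept, since cluster evidence is
carried by the mutations, not the model confidence.

### Clusters

In-frame mutations are expanded to residue footprints — a point for
missense, the full range for in-frame deletions, the anchor residues for
insertions (a deliberately conservative convention; footprints never
extend beyond what the variant touches). The induced subgraph on mutated
residues decomposes into connected components: clusters. A mutated
residue covered by a graph but with no mutated neighbor is a singleton
cluster — for predicted models every residue is covered, and we treat
experimental coverage the same way for symmetry. The observed count
`O_C` is the number of mutation *events* (a recurrent residue hit in two
tumors counts twice; one deletion spanning three cluster residues counts
once), because a recurrence test needs events, not footprints.
Predicted-structure clusters sharing any residue with an experimental
cluster are dropped as redundant; overlap with inter-protein clusters
does not trigger removal, because the families answer different
questions and are corrected separately. The same residue may therefore
appear in one intra, one per-PPI inter, and one interface cluster.

### Background mutation rates and expected counts

The local BMR of a gene is the quotient of pooled silent/noncoding event
counts over pooled opportunity, where opportunity `X` is accumulated in
base·sample units (per-sample covered bases × cohort size). This unit
contract makes BMR "per base per sample", so the expected in-frame count
per gene per sample is

```
E_in_frame = N_coding · A_missense · (BMR_SNV + α · BMR_indel)
E_lof      = N_coding · (A_nonsense + A_splice) · (BMR_SNV + (1−α) · BMR_indel)
```

and the cluster expectation `E_C = E_u · (k/l_u) · n_p` is an event
count, dimensionally consistent with `O_C`. The pooling neighborhood is
the gene itself plus nearest neighbors in z-scored covariate space
(euclidean distance, ties broken by gene id), expanded until the pooled
silent SNV count reaches `min_background_count` (default 50; indels are
pooled over the same neighbor list). α defaults to 0.09 — the in-frame
fraction of coding indels — and is exposed as a parameter. Both
expectation families are floored at their cohort-wide 1st percentile so
that genes with vanishing local rates cannot produce arbitrarily small
p-values; proteins without any background-covered encoding gene fall
back to the median gene expectation. `A_t` can be computed from a
per-base consequence table (each base contributes its three possible
substitutions fractionally) or supplied directly in the covariate table,
which is what the synthetic generator does to avoid requiring a codon
model in tests.

### Significance and its limits

Clusters are scored with a one-sided Poisson upper tail
(`stats::ppois`, verified against an independent series-summation oracle
to 1e-12 relative error) and Bonferroni-corrected within two families:
structure-derived (C1∪C2∪C3) and interface (C4). All constructed
clusters count toward the family size; there is no pre-filtering. The
protein-level LOF test is the same machinery over the whole sequence.

A caveat that the package's own calibration study quantifies (see
below): the test conditions on clusters being *built from mutated
residues*, so every cluster has `O_C ≥ k ≥ 1` by construction, and
correcting over realized rather than possible clusters cannot control
the family-wise error rate under a uniform null — chance co-occurrence
of two events on one residue or on residues in contact is itself
reported as a small p-value. The p-values are best read as a recurrence
*ranking*, and the network stage consumes them exactly that way (as
monotone evidence scores); downstream module calls are additionally
guarded by the randomization-calibrated δ threshold.

### Heat diffusion and modules

Raw (not adjusted) p-values feed the heat and weight formulas: the
equations are monotone transforms of evidence, and adjusted values would
re-introduce family sizes into a stage that has its own null
calibration. Adjusted significance gates only the final driver-mutation
extraction. Each log term is capped at 300 before summation so zero
p-values cannot produce infinite heat; empty evidence sets contribute 0
(heat) or leave the baseline `w0 = 1` (weights), keeping every edge
weight positive. Degree-0 vertices are dropped before the
column-stochastic transition matrix is formed (a zero column would break
conservation). The diffusion matrix is obtained by a direct linear solve
(never an explicit inverse); the contract is the residual bound
`‖(I−(1−β)W)F − βI‖ ≤ 1e-9`, with heat conservation
(`colSums(E) = h`) tested alongside. β = 0.5 follows established
insulated-diffusion practice.

δ is selected on 20 degree-preserving double-edge-swap randomizations
(10·|E| attempted swaps each, rejecting loops and multi-edges; the
original weight multiset is randomly reassigned to the swapped edges;
heats stay fixed). For each replicate, the candidate grid is the set of
distinct positive exchanged-heat entries, and binary search finds the
smallest candidate at which every strongly connected component has at
most 5 proteins; the final δ is the smallest across replicates. Note the
direction of this rule: δ is the *least conservative* threshold any
single randomization tolerates, so replicates with larger per-replicate
minima would show oversize components at the final δ — the per-replicate
minimum, not the global one, is what tests verify. If every replicate's
exchanged heat is identically zero (no heat anywhere), δ degenerates and
the implementation falls back to machine epsilon with a message.
Thresholding is strict (`E(i,j) > δ`); modules are strongly connected
components; modules with more than 5 proteins are significant. All
randomness flows from one seed, with replicate seeds derived as
`seed + replicate`.

## The synthetic-data generator

`synth_chain()` places one C-alpha per residue on a compact zigzag coil:
consecutive residues 3.8 Å apart (the C-alpha virtual bond length) with
a 2.9 Å axial rise, giving i/i±1 ≈ 3.8 Å and i/i±2 ≈ 5.8 Å — both
genuine contacts, as in real folded backbones — while i/i±3 ≈ 9.0 Å
falls outside the 6 Å cutoff. A straight extended chain (contacts only
at i±1) was rejected as unrealistically sparse for folded proteins.
`synth_structurome()` builds two-chain complexes whose backbones cross
perpendicularly at a configurable gap, producing a compact interface
patch of a few residues per side at `gap = 5` and nothing at
`gap > 9`; interface annotations are derived from the same geometry, so
annotation and contact channels agree by construction.

`synth_cohort()` draws per-residue in-frame counts as Poisson with
cohort rate `E_g^in-frame / l_g × n_samples` (times any planted
multiplier), LOF counts per gene analogously, and silent/noncoding
background counts at the same per-base rates — generator and background
model share one parameterization, so calibration runs test the
statistics rather than unit conversions. Default rates
(`BMR_SNV = 2e-6`, `BMR_indel = 2e-7` per base per sample, i.e. about
2 coding SNVs/Mb per tumor) are typical pan-cancer magnitudes.
What the generator does *not* emulate: trinucleotide mutational
signatures, per-patient burden heterogeneity, covariate-correlated rate
structure (covariates are drawn independently of the rates, so neighbor
pooling is exercised mechanically, not biologically), real fold
geometry, and multi-gene isoform complexity. Passing tests therefore
demonstrate correctness of the machinery and its statistical behaviour
under an idealized null — not performance on real cohorts.

## Calibration studies

`calibration_conditions()` fixes the simulation conditions used by the
test suite and the acceptance script: 50 proteins of 200 residues,
cohorts of `n_p = 1000`, clustering on the predicted-structure graph of
the coil geometry (built once; it is seed-independent).

* `run_null_calibration()`: 200 cohorts at default background rates with
  nothing planted; reports the fraction of cohorts with ≥ 1
  Bonferroni-significant cluster. As anticipated above, this fraction is
  far above the nominal 0.05 (about 0.3 under the defaults) — the
  realized-cluster Poisson test is anti-conservative by construction,
  at every background density. The package reports this honestly rather
  than repairing it with a permutation layer, which is out of scope.
* `run_detection_calibration()`: the background is raised so each
  protein expects 0.04 in-frame events per sample — a 5-residue patch
  then has `E_C = 1` over the cohort — and a 10× elevation is planted on
  residues 48–52 of one protein; detection (a significant cluster
  overlapping the patch) lands at ≈ 0.92 over 200 seeds.
* `demo_hub_scenario()` / `demo_clique_scenario()`: end-to-end runs in
  which a lone hot hub yields no significant module (one-way heat flow
  cannot form a strongly connected component, and δ rises to cut
  hub–leaf reciprocity), while a mutually-hot 6-clique with pairwise
  interface clusters yields exactly one significant module of size 6.

Problem sizes throughout (50×200 calibration cohorts, ≤ 300-node
δ-selection graphs, 200 Monte-Carlo seeds) were chosen so the full suite
runs comfortably on a laptop while keeping Monte-Carlo standard errors
small relative to the thresholds being checked.

## Numerical and degenerate-input decisions

* Poisson tails: `ppois(O−1, E, lower.tail = FALSE)`; `O = 0` returns
  exactly 1; `E ≤ 0` is an error upstream (floors and medians guarantee
  positivity in the pipeline).
* p-values are clamped at 1e-320 before `−log10` only to avoid `Inf`
  transiently; the 300 cap makes the clamp value irrelevant.
* Cluster ids are deterministic (`source:protein:first-residue`), row
  orders sorted, and serialized distances printed at full precision
  (`%.17g`) so cached contact graphs round-trip bit-exactly.
* Duplicate mutation rows collapse on (sample, protein, range, term);
  strict parsing mode turns malformed rows into errors, permissive mode
  (default) skips them with a per-row report.
* Empty evidence sets: no clusters → zero in-frame heat; no LOF events →
  `p_u = 1` → zero LOF heat; no inter-protein clusters on an edge →
  weight `w0`; empty network → error.
* The open mapping question of multiple UniProt accessions per gene is
  resolved by treating the (protein, gene) map as explicit caller input;
  the package never guesses a fallback priority.

## Known limitations

* FWER is not controlled for cluster calls (quantified above); treat
  cluster p-values as rankings and rely on module-level calibration.
* Interface clusters treat a PPI's whole mutated interface as one
  cluster; no sub-interface structure is resolved.
* Clusters never span more than two proteins, and no distance-weighted
  membership is attempted.
* The expression filter needs per-sample FPKM; other units are the
  caller's responsibility to normalize.
* Homomeric inter-chain clusters are folded into the single protein's
  side of the formulas (tagged by having one protein id), a simplication
  consistent with their single-protein background.
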