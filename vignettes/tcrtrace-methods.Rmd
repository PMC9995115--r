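---
title: "Methods: models, simulators and validation in tcrtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and validation in tcrtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtrace)
```

## What the package computes

`tcrtrace` analyses TCR-beta clonotype tables from repertoires sampled at
multiple anatomical sites (left/right inflamed joints, peripheral blood),
in two cell subsets (regulatory and conventional CD4 T cells), over repeated
visits. The scientific question it addresses is whether the dominant,
persistent clones in such repertoires are *antigen-driven*: shared across
joints and over time, over-similar in sequence, and expanded beyond what
their generation probability alone would predict. Four analysis stages
correspond to four lines of evidence:

1. **Clone sharing** across compartments and visits (clonal proportions,
   sequential top-N intersection, Jaccard matrices, sharing classes,
   top-100 Venn counts).
2. **Convergent recombination vs convergent selection**: the Spearman
   correlation between clone frequency and generation probability
   (p~gen~), separately for clones shared between two samples and clones
   private to one. Frequencies driven by recombination statistics correlate
   with p~gen~; antigen-selected expansions do not.
3. **Diversity** via sample-size-based rarefaction/extrapolation of Hill
   numbers q = 0 (richness) and q = 1 (exponential Shannon entropy).
4. **Sequence-similarity networks**: junctions become nodes, connected when
   they share at least `tau` distinct amino-acid k-mers; patient networks
   are compared against repertoires sampled from a generative model of
   V(D)J recombination.

## The recombination model

The generative model is deliberately minimal: choose a V segment (only its
junction-proximal nucleotide suffix matters), trim `del_v` nucleotides,
insert an i.i.d. nucleotide segment of random length, trim `del_j` from a J
prefix, concatenate, and translate from the first V nucleotide. There is no
explicit D segment: D and both insertion zones are collapsed into the single
insertion segment. This preserves the one property the analyses rely on —
junctions with fewer insertions and matched segment ends are generated far
more often, so p~gen~ spans orders of magnitude — while keeping the model
small enough that *exact* generation probabilities can be verified against
exhaustive scenario enumeration (`enumerate_pgen_oracle()`). Insertion
nucleotides are i.i.d. (no dinucleotide Markov dependence); that is a
documented simplification, not an estimate of the human process.

`pgen_nt()` sums scenario probabilities over every (V, del~v~, insertion,
del~j~, J) decomposition of the query. `pgen_aa()` sums `pgen_nt` over all
nucleotide sequences translating to the query without enumerating codon
combinations: conditional on a V/J trimming scenario, nucleotide positions
are independent, so the probability factorises over codons and each codon
factor sums over synonymous codons. p~gen~ is unconditioned on productivity
by default; `conditioned = TRUE` divides by a seeded Monte-Carlo estimate of
the productive mass.

The packaged toy model (8 V suffixes of 5 codons, 6 J prefixes of 5 codons,
0–4 nt deletions per side, 0–10 nt insertions, mildly skewed usage) yields
productive junctions of 8–13 amino acids with log10 p~gen~ roughly between
−8 and −3. The 5-codon anchors were chosen so that two junctions sharing
both V and J contribute only ~6 shared 3-mers — below the network edge
threshold of 8 — so random-repertoire networks are sparse, as expected for
repertoires without antigen selection.

## The synthetic cohort and its two worlds

`generate_cohort()` emits repertoires with Zipf clone-size counts
(exponent `alpha`, default 1.5 — a heavy tail with a hyper-expanded head;
the exact law is a free parameter, and no validation number depends on it).
Which clone gets which count is governed by `selection_mode`:

* **NEUTRAL** (convergent recombination): a sample's clonotypes are the
  most frequently drawn distinct junctions in a large tally of model draws,
  and Zipf ranks follow the tally order. Frequency is therefore positively
  coupled to p~gen~.
* **ANTIGEN** (convergent selection): ranks are assigned by a random
  permutation, independent of clone identity. Planted shared clones are
  drawn uniformly *from the intersection of the configured samples'
  candidate pools* and placed in a configured top-rank band in every
  configured compartment and visit. Drawing them from the same pool
  intersection that produces chance-shared clones matters: it makes the
  planted and chance-shared clones follow the same p~gen~ law, so within
  the shared group frequency is exchangeable with respect to p~gen~ and the
  measured correlation is consistent with zero. (An earlier design that
  drew planted clones directly from the model produced a spurious negative
  correlation — a mixture artifact of two p~gen~ laws — and was rejected.)

Planted similarity families are built by drawing a 13–15 aa seed junction
from the model and substituting `s` (default 1) *fixed* position(s) per
member: all members mutate the same position, so any two members differ at
at most 2·s positions within a 3-residue window and share at least
`L − 2 − 3s ≥ 8` distinct 3-mers, which the generator verifies pairwise and
regenerates (then errors) if violated. Members are assigned alternately to
the left/right compartments, producing the mixed (low-purity) cross-knee
clusters the network stage is designed to detect.

Defaults describe the reference world: 2 patients, SF-left/SF-right/PB,
2 visits, both subsets, 2000 clonotypes and 50,000 templates per sample,
40 planted shared clones (doubled for Tregs via `treg_multiplier = 2`,
reflecting stronger Treg sharing), six families of eight members. What the
generator does **not** emulate: sequencing error, PCR amplification bias,
V/J-call noise, thymic selection, or realistic human V/J diversity. A green
test therefore establishes that the *pipeline* recovers planted structure
under its stated sampling laws — not that the toy model reproduces human
repertoire statistics.

## Statistics

Spearman's rho is computed on average ranks. Its default p-value is a
continuity-corrected t approximation: the permutation distribution of rho
lives on a lattice of spacing `12/(n(n^2−1))`, and the raw t statistic
systematically undershoots the inclusive tail probability at small n, so
|rho| is shifted by half a lattice step before the t transform. With this
correction the approximation is within 0.05 of the exhaustive permutation
p-value for *every* permutation at n = 5 (worst case 0.047); an exact
permutation method is available for n ≤ 8. Confidence intervals use the
Fisher z transform with the Fieller variance 1.06/(n−3), the standard
adjustment for rank correlation.

The Mann-Whitney U test uses average ranks with a tie-corrected,
continuity-corrected normal approximation for large samples. When the
smaller group has ≤ 8 observations the two-sided p-value is *exact*: the
full conditional permutation distribution of U given the observed (possibly
tied) pooled values is obtained by subset-sum dynamic programming over
doubled ranks — identical to enumerating all `choose(nA+nB, nA)`
assignments, but polynomial, so a 5-vs-500 comparison (the network purity
test) is still exact. Two-sided p is the probability of a U at least as far
from its null mean as observed.

Diversity interpolation for q = 0 uses the exact hypergeometric expectation
on the log-binomial scale; extrapolation uses the Chao1 unseen-species
estimate. For q = 1 the package deliberately deviates from closed-form
rarefaction estimators: the expected subsample entropy is estimated by
seeded Monte-Carlo subsampling (default 200 replicates), because that
estimator can be validated against exhaustive subset enumeration on toy
communities and is amply precise for group comparisons; beyond the observed
depth a coverage-adjusted asymptotic entropy is returned as a flagged
plateau rather than a pretended extrapolation. Group comparisons happen at
the smallest common sample size by default.

## Networks

Edges require at least `tau = 8` shared *distinct* 3-mers (presence, not
multiplicity), independent of junction length; a junction shorter than
`tau + k − 1 = 10` residues can never gain an edge. Clusters are connected
components — no community detection is imposed, matching the blob-like
cluster structure the rule produces. Cluster purity defaults to the
label reading: nodes carry origin labels LEFT/RIGHT/SHARED (a junction
present in both joints is one SHARED node) and purity is the share of the
most common label. The alternative reading of purity — the share of the
most abundant *sequence* — is degenerate when nodes are deduplicated
junctions, so it is provided only as an explicit option
(`purity = "abundance"`, using clone counts when supplied). Junctions are
k-merised whole; trimming the conserved C/F anchors is available
(`trim_anchors`) but off by default, since anchor-induced baseline
similarity stays below the edge threshold in this model. Random comparison
repertoires are sampled productive-only, deduplicated to unique junctions,
and size-matched to the patient samples; `n_random = 100` pairs by default.

## Reproducibility and numerical choices

Every random stage derives its seed as `stage_seed(global_seed, stage_name)`
(a 31-bit polynomial hash), so stages have independent streams, reruns are
byte-identical, and changing the global seed changes everything. Pipeline
tables carry a provenance header line (stage, seed, config hash). Pgen
values of 0 (junctions outside the model support, e.g. mutated family
members) are excluded from correlations and counted in the report rather
than silently dropped; groups with fewer than 3 clones are flagged
`UNDEFINED`. Probability vectors must sum to 1 within 1e-12; the
enumeration oracle must total 1 within 1e-9 and agree with the dynamic
program within 1e-12 per sequence.

## Validation protocol and scale choices

The acceptance suite fixes Monte-Carlo protocols (25 seeds for
planted-family recovery, 50 for null calibration and for the convergence
dichotomy) and uses reduced cohort sizes chosen *a priori* for runtime:
300 clonotypes/sample for network-purity runs and 800/sample for
convergence runs (power is ample — the non-shared group alone has several
hundred clones, and rho ≈ 0.35–0.45 under NEUTRAL sampling). The end-to-end
reproducibility check runs the full 2 × 2 × 2 × 2 × 2000 reference world.

## Known limitations

* The toy recombination model is not a fitted human TRB model; absolute
  p~gen~ values and published correlation coefficients from full-scale
  models are not reproducible with it, and are not targeted.
* Insertion nucleotides are i.i.d.; deletion and insertion distributions
  are not inferred from data (no IGoR-style fitting).
* Shannon rarefaction is Monte-Carlo, so interpolated values carry a small
  seed-dependent error (reported as `se`).
* Clusters are connected components; alternative community structures are
  out of scope.
* Singleton clonotypes are not filtered before overlap analyses (the
  source protocol does not state a filter); `min_count` filtering can be
  applied upstream by the caller.
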