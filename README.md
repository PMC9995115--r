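# tcrtrace

Spatial and temporal analysis of T-cell receptor (TCRβ) repertoires, built
for the question: are the dominant T-cell clones in a chronically inflamed
tissue **antigen-driven**? In autoimmune arthritis, regulatory and
conventional CD4⁺ T cells sorted from synovial fluid of both affected knees
and from blood, across repeated visits, show hyper-expanded clones that are
shared across joints and persist over time. `tcrtrace` implements the
quantitative toolkit behind that kind of claim, for anyone working with
clonotype tables (AIRR-style TSV: amino-acid junction, V/J calls, count):

* **Clone sharing** — clonal proportion bins, sequential top-N
  intersection curves, Jaccard overlap matrices J(A,B) = |A∩B|/|A∪B|,
  per-clone sharing classes, paired frequency tables, top-100 Venn region
  counts.
* **Convergent recombination vs convergent selection** — a generative
  V(D)J model (V suffix – trim – i.i.d. insertions – trim – J prefix)
  supporting seeded sampling and *exact* generation probabilities
  p_gen(σ) = Σ_scenarios P(V)P(del_V)P(ins)P(del_J)P(J) at nucleotide and
  amino-acid level; Spearman correlation of clone frequency with p_gen,
  separately for shared and non-shared clones. Frequency tracking p_gen
  indicates convergent recombination; antigen-selected expansions do not.
* **Diversity** — sample-size-based rarefaction/extrapolation of Hill
  numbers ⁰D (richness, exact hypergeometric + Chao1 extrapolation) and
  ¹D = exp(H) (seeded Monte-Carlo interpolation), with Mann-Whitney group
  comparisons at a common depth.
* **Similarity networks** — junctions as nodes, an edge when two junctions
  share ≥ τ (default 8) distinct amino-acid k-mers (k = 3); connected
  components as clusters; cluster purity over LEFT/RIGHT/SHARED origin
  labels; benchmarking against 100 size-matched random repertoires drawn
  from the generative model, with an exact small-sample Mann-Whitney test.
* **Synthetic cohorts** — a simulator with planted ground truth
  (hyper-expanded shared clones, persistent clones, sequence-similar clone
  families, Zipf clone sizes, NEUTRAL vs ANTIGEN selection modes) so every
  stage is testable end-to-end without patient data.

## Worked example

Simulate one patient's left/right synovial-fluid Treg repertoires (300
clonotypes each, antigen-driven world: 80 planted shared hyper-expanded
clones, six cross-knee similarity families), then run the three core
analyses:

```r
library(tcrtrace)

cfg <- cohort_config(n_patients = 1, compartments = c("SF_LEFT", "SF_RIGHT"),
                     subsets = "TREG", visits = 1,
                     repertoire_size = 300, reads_per_sample = 6000, seed = 2)
sim  <- generate_cohort(cfg)
left  <- collapse_by_junction_aa(sim$cohort$P1_SF_LEFT_TREG_V1)
right <- collapse_by_junction_aa(sim$cohort$P1_SF_RIGHT_TREG_V1)

jaccard_matrix(list(left, right))
#>                     P1_SF_LEFT_TREG_V1 P1_SF_RIGHT_TREG_V1
#> P1_SF_LEFT_TREG_V1               1.000               0.212
#> P1_SF_RIGHT_TREG_V1              0.212               1.000

top_n_intersection(left, right, n_grid = c(10, 100, 300))
#>     n percent_overlap
#> 1  10               0
#> 2 100              80
#> 3 300              35
```

A fifth of all unique junctions appear in both knees, and the top-100
overlap of 80% is exactly the planted hyper-expanded block (their order
*within* the top band is randomized per sample, hence the 0% at n = 10).
Frequencies do not track generation probability in this antigen-driven
world:

```r
convergence_report(sim$cohort, toy_recomb_model())[, c("group", "n_clones", "rho", "p_value")]
#>        group n_clones      rho p_value
#> 1     SHARED      105  0.09025   0.360
#> 2 NON_SHARED      369 -0.00178   0.973
```

(In a `selection_mode = "NEUTRAL"` cohort the non-shared group instead
shows rho ≈ 0.35–0.45 with p ≪ 0.001 — convergent recombination.) The
similarity network recovers the planted cross-knee families as its top
clusters, whose left/right mixing (purity 0.5) is far below random
expectation:

```r
net <- joint_network(left, right)
net
#> TCR similarity network: 495 nodes, 168 edges, 453 clusters (k=3, tau=8)
st <- cluster_statistics(net)
st
#>   cluster n_sequences n_connections purity
#> 1       1           8            28    0.5
#> ...
cmp <- compare_to_random(st, toy_recomb_model(), c(300, 300),
                         cfg = network_config(n_random = 100, seed = 99))
#> patient median purity 0.50 vs random 1.00, Mann-Whitney p = 0.0012 (patient_lower)
```

`run_pipeline()` (or the CLI at `inst/cli/tcrtrace.R`: subcommands
`simulate | spatial | temporal | network | diversity | all`) orchestrates
all stages from a sample sheet, writes provenance-stamped TSV tables, and
is byte-reproducible under a fixed seed.

## Acceptance script

`scripts/acceptance.R` regenerates the package's reference synthetic world
(2 patients × left/right SF × Treg/non-Treg × 2 visits, 2000 clonotypes
per sample) from the given seed and runs the complete pipeline — sharing,
convergence, networks with 100 random-repertoire comparisons, diversity —
writing its result JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The statistical validation itself (exact p_gen vs exhaustive enumeration,
sampling consistency, k-mer and rank-statistic oracles, planted-structure
recovery, null calibration, reproducibility) lives in the test suite; see
`vignettes/tcrtrace-methods.Rmd` for the models, parameter choices and
their rationale.
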