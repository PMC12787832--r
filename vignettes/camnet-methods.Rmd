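---
title: "Methods: multi-omics integration and module-network contraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration and module-network contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camnet)
```

# The analytical chain

`camnet` models a three-group treatment-gradient experiment (a control
and two treatment levels, labelled `T0`/`T2`/`T4` by default) profiled
on three omics layers: transcript abundances with n = 3 biological
replicates per group, protein intensities with n = 3, and metabolite
peak intensities with n = 6 plus pooled-QC injections. The chain runs

1. metabolomics QC cascade,
2. per-layer differential-feature calling per pairwise contrast,
3. enrichment statistics over pathway annotations,
4. contraction of the differential interaction network into a
   functional-module network ranked by connectivity.

Every stage is exercised on synthetic data with planted ground truth;
the generator is first-class, tested code, not a fixture.

# Metabolomics preprocessing

The cascade order is fixed:
`presence_filter` → `impute_min` → `sum_normalize` → `qc_rsd_filter` →
`log10_transform`. Each operation checks the `stage` tag of its input,
so running stages out of order raises an error instead of silently
reordering; the two filters additionally accept their own output stage,
making re-application a checked no-op (idempotence).

Parameter conventions, each a deliberate choice where the field's usage
varies:

* *Detected* for the presence filter means non-missing **and** strictly
  positive; a recorded zero intensity carries no more evidence than a
  missing cell. The 80 % boundary is inclusive ("at least 80 %").
* Minimum imputation defaults to `per_feature` scope (each feature's own
  observed minimum), because sub-quantification censoring is a
  feature-level phenomenon; a `global` scope is exposed for users whose
  acquisition software reports one matrix-wide floor.
* RSD uses the sample standard deviation (n − 1 denominator), the
  metabolomics-QC convention, and is computed on sum-normalized,
  pre-log intensities — the order in which the stages are defined. The
  exclusion rule is strict (`RSD > 0.30` removed), so a feature at
  exactly 30 % is retained.
* Sum normalization targets column total 1. Any positive constant is
  equivalent up to an additive shift after the log, so the target is a
  convention, not a parameter.

# PLS-DA VIP

Metabolite significance combines a t-test with a variable-importance
score from a two-class partial-least-squares discriminant model, fitted
by NIPALS on autoscaled data with the class coded ±1. For feature *j*,

$$\mathrm{VIP}_j \;=\; \sqrt{\,p \cdot
  \frac{\sum_a \mathrm{SSY}_a\,(w_{ja}/\lVert w_a\rVert)^2}
       {\sum_a \mathrm{SSY}_a}}$$

with *p* the number of scored features, $w_a$ the component-*a* weight
vector and $\mathrm{SSY}_a = q_a^2\,t_a^\top t_a$ the response variance
captured by component *a*. Because the weights are unit-norm, the mean
of the squared VIP over scored features is exactly 1 — an algebraic
identity the tests assert to 1e−8 on every fit.

Two deliberate choices: the default is plain PLS-DA rather than OPLS-DA,
with a single orthogonal-signal-correction pre-step available via
`orthogonal = 1`. For a two-class contrast the two models rank features
nearly identically on their predictive structure, and making the
orthogonal step explicit is preferable to silently assuming it. The
component count defaults to 2 (truncated to the admissible maximum);
with the small sample sizes typical here, later components chase noise.
Constant features cannot be autoscaled: they get VIP 0 with a warning
and are excluded from the normalization identity.

# Differential calling

Per contrast `c(test, reference)`:

* **transcripts** — Welch t on `log2(x + 1)` (pseudocount 1 on count
  data), fold change from the pseudocounted group means, BH FDR within
  the contrast and layer; called when `|log2FC| ≥ 1` (inclusive) and
  `FDR < 0.05`. This is an explicit substitution: the negative-binomial
  shrinkage machinery of dedicated RNA-seq packages is out of scope
  here, and a t-test at n = 3 is conservative — on synthetic data it
  recovers few true transcripts, which the pipeline reports honestly
  rather than masking. The protein and metabolite rules, and everything
  downstream, do not depend on it.
* **proteins** — Welch t on `log2(x)` (intensities are strictly
  positive), fold change on the raw scale; `|log2FC| ≥ 1` and raw
  `p < 0.05`. The Welch/pooled-Student choice is a flag
  (`var_equal`), defaulting to Welch: equal group variances are an
  assumption, not a given.
* **metabolites** — operates on the logged matrix from the cascade;
  the log2 fold change is the difference of logged group means divided
  by log10(2), i.e. the log2 ratio of raw-scale geometric means;
  called when `VIP > 1` (strict) and `p < 0.05`. No fold-change
  threshold is applied to metabolites.

The boundary readings (fold inclusive, VIP strict) follow the
conventional statements of these rules. Degenerate rows (zero variance
in both groups, equal means) return p = 1 by convention with a warning;
zero variance with unequal means floors p at the smallest positive
double so the contract p ∈ (0, 1] holds.

`bh_adjust()` wraps `stats::p.adjust(method = "BH")` — the canonical
step-up implementation — and the test suite verifies it against an
independent direct-scan evaluation of the step-up definition on 1000
random p-vectors.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ k) with population N, set size K, selection n, overlap k, and BH
across tested sets. The universe is the features present in the layer
**after** preprocessing, not the whole annotation — the conservative
convention, since features that could never have been selected should
not inflate significance. The implementation calls `stats::phyper`;
tests compare it to exhaustive combinatorial enumeration for every
parameter combination with N ≤ 12.

Pre-ranked GSEA uses the weighted running-sum statistic: increments of
$|s|^q / \sum_{hits} |s|^q$ at members, decrements of $1/(N-K)$
elsewhere; ES is the signed maximum deviation, bounded in [−1, 1] and
invariant to positive rescaling of the scores. Significance comes from
gene-label permutation, $p = (1 + \#\{|ES^*| \ge |ES|\})/(1 + n_{perm})$
— phenotype permutation would require per-sample recomputation of the
ranking metric and is unnecessary at this scale. The default ranking
metric fed to GSEA in the pipeline is the log2 fold change. No
multiplicity correction is applied across GSEA sets by default.

# Network integration and contraction

The differential subnetwork is the subgraph induced by DEG ∪ DEP,
keeping edges with confidence ≥ `min_score` (default 0.4, the common
"medium confidence" convention for STRING-style scores; purely a knob).
Isolated selected nodes are retained and flagged. Features differential
at both the transcript and the protein level (`concordant_nodes`, with
an explicit protein↔transcript id mapping, identity by default) are the
designated central nodes.

Contraction is the quotient-graph construction. Each node is assigned
to a pathway module; since real KEGG genes are multi-pathway, the
assignment policy is explicit:

* `unique_lexicographic` (default) — deterministic, no hidden choice;
* `unique_smallest_set` — prefer the most specific pathway;
* `multi` — keep all assignments; a node edge then supports module pair
  {P, Q} once per ordered pathway combination, and contributes
  within-module support for every pathway shared by both endpoints.

"Redundant edge removal" is read as collapsing parallel module edges
into one edge with a `weight` equal to the count of supporting node
edges, and keeping within-module connectivity out of the displayed graph
(reported separately as `self_support`). Edges touching unannotated
nodes are dropped but counted, never silently lost. In unique mode the
accounting is conserved exactly:
`Σ weights + Σ self_support + dropped = |node edges|`.

Module importance is connectivity degree. Both variants are provided:
`degree` (distinct neighbouring modules) and `weighted_degree` (sum of
incident edge weights). The pipeline default is `weighted_degree`, for a
structural reason: in a dense network the module graph saturates — with
8 modules of 12 nodes at inter-module density 0.05, a module pair has
probability ≈ 1 − 0.95^144 ≈ 0.9994 of at least one cross edge, so every
unweighted degree equals 7 and the ranking degenerates to the
tie-break. The weighted degree keeps resolving hubs in that regime,
and coincides with the unweighted notion on sparse graphs. Ties are
always broken lexicographically, making rankings deterministic.

`contraction_oracle()` is an independent brute-force verifier (per
module pair, scan all node edges) shipped with the package; the test
suite requires exact equality with `contract()` on 100 random 50-node
instances across policies.

# The synthetic generator

What it emulates: a 3-group design; overdispersed counts for
transcripts (negative binomial, mean/dispersion parameterization,
default dispersion 0.1); mean-exact log-normal intensities for proteins
and metabolites (default biological CV 0.2), so a planted log2 effect of
2 yields an expected group-mean ratio of exactly 4; pooled-QC injections
as technical replicates of the grand mean with CV 0.05; planted
differential features with signed ±2 log2 effects; metabolite
missingness at a stated overall rate (default 0.15), with cell-wise
missingness probability decreasing in intensity so that minimum
imputation is meaningfully exercised; a planted fraction (default 0.10
where used) of QC-unstable features with CV 1.0 — representative of
instrument-unstable LC–MS features, whose RSDs typically fall in the
50–150 % range; and a pathway-structured interaction network (intra- /
inter-module densities 0.3 / 0.05) with one hub module whose members'
inter-module edge probability is multiplied by 3. Planted differential
sets include the hub module's members, so concordant differential nodes
are genuinely central — the structure the integration step is meant to
find.

What it does not emulate: raw reads or spectra, library-size artifacts,
batch effects, correlated features, heavy-tailed or missing-not-at-
random protein data, annotation incompleteness bias, or score-structured
interaction confidences (scores are uniform). Passing recovery tests
therefore demonstrates the correctness and calibration of the chain
under its stated noise models, not performance on any real dataset.

# Numerical and scale choices

All randomness flows through explicit integer seeds; per-stage seeds in
the pipeline are derived arithmetically from the run seed, so stages are
independently reproducible and two equally configured runs write
byte-identical artifacts (asserted via file checksums). Sum-normalized
columns are checked to total 1 within 1e−9; the VIP identity to 1e−8;
BH and hypergeometric cross-checks to 1e−12; the row t-test matches the
reference implementation to 1e−10.

Test and acceptance problem sizes are chosen to make the statistical
assertions sharp while keeping the suite quick on a laptop: 100 random
graphs for the contraction oracle; 20 seeds for hub recovery
(8 modules × 12 nodes), protein-rule calibration (2000 features), and
VIP sweeps (50 features); 200 repetitions × 199 permutations for the
GSEA size check, whose rejection count is compared to the central 99 %
binomial band at nominal 0.05; a 500-feature, 22-sample peak table for
the cascade. The default pipeline simulates 600 transcript/protein
features and 500 metabolite features.

# Known limitations

* The transcript rule's t-test at n = 3 is underpowered relative to
  shrinkage-based count models; transcript DE counts from the pipeline
  should be read accordingly.
* Unique module assignment discards genuine pathway multiplicity;
  `multi` mode is available but changes the meaning of edge weights.
* The VIP score is reported for a fixed component count, not selected
  by cross-validation.
* The generator's independence assumptions (edges, features, cells)
  make recovery tests easier than correlated real data would be.
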