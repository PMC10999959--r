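---
title: "Methods: Euclidean clock spaces and pacemaker tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Euclidean clock spaces and pacemaker tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `clockspacer`, the
choices we made where the design was genuinely open, and what the simulation
engine does and does not emulate. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The model

### Concordance-based rate collection

The unit of observation is a *branch rate*: for locus $i$ and species-tree
branch $j$, $r_{ij} = \ell_{ij} / t_j$, where $\ell_{ij}$ is the length (in
expected substitutions per site) of the gene-tree branch whose bipartition
uniquely matches branch $j$, and $t_j$ is the branch's duration in time
units. Matching is by split identity after restricting both trees to their
shared taxa:

- **matched** — exactly one species branch restricts to the gene branch's
  split; the rate is recorded (pendant branches included, since terminal
  branches carry most of the rate signal in shallow trees; use
  `internal_only = TRUE` for the alternative);
- **ambiguous** — two or more species branches collapse onto the same
  restricted split because of missing taxa. We record a missing value rather
  than apportioning the gene branch's length along the collapsed path: each
  column keeps the semantics of one species branch, and any apportionment
  rule would be invented;
- **conflicting** — the split is incompatible with the restricted species
  tree (gene-tree discordance or estimation error); missing value;
- **unmatched** — compatible with, but absent from, the restricted species
  tree (e.g. an edge resolving a collapsed region); also missing, noted in
  the per-locus log.

An unrooted gene tree cannot distinguish the two species-tree branches
incident to the root, so those two branches form a single merged column whose
duration is the sum of the two (splitting the unrooted gene edge's length
between them would be arbitrary). Loci sharing fewer than four taxa with the
species tree have no nontrivial splits and are dropped with a warning.
Zero-length gene branches are recorded as rate 0 at collection; the default
log transform later maps them to missing, keeping the decision at the
transformation step.

### The clock space

`prepare_rates()` makes the matrix complete: optional natural-log transform
(default on for rates — rates are right-skewed and multiplicative effects
such as 5× accelerations become additive), column/row missing-data filters
(default maximum 50% missing), column-mean imputation, and
centre-and-scale to unit variance. Column-mean imputation is neutral under
centering (imputed cells become exact zeros in the standardised matrix); the
choice of imputation is open in the literature, and the matrix interface
accepts externally imputed data.

`clock_space()` eigendecomposes the branch–branch **correlation** matrix.
Correlation rather than covariance scaling is deliberate: branch durations
differ by orders of magnitude, and the φ/ψ statistics below are defined on
correlation-matrix eigenvalues (which sum to the number of branches $p'$).
Eigenvector signs are fixed so each loading column's largest-magnitude entry
is positive, making output reproducible across eigen-solvers.

### Pacemaker tests

The null hypothesis is fully independent rates across loci and branches,
realised by permuting values independently within each column. All three
tests share one seeded permutation set for efficiency, and permuted
replicates pass through the *identical* standardise-then-eigendecompose code
path as the observed matrix, guarding against preprocessing asymmetries.

With eigenvalues $\lambda_1 \ge \dots \ge \lambda_{p'}$ of the correlation
matrix:

$$\psi = \sum_i (\lambda_i - 1)^2, \qquad
  \phi = \sqrt{\frac{\sum_i \lambda_i^2 - p'}{p'(p'-1)}}.$$

Both are 0 when all eigenvalues equal 1 (no correlation) and maximal
($\phi = 1$, $\psi = p'(p'-1)$) under perfect correlation. These are the
classical eigenvalue-dispersion indices of the multivariate literature; we
pin these exact formulas for testability. p-values use the add-one
convention $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, so the
smallest attainable p-value is $1/(B+1)$ and ties count against rejection.

`pPCs` compares each component's variance proportion with the permutation
distribution of the *same rank's* proportion; `pIL` does the same for each
branch's absolute loading at each rank. Comparing by rank accepts some
rank-swapping noise under the null but avoids eigenvector-matching
heuristics; it is the simplest reading of "per component", and we document it
rather than hide it. Raw p-values are always reported;
Benjamini–Hochberg adjustment of `pIL` across branches within a component is
opt-in (`adjust = "BH"`).

A caution on *mean* rate shifts: a multiplier applied to one branch equally
across all loci moves that column's mean, which standardisation removes. A
uniformly accelerated branch is therefore detectable only through its
interaction with locus-level structure (e.g. amplified cluster contrasts or
reduced relative noise), which is why branch identification is easiest in
"broadly spread" data with clustered rate patterns — the behaviour the
simulation study quantifies.

### Distance embedding and clustering

The legacy route maps gene trees directly: `sbsd_min` compares the matched
branch-length vectors $a, b$ of two trees after the closed-form rescaling
$s^\* = \sum a_i b_i / \sum b_i^2$, normalises by the first vector's norm and
takes the minimum over both directions, so trees differing only in overall
rate are at distance 0. Classical Torgerson MDS (negative eigenvalues
truncated at zero) embeds the distance matrix in two dimensions.

`group_clocks()` runs PAM (k-medoids, via the `cluster` package; the PAM
build-then-swap algorithm is deterministic) for $k = 1..k_{max}$ either on
MDS coordinates or PCA scores, and selects $k$ with the gap statistic:
$\text{gap}(k) = \overline{\log W_k^{ref}} - \log W_k$, with $W_k$ the
within-cluster sum of squares and $B$ uniform reference draws over the data's
bounding box; $s_k = \text{sd}(\log W_k^{ref})\sqrt{1 + 1/B}$, and the
selected $k$ is the smallest with
$\text{gap}(k) \ge \text{gap}(k+1) - s_{k+1}$ ($k_{max}$ if none). We
implement the selection rule directly (rather than delegating) so the
reference space (bounding box) and dispersion definition are pinned.

## The simulation engine

The generator emulates the standard validation setting for this class of
methods:

- **Species trees:** constant-rate birth–death, conditioned on $N = 50$
  extant tips (λ = 0.5, μ = 0.1), node times rescaled so the root age is
  exactly 50 time units. Conditioning-then-rescaling is delegated to
  `ape::rphylo` plus an exact rescale.
- **Gene trees:** multispecies coalescent with one haploid sample per
  species and a constant population-size parameter θ on all branches; with
  $j$ lineages the next coalescence is exponential with rate $j(j-1)/\theta$.
  θ ∈ {0.02, 0.5, 1} spans negligible to substantial incomplete lineage
  sorting on this tree scale.
- **Clocks:** white-noise model — each gene-tree branch draws an independent
  gamma rate with mean `mean_rate × multiplier` and standard deviation
  `rate_sd`. Gamma keeps rates positive with exactly controlled first two
  moments; `rate_sd = 0` degenerates to a strict clock. The grid levels are
  mean rate ∈ {0.01, 0.05, 0.1} substitutions/site/time and
  rate_sd ∈ {0.005, 0.05, 0.5}; we read the "standard deviation" levels as
  the sd parameter itself (the alternative reading — a mean of per-branch
  sds — is indistinguishable here because the sd is homogeneous).
- **Clusters:** loci are assigned to $k$ ∈ {1, 3, 5} groups in near-equal
  blocks; each group shares one per-branch multiplier vector drawn lognormal
  with median 1 and log-sd `spread = 0.5`. The spread is not specified by
  the validation literature; lognormal keeps rates positive and symmetric on
  the log scale, and log-sd 0.5 yields multipliers mostly within $e^{\pm 1}$,
  i.e. the few-fold between-locus-group differences seen in empirical
  phylogenomic data. $k = 1$ yields all-ones multipliers.
- **Accelerations:** `round(fraction × n_edges)` branches (fraction ∈
  {0, 0.02, 0.10}) drawn uniformly are multiplied by 5. Accelerated branches
  are fixed per data set and compose multiplicatively with cluster
  multipliers; gene branches inherit the species branch containing their
  midpoint (a deterministic rule for branches spanning species nodes).
- **Design:** the full factorial of the six three-level factors is 729
  scenarios; per-run seeds derive from
  `(base_seed + 1000003 × index) mod (2^31 − 2) + 1`, a documented stable
  hash keeping every seed in 32-bit range.

What it does **not** emulate: sequence-level noise and gene-tree
re-estimation error (gene trees are simulated directly, so branch lengths
are error-free given the coalescent genealogy), rate autocorrelation along
the tree, migration/hybridisation, and locus-specific overall rate ("gene
effect") variation beyond the cluster structure. Passing tests therefore
show that the pipeline recovers known structure from idealised gene trees;
they do not bound the additional distortion that tree-estimation error
contributes in real data.

## Scoring recovery

`run_scenario()` executes the full pipeline on one design cell and scores:
(i) rejection of the degenerate model by `pPhi`/`pPsi`; (ii) the
gap-statistic $\hat k$ versus the true $k$; (iii) accelerated-branch
recovery. For (iii), a truth-flagged branch counts as recovered at level α
when its minimum `pIL` across significant components is below α. Because
`pIL` has coarse granularity at small permutation counts, we also report a
threshold-free variant: branches are scored by their largest absolute
loading on significant components, and sensitivity is read at a fixed
specificity (default 0.95) on the negatives' score distribution. Columns
dropped by the missing-data filter cannot be detected and count against
sensitivity — this is how incomplete lineage sorting degrades recovery.

## Numerical choices and edge cases

- Ultrametricity is required within a relative tolerance of $10^{-6}$ of
  root height (scale-free).
- Eigenvalues are clamped at 0; $\Sigma\lambda = p'$ is enforced within
  $10^{-6}$ before φ/ψ.
- `sbsd_min` with one all-zero length vector returns 1 (0 if both are zero);
  fewer than 3 matched branches is an error.
- All-zero distance matrices embed at the origin; rank-deficient
  configurations pad with zero coordinates.
- PAM ties and reference draws are fixed by the seed; the whole
  clustering/testing stack is reproducible given (seed, B, k_max).
- Polytomies are accepted; their absent internal edges simply yield no
  splits.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: 500
independent 200 × 10 matrices for type-I calibration (99 permutations); 50
replicates at n_loci = 500, k = 3, θ = 0.02, rate_sd = 0.005 for power; 8
replicates per condition at n_loci = 500, rate_sd = 0.05, 49 permutations
for accelerated-branch recovery under {2%, 10%} accelerations × θ ∈
{0.02, 1}; 2000 four-taxon loci for the coalescent concordance check against
$1 - \tfrac{2}{3}e^{-2t/\theta}$. These sizes give stable Monte-Carlo
estimates for the directional and calibration claims being checked while
keeping the validation quick to re-run.

## Known limitations

- `pIL`'s rank-based comparison loses power when eigenvalue ranks swap under
  the null (near-degenerate spectra).
- Column-mean imputation shrinks imputed loci toward the centre of the
  space; loci with heavy missingness are better dropped (the default row
  filter) than imputed.
- The gap statistic is conservative on overlapping clusters — consistent
  with the general finding that identifying the number of rate clusters is
  hard, and that axis-based exploration is preferable to hard clustering.
- The sBSDmin/MDS route is retained for continuity but distorts large
  spaces; PCA is the preferred method.
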