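---
title: "Benchmarking gene regulatory network inference with grnbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene regulatory network inference with grnbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Dozens of algorithms infer gene regulatory networks (GRNs) from steady-state
expression compendia, and their published evaluations are rarely comparable:
each paper picks its own data, noise conditions, and scoring conventions.
`grnbench` provides a self-contained, fully reproducible pipeline for
comparing such methods under controlled conditions:

1. **generate** a datasource — a large noise-free expression matrix with a
   known gold-standard regulatory network;
2. **perturb** — subsample many smaller, homogeneous datasets and contaminate
   each with calibrated noise;
3. **infer** — run a battery of network-inference algorithms, each mapping an
   expression matrix (rows = experiments, columns = genes) to a G×G
   edge-confidence score matrix;
4. **evaluate** — score each inferred ranking against the gold standard on
   the top fraction of possible edges (AUPR, AUROC, mean precision);
5. **benchmark** — aggregate over replicate datasets, flag statistical
   winners, aggregate ranks across datasources, and sweep noise intensity and
   sample size.

Everything is driven by a single master seed, so a full study is reproducible
bit for bit.

## Synthetic datasources

Real benchmark collections are produced by heavyweight kinetic simulators.
`grnbench` instead ships transparent generative models whose statistical
behaviour reproduces the features that matter for method comparison: sparse
scale-free topology, interventional (knockout) versus observational
(multifactorial) designs, and regulator–target dependence that co-expression
methods can exploit.

### Topology

`grn_powerlaw_topology(n_genes, n_edges, seed)` draws an out-degree sequence
from a discrete power law (default exponent 2.5, in the range reported for
transcriptional networks), assigns the heaviest degrees to the most upstream
regulators, wires edges downstream only — so the graph is acyclic by
construction and steady states are closed-form in topological order — and
trims or augments uniformly to the exact requested edge count. Acyclicity is
a deliberate simplification: real GRNs contain feedback, but forcing a DAG
keeps the steady state exact, and none of the benchmarked methods models
feedback either.

### Knockout datasources

`grn_simulate_knockouts()` builds one experiment per gene. The wild-type
operating point $\mu$ solves a linear structural-equation model
$x_j = b_j + \sum_i w_{ij} x_i$; in experiment $k$ gene $k$ is clamped to 0
and the deviation $-\mu_k$ propagates linearly downstream. Basal levels are
offset by the worst-case single-knockout deviation (computed exactly from
the path-product matrix of $|W|$), so every non-clamped abundance stays
strictly positive and the knocked-out gene is always the minimum of its
column — the detection rule that interventional scoring methods rely on.

Interaction weights have uniform magnitude in `weight_range` with random
sign. The default is $U(0.1, 0.35)$, and the choice is load-bearing: the
score separating direct from indirect effects is the ratio of a one-hop gain
to a multi-hop product of gains. With gains near 1, two-hop products overlap
one-hop weights and no interventional method can cleanly separate parents
from grandparents; with gains well below 1, indirect influences decay
geometrically with path length — the same qualitative attenuation that
saturating kinetics produce in nonlinear simulators. Under the default, the
interventional Zscore method recovers the known network almost perfectly on
noise-free knockout data (top-E precision above 0.9 across seeds), which is
the behaviour this design is meant to emulate.

### Multifactorial datasources

`grn_simulate_multifactorial()` emulates compendia in which every experiment
perturbs all genes slightly: each gene's basal production is scaled by an
independent lognormal factor (default spread 0.5 on the log scale), and
expression relaxes to the steady state of a saturating regulation function.
Each regulator acts through a Hill term (default coefficient 2,
half-saturation at half the abundance scale), scaled so activation at most
doubles and repression at most silences the target's production; abundances
are bounded in $(0, x_\max]$. The model is deliberately nonlinear and
bounded — multiplicative inputs pushed through saturation — because that is
the regime in which mutual-information methods have an edge over plain
correlation.

What the generators do **not** emulate: feedback loops, time series,
mRNA/protein separation, intensity-dependent microarray error, missing
values, and the specific kinetic laws of any published simulator. Passing
benchmarks on these datasources therefore demonstrates correct machinery and
the expected qualitative method behaviour, not performance on any particular
real organism.

## Noise model

Two independent contamination components, applied after subsampling:

* **Local noise** (per gene): additive and zero-mean, with standard
  deviation $\sigma_g \cdot U(0.8\kappa, 1.2\kappa)/100$ where $\sigma_g$ is
  the gene's standard deviation *within the dataset at hand*. Every gene
  thus has a similar but not identical signal-to-noise ratio; the ±20% band
  (configurable via `range_fraction`) gives replicate datasets the mild
  heterogeneity seen between labs.
* **Global noise** (per dataset): one shared standard deviation,
  $\bar{\sigma_g} \cdot U(0.8\kappa_g, 1.2\kappa_g)/100$, where
  $\bar{\sigma_g}$ is the mean of the per-gene standard deviations (we read
  the "mean variance" of the construction as the mean of the standard
  deviations, matching its symbol).

Either component can be Gaussian or lognormal. Lognormal draws are
parameterized to the target standard deviation and then recentred to zero
mean, so contamination never shifts the signal — noise is read as
measurement corruption, not a systematic bias. The defaults (20% local
Gaussian + 10% global lognormal) are the reference study conditions.

The noise stream is seeded independently of the subsampling stream, so a
noise sweep reuses identical experiment draws at every intensity — the
κ = 0 column of a sweep is exactly a noise-free run. Sweeps vary local noise
only (global noise is switched off inside `grn_noise_sweep()`), which keeps
the κ grid interpretable as a pure SNR axis.

## Inference methods

All methods share one contract: expression in, finite G×G score matrix out,
higher score = more confident, zero diagonal. `zscore` and `genie3` are
directed (row regulates column); the rest are symmetric.

* **relnet** — pairwise mutual information (MI), thresholding left to the
  evaluator.
* **clr** — MI normalized against each gene's row background:
  $c_{ij} = \sqrt{c_i^2 + c_j^2}$ with
  $c_i = \max(0, (M_{ij} - \mu_i)/\sigma_i)$; row statistics use all G
  entries (including the zero diagonal) with a $G-1$ denominator.
* **aracne** — MI with data-processing-inequality pruning: the weakest pair
  of every triplet is removed (tolerance `eps`, default 0).
* **c3net** — MI thresholded at the $1-\alpha$ quantile of a permutation
  null (default 100 permutations, α = 0.05), then only each gene's single
  strongest partner survives; at most G nonzero pairs by construction.
* **mutrank** — each gene ranks its absolute Pearson correlations; the pair
  statistic is the printed product form $r_{ij} r_{ji} / 2$ (the
  construction is sometimes described as a geometric mean; we implement the
  printed formula and note the discrepancy). Confidence is the negated
  statistic so that higher = better.
* **zscore** — interventional scoring: the knocked-out gene of each
  experiment is detected as the row argmin (first index on ties), and its
  effect on gene $j$ is $|x_{jk} - \mu_j|/\sigma_j$; repeated detections
  average, never-detected genes emit zero rows.
* **mrnet / mrnetb** — minimum-redundancy maximum-relevance feature
  selection per target on the MI matrix. `mrnet` selects forward, stopping
  when the best relevance-minus-redundancy score drops to zero. `mrnetb`
  eliminates backward along the full greedy trajectory, keeps the best set
  seen, and then runs a replacement pass (swaps, single additions, single
  drops to a fixed point); the trajectory-best rule matters because the
  first local maximum of the set objective can be worse than the forward
  solution.
* **pcit** — first-order partial correlations in every triplet define a
  local tolerance (mean of the three |partial|/|marginal| ratios); a pair
  flagged in every triplet it shares is removed, survivors score |r|.
* **genenet** — shrinkage-regularized full-order partial correlation
  (analytic shrinkage of off-diagonal correlations toward zero, which
  guarantees invertibility at N < G). The original heuristic's subsequent
  causal-orientation step is out of scope; the output is undirected.
* **genie3** — one random-forest regression per target gene
  (impurity/variance-reduction importance, 500 trees by default,
  `mtry = ceil(sqrt(G-1))`), the field's standard reduction from the
  original 1000 trees to halve compute.
* **random** — i.i.d. uniform scores, the floor every method must beat.

### Numerical choices

* **MI estimator**: plug-in estimator on equal-frequency bins. The bin
  count defaults to $\lceil N^{1/3} \rceil$: the estimator's positive bias
  for independent pairs is approximately $(B-1)^2/(2N\ln 2)$ bits, and the
  cube-root rule keeps it below 0.05 bits at every sample size, whereas
  square-root binning lets it grow without bound (0.7 bits at N = 5000).
  Equal-frequency binning makes all MI-based scores invariant under
  strictly monotone per-gene transforms.
* **Ties and column order**: greedy selections (MRNET/MRNETB) process genes
  in lexicographic name order and recompute MI in that canonical order, so
  results are bitwise invariant to the input's column order. Stochastic
  methods (genie3, c3net permutations) derive per-gene seeds from gene
  identifiers for the same reason.
* **Degenerate inputs**: constant genes yield zero MI, zero correlation and
  zero z-scores rather than NaNs; a constant score matrix is evaluated under
  the tie-break only and flagged as degenerate.

## Evaluation protocol

Only the strongest predictions matter in practice, so scoring is restricted
to the top fraction $x$ (default 20%) of possible connections: $G^2 - G$
ordered pairs in a directed evaluation, $(G^2-G)/2$ unordered pairs in an
undirected one (undirected pair score = max of the two directed scores, a
pair is true if either direction is). Self-interactions are never
considered. Candidates are sorted by decreasing score with a fixed
lexicographic tie-break (recorded in the result), and confusion counts are
accumulated at every rank up to $t = \mathrm{round}(x \cdot n_{cand})$.

Three scalar metrics summarize the truncated curves:

* **AUPR** — trapezoid area under precision-vs-recall, normalized by the
  recall span the ranking actually covers. Under this normalization a
  perfect ranking scores exactly 1 at any truncation and a uniformly random
  ranking scores the gold density in expectation, which makes values
  comparable across datasources of different sparsity. (The truncated-area
  convention differs between published benchmarks; this one is ours and is
  stated here so numbers are interpreted accordingly.)
* **AUROC** — trapezoid area of TPR vs FPR normalized by the FPR span
  covered; 1 by convention if no false positive occurs within $t$.
* **mean precision** — the average precision over ranks $1..t$.

## The replicated study

`grn_benchmark()` runs the full grid (datasources × datasets × methods) and
summarizes per-cell AUPR means and variances. Two aggregation layers mirror
standard benchmarking practice:

* **Winner flags**: within a datasource, the best-mean method is compared to
  every other with a two-sided Wilcoxon rank-sum test on the per-dataset
  AUPR values (exact enumeration when both samples are ≤ 10 without ties,
  normal approximation with tie correction otherwise), Bonferroni-corrected
  over the comparisons; the winner set is the top method plus everything not
  significantly different from it.
* **Rank aggregation**: methods are ranked within each datasource by mean
  AUPR (average ranks on ties) and the rank vectors are summarized across
  datasources — scale-free, unlike averaging raw AUPRs.

A method that errors on a dataset becomes a missing cell (excluded pairwise
from tests and ranks), not a crashed run.

### Study sizes used in the shipped checks

The automated checks run the full pipeline at sizes a laptop handles in
minutes, chosen once as representative rather than maximal: knockout
specialization at G = 100, E = 135 over 10 topologies; the replicated
benchmark and both sweeps on a G = 150, E = 200 multifactorial datasource
with 1000 stored experiments, 10 datasets per condition; the sample-size
sweep compares 20 vs 800 experiments with 50 trees per forest for the
random-forest method — the sample-size trend is insensitive to tree count,
and 50 trees keeps ten replicate forests per condition affordable.

## Known limitations

* Acyclic topologies and exact steady states: no feedback, no dynamics.
* The generators are calibrated for *relative* method comparison; absolute
  AUPR values on them do not transfer to any real organism.
* `genenet` omits the causal-orientation step of the original heuristic, so
  it competes as an undirected method.
* PCIT's local-tolerance rule follows the published concept but fixes its
  own dialect for the unspecified details (documented above); results can
  differ from other implementations in edge cases.
* The Wilcoxon winner test treats replicate datasets as independent; they
  share the parent datasource, so flags are mildly anti-conservative across
  heavily overlapping subsamples.
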