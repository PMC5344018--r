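---
title: "Models and methods behind renschkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind renschkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

renschkit studies how sexual size dimorphism (SSD) evolves across a clade:
whether male body size is evolutionarily more labile than female body size
(Rensch's rule), which sex drives per-branch changes in SSD, and how
dimorphism relates to the size and complexity of male genitalia. This
vignette explains the models, the tunable parameters, and the design
decisions, in the order an analysis runs.

## The Brownian-motion null model

All continuous-trait machinery assumes Brownian motion (BM): along a branch
of duration $t$ My a trait changes by a normal increment with mean 0 and
variance $\sigma^2 t$. BM is deliberately the *simplest* null — homogeneous,
directionless change — so departures from it (allometric slopes away from 1,
K away from 1) are the scientific signal, not the model.

**Ancestral reconstruction** (`asr_bm`). Point estimates are the GLS/ML
values: a tip-to-root pass combines each node's daughters by
precision-weighted averaging (variance of a daughter message = branch length
+ the daughter's accumulated term $v_i v_j/(v_i+v_j)$), and a root-to-tip
pass combines each node's subtree message with the message from the rest of
the tree. The root estimate equals the phylogenetic mean
$(\mathbf{1}' V^{-1} x)/(\mathbf{1}' V^{-1} \mathbf{1})$ with $V$ the tip
covariance matrix; the test suite verifies all internal estimates against a
dense solve of that system to $10^{-8}$. The ML rate is
$\hat\sigma^2 = \frac{1}{n}\sum u_k^2$ over the $n-1$ standardized
contrasts; 95% intervals are
$\hat x_k \pm 1.96\sqrt{\hat\sigma^2 v_k}$ with $v_k$ the conditional
variance from the two messages. Two caveats are properties of the model, not
bugs: tip estimates equal the observations exactly (they are data), and
internal estimates shrink towards intermediate values, so branch-wise rates
read from a reconstruction are conservative. Children of zero-length
branches (polytomy inserts) inherit the parent estimate exactly — a
zero-variance message dominates the combination.

**Independent contrasts** (`pic_contrasts`). Felsenstein's pruning:
contrast $(x_i-x_j)/\sqrt{v_i+v_j}$ at every internal node, branch-length
correction $v' = v + v_i v_j/(v_i+v_j)$. Under BM the $n-1$ contrasts are
i.i.d. $N(0,\sigma^2)$, which licenses ordinary regression on them.
Zero-length branches get an additive $10^{-8}\times$(tree depth) inside the
variance terms only, with a message; patristic structure is untouched.

## Allometry: reduced major axis regression

Both sexes' sizes carry comparable "error" (biological variance), so the
allometric line is fitted symmetrically (type II / RMA):
slope $=\mathrm{sign}(r)\,\mathrm{SD}(y)/\mathrm{SD}(x)$, and through the
origin $\mathrm{sign}(\Sigma xy)\sqrt{\Sigma y^2/\Sigma x^2}$. Contrast
regressions run through the origin after positivizing each x-contrast (and
flipping its paired y-contrast), the standard contrast convention — a
contrast's sign is arbitrary, only the paired orientation is meaningful.
Sizes enter as log10, so the slope is dimensionless and slope $>1$ is
positive allometry of male on female size.

Choices that were genuinely open:

* **Confidence intervals**: percentile bootstrap over pairs, 1,999
  replicates, seeded (default), or Jolicoeur's analytic RMA interval.
  Bootstrap is the default because the contrast pairs are exchangeable but
  not bivariate-normal in small clades.
* **p-values**: from the correlation, $t = r\sqrt{df/(1-r^2)}$ with
  $df = n-2$, or $n-1$ through the origin. For raw-data rows both a
  correlation test and the isometry check (1 outside the CI) are reported,
  labelled, since they answer different questions.
* **Log base**: log10 for both contrast and raw regressions, for
  comparability of the slopes.

## Phylogenetic signal: Blomberg's K

$K$ compares observed to BM-expected tree fit:
$K = \frac{(MSE_0/MSE)_{obs}}{(\mathrm{tr}(V) - n/\Sigma V^{-1})/(n-1)}$,
where $MSE_0$ uses deviations of tips from the phylogenetic mean and $MSE$
is the GLS mean squared error. $K$ is invariant to affine trait maps and to
rescaling all branch lengths — it measures pattern, not scale. Significance
is a one-sided permutation test on the variance of independent contrasts
(smaller = more signal), default 999 permutations, reported as
$(\mathrm{hits}+1)/(N+1)$. The test suite checks the calibration property
that defines $K$: mean $K \approx 1$ for BM data on the analysis tree, and
$K < 1$ for tip-shuffled data.

## Per-branch change, darwins, and the 5% coding

Each branch yields the arithmetic change (final − initial), its absolute
value, and the rate in **darwins**: $|\ln(x_{final}/x_{initial})|/t$. The
log-ratio makes the rate proportional — invariant to trait units (mm vs µm)
— and 1 darwin is a factor-$e$ change over 1 My. darwins are computed only
for strictly positive endpoints and positive durations; other branches are
flagged undefined (never zeroed) and excluded from darwins summaries with a
reported count. SSD itself can be negative, so it is analysed by arithmetic
change only.

Qualitative coding: a sex's change below 5% of the branch's initial value is
within measurement error, coded `=`; SSD changes below 5% of the total range
of observed SSD are `=`. The "total range" is taken over **all** nodes of
the reconstruction (tips + ancestors), since the rule is applied to
reconstructed branch changes; a tips-only range can be passed explicitly.
An "all changes" mode codes every branch by raw sign. Codes are
cross-tabulated (female × male × SSD), and branches where SSD moved with
exactly one sex moving are counted and tested with the exact two-sided
binomial test for equal odds.

The male−female rate-difference regressions are ordinary least squares, not
RMA: their slopes are signed and expected to sit near zero for the
non-driving sex, which an RMA slope (a ratio of SDs) cannot represent.

## Parsimony for secondary sexual characters

Binary characters are reconstructed with Fitch/Sankoff dynamic programming;
down- and up-pass cost tables give the exact most-parsimonious state set at
every node, so ambiguity is reported rather than resolved away. Per-branch
gains and losses are listed under a DELTRAN-style resolution (changes
delayed towards the tips, ties keep the parent state), with the ACCTRAN
counts as the alternative; when the root set is ambiguous the DELTRAN pass
takes state 0 (character absent) as ancestral — the natural prior for
derived male ornaments — and the ambiguity is still flagged. The test suite
verifies lengths against exhaustive enumeration of all internal labelings.

## Box-counting fractal dimension

Genital outlines are binary rasters standardized to the acquisition
geometry (2,100 px canvas, 2,000 px base-to-apex span;
nearest-neighbour resampling keeps the raster strictly binary). The
box-counting estimator fixes three free choices: origin-anchored grids,
box sizes = powers of two from 2 to canvas/4, and an OLS fit of log(count)
on log(size) over all scales; the dimension is the absolute slope.
Calibration is against analytic phantoms — a straight line (1), a filled
square (2), a circle outline (1), and the Koch curve ($\log 4/\log 3
\approx 1.2619$) — rather than bit-agreement with any particular desktop
tool, whose internals differ in exactly these choices. Origin-anchored
grids make counts at coarse scales sensitive to sub-box translations; at
adequate resolution (canvas $\geq$ 1024 px for curve-like shapes) the
estimate is stable to within 0.05 under random small shifts. Perimeter
tracing is out of scope: perimeters are consumed as measured numbers and
standardized as perimeter/length.

## Synthetic data: what it emulates, what it does not

The generators produce every input the pipeline consumes, with ground truth
retained:

* `simulate_yule_tree` — pure-birth trees; default birth rate 0.11/My gives
  ~30 My crown ages at 60–71 tips, an Oligocene-scale radiation.
* `simulate_bm_bivariate` — correlated (male, female) BM. Defaults:
  $\sigma_f = 0.035$, $\sigma_m = 0.0504$ mm/$\sqrt{\mathrm{My}}$ (rate
  ratio 1.44), $\rho = 0.9$, roots 1.50/1.45 mm. The ratio and correlation
  are the male-biased, genetically coupled regime that produces Rensch's
  rule; the absolute scale is chosen so a BM walk on the mm scale stays
  $>5$ SD from zero at those tree depths — body length is positive, and BM
  on a linear scale has no hard floor, so the scale must keep excursions
  below zero negligible.
* `simulate_binary_character` — exponential waiting-time gains/losses
  (defaults 0.02/0.01 per My), true event list retained.
* `generate_phantom` — the calibration shapes above.
* `limnebius_like_dataset` — the study-scale bundle: 71 species, the BM
  regime above, one SSC history, and genital metrics (aedeagus length from
  a slow BM; perimeter complexity and fractal dimension with
  rSSD-correlated components plus noise, emulating the observed positive
  dimorphism–complexity association).

What the synthetic data deliberately does **not** contain: measurement
error and intraspecific variance; non-ultrametric sampling; selection,
rate shifts or OU attraction; topological uncertainty (one fixed tree per
run); any mechanistic model of sexual selection. Passing tests therefore
show that the estimators recover known generating parameters under the
null-model assumptions — not that real measurements satisfy those
assumptions.

## Numerical and reproducibility choices

* Every stochastic step (tree simulation, BM, bootstrap, permutations,
  polytomy resolution) takes an explicit seed; `run_full_analysis` derives
  independent named sub-seeds from one master seed and records them, so a
  rerun is identical. Seeded helpers restore the caller's RNG state.
* Polytomies are resolved to zero-length bifurcations (patristic distances
  preserved); downstream, zero-length branches mean "inherit the parent"
  in reconstruction and get the $10^{-8}$-of-depth variance floor in
  contrasts.
* Binary-tree checks require rootedness as well as bifurcation — an
  unrooted basal trichotomy is not an analysable binary tree here.
* Degenerate inputs fail loudly with the offending species or node named:
  missing tip values, constant data for $K$, non-positive lengths for
  complexity ratios, zero contrast variance.
* Test problem sizes are chosen for tight oracles, not realism: dense-GLS
  and exhaustive-parsimony comparisons run on 4–8-tip trees where the
  oracle is exact; calibration properties (slope recovery, K, rate
  recovery) run on 50–150-tip Yule trees with 25–100 replicates.

## Interfaces

The package is function-first: `run_full_analysis()` is the single-command
entry point, `write_report()` exports the delimited bundle, and all I/O
uses standard formats (Newick/NEXUS via ape, CSV/TSV trait tables, PNG/TIFF
outlines). There is no shell executable; an R script calling these
functions is the scripted interface, as in `scripts/acceptance.R`.

## Known limitations

* ML reconstruction on a fixed tree ignores phylogenetic uncertainty; the
  per-branch tables accept externally reconstructed node values
  (`branch_changes(tree, numeric_vector)`) if a posterior-based
  reconstruction is preferred.
* BM shrinkage compresses reconstructed per-branch changes; counts of
  ">5%" branches are conservative.
* The box-counting schedule is fixed; per-image dimension values are
  comparable within this package but not bit-identical to other software.
* A strictly binary rooted tree is required after polytomy resolution;
  reticulations and sampled-ancestor trees are unsupported.
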