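# renschkit

Phylogenetic comparative analysis of sexual size dimorphism (SSD) and
Rensch's rule, built for species-rich insect clades — the motivating case is
the minute moss beetle genus *Limnebius* (Hydraenidae), where male body size
varies far more across species than female body size and male genitalia range
from simple to extravagantly complex.

## What it computes

**SSD and allometry.** For each species, SSD is the direct difference
male − female body length (mm) and rSSD the ratio male/female. Rensch's rule —
SSD increases with size where males are the larger sex — is tested as positive
allometry of male on female size: a reduced major axis (type II) regression of
log₁₀ male on log₁₀ female length with slope

  b = sign(cov) · SD(y)/SD(x),  or through the origin b = sign(Σxy)·√(Σy²/Σx²),

fitted either to raw species data or to phylogenetic independent contrasts
(Felsenstein's pruning algorithm, contrasts sign-positivized on x before the
through-origin fit). A slope whose confidence interval excludes 1 rejects
isometry.

**Ancestral states and per-branch change.** Continuous traits are
reconstructed on a time-calibrated tree under Brownian motion by two-pass
GLS/ML pruning (the root estimate is the phylogenetic mean
(1ᵀV⁻¹x)/(1ᵀV⁻¹1)). Every branch then yields the arithmetic change
Δ = final − initial, |Δ|, and the rate in darwins, |ln(final/initial)|/t with
t in My. Branches are coded +/−/= per sex (changes under 5% of the initial
value are "no change") and for SSD (under 5% of the total observed SSD range),
cross-tabulated, and the branches where SSD moved through one sex only are
tested with an exact binomial sign test.

**Phylogenetic signal.** Blomberg's K with a permutation test (K = 1 under
Brownian motion; K < 1 labile/convergent; K > 1 strong signal).

**Secondary sexual characters.** Binary SSC (modified hind tibiae, abdominal
protuberances…) are reconstructed by Fitch parsimony with explicit
most-parsimonious-state sets, and per-branch gains/losses under a DELTRAN
resolution (ACCTRAN counts reported as the alternative).

**Genital complexity.** Perimeter-per-length of the aedeagus, and the
Minkowski (box-counting) fractal dimension of binary outline images: the
absolute slope of log(count) vs log(box size) over power-of-two boxes, with
raster phantoms of known dimension (line, filled square, Koch curve) for
calibration.

**Synthetic data.** Yule trees, correlated bivariate sex-specific Brownian
traits (ground-truth node values retained), binary character histories with
true event lists, and fractal phantoms — so the whole pipeline can be
validated without any empirical data.

## Worked example

```r
library(renschkit)

d <- limnebius_like_dataset(seed = 42)   # 71-species synthetic dataset
rep <- run_full_analysis(d$tree, d$traits,
                         ssc_states = d$ssc$tip_states, seed = 7)
rep
```

```
renschkit analysis report: 71 species, 140 branches

Allometry (RMA, male ~ female log10 size):
  group      data  n slope ci_low ci_high    r2        p isometry_rejected
1   all contrasts 70  1.39   1.24    1.56 0.738 1.00e-21              TRUE
2   all       raw 71  1.43   1.27    1.60 0.822 1.49e-27              TRUE

Phylogenetic signal (Blomberg's K):
          trait     K     p  n
1          rssd 0.672 0.001 71
2   male_length 0.826 0.001 71
3 female_length 0.762 0.001 71

Single-sex SSD changes: male-only = 15 , female-only = 2 , exact binomial p = 0.00235
```

The generator evolved male size 1.44× faster than female size (cross-sex
correlation 0.9), and the analysis reads it back: the contrast RMA slope is
1.39 with a CI excluding 1 (positive allometry — Rensch's rule), rSSD carries
less phylogenetic signal than either sex's size, and SSD changes confined to
one sex are overwhelmingly male-driven (15 vs 2; p < 0.01). Continuing:

```r
rep$rate_difference$darwins
#> Regression of (male - female) darwins on each sex's change (140 branches)
#>   vs male   slope +0.3683, R^2 0.341, p 3.67e-14
#>   vs female slope -0.04464, R^2 0.003, p 0.499

fractal_dimension(generate_phantom("koch", 1024, iterations = 5))
#> Box-counting fractal dimension 1.1996 (fit R^2 0.9962, 8 scales)
```

The male−female rate difference tracks male change, not female change, and
the box-counting estimator lands near the Koch curve's analytic dimension
log 4/log 3 ≈ 1.2619.

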