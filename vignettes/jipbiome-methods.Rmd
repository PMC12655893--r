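---
title: "Models and design choices in jipbiome"
author: "jipbiome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in jipbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jipbiome)
options(jipbiome.verbose = FALSE)
```

jipbiome analyses experiments that phenotype crop varieties of
contrasting saline–alkaline tolerance (tolerant T, sensitive S) in
normal (N) and saline–alkaline (A) soil — four groups TN, TA, SN, SA —
on two sides at once: photosystem II function read out from fast
chlorophyll-fluorescence induction, and rhizosphere community structure
read out from taxa-abundance tables. This vignette documents the models
behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic generators do and do not emulate, and
the numerical decisions taken where the design was genuinely open.

## The OJIP transient and the JIP test

A dark-adapted leaf exposed to a saturating pulse shows a fluorescence
rise over about five decades of time with the characteristic
inflections O (origin, the initial fluorescence F0), K (~300 µs), J
(~2 ms), I (~30 ms) and P (the peak Fm, reached between 0.1 and 1 s).
The JIP test turns five cardinal readings of this curve — F0, F300, FJ,
FI, Fm, plus the area between the curve and the F = Fm line — into
energy-flux and yield parameters of photosystem II.

### Cardinal-point extraction

`extractCardinalPoints()` makes the following operational choices:

* **F0 at 20 µs.** "Initial fluorescence" is operationally the first
  reliable reading of the analyzer, conventionally 20 µs after flash
  onset. We interpolate to 20 µs when the grid brackets it and
  otherwise take the earliest point at or before 50 µs; transients
  starting later cannot support an F0 estimate and are rejected.
* **Interpolation linear in log-time.** OJIP sampling is log-spaced and
  the curve is conventionally analysed on a log axis, so F300, FJ and
  FI are interpolated linearly in log10(t). On a 120-point grid this
  leaves interpolation errors of a few 10^-4 in Vt units, an order of
  magnitude below biological differences of interest.
* **Fm and the area.** Fm is the curve maximum, first index on ties;
  the area is the trapezoidal integral of (Fm − F(t)) from t(F0) to
  t(Fm). The area is also stored divided by (Fm − F0), making
  Sm = Area/(Fm − F0) dimensionless in Vt × ms units and therefore
  comparable across instruments and gain settings.

### The derived parameter set

With VJ = (FJ − F0)/(Fm − F0) and Fv = Fm − F0, `jipTest()` computes
Wk, φPo = Fv/Fm, ψo = 1 − VJ, φEo = φPo·ψo, Mo = 4(F300 − F0)/Fv,
Sm, the per-reaction-center fluxes and
PI_ABS = [RC/ABS]·[φPo/(1 − φPo)]·[ψo/(1 − ψo)].

Two closures deserve comment:

* **RC/ABS = φPo·(VJ/Mo).** This is the standard JIP-test identity for
  the reaction-center density per absorption and the only closure that
  makes PI_ABS computable from the cardinal points alone. The
  per-reaction-center fluxes follow the standard definitions
  (TRo/RC = Mo/VJ, ABS/RC = TRo/RC/φPo, ETo/RC = TRo/RC·ψo,
  DIo/RC = ABS/RC − TRo/RC).
* **RC/CSm.** Field reports sometimes write RC/CS = φPo·(ABS/CS)
  with ABS/CS approximated by Fm. The standard expression carries the
  additional VJ/Mo factor. The default is the standard
  RC/CSm = RC/ABS·Fm; the simpler closure is available behind
  `simpleRCCS = TRUE` rather than being silently corrected,
  because neither can be asserted to be the other's typo from the
  printed formulas alone.

Degenerate inputs are reported, not guessed at: a flat curve raises
"no variable fluorescence", FJ = F0 yields a missing Wk with a warning,
and φPo or ψo reaching 1 flags PI_ABS as infinite instead of emitting a
number.

## The synthetic transient generator

`simulateTransient()` draws from a three-exponential phase mixture plus
an optional K-component,

$$V(t) = \sum_{x \in \{J, I, P\}} w_x\,(1 - e^{-s/\tau_x}) +
  \kappa\,(1 - e^{-s/\tau_K}), \qquad s = \max(t - 20\,\mu s,\, 0),$$

renormalized to V = 1 at the grid endpoint, then scaled into
F(t) = F0 + (Fm − F0)·Ṽ(t) with additive Gaussian noise. This is a
shape model with controllable cardinal points, deliberately not a
mechanistic energy-flux model: the acceptance surface needs known
ground truth for VJ, Wk and φPo, not photochemistry.

Design choices:

* **Time origin at 20 µs.** The mixture is evaluated in time shifted by
  the 20-µs instrument origin (V = 0 for t ≤ 20 µs), so the first
  measurable point is exactly F0, exactly as the analyzer reports Fo.
  This makes noise-free φPo recovery exact and keeps the curve
  non-decreasing.
* **Default grid** of 120 log-spaced points from 20 µs to 1 s, the
  duration of the saturating pulse.
* **Defaults** F0 = 500, Fm = 2500 (Fv/Fm = 0.8, a healthy leaf),
  weights (0.5, 0.3, 0.2) and time constants (1, 10, 150) ms chosen to
  put VJ near 0.5 and VI near 0.8; τK = 0.3 ms places the K-component
  at the K step.
* **Group shifts** (`defaultStressDeltas()`): stressed groups get a
  raised κ and lowered Fm, the sensitive variety more so (κ + 0.25,
  Fm scaled 0.75, J-weight scaled 1.25 for SA versus κ + 0.05,
  0.95, 1.05 for TA), reproducing the qualitative stress phenotype —
  K-band appearance, Fv/Fm decline, ψo decline — at magnitudes that
  leave the four groups statistically separable at n = 10 per group.
* **Per-sample jitter** is lognormal with CV 5%, the replicate-level
  spread typical of leaf-clip fluorimetry on a uniform canopy.

What the generator does not emulate: instrument saturation,
photoinhibition during the pulse, the sigmoidal (cooperative) O–J rise,
or L-band phenomena. Passing recovery tests therefore demonstrates the
correctness of the extraction arithmetic on well-formed curves, not
robustness to every field artifact.

## Group physiological statistics

T-versus-S comparisons within a soil stratum use the Welch
unequal-variance t-test by default; the pooled-variance test is a flag.
The choice is deliberate: with n per group in the single digits,
assuming equal variances buys little power and risks miscalibration,
and where the variances happen to be equal Welch converges to the same
answer. Tests are two-sided, matching the conventional star thresholds
(* p < 0.05 through **** p < 0.0001, "ns" otherwise). Percent changes
are reported raw and rounded to one decimal. Fold ratios refuse
left-censored inputs (values known only as "< bound") rather than
treating bounds as measurements; censored entries are carried through
`readSoilTable()` with an explicit flag.

## The community generator

`simulateAbundance()` draws each sample's relative abundances from a
Dirichlet with concentration exp(base + group effects)/θ and counts
from a multinomial at fixed depth, so sample totals equal the depth
exactly. Defaults:

* **Base profile**: a log-linear ramp spanning about e^6 (~400-fold)
  between the most and least abundant of 200 taxa — a crude but
  serviceable stand-in for the steep rank-abundance curves of soil
  communities.
* **Overdispersion θ = 0.001** (total Dirichlet concentration ≈ 1000),
  giving mid-abundance taxa a between-replicate CV of roughly 50–100%,
  the order observed in replicated soil metagenomes. This is an
  artifact choice: the abundance tables this package consumes carry no
  distributional information of their own.
* **Planted markers** add log2 effects to chosen taxa in chosen groups
  before normalization, giving every downstream differential stage a
  known truth.
* **Depth 10^5** per sample keeps multinomial noise well below the
  Dirichlet component while staying cheap to simulate.

Physiology linkages (`simulatePhysiology()`) are linear in
log10(relative abundance + 1/depth) with Gaussian noise; the
pseudocount 1/depth avoids −∞ at zero counts while preserving the rank
order of nonzero abundances, which is what a rank-correlation stage
consumes.

## Community statistics

* **ACE** uses the Chao–Lee estimator with the conventional
  rare/abundant cutoff of 10. When no rare taxa exist or coverage is
  zero the estimator is undefined; we return the observed richness
  with an explicit fallback flag, because defined behavior beats an
  exception in the middle of a pipeline.
* **Bray–Curtis** distances are computed on total-sum-scaled data
  (the upstream normalization of the consumed tables being unknown,
  relative abundance is the only safe common scale) and delegate to
  vegan's implementation behind the package's interface.
* **PCoA** is classical scaling of the double-centered −D²/2 matrix
  with no Lingoes/Cailliez correction; negative eigenvalues are
  reported separately and excluded from the variance-explained
  denominator, so "PC1 explains x%" always refers to the positive
  part of the spectrum.
* **ANOSIM** uses the standard rank statistic
  R = (r̄_between − r̄_within)/(M/2). The permutation p value follows
  the add-one rule p = (1 + #{R* ≥ R})/(1 + n_perm) and the null is
  enumerated exhaustively whenever the number of distinct labelings is
  at most 10,000. With two equal groups exhaustive labelings come in
  mirror pairs, which makes the exact test conservative by
  construction; calibration checks therefore use unequal group sizes.
* **Correlation screening** is Spearman by default (robust to the
  compositional scale; Pearson by flag). P values use the exact
  permutation null of the rank statistic whenever there are at most 9
  untied shared samples, and the t-approximation otherwise: at the
  replication levels typical of these designs the t-approximation
  overstates far-tail significance severalfold, which would defeat the
  point of adjusting for multiplicity. Benjamini–Hochberg adjustment
  is applied jointly across the whole taxon × indicator grid; raw-p
  stars are also emitted for heatmap-style annotation.
* **Biomarker discovery** re-derives the LEfSe recipe for the
  two-group case: a Kruskal–Wallis screen at α = 0.05, then 30
  bootstrap rounds, each subsampling two thirds of every group and
  fitting a linear discriminant on the surviving per-million
  abundances with a small ridge (10^-6 of the mean within-class
  variance) for singular scatter matrices. A feature's effect is half
  the sum of its raw class-mean difference and its unit-loading share
  of the projected class separation, averaged over rounds,
  log10-transformed with a floor at 1; biomarkers pass at score > 2.
  There is no subclass (within-class Wilcoxon) stage because the
  designs addressed here have none. Numeric parity with the original
  LEfSe implementation is not promised — threshold behavior on strong
  effects is.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: 500 noise-free
transients for parameter recovery (φPo exact, VJ within 2 × 10^-3 of
the generating value), 10 K-band levels for Wk monotonicity, 1000
random count vectors against a direct-formula ACE oracle, 10 random
Euclidean configurations for PCoA reconstruction (errors at machine
precision), 400 null communities for ANOSIM type-I calibration, 100
replicates at n = 6 per group and depth 10^5 for biomarker power at a
planted log2 effect of 3 (power ≥ 0.95), and 200 global-null grids of
50 taxa × 7 indicators for BH calibration. These sizes were chosen so
each Monte-Carlo answer is stable to well within the tolerance being
asserted.

## Known limitations

* The JIP engine does not fit kinetic models, detect L-bands, or
  compute PItotal/φRo; it derives the printed parameter set only.
* The abundance stages act on one taxonomic rank at a time; multi-rank
  cladogram aggregation is out of scope.
* The generators produce downstream-of-pipeline tables; read-level
  artifacts (classification error, contamination, uneven depth) are
  not modelled, so passing tests say nothing about upstream
  bioinformatics.
* ANOSIM and the biomarker stage require seeds; identical seeds give
  identical results, and all stochastic functions log their seed.
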