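---
title: "Methods: drug sensitivity and synergy scoring for ascites-conditioned screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug sensitivity and synergy scoring for ascites-conditioned screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aafscreen)
```

## Scope and study design

`aafscreen` analyses high-throughput viability screens of epithelial ovarian
cancer (EOC) cell lines cultured either in plain media or in a 1:1 dilution
of patient-derived acellular ascites fluid (AAF), a stimulation known to
induce chemoresistance. The emulated design is 5 cell lines x (media + 5
AAFs) = 30 conditions, a panel of 11 drugs (carboplatin and paclitaxel as
standard of care plus 9 repurposed compounds), 6-8-point half-log
titrations spanning roughly 1 µM-10 mM, anchored combinations in which a
priming drug is fixed at its average IC20 while the partner is titrated
(shifted one decade down to accommodate the stronger combined effect), and
3 technical x 2 biological replicates. Raw patient screens are not
publicly available, so every stage of the pipeline is driven and validated
by a synthetic-screen generator with known ground truth.

## The dose-response model

Viability follows the four-parameter log-logistic (LL4) curve

$$V(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}},$$

with slope $b > 0$, lower asymptote $c$ (% viability at saturating dose,
fixed at 0 by default — the convention under which screens are normalized
so that a full kill reads 0%), upper asymptote $d$ and midpoint
concentration $e$ (molar). Fitting is bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`) with starts $d_0 = \max V$, $e_0$ at the dose nearest
$d_0/2$, $b_0 = 1$, and five log-jittered restarts before a fit is flagged
non-converged (no exception is thrown; downstream scores refuse
non-converged fits unless forced). A single outlier pass drops points with
absolute studentized residual above 3 (at most 20% of points) and refits
once; if removal would leave fewer than four distinct doses, all points are
kept and flagged.

ICp values invert the fitted curve in closed form. The default convention
is *absolute* inhibition on the normalized scale (IC50 = the dose of 50%
viability), which keeps IC20 well defined for full-efficacy drugs and
matches the zero lower boundary; a relative-to-asymptote mode is available
behind a flag. An ICp whose target viability lies outside $(c, d)$ is an
error rather than an extrapolation.

### Generator truth: efficacy parameterization

The generator's true curves are parameterized by drug *efficacy*: its `d`
is the maximal percent inhibition, so expected viability is
$100 - d/(1 + (e/x)^b)$ — untreated cells are always fully viable, and an
AAF-induced `efficacy_loss` subtracts from `d`, *raising the high-dose
viability floor*. This reproduces the characteristic resistance pattern in
which cells retain substantial viability even at the highest drug doses;
a multiplicative `resistance_shift` on `e` models potency loss. The
analysis side still fits viability curves with the lower asymptote fixed at
zero, exactly as the screens are analysed in practice; for a strongly
resistant condition that mis-specification compresses the fitted inhibition
and lowers the DSS, which is the scientifically intended direction. The
magnitudes of AAF shifts are free generator parameters (the source screens
do not constrain them); defaults are a log-uniform midpoint shift in
[1, 4] and an efficacy loss uniform in [0, 20] points, with a convenience
override (`set_condition_resistance`) to engineer a fully resistant
condition (10x shift, 50-point loss) for end-to-end checks.

Raw signal is modelled as `rfu = plate_gain x viability_fraction x
exp(N(0, sigma))` with `sigma = sqrt(log(1 + CV^2))` — multiplicative
log-normal noise, appropriate for scale-dependent plate-reader
luminescence; the default CV is 5%. Plate gain is drawn once per plate,
uniform in [0.8, 1.2] x nominal, to exercise per-plate normalization.
Biological replicates perturb the true midpoint by an independent 5%-CV
log-normal factor (passage effects); technical replicates share the truth.
What the generator does **not** emulate: growth kinetics, spatial/edge
effects, cytokine concentrations, dose-dependent interaction, or
heavy-tailed measurement artefacts. Passing tests therefore demonstrate
correctness of the scoring pipeline under its stated noise model, not
robustness to every failure mode of real plates.

## Plate QC and normalization

Plate quality uses the standard screening-window coefficient
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|$ with a
pass cutoff of 0.5 (standard HTS practice; the underlying studies report
QC without stating a numeric cutoff). Two normalization modes are
provided, selected per experiment:

* **control-based** (sensitivity screens): per plate,
  `100 (rfu - mu_pos) / (mu_neg - mu_pos)` — affine, hence invariant to
  plate gain;
* **vehicle-based** (concentration-response experiments): the zero-dose
  reference is built from the DMSO gradient wells. The source description
  of this reference admits two readings; the default averages the mean
  high-DMSO and mean low-DMSO signal (`mean_of_means`), with the pooled
  grand mean selectable. Water-solvent drugs carry no vehicle gradient and
  use a unit reference ratio (100% viability at zero dose).

Viability is *not* clipped by default — values above 100% or below 0%
carry information for fitting, whose bounds are imposed by the model; an
optional guard clips to [0, 150] and flags gross outliers.

## Drug sensitivity score

DSS summarizes a fitted curve as the normalized area of percent inhibition
$I(x) = 100 - V(x)$ above an activity threshold $t$ (default 10%),
integrated over the tested log10-molar window $[x_{min}, x_{max}]$. The
integral uses the closed-form antiderivative of the log-logistic (tested
against a dense trapezoid oracle), with the region boundary at the
closed-form $t$-crossing. Variants: (1) area fraction of the maximal box
$100A/((100-t)(x_{max}-x_{min}))$; (2) variant 1 divided by
$\log_{10} R_{max}$ with $R_{max}$ the maximal fitted inhibition in the
window, discounting shallow curves; (3) variant 2 scaled by the responsive
fraction of the window. The default is variant 2 — the common convention
of the DSS family; the source analysis does not state which variant it
used, so all three are implemented and the choice is configurable. Scores
are clamped to [0, 100] and are exactly 0 when maximal fitted inhibition
does not exceed $t$.

## Combination scoring

**Combination Ratio.** `CR = (DSS_combo + 100) / (DSS_mono + 100)`; the
augmentation by 100 keeps the ratio finite and defined when either score is
0, and bounds CR in [0.5, 2]. The comparator is the priming
standard-of-care drug's monotherapy DSS in the same condition. CR > 1
means the combination improves on the monotherapy; CR < 0.75 (strict) is
flagged as non-improvement.

**ZIP delta.** On the inhibition-fraction scale the zero-interaction
expectation is the Bliss form $y_1 + y_2 - y_1 y_2$ built from fitted
monotherapy marginals. The observed surface comes from directional
logistic refits — at each fixed dose of one drug, the response along the
other is refit as a logistic rising from a free baseline to full
inhibition; the two directions are averaged in factorial designs, while the
anchored design (one priming dose) uses its single direction with the
priming drug's marginal taken from the monotherapy fit. The per-pair delta
is `(observed - y_zip) x 100`, defined only where both doses are positive;
the summary is the *mean* delta (whether the source screens summarized ZIP
by mean or maximum is unstated; the mean is implemented). The baseline of
each directional refit is left free rather than pinned to the marginal so
that a constant interaction offset is absorbed by the baseline instead of
distorting the potency parameters; saturated directions where the logistic
is unidentifiable fall back to the observed response and are recorded.
Synergy is called above the empirical 95th percentile (type-7 quantile,
linear interpolation — stated because the threshold depends on the
convention) of all ZIP summaries sharing a standard-of-care backbone;
populations below 20 summaries are flagged unstable.

**100-VUS.** The dose-pair viability surface is integrated by the iterated
trapezoid rule along the two log10-dose axes and normalized by the
enclosing cube (100 x the product of axis spans); the complement 100-VUS
reads as efficacy (0 = fully viable surface, 100 = complete kill). Zero
doses have no logarithm: zero-dose rows/columns anchor the marginals but
integration runs over positive doses only. Anchored grids are scored by
the 1D area analogue along the titrated drug.

**Ranking.** Treatments are ranked per condition by CR (combinations) or
DSS (monotherapies), descending, with deterministic tie-breaks: higher
DSS, then fewer drugs, then lexicographic label. The rank-1 entry is the
nominated best treatment for that condition.

## Downstream statistics

Standard inference is delegated to base R and established packages, behind
the pipeline's interfaces: two-way ANOVA on DSS with cell line and
condition as factors (additive model with type-II sums of squares via
`car::Anova` — the screen yields one DSS per condition per drug, so
interaction replicates are usually absent; a full-interaction option exists
for replicated tables), Tukey HSD over all pairwise condition contrasts
(`TukeyHSD`), Pearson correlation matrices of phospho-marker fold changes
with two-sided p-values Holm-corrected over all unique pairs
(`cor.test`, `p.adjust`), and Ward-D2 hierarchical clustering on Euclidean
distances (`hclust`) with Newick export through `ape`. Phospho-marker
tables are normalized per sample to the IgG control; the exact transform
behind such heatmaps is not formula-level specified in the field, so the
default log2 ratio is complemented by an arcsinh alternative (cofactor 5)
— both standard for median-fluorescence data.

## Numerical choices and degenerate inputs

* Dose grids must be strictly positive and increasing; zero doses are
  segregated as marginals, never log-transformed.
* Flat (non-responding) curves converge with a near-zero effect and are
  flagged `nonresponder`; their DSS is 0 by the threshold rule.
* `Z'` requires at least two wells per control group and distinct means;
  degenerate plates are errors, not silent NAs.
* Marker correlation targets are zero-completed into a full matrix that
  must be positive semi-definite; infeasible target sets fail before any
  sampling. Tables with fewer than 10 stimulations carry an explicit
  "correlation recovery unreliable" flag.
* All generation is seed-deterministic; the RNG state is restored after
  each generator call so package functions do not perturb a session's
  random stream.

## Validation scale

The test suite validates each stage against independent oracles (dense
trapezoid integration for DSS, brute-force step-down for Holm, exhaustive
Ward-D2 agglomeration for clustering, root finding for ICp) and runs
simulation checks at the following sizes, chosen to give stable Monte
Carlo estimates at desk scale: 1000 random curve draws for the closed-form
DSS check, 200 seeds for midpoint recovery (8 doses x 6 replicates, 5%
CV), 500 noiseless Bliss grids plus 200 noisy seeds for ZIP calibration
and sign recovery, 500 null simulations for ANOVA calibration, and 30
full-screen replicates (30 conditions x 11 drugs each) for the end-to-end
resistance-ranking check.

## Known limitations

* The anchored ZIP uses one directional refit by necessity; its deltas are
  noisier than factorial ones and inherit any bias of the priming drug's
  monotherapy fit.
* A constant (dose-independent) injected interaction is the only
  ground-truth interaction the generator supports; clipping of the
  inhibition fraction to [0, 1] attenuates injected interactions near
  saturation, so synergy recovery is assessed on sub-saturating surfaces.
* DSS variant 2 is undefined for maximal inhibition at or below 1% and is
  set to 0 there.
* With the lower asymptote fixed at zero, midpoint estimates are biased
  upward when the true viability floor is materially above zero; the
  parameter-recovery analysis therefore frees the asymptote. The fixed-zero
  convention is retained for scoring because DSS integrates the fitted
  curve only over the tested window, where the two fits nearly coincide.
* No spatial/edge-effect correction and no Loewe/HSA models are provided.
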