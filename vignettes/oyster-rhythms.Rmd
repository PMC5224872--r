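---
title: "Validating behavioral rhythms and clock-gene co-expression in oysters"
author: "oysterClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating behavioral rhythms and clock-gene co-expression in oysters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oysterClock)
```

## The problem

Bivalves such as the Pacific oyster *Crassostrea gigas* express daily
behavioral rhythms that can be read non-invasively from valve gaping: the
percentage of each hour an animal spends with its valves open. Under an
imposed light:dark (L:D) cycle the behavior is entrained by light (a
*zeitgeber*); under constant darkness (D:D) any persisting rhythm is
free-running and reveals the endogenous clock, often with a period that
deviates from 24 h and with additional ultradian (< 20 h) components.
Establishing that such a rhythm is real — and not an artifact of noise in a
short, noisy record — requires a statistical validation chain, not a single
test. This package implements that chain, together with the molecular
analyses that typically accompany it (comparative-Ct qPCR quantification and
correlation-based grouping of clock-gene expression) and small sequence
utilities (ORF accounting, E-box promoter scanning).

## The rhythm-validation chain

A series enters the chain only if it carries at least 48 samples. The stages
are:

1. **Quality gate.** The autocorrelation function (ACF) up to lag 72 is
   compared against the white-noise 95% band $\pm 1.96/\sqrt{n}$. The series
   is *non-random* when at least 5% of lags exceed the band and the maximum
   $|\mathrm{ACF}|$ beyond lag 3 exceeds twice the band. The partial
   autocorrelation function is computed and reported as a diagnostic but
   does not gate: the combined ACF rule is our operationalization of
   "absence of randomness", and its thresholds are configurable. Zero
   variance fails the gate outright.

2. **Spectral detection.** A Lomb–Scargle periodogram is computed over a
   period grid (default 2–36 h in 0.1 h steps, which represents 24.0, 20.6
   and 12.5 h exactly). We use the classic variance-normalized form with the
   time-offset $\tau_0$ that makes the estimator invariant to time-origin
   shifts. The significance ("noise limit") threshold converts a familywise
   false-alarm probability $\alpha = 0.05$ into a power level through the
   exponential null distribution with the independent-frequency
   approximation $M = n$:
   $z^* = -\log\!\left(1 - (1-\alpha)^{1/M}\right)$.
   Since the default grid spans fewer than $n$ independent frequencies, the
   threshold is mildly conservative; measured on white noise the familywise
   false-alarm rate stays below 10% (and in practice below 5%). Significant
   periods are grid local maxima above the threshold, strongest first.

3. **Cosinor modelling.** At the strongest significant period $\tau$ the
   model $Y(t) = A\cos(2\pi t/\tau + \phi) + M + \epsilon(t)$ is linearized
   onto $\cos(2\pi t/\tau)$ and $\sin(2\pi t/\tau)$ with an intercept and
   fitted by ordinary least squares; $A = \sqrt{\beta^2+\gamma^2}$,
   $\phi = \operatorname{atan2}(-\gamma, \beta)$, and the percent rhythm is
   $\mathrm{PR} = 100\,(1 - SS_{resid}/SS_{total})$. Two tests validate the
   fit: the zero-amplitude F-test ($H_0: \beta=\gamma=0$, $F(2, n-3)$) must
   give $p < 0.05$, and the joint 95% confidence ellipse of
   $(\beta, \gamma)$ must exclude the origin. For a linear model these are
   the same hypothesis tested through the same covariance, so the two
   criteria agree case by case — the package asserts this rather than
   assuming it, because the agreement is a useful integrity check on both
   code paths.

4. **Period confidence interval.** The interval for $\tau$ is obtained by
   profiling the residual sum of squares over a grid around the estimate
   (half-width 3 h, step 0.02 h) and retaining the contiguous region where
   $SSE(\tau') \le SSE_{min}\,(1 + F_{0.95}(1, n-4)/(n-4))$, with $n-4$
   degrees of freedom because mesor, two linear coefficients and the period
   itself are estimated. The exact computation used by legacy chronobiology
   software is not published, so this profile-likelihood interval is our
   documented stand-in; simulations show it covers the generating period in
   well over 90% of runs at moderate noise and shrinks to zero width as
   noise vanishes.

5. **Residual reinjection.** When a component is accepted, its residuals
   (plus the mesor, so the series keeps its level) re-enter the spectral
   stage, and the loop repeats until no significant period remains, a fit
   fails validation, or `maxComponents` (default 3) components have been
   accepted. Many significant periodicities can exist in valve records; the
   cap is a pragmatic bound, not a biological claim. The quality gate runs
   once, on the raw series — it is a data-quality check, not a model test.

6. **Classification and population summary.** The primary (first validated)
   period classifies the series: ultradian below 20 h, circadian from 20 to
   28 h inclusive on both ends (the boundary convention is ours; published
   bin definitions are ambiguous at exactly 20 h), infradian above 28 h.
   `populationSummary()` validates the per-timestamp mean series of a panel
   (population-level analysis uses the mean series rather than pooled
   individuals — a deliberate choice where published methods are silent) and
   every individual, reporting the percentage rhythmic and the percentage
   circadian among the rhythmic.

Double-plotted actograms binarize each time bin against its own day's 24-h
mean (strictly above = black; ties white, which makes the grid invariant to
adding a constant) and concatenate consecutive day pairs per row.

## What the synthetic generators emulate

No machine-readable valve recordings or Ct tables are distributed with the
studies this package is aimed at, so the generators create data with the
statistical structure the analysis stages assume, at the published design
sizes.

**Valve panels.** `ldPreset()` emulates 15 oysters recorded hourly for 15
days under L:D 10:14: a single 24.0 h component peaking at hour 9 (end of
the photophase), and 1/15 individuals arrhythmic. `ddPreset()` emulates the
subsequent 15 days of D:D: a 20.6 h circadian component plus a 12.5 h
ultradian component, more noise, and 3/15 individuals arrhythmic. The
*periods* and design sizes are the published values; amplitudes (15% and
12/8% around a 50% mesor), noise SDs (10 and 12%) and the arrhythmic
fractions are the package's calibrated choices — no amplitude, mesor or
noise figures are published for this behavior — selected once so that the
L:D design yields at least the published ~93% individual detection rate
while leaving the D:D design visibly degraded, and documented here as
tuning. Noise is i.i.d. Gaussian then clipped to [0, 100], the simplest
model compatible with an additive error term; arrhythmic individuals are
pure noise around the mesor, with no weak residual rhythm. Acrophases follow
the convention $t_{peak} = -\phi\,\tau/(2\pi) \bmod \tau$.

**Ct matrices.** Expression is generated in Ct space (not in relative
quantities) so the comparative-Ct stage is exercised end to end. Ten target
genes form two groups of six and four; each gene in group $G$ follows
$Ct_{g,s} = b_g - g_{Ct} L_G(t_s) - u_{G,s} + \varepsilon_{g,s}$ with a 24 h
cosine latent, a per-sample group-level random effect $u$, and measurement
noise (SD 0.65 Ct). The random-effect SD is solved from a variance
decomposition so the expected within-group Pearson correlation of $-\Delta
Ct$ equals `withinGroupRho` (default 0.70, chosen to center the realized
within-group Spearman span inside the published 0.4–0.944 band). Group
acrophases sit 12 h apart, consistent with the negative cross-group
correlations reported under D:D, which makes the two blocks separable by a
positive-correlation rule. The design is 8 timepoints 3 h apart × 9 animals
= 72 samples per regime, and the reference gene (`EF1`) is flat with SD
0.08 Ct.

**Promoters.** Uniform-background sequences (GC fraction 0.35, roughly the
AT-rich promoter neighborhoods of this genome) of 2 kb upstream of a TSS
plus a 50 bp downstream stub, with `CACGTG` written at requested negative
offsets. Offsets name the motif's 5′-most base, with TSS = +1 and no
position 0. Chance background occurrences are allowed and reported as
collisions; `excludeMotif = TRUE` scrubs them for negative controls.

What passing tests on these data do **not** show: real valve records have
non-Gaussian, autocorrelated noise, transients at regime changes, and
missing stretches; real expression has per-animal (not per-sample) random
effects and amplification-efficiency variation. The generators validate the
machinery, not the biology.

## Expression analytics

`relativeQuantity()` implements $2^{-\Delta\Delta Ct}$:
$\Delta Ct_{g,s} = Ct_{g,s} - Ct_{ref,s}$, then
$\Delta\Delta Ct_{g,s} = \Delta Ct_{g,s} - \overline{\Delta Ct_g}$ over the
calibrator samples, then $RQ = E^{-\Delta\Delta Ct}$ with efficiency
$E = 2$ by default (an optional per-assay efficiency generalizes the form).
The calibrator baseline "all samples" is ambiguous between per-regime and
global means; the default is the per-regime mean (so each regime's geometric
mean RQ is 1 per gene), switchable via `calibrator`. Reference-gene
stability is screened with a transparent minimal score — SD of Ct plus mean
pairwise $\Delta Ct$ SD, lower is stabler — rather than a geNorm-style
iterative scheme. Per-timepoint comparisons screen normality (Shapiro–Wilk
on centred residuals) and homoscedasticity (Levene) at 0.05 and then run
one-way ANOVA or Kruskal–Wallis, with Holm–Šidák-adjusted pairwise
comparisons. `spearmanMatrix()` computes pairwise Spearman $\rho$ and
p-values per regime (exact for small tie-free n), and
`correlationGroups()` takes connected components of the graph with edges
where $\rho > 0$, $\rho \ge$ 0.25 and $p < 0.05$; the 0.25 floor sits just
below the weakest within-group coefficients such screens retain, and is
configurable.

## Sequence conventions

`findLongestOrf()` scans the three forward frames of oriented cDNA (RACE
products have known orientation; genomic both-strand scans are out of
scope), breaking ties by the smallest start. Coordinates are 1-based and
inclusive, R's native convention. `codonCount()` reports frame length / 3 —
the stop-inclusive "encoded amino acids" convention in which a 3945 bp frame
encodes 1315 — while `translateOrf()` returns the biological protein (stop
excluded, length `codonCount - 1`, `N`-containing codons as `X`); reporting
both avoids the off-by-one ambiguity between the two conventions. The E-box
`CACGTG` is its own reverse complement, so single-strand scanning of the
2 kb upstream window is strand-complete for it — a property the test suite
verifies on random fixtures rather than assumes.

## Numerical choices and degenerate inputs

- Period grid 2–36 h at 0.1 h: bounded by twice the hourly sampling interval
  and by the 15-day record length; the key periods are exact grid points.
- Zero-variance series: fail the quality gate; the periodogram refuses them.
- Cosinor at $\tau \ge$ the observation span errors (regressors collinear);
  fitting with under two full cycles warns.
- Actogram ties (value equal to the daily mean) are white.
- Trailing partial days are padded as missing and flagged.
- Arrhythmic declarations carry the failing stage as a reason string instead
  of raising errors, so population summaries never abort on one bad animal.
- All generators consume an explicit integer seed; identical configurations
  are bit-identical.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
panels of 15 × 360 hourly samples, Ct designs of 11 genes × 72 samples,
promoter sets of ≤ 2.1 kb. Monte-Carlo calibration checks use 100–1000
replicates (test size, false-alarm rate, coverage), and recovery checks use
20 seeds; these sizes give binomial standard errors comfortably inside the
asserted bands.

## A worked example

```{r example, eval = FALSE}
panel <- generateValvePanel(ddPreset(seed = 1))
report <- validateRhythm(meanSeries(panel))
report
#> RhythmReport 'population-mean': rhythmic (circadian), periods 20.6, 12.5 h

summary <- populationSummary(generateValvePanel(ldPreset(seed = 1)))
pctRhythmic(summary)
#> [1] 93.33333
```

## Known limitations

- The Halberg-style period CI is a profile-likelihood stand-in for an
  unpublished legacy computation; absolute interval widths should not be
  compared against outputs of that software.
- The independent-frequency approximation $M = n$ makes the spectral
  threshold conservative on oversampled grids.
- No tidal-entrainment generator and no simulation of the molecular
  feedback-loop dynamics are provided.
- Reference-gene stability scoring is a screen, not a replacement for
  geNorm/NormFinder-class methods.
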