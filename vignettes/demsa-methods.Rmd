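---
title: "Niche-segmentation analysis of EcoPlate profiles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche-segmentation analysis of EcoPlate profiles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demsa)
```

## The data and its preparation

A Biolog EcoPlate assays one soil suspension (here diluted to 10^-4 and
incubated to the colour-development plateau, about five days) against 31
carbon substrates plus a water blank, each in three 32-well blocks, read
as optical density (OD) at 590 nm. `demsa` treats each field replicate as
one 31-element substrate profile:

* **Blank correction.** The plate's three blocks each carry their own
  water well. Every substrate well is corrected by subtracting the water
  OD *of its own block*; negative corrected values are clipped to 0 (OD
  below blank carries no usable signal), and the three block values are
  averaged. Clipping before averaging keeps the operation idempotent and
  the output non-negative.
* **Plateau selection.** One timepoint per sample enters the analysis.
  The default policy takes the last reading (the protocol incubates until
  no further increase is observed); `max_awcd` picks the timepoint with
  the highest mean corrected response, and `fixed:T` the reading nearest
  to `T` hours, with equidistant ties resolved toward the *later* reading
  (closer to plateau) and a warning when the nearest reading is more than
  12 h away.

Substrates (functional groups) belong to five chemical guilds:
carbohydrates (CH, 10), carboxylic and acetic acids (CX, 9), amino acids
(AA, 6), polymers (P, 4) and amines/amides (AM, 2).

## The niche-segmentation model

The control treatment's replicates define, per substrate `s`, the native
niche range: lower limit `l_s` (replicate minimum), center `c_s`
(replicate mean) and upper limit `u_s` (replicate maximum). Min/max
limits, rather than mean ± sd, are used deliberately: with the small
replicate numbers typical of field CLPP (3–4), the observed extremes are
the honest description of the control's variation range, and they make
the control's own decomposition exactly consistent (no control replicate
can "expand" its own range).

For an observed response `x_s`, the deviation from the center is split at
the limits into four non-negative segments:

| condition | inside the niche | beyond the niche |
|---|---|---|
| `x_s >= c_s` | intensification `min(x_s, u_s) - c_s` | expansion `max(0, x_s - u_s)` |
| `x_s < c_s` | narrowing `c_s - max(x_s, l_s)` | contraction `max(0, l_s - x_s)` |

Two identities pin the decomposition down and are enforced by tests:
`int + exp - nar - con = x_s - c_s` exactly, and at most one side
(increase or decrease) is non-zero per substrate. Expansion implies the
within-range gain is saturated (`int = u_s - c_s`), contraction that the
within-range loss is (`nar = c_s - l_s`).

Some analyses call the within-range loss a *restriction*; the package
uses one name throughout: **narrowing**.

### Synthetic indices, associations and community comparison

* **Segment indices.** `I_seg = 100 * (sum_s seg_s) / S`, where `S` is the
  *sample's own* total activity. This denominator reproduces the
  published index rows from the published guild sums and treatment totals
  to about one percent (limited by the two-decimal rounding of the
  printed inputs); a control-total denominator does not. Indices
  are computed per replicate and then averaged (mean ± s.e.), not
  computed on treatment means.
* **Functional alteration.** `FA = 100 * (S - S_c) / S_c` with `S_c` the
  control mean total activity — a signed percent oversizing/reduction of
  the whole functional community.
* **Guild association.** Per treatment and segment, the five guild-level
  means are ranked and the top two reported (e.g. `CH–CX`). Ties at full
  precision are broken by the guild's total over all four segments, then
  alphabetically; any pair whose members are indistinguishable at the
  reporting precision (two decimals by default) carries a tie flag rather
  than a silently arbitrary order.
* **Dominance–codominance.** The same ranking applied to the 31
  per-substrate treatment means of a segment, naming the dominant and
  codominant functional groups. Substrates with zero mean never enter the
  pair; a fully inactive segment yields an empty, flagged pair.
* **Within-community resemblance.** Czekanowski percentage similarity
  `PS(a, b) = 200 * sum_s min(a_s, b_s) / (sum_s a_s + sum_s b_s)` over
  all replicate pairs of a treatment; each replicate is summarised by the
  mean of its pairs, the treatment by mean ± s.e. over replicates.
* **Between-community resemblance.** For replicate `r` of treatment `t`,
  coverage in treatment `u` is `100 * sum_s min(x_rs, m_us) / sum_s x_rs`
  against `u`'s mean profile `m_u` — a directional "how much of `r` is
  present in `u`". The replicate's value averages over all other
  treatments; whether the control counts among them was a genuinely open
  choice, resolved as *include it* (the least-assuming reading of
  community sharing across the experiment), with
  `include_control = FALSE` available.
* **Common microbiome.** The shared-with-control profile
  `min(x_s, c_s)`, whose sample matrix is the input of the
  common-microbiome PCA.

The within/between formulas are reconstructions of the community-sharing
idea validated against the published qualitative ordering (they cannot be
verified numerically without raw plate data); they are isolated behind
their own functions so alternatives can be swapped in.

## Conventional statistics

* **ANOVA.** Classical one-way fixed-effects decomposition via
  `stats::lm`. Degenerate inputs follow a fixed convention: all values
  identical gives `F = 0, p = 1`; zero within-group variance with
  distinct means gives `F = Inf, p = 0`.
* **LSD letters.** Unprotected least-significant-difference tests on the
  pooled mean square (`alpha = 0.05`, two-sided), with the
  insert-and-absorb compact-letter algorithm on groups ordered by
  descending mean, so two groups share a letter exactly when their
  pairwise test is non-significant. Unprotected is the field's common
  default; `protect = TRUE` gates the display on the omnibus F test.
* **PCA.** Centered singular-value decomposition, unscaled by default
  (all variables are ODs in commensurable units); unit-variance scaling
  is available. Constant columns — routine in segment matrices, where
  many substrates are inactive — are dropped. Axis signs follow a
  deterministic convention (largest-magnitude loading positive) so
  repeated runs are byte-identical.
* **Diversity.** Shannon `H = -sum p_s log p_s` in nats (maximum
  `log 31 ≈ 3.43`) and Gini–Simpson `D = 1 - sum p_s^2`, with
  `0·log 0 := 0`. Both are invariant to rescaling the profile.

One bookkeeping note: the package defines total activity as
`S = sum` over the 31 blank-corrected substrate responses and
`AWCD = S/31` exactly. Published Sum/AWCD pairs do not always satisfy
that ratio (their divisor is not stated); the package does not attempt to
reverse-engineer an alternative divisor.

## The synthetic generator

`simulation_config()` + `generate_experiment()` emulate a five-treatment,
four-replicate fertilization trial at the plateau timepoint:

* per-substrate control means `mu_s ~ Uniform(0.3, 2.5)` OD, giving
  control totals near 40–50 OD — the magnitude of field EcoPlate profiles;
* replicate noise `sigma_s = 0.1 * mu_s`, truncated-normal (clipped at 0):
  simple, and it respects the OD floor; with these defaults clipping is
  a < 3-sigma event and practically never binds;
* guild-level effect multipliers `kappa[t, g] > 0` on the mean. The
  defaults encode the directions observed in long-term grassland
  fertilization — organic input (V2) inflating carbohydrate/polymer use
  (about +18% total activity), mineral input (V4) deflating it (about
  -10%), organo-mineral treatments intermediate — and were fixed once on
  that basis.

The generator reproduces the *structure* the model expects (guild-level
mean shifts, independent truncated-normal replicate noise); it does not
emulate kinetic colour development, substrate correlations within a
sample, plate-position effects or reader drift. Tests passing on this
generator therefore demonstrate correct recovery of guild-structured mean
effects under honest replicate noise — not robustness to correlated or
heteroscedastic field data.

## Validation strategy and problem sizes

The test suite checks every formula against independent routes: the
decomposition against an interval-measure oracle, ANOVA against the hand
sums-of-squares table and `stats::aov`, LSD letters against a
first-principles pairwise-test oracle (the share-a-letter-iff-
non-significant property), PCA variance against covariance eigenvalues,
and diversity against `vegan::diversity`. Property checks run on 10^4
random substrate/range draws for the decomposition identity, 100 random
4-group instances for the letters, and 200 seeded generator runs each for
parameter recovery (a 1.5× guild effect must lead the expansion
association in at least 95% of runs) and for the neutral-model
calibration (mean functional alteration within 3 s.e. of zero). These
sizes give the property checks high power while keeping the full suite in
the tens of seconds.

## Limitations

* The niche range inherits the coarseness of few control replicates; with
  2–3 controls the min/max limits are noisy and expansion/contraction are
  conservative.
* Indices are ratios of sums; treatment-mean reconstructions (ratio of
  means) differ from replicate-averaged indices (mean of ratios) by a
  Jensen gap of order 1% at field noise levels.
* The between/within resemblance measures are one defensible formalisation
  of community sharing among several; they are versioned behind their own
  functions precisely so alternatives can be compared.
* No kinetic modelling: analyses condition on a single plateau timepoint.
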