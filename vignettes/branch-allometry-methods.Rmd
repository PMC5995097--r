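---
title: "Methods: branch-level allometry, SMA estimation and process-based predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-level allometry, SMA estimation and process-based predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchallom)
```

## The scientific problem

A woody plant's architecture is summarised by power-law allometries
$y = b\,x^a$ between pairs of branch dimensions — length $L$, basal
diameter $D$, surface area $SA$, volume $V$, dry mass $M$. In log10–log10
space $a$ is a slope and $\log_{10} b$ an intercept. Two process-based
theories predict $a$. The WBE fractal branching model fixes the interplay
of hydraulics and biomechanics and yields point predictions, most
prominently $M \propto D^{8/3}$ (from area-preserving branching,
$M \propto D^2 L$, combined with elastically similar lengths
$L \propto D^{2/3}$). The Flow Similarity (FS) model instead
parameterises the length–diameter exponent $\alpha_F$ and lets it range
between a hydraulic endpoint ($\alpha_F = 2$, constant flow rate and
velocity through area-preserving branching) and a biomechanical endpoint
($\alpha_F = 2/3$, every branch at its elastic buckling limit). All six
pairwise exponents among $L, D, SA, V$ follow from $\alpha_F$ through
cylinder geometry; `prediction_table()` emits them as exact fractions.

This package implements the complete comparison for per-branch
measurement tables of orchard trees: ingest, morphology, estimation,
classification against theory — validated throughout on synthetic trees
with known exponents.

## Branch classifications

Field measurements are *segment*-level: each row of the table is one
branch between two branching nodes. Theory, however, speaks about
networks, so the package re-aggregates segments at two further
classifications before fitting:

* **path** — a branch plus the longest continuous chain of distal
  branches. At each node the child with the greatest *path length* is
  followed; length, mass, surface area and volume are summed along that
  chain. Length alone defines the chain (the classification is "longest
  continuous length"); the other quantities are then summed along it.
* **subtree** — a branch plus *all* distal branches, summed in a single
  post-order traversal.

Diameter is never aggregated: at every classification it is the branch's
own basal diameter. Terminal branches have segment = path = subtree, and
for every branch and additive quantity subtree ≥ path ≥ segment; the root
subtree mass equals the sum of all segment masses (tested to 1e-9
relative).

Two details the field definition leaves open were fixed for determinism:
path ties go to the larger-diameter child, then to the lexicographically
smallest branch id; and whether "path mass" should sum the whole
length-maximal chain (as here) or only part of it is a genuine ambiguity —
the chain-sum convention is used because the chain is what the
classification defines, and the alternative is one aggregation rule away.
Missing mass propagates (`NA`, never zero-filled), so a mass fit silently
restricts to branches whose whole aggregate was weighed; twigs (stems
under 2 cm supporting only buds/spurs) are excluded from all aggregates by
default because the main branch-level analysis excludes them, with
`include_twigs = TRUE` as the escape hatch. Twig status itself is taken
from an indicator column when the schema maps one — it is partly
observational and deliberately not inferred from geometry alone.

Canonical units are cm (diameter, length) and g (mass); source tables in
other units declare multiplicative conversions in `branch_schema()`. The
ingest accepts tables that do or do not include the trunk as a record —
whichever convention the data uses, exactly one row per tree must have an
empty parent id.

## SMA estimation

Exponents are estimated by standardized (reduced) major axis regression,
the line-fitting method appropriate when both variables carry error. With
$u = \log_{10} x$, $v = \log_{10} y$:

$$\hat a = \mathrm{sign}(r)\,\frac{s_v}{s_u}, \qquad
  \hat b = \bar v - \hat a\,\bar u, \qquad r^2 = \mathrm{cor}(u,v)^2.$$

The 95% CI uses the standard analytic construction,
$Q = F_{0.95}(1, n-2)\,(1-r^2)/(n-2)$ and
$\hat a\,(\sqrt{Q+1} \mp \sqrt{Q})$, mirrored for negative slopes (which
are first-class: segment-level length–diameter allometries of heavily
pruned trees can be negative). Whether the original analyses used this
analytic formula or a resampling interval is not generally stated in the
literature; the analytic formula is implemented and the choice documented
here. The intercept CI re-evaluates $\hat b$ at the slope CI endpoints —
an approximation (it ignores the variation of the means) flagged in the
docs. Log base 10 is used throughout: published allometry tables report
intercepts on that scale. Pairs with missing or non-positive values are
dropped per fit with counts kept in `n_dropped`; fits need $n \ge 3$,
non-degenerate variance and nonzero correlation, and anything else
becomes an explicit failure row in `fit_grid()` output rather than a
silent omission.

Linearity on the log–log scale is checked by comparing degree-1 and
degree-2 OLS fits via AICc, $AIC + 2k(k+1)/(n-k-1)$ with $k$ counting
coefficients plus the residual variance; ties within 1e-9 prefer the
simpler model. Empirical CIs are compared to theory with closed
intervals — published CI endpoints are rounded, so boundary contact counts
as overlap — and no multiplicity correction is applied, matching how raw
95% CI overlap is conventionally interpreted in this literature (noted in
the report manifest).

The `tendency()` convention: across the ordered classifications
(segment → path → subtree) the shift is `toward_flow` when the distance to
the flow endpoint is non-increasing with at least one strict decrease,
symmetrically `toward_elastic`, otherwise `mixed` (constant sequences are
`mixed`: no movement is not evidence of direction).

WBE values: $M \sim D^{8/3}$ is the model's canonical prediction; the
$L \sim D^{2/3}$ and $L \sim M^{1/4}$ points are the standard derivation's
companions and are marked `reconstructed` in the prediction table, since
unlike 8/3 they are carried here on the derivation's authority rather than
a tabulated source. All predictions are exact integer rationals
internally, converted to doubles only at comparison time.

## The synthetic-data generator

`generate_tree()` grows a full $n$-ary tree of $\ell$ levels with
per-level scaling $D_i = D_0\beta^i$, $L_i = L_0\gamma^i$, which makes the
segment-level length–diameter exponent exactly
$a = \ln\gamma/\ln\beta$ — the generator's key property: every estimate
can be checked against a closed form. `wbe_geometry()` presets
$\beta = n^{-1/2}$ (area-preserving) and $\gamma = n^{-1/3}$ (elastic
similarity), under which segment mass scales exactly as $D^{8/3}$.

Defaults and why:

* `n_children = 2`, `levels = 6–8`: bifurcation is the canonical branching
  model; 8 levels give 255 branches, comparable to the few-hundred-branch
  tables of real orchard individuals.
* `root_diameter = 10` cm, `root_length = 100` cm, `wood_density = 0.6`
  g/cm³: typical trunk dimensions and dry wood density for temperate
  fruit trees.
* `noise_sigma = 0.05`: multiplicative lognormal noise, applied
  independently to diameter and length, then to mass after the
  density × volume computation. Multiplicative noise keeps log–log
  residuals homoscedastic, which is the SMA error model; 5% is a realistic
  field-measurement error for calipers and tape.
* pruning: `prune_fraction` deletes whole subtrees at depth ≥
  `prune_min_depth` (branch-removing cuts, the free-standing-tree style),
  `tip_trim` shortens terminal segments and proportionally their mass
  (length-reducing cuts, the trellised-tree style). These are idealised
  operators for the two qualitative classes of dormant-season cuts; no
  regrowth/invigoration response is modelled. Removed-mass fraction is
  returned, is monotone in `prune_fraction` and exactly linear in
  `tip_trim`.
* one seeded RNG stream in a documented order (diameter noise, length
  noise, mass noise, then pruning draws) makes every fixture
  bit-reproducible.

The closed-form exponent is reported for the segment level only:
path/subtree exponents of a truncated self-similar tree depend on depth,
so those levels are validated against brute-force enumeration oracles
(exhaustive reachability for subtrees, exhaustive chain enumeration for
paths) rather than formulas.

What the generator does *not* emulate about real orchard data: ties and
reiteration in topology (real trees are not perfect $n$-ary), crotch
angles and 3-D geometry, within-tree heteroscedasticity, fruiting spurs
and twig biology, rootstock effects, or regrowth after pruning. Passing
tests on synthetic trees therefore demonstrate correctness of the
computations and estimator calibration under the stated error model — not
that any particular field dataset satisfies that model.

`simulate_allometry_pairs()` backs the CI-calibration checks. It draws a
latent log-size $t \sim N(0, \mathrm{spread}^2)$ and adds independent
normal errors to both log-coordinates with sd ratio equal to the slope —
the errors-in-both-variables model under which the SMA sd-ratio estimator
is consistent, hence the model against which its interval should be
calibrated. Coverage of the analytic 95% CI over 200 replicates of
$n = 50$ sits in the mid-90s. For the AICc sanity property (truly linear
data should be called linear) replicates use $n = 20$ points at
$\sigma = 0.05$: the small-sample penalty at that size keeps the expected
false-curvature rate below 10%, which is the behaviour a practitioner
relies on when screening many relationships.

## Problem sizes and numerical choices

The test suite and acceptance script run on trees of 31–255 branches,
50-branch random topologies for the aggregation oracles, 100–200 replicate
datasets for estimator identities, coverage and model-selection rates —
sizes chosen to match the scale of real branch tables while keeping every
check exact or tightly toleranced. Exact identities (noiseless slopes,
aggregation sums) are asserted at 1e-9–1e-12; stochastic rates are
asserted as ranges (coverage in [90%, 99%]). Report CSVs keep full double
precision; the run manifest serialises doubles with 17 significant digits
so that replaying a manifest byte-reproduces every table, which is tested.

## Known limitations

* The intercept CI is an approximation (see above).
* FS/WBE are compared only through their exponent predictions; the models
  are not re-derived, and no slope-heterogeneity test beyond CI overlap is
  offered because overlap is the comparison convention in this literature.
* Mass fits quietly lose branches whose aggregates contain unweighed
  members; the loss is logged, but users with substantial missing mass
  should inspect `n_dropped` before interpreting.
* The pruning operators are static; questions about compensatory regrowth
  need a growth model, which is out of scope.
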