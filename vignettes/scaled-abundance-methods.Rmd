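---
title: "Scaled Abundances: model, evaluation procedures, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaled Abundances: model, evaluation procedures, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaledabund)
```

## The measurement model and why relative abundances mislead

Metagenomic sequencing (MGS) reports, for each sample, the share of reads
assigned to each taxon. Two distortions separate those shares from the
biology. First, every step of the pipeline — DNA extraction, library
preparation, sequencing, read classification — responds differently to
different organisms; under a locked-down (fully specified and reproducible)
protocol these per-step effects can be folded into a single aggregate,
taxon-specific multiplicative **bias**, so the analytical response of taxon
$z$ is

$$\mathrm{Response}_z = A_z \times B_z,$$

with $A_z$ the actual abundance (e.g. genome copies/mcL) and $B_z$ the
bias. Second, a sequencing run analyzes an essentially arbitrary total
number of molecules, so only the **closure** of the responses is observed:

$$\mathrm{RA}_z = \frac{A_z B_z}{\sum_j A_j B_j}.$$

The denominator couples every taxon to every other — the
*compositionality* of MGS data. A taxon's relative abundance can move
because its own abundance changed or because anything else in the sample
did, and the two cases are observationally identical.

## The Scaled Abundance metric

If an exogenous **internal standard** (IS) — an organism or its DNA that
is absent from the samples of interest and distinguishable by sequence —
is added to every sample at a known concentration $A_{IS}$, the shared
denominator cancels in the ratio of relative abundances, and defining

$$\mathrm{SA}_z = \frac{\mathrm{RA}_z}{\mathrm{RA}_{IS}} \times A_{IS}$$

gives

$$\mathrm{SA}_z = A_z \times \frac{B_z}{B_{IS}}.$$

Scaled Abundance is therefore proportional to the taxon's actual
abundance, with a constant of proportionality — the **bias ratio**
$B_z/B_{IS}$ — that depends only on the protocol, not on the sample's
composition. Two consequences drive everything in this package:

* with spike-ins of known concentration, the bias ratio can be estimated
  from replicates (`estimate_bias_ratio()`), after which SA converts to
  absolute abundance (`quantify_actual()`);
* without any bias knowledge, the fold change of SA between two samples
  measured under the same protocol equals the fold change of actual
  abundance (`fold_change()`), since the bias ratio cancels.

`scaled_abundance()` implements the metric. Relative abundances are
computed with no pseudocount by default — the defining equations have
none, and a silent offset would change every downstream number; a
`pseudocount` argument exists for log-scale workflows. A sample in which
the internal standard was not observed is uninterpretable; the default
policy is a hard error, with an explicit `is_zero = "drop"` escape that
logs a warning.

## Estimation choices

**Bias ratios.** Each replicate with known truth yields one observation
$r_i = \mathrm{SA}_i / A_z$. The estimate is the arithmetic mean of the
$r_i$ with a two-sided Student-t interval (default 95%). The arithmetic
mean is the most direct reading of "ratio estimated from replicates"; a
`aggregate = "geometric"` flag performs the t-interval on log ratios
instead, which some practitioners prefer for strictly positive ratios.
Back-calculated abundance intervals invert the bias interval
($\mathrm{SA}/\mathrm{ci}_{high}$, $\mathrm{SA}/\mathrm{ci}_{low}$).

**Proportionality regressions.** Agreement between a measured metric and
known truth (actual abundance or dilution fraction) is assessed by least
squares through the origin — the proportionality above has no intercept —
with an `through_origin = FALSE` flag for exploratory fits.
Goodness-of-fit is summarized as a coefficient of variation,

$$\mathrm{CV} = 100 \times \frac{\mathrm{RMSE}}{\bar y},$$

with RMSE the regression standard error $\sqrt{\mathrm{RSS}/(n-p)}$. This
CV(RMSE) definition is an interpretive choice (regression goodness-of-fit
has no single canonical CV) and is used consistently everywhere:
per-taxon regressions, internal-standard rotation averages, and
limit-of-quantitation profiles. Regressions are fit on linear axes. Taxa
observed in fewer than 3 samples are skipped (a slope CI needs at least
one residual degree of freedom) and reported in a skip list.

**Rotation.** `rotate_internal_standard()` treats each taxon of a
mock-community design in turn as the internal standard, computes SA for
the remaining taxa from its known abundance, and averages the per-taxon
regression CVs with a t-interval across taxa. On noise-free data every
rotation gives mean CV 0 — the choice of internal standard is
mathematically immaterial — while the relative-abundance baseline does
not, which is the entire argument for the metric.

## The simulator

`simulate_counts()` generates data from exactly the measurement model
above: actual abundances × biases → closure → read sampling. Read-count
saturation is modeled as a multinomial draw at fixed depth (optionally
Poisson-distributed depth), the canonical closure model for "a fixed
budget of reads"; an `expectation` mode returns `depth × expected RA`
without noise so that the algebraic identities can be tested to floating
point tolerance. Biases are lognormal (meanlog 0, sdlog 1) by default —
spanning roughly an order of magnitude either way, the regime in which
taxon biases are reported to vary substantially between organisms and
protocols — and fixed user vectors are always accepted. PCR and
extraction are not simulated as separate steps: the single aggregate bias
term is the model. Per-sample bias jitter is deliberately absent from the
defaults; the framework's assumptions hold biases constant within a
protocol, and testing that assumption is a robustness study, not a
default.

Three scenario builders encode the study designs the package is
evaluated on:

* `scenario_mock_community()`: 80 communities assembled from a 7-strain
  panel, member abundances drawn from stock dilutions {1/2, 1/3, 1/7},
  random subsets of at least 2 strains.
* `scenario_spikein_backgrounds()`: five distinct ~50-taxon backgrounds
  (symmetric Dirichlet, α = 0.5 — uneven, stool-like), each carrying four
  spike-ins at 4.8×10⁴, 9.6×10³, 5.4×10³ and 6.2×10² copies/mcL and the
  internal standard at 2.16×10⁵ copies/mcL. The background total is
  1×10⁶ copies/mcL, chosen so the smallest spike sits near relative
  abundance 5×10⁻⁴ — the low-abundance regime the design is meant to
  probe.
* `scenario_dilution_series()`: one ~50-taxon community (lognormal
  abundances, sdlog 2, spanning several orders of magnitude) diluted to
  fractions 0.2–1.0, with the internal standard added at constant
  concentration after dilution. An optional sentinel taxon is constructed
  to land at a requested expected relative abundance in the undiluted
  sample (solving $A_s = r\,S/(1-r)$ against the summed analytical
  response $S$ of everything else), to probe the limit of quantitation at
  e.g. 3×10⁻⁵.

Scenario builders realize the design and biases at build time (seeded),
so a serialized scenario (`write_scenario()`/`read_scenario()`) plus a
sampling seed reproduces counts bit for bit.

### What the simulator does and does not emulate

It emulates taxon-specific multiplicative bias, compositional closure,
and counting noise at finite depth — the three effects the framework is
about. It does not emulate read-level artifacts (sequencing error,
chimeras), taxonomic misassignment between related taxa, zero-inflation
from extraction dropout, or bias drift between samples. Passing tests
therefore demonstrate that the algebra and estimators behave correctly
under the framework's own assumptions; they do not certify performance on
real data where those assumptions (notably bias constancy) may be
violated.

## Numerical choices and degenerate inputs

* Proportions are detected on read when every row sum is within 1e-6 of
  1, then renormalized to sum to exactly 1; ambiguity is resolved by an
  explicit `mode_hint`, and a table *forced* to proportions outside the
  detection band is an error, because silently misreading counts as
  proportions (or vice versa) corrupts everything downstream.
* Floats are written with 15 significant digits so write/read round-trips
  are faithful to better than 1e-12 relative.
* `group_cv()` returns an undefined marker (`NA`) for a zero mean; fold
  changes involving a zero Scaled Abundance are `NA`, never infinities.
* Zero-width confidence intervals (all replicates identical) are
  legitimate outputs, not errors.
* Seeds: every stochastic operation takes an explicit seed and
  saves/restores the global RNG state, so library calls never perturb a
  caller's random stream.

## Problem sizes used in the package's own evaluation

The bundled evaluation (tests and the acceptance script) runs the
spike-in design at depth 10⁵ with five backgrounds, the dilution series
at depth 10⁶ (10⁶–2×10⁶ for the limit-of-quantitation sentinel, averaged
over 20 replicate simulations), bias-ratio coverage over 200 simulations
of 5 replicates at depth 10⁶, and oracle cross-checks on 1,000 random
small inputs. These sizes give stable Monte-Carlo summaries in seconds
while exercising the same designs at their target precision bounds
(CV ≤ 16% for spikes across backgrounds; CV ≤ 25% down to relative
abundance ≈ 3×10⁻⁵ in the dilution series). At depth 10⁵ the smallest
spike receives on the order of 30 reads, so its between-background CV
fluctuates around the 16% bound from one random protocol (bias draw) to
another — the same counting-statistics limit that makes low-abundance
taxa the hard case in practice.

## Known limitations

* The bias-constancy assumption is taken as given; no diagnostics are
  provided for detecting bias drift between samples.
* The CV(RMSE) goodness-of-fit definition, while standard, is one of
  several reasonable choices and is not comparable across datasets with
  different dynamic ranges.
* No compositional log-ratio machinery (CLR/ALR/ILR) or differential
  abundance testing is included; the package ends at absolute-abundance
  estimates and fold changes.
* Taxon identifiers are opaque strings: the framework applies unchanged
  at strain, species, or genus level, and no taxonomy parsing is
  attempted.
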