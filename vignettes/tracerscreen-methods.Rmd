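---
title: "Rule-based screening for tracer-derived isotopolog patterns: methods and design"
author: "tracerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based screening for tracer-derived isotopolog patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerscreen)
```

## The screening problem

Fatty acids and polyketides are assembled by iterative addition of
two-carbon (C2) extension units derived from malonyl-CoA.  When a culture is
fed a stable-isotopically distinguishable malonate tracer, some of the
extension units incorporated into each biosynthesized molecule are
tracer-derived, and the molecule's isotopolog distribution in an LC-HRMS
full-scan acquisition acquires a highly diagnostic shape: a ladder of
satellites spaced by two carbon-isotope exchanges, with smaller
odd-numbered satellites in between.

Two complementary set-ups produce mirror-image ladders:

* **standard tracer approach** — a 13C-labelled tracer in a native (12C)
  background; the principal isotopolog X is the monoisotopic all-12C ion and
  incorporation shifts satellites *up* in mass (X+1, X+2, ...);
* **reversed tracer approach** — a native (12C) tracer fed to an organism
  grown on uniformly 13C-labelled carbon; X is the fully labelled ion and
  satellites extend *down* in mass (X-1, X-2, ...).

`tracerscreen` screens centroided runs for any such user-definable pattern.
Every centroid of every MS1 scan is provisionally treated as X; a
declarative rule set decides whether the satellite intensities around it
match the target pattern; surviving signals are clustered, re-verified in
the chromatographic domain, bracketed across samples and reported as a TSV
data matrix.

## The rule engine

A rule set is an ordered list of rule objects evaluated on a map
offset → intensity (`evaluate_rules()`), where the offset is the signed
number of 12C↔13C exchanges relative to X and the satellite m/z is
`x_mz + offset * 1.0033548378 / charge` (the exact 13C−12C mass
difference).  The same pure function runs on per-scan intensities and,
later, on chromatographic peak areas.  Available rules:

* `presence_rule` — offsets that must be present, optional per-offset
  minimum intensities, and relative intensity ranges against one or more
  anchor offsets (checked against **each** anchor separately — the
  conservative reading of "relative to X and X+2");
* `absence_rule` — forbidden offsets, with a noise allowance expressed as a
  fraction of X (default 5 %);
* `ratio_rule` — a group ratio confined to a range, or several group ratios
  required to agree pairwise within a relative tolerance,
  `|r_i − r_j| / min(r_i, r_j) ≤ tol` (symmetric and strict);
* `any_intensity_rule` / `all_intensity_rule` — plain intensity thresholds.

User-defined subclasses of `"iso_rule"` only need `evaluate_rule()` and
`rule_offsets()` methods; the engine dispatches on class and needs no
modification.  Rule sets are also expressible as YAML/JSON configuration
files (`read_ruleset()`, `lint_ruleset()`).

The built-in `standard_tracer_ruleset()` requires X ≥ 1e5 counts; X+2 and
X+4 ≥ 5e4 counts and within 10–300 % of X and X+2 respectively; X+1 and X+3
within 10–200 % of each even neighbour; X−1/X−2 below 5 % of X; and
`(X + X+2)/X+1 ≈ (X+2 + X+4)/X+3` within ±10 %.  The
`reversed_tracer_ruleset()` mirrors this and extends it by a third unit
(X−5, X−6, three paired ratios), because the reversed approach yields more
abundant satellites.

The per-offset range bounds of 10–300 % (even) and 10–200 % (odd) are read
*distributively*: X+2 is checked against X, X+4 against X+2.  The
alternative reading (both against X) is noted but not implemented; the
distributive one matches the explicitly chained phrasing of the reversed
rule set.

## The incorporation model

The synthetic generator needs the theoretical isotopolog distribution of an
ion with `n_units` C2 units of which each is tracer-derived with
probability `q`, per-carbon tracer purity `p`, natural 13C abundance `a`
(default 0.0107) and, in the reversed mode, a global label purity (default
0.99).  `theoretical_pattern()` offers two variants.

**First-order model (default).**  The even-offset backbone is the
leading-order weight of k incorporated units,

$$E_k = \binom{n}{k} q^k (1-q)^{n-k}\, p^{2k} (1-a)^{n_C - 2k},$$

and each odd satellite draws on its two even neighbours with a single
constant effective single-exchange rate $c$:

$$O_k = c\,(E_k + E_{k+1}), \qquad
  c = \tfrac12\left[(n_C - 2nq)\frac{a}{1-a} + 2nq\frac{1-p}{p}\right].$$

The two terms of $c$ are the expected number of one-heavy exchanges from
natural 13C among the (on average) $n_C - 2nq$ unlabelled carbons and of
one-light exchanges from isotopic impurity among the $2nq$ labelled ones.
Because $c$ is one constant, every paired sum ratio
$(E_k + E_{k+1})/O_k = 1/c$ is *identical* — which is precisely the
property the ratio-equality rule exploits, and why the odd satellites make
such reliable filters: their ratio to the neighbouring even isotopologs is
independent of how many tracer units a particular metabolite incorporated.
The model also reproduces the other qualitative features of the measured
patterns: a staircase of even offsets whenever $nq/(1-q) < 1$, and every
odd satellite below the mean of its even neighbours (since $c < 1/2$).

**Exact enumeration (`variant = "exact"`).**  The full carbon-level model —
k ~ Binomial(n, q) tracer units, each tracer carbon heavy with probability
p, every remaining carbon heavy with probability a, convolved exactly — is
also provided.  It is physically complete, but its paired sum ratios are
only *approximately* constant: the binomial staircase is not geometric
(step ratios fall like 1/k), and the single-exchange rates genuinely differ
between neighbouring clusters, so the ratios drift by several percent to
tens of percent across realistic parameters.  One can verify both claims
directly:

```{r exact-vs-first-order}
m <- incorporation_model(9, q = 0.1, n_carbons = 18)
ratio_dev <- function(p) {
  r1 <- (p[["0"]] + p[["2"]]) / p[["1"]]
  r2 <- (p[["2"]] + p[["4"]]) / p[["3"]]
  abs(r1 - r2) / min(r1, r2)
}
ratio_dev(theoretical_pattern(m))                      # ~1e-16
ratio_dev(theoretical_pattern(m, variant = "exact"))   # ~0.2
```

The first-order variant is the default because the ratio-constancy
identity is the scientific core of the filtering strategy — the measured
spectra that motivated the built-in ±10 % equality tolerance evidently obey
it — whereas under the exact independent-carbon enumeration a large part of
the realistic parameter space would violate the very rule set the generator
is meant to exercise.  The deviation of the exact variant is kept visible
(and tested) as a documented limitation of the independence assumptions
rather than hidden.

In the reversed direction the same core runs with the roles of heavy and
light swapped (tracer carbons light with probability `tracer_purity`,
background carbons light with probability `1 − label_purity`) and offsets
negated, which makes the mirror identity between the two approaches exact
by construction.

## The synthetic generator and what it emulates

`make_synthetic_truth()` plants compounds on a retention-time ladder
(default spacing 40 s, apex σ 2.5–5 s, scan interval 0.5 s) and
`generate_run()` renders them into centroided scans: per isotopolog one
centroid at the theoretical m/z with intensity
`height × relative_intensity × Gaussian(rt)`, optional multiplicative
log-normal intensity noise (default CV 5 % when enabled), ppm-scale m/z
jitter, uniform noise centroids (< 5e4 counts), and optional whole-run
retention-time/m/z shifts emulating inter-sample variability.  Runs are
written as minimal indexed mzXML (32-bit network-order peak arrays, the
format the converter settings of a typical workflow produce) and read back
through `mzR`.

Compliant compounds draw `q` from 0.07–0.15 and carbon counts from 16–30
(18–30 reversed).  These ranges are chosen once, from the model: the even
steps `E_{k+1}/E_k` must stay inside the 10–300 % rule window down to X+4
(X−6 reversed), and the odd fraction `c(1 + E_{k+1}/E_k)` must clear the
10 % floor, which requires roughly a dozen or more carbons at natural
abundance — consistent with the C16–C30 fatty acids and polyketides the
tracer experiment targets.  Construction asserts that each compound marked
compliant passes the rule set at its apex, so the ground truth is true by
definition, not by luck.  Decoys violate exactly one rule each:
a missing odd satellite, a forbidden offset at 15 % of X, a 3-fold
inflation of X±1 (breaking only the ratio-equality rule while staying
inside the 10–200 % range window), or an X±2 trace shifted by 3.5 σ
(breaking only chromatographic coelution — such decoys still pass at the
apex scan and must be caught in the chromatographic domain).

What the generator does **not** emulate: realistic full-metabolome
complexity (thousands of co-eluting features), adduct/fragment chemistry
beyond a simple co-eluting companion trace, detector saturation,
centroiding artifacts, or retention-time drift within a run.  Passing the
synthetic suites therefore demonstrates the correctness of the algorithmic
chain under its stated assumptions, not field performance on crowded
biological matrices.

## Chromatographic verification

Scan-level hits are clustered on X m/z by complete-linkage hierarchical
clustering of log(m/z) with the dendrogram cut at the inter-scan mass
deviation (8 ppm), which bounds every cluster's relative m/z diameter;
clusters are then split at scan gaps > 3 and require ≥ 3 member scans.
Complete linkage is chosen precisely because its cut criterion bounds the
cluster diameter; the clustering is permutation-invariant.  A scan-level
pass is required in member scans but not across the whole peak — weak
satellites vanish in peak tails, so final arbitration happens on peak
areas.

EICs (±5 ppm, intensities within the window summed; summation is the
configurable default since split centroids should pool rather than
compete) are peak-picked with a Mexican-hat continuous wavelet transform:
16 log-spaced scales spanning the 5–25 s width bounds with margins, ridge
lines linked from coarse to fine scales within half a scale, ridges of ≥ 3
scales kept.  With the L2 wavelet normalisation used here the
coefficient-versus-scale curve of a Gaussian peak of width σ peaks at scale
√5 σ (the response is ∝ s^{5/2}/(s²+σ²)^{3/2}), so the best ridge scale is
refined by log-parabolic interpolation and divided by √5 to estimate σ;
peaks with 4σ outside 5–25 s are rejected, as are apexes below an SNR of 3
(noise = MAD of the EIC outside peak cores, floored at one count).
Boundaries descend from the apex to local minima (tolerating noise upticks
up to twice the running minimum) or to a 0.1 % baseline; areas are
trapezoidal integrals between the boundaries.  On noiseless Gaussians this
recovers apexes within one scan and areas within a fraction of a percent
of the analytic hσ√(2π).

Each X peak in a candidate window is verified independently (isomers yield
separate features): every required offset needs a picked peak with apex
inside the X peak bounds; all pairwise Pearson correlations of the
required-offset EICs inside the X bounds (not the full EIC, so neighbouring
isomers cannot depress r) must reach 0.85; a coeluting forbidden-offset
peak enters the area map and the absence rule bounds it at 5 % of the X
area; finally the full rule set is re-evaluated on peak areas.  Two
Gaussians offset by d decorrelate as r ≈ exp(−d²/4σ²), so the 0.85 gate
corresponds to shifts of roughly 0.8 σ and a 3 σ shift is rejected with a
wide margin.

## Bracketing, convolution, reintegration

Features are bracketed across samples greedily in descending order of
summed isotopolog area, merging features within 0.1 min and 5 ppm, at most
one per sample per bracket — bracketing is idempotent and deterministic.
Brackets co-eluting within the same tolerance whose X EICs correlate at
≥ 0.85 in a shared sample form connected components (feature groups); the
0.85 threshold is reused from coelution for consistency, as no separate
value is established.  For samples without a detected feature the X and
satellite EICs are integrated over the consensus peak bounds and flagged
`reintegrated` (detected members are never altered).  The TSV reports one
row per bracketed feature — consensus m/z, rt in minutes, charge, group id,
and per sample one area column per required offset plus a flag.

## Numerical and interface choices

* Internal retention-time unit is seconds; configuration and the TSV use
  minutes where that is conventional.
* Charge defaults to 1 (protonated/deprotonated molecules); satellite
  spacing scales as Δm/charge; no automatic charge-state deconvolution.
* Within a lookup window the most intense centroid wins, with ties broken
  by smaller |Δm/z| — noise centroids are low-intensity, so this stabilises
  matching against split centroids.
* MS2 scans are ignored; mixed-polarity files are split on read.
* mzXML is the primary dialect, mzML is accepted; 32- and 64-bit peak
  arrays round-trip within 1e-6 relative (32-bit float precision).
* The dendrogram-cut window, scan-gap (3) and minimum cluster size (3) are
  documented defaults where no established value exists; all are
  configurable via `processing_params()`.
* Default problem sizes in the validation suites (runs of a few hundred to
  a few thousand 0.5 s scans, 20 compliant compounds + 20 decoys per
  approach) keep a full run of all suites within a few minutes on one CPU.

## Known limitations

* The CWT picker estimates σ from the ridge scale; for strongly overlapping
  peaks the neighbour's negative wavelet lobes bias σ low (detection and
  apex location are unaffected; areas split at the valley minimum).
* No peak deconvolution of co-eluting isomers within one EIC peak, and no
  gap-filling beyond consensus-window reintegration.
* The built-in rule sets cover carbon isotopes only; other elements work
  through a configurable mass difference but ship with no built-in set.
* Scan-level screening treats each scan independently; patterns present in
  fewer than `min_cluster_size` scans are not reported.
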