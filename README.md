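# tracerscreen

Rule-based screening of LC-HRMS data for tracer-derived isotopolog patterns.

## What problem this solves, and for whom

Fatty acids, polyketides and their hybrids are built by iterative addition of
malonyl-CoA-derived C2 extension units. Feeding a culture a stable-isotope
malonate tracer stamps every biosynthesized molecule of this class with a
diagnostic isotopolog ladder: satellites of the principal isotopolog X spaced
by two carbon-isotope exchanges (X+2, X+4, ... when a ¹³C tracer is used in a
native background — the *standard* approach; X−2, X−4, ... when a native
tracer is fed to a globally ¹³C-labelled organism — the *reversed* approach),
with small odd-numbered satellites in between that arise only from natural
¹³C abundance and tracer isotopic impurity.

`tracerscreen` is for metabolomics researchers running such
stable-isotope-assisted experiments who want those patterns mined out of
centroided full-scan chromatograms (mzXML/mzML) automatically. The target
pattern is not hard-wired: it is described by a declarative, extensible rule
set, so any isotopolog pattern — not only the malonate one — can be screened
for.

## The method

For every centroid of every MS1 scan, treated provisionally as X, the rules
are checked on the matched satellite intensities at
`mz(X) + offset × 1.0033548378 / charge` (±5 ppm):

* **presence** rules — required satellites, minimum intensities, and relative
  intensity windows against anchor isotopologs (e.g. X+2 within 10–300 % of
  X; X+1 within 10–200 % of X and of X+2);
* **absence** rules — forbidden offsets (e.g. X−1, X−2 in the standard
  approach), tolerated up to 5 % of X as noise;
* **ratio** rules — group ratios confined to a range, or required to agree:
  the paired sum ratios (X + X+2)/X+1 and (X+2 + X+4)/X+3 depend only on the
  constant isotope fractions, not on how many tracer units a molecule
  incorporated, and must be equal within ±10 %;
* **intensity** rules — any/all-of thresholds.

Scan-level hits are clustered on X m/z (time-aware, complete linkage, 8 ppm
diameter cut, so non-coeluting isomers separate), then re-verified in the
chromatographic domain: Mexican-hat continuous-wavelet-transform peak picking
bounded to 5–25 s peak widths, pairwise Pearson coelution of all isotopolog
traces at r ≥ 0.85 inside the X peak bounds, and a re-evaluation of the full
rule set on peak areas. Verified features are bracketed across samples
(0.1 min, 5 ppm), convoluted into metabolite-level groups, reintegrated where
a sample lacks a detection, and written as a TSV data matrix.

A ground-truthed synthetic-run generator (binomial tracer-unit incorporation,
constant effective single-exchange satellites, Gaussian elution, noise and
single-rule-violation decoys; indexed mzXML output) supports end-to-end
validation — see `vignette("tracerscreen-methods")` for the model and every
numerical choice.

## Worked example

```r
library(tracerscreen)

# theoretical pattern of a C18 ion with 9 extension units, 10 % incorporation
m <- incorporation_model(n_units = 9, q = 0.10, n_carbons = 18)
round(theoretical_pattern(m)[as.character(0:6)], 4)
#>      0      1      2      3      4      5      6
#> 0.9986 0.1933 1.0000 0.1397 0.4451 0.0542 0.1156   (names = offsets)

# plant 3 compliant compounds and 3 single-rule-violation decoys
truth <- make_synthetic_truth(3, 3, "standard", seed = 42)
run <- generate_run(truth)
run
#> <ms_run> 'synthetic': 521 MS1 scans, polarity -, rt 30.0-290.0 s
write_mzxml(run, "demo.mzXML")          # readable back via read_run()

res <- run_pipeline(list(run), ruleset = "standard",
                    out = "results.tsv", verbose = TRUE)
#> [synthetic] scans 521 | attrition 348 -> 106 -> 87 | clusters 3 | features 3
#> bracketed 3 features into 3 brackets, 3 groups

res$results[, 1:6]
#>   group_id feature_id       mz rt_min charge synthetic_area_X
#> 1        1          1 677.0450 1.0000      1         13817305
#> 2        2          2 540.5303 3.6667      1          5174066
#> 3        3          3 695.3603 4.3333      1          8262561
```

The relative pattern shows the even-offset staircase (X ≈ X+2 > X+4 > X+6)
with every odd satellite below the mean of its even neighbours. The
attrition line counts scan-level candidates surviving the intensity rules,
then additionally the absence rules, then the ratio rules (348 → 106 → 87).
Exactly the three compounds planted as rule-compliant
(677.0450, 540.5303, 695.3603) come through as rows of the result matrix —
the decoys, each violating a single rule, are filtered out; the per-sample
columns carry one peak area per required isotopolog plus a
detected/reintegrated flag.

A thin command-line wrapper is installed with the package
(`system.file("cli", "tracerscreen.R", package = "tracerscreen")`) with
subcommands `screen`, `simulate`, `pattern` and `rules-lint`.

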