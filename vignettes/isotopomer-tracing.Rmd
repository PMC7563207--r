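---
title: "Untargeted isotopomer tracing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted isotopomer tracing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofinder)
```

## The model

A molecule carrying `n` ¹³C labels produces an ion whose m/z exceeds the
unlabeled (M+0) ion by `n · 1.0033548378 / z`, where 1.0033548378 Da is the
¹³C–¹²C monoisotopic mass difference and `z` the charge magnitude. Because
isotope substitution barely perturbs chromatography, all isotopomers of one
molecule co-elute with their unlabeled parent. These two facts turn
untargeted tracing into a search problem: expand every identified reference
ion into its theoretical ladder, then look for labeled-sample MS1 features
that sit on a rung *and* at the parent's retention time.

A candidate rung and a feature are compared with the score

$$ S = 1 - \sqrt{(\Delta m/z \cdot \beta)^2 + (\Delta RT)^2} $$

a weighted Euclidean distance from the perfect match, with Δm/z in Th
against the theoretical rung and ΔRT against the reference retention time.
β (default 0.1) fixes the unit mismatch between the two axes. The feature
with the highest score wins the rung if S ≥ 0.61; ties go to the higher
intensity, then the smaller |Δm/z|. Each candidate claims at most one
feature per sample, but one feature may serve several candidates —
overlapping envelopes of different molecules are physically real, and such
hits are flagged (`feature_shared`) rather than suppressed.

Before scoring, two hard gates apply: |Δm/z| ≤ 10 ppm and |ΔRT| ≤ the
configured window. The ppm gate does the real false-positive screening.
With β = 0.1 the m/z term contributes at most ~10⁻³ to the score at any
plausible mass error, so the score alone cannot reject an impostor ~0.07 Th
away — exactly the co-elution scenario of the formate ion of PC(16:0/18:1)
(m/z 804.58) invading the M+26…M+40 region of PC(16:0/16:0) (m/z 778.56).
At m/z 804 that offset is ≈ 89 ppm, far outside the gate, while genuine
Orbitrap mass errors are a few ppm. The score's job is then to arbitrate
*within* the gate, where retention time dominates.

The printed form of the score lacks a radical sign; we read it as the
Euclidean distance above, since a "unit-fixing weight" only makes sense
inside a distance. The literal sum-of-squares reading is preserved as
`match_params(score_form = "sum_of_squares")`.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `beta` | 0.1 | s·C/g | m/z weight inside the score |
| `score_min` | 0.61 | – | acceptance cutoff; equals the score of a 0.39-RT-unit deviation at zero mass error |
| `mz_window_ppm` | 10 | ppm | hard m/z gate |
| `rt_window` | 30 | RT units | hard RT gate |
| `rt_unit` | seconds | – | unit of ΔRT inside score and gate |
| `n_max_metabolite` / `n_max_lipid` | 10 / 40 | labels | isotopomer caps per molecule type |
| `grade_max` / `mscore_min` | C / 5.0 | – | lipid identification acceptance filter |

The caps reflect carbon counts: polar metabolites rarely exceed ten
carbons, phospholipids and triglycerides run to forty. When a formula is
known the cap is tightened to its carbon count (`cap_by_formula = TRUE`) —
a molecule cannot carry more labels than carbons. M+0 is deliberately
generated as a candidate even though it is not a "heavy" isotopomer: the
labeling ratio needs the ¹²C intensity measured *in the labeled run*, not
in the reference run.

**Choosing `rt_unit`.** With RT in seconds, the 0.61 cutoff tolerates only
0.39 s of RT deviation — appropriate for data whose replicate RT scatter is
of order 0.1 s. Chromatography with seconds-scale scatter (typical
run-to-run reproducibility for many LC systems) should use
`rt_unit = "minutes"` with a correspondingly scaled gate, e.g.
`match_params(rt_unit = "minutes", rt_window = 0.5)`: the cutoff then
implies a ±23 s tolerance. All simulation-based validation in this package
uses the minutes configuration, because the generator's default RT jitter
(2 s SD) models that second regime; with seconds-unit scoring, most genuine
isotopomers in such data would be rejected on RT alone.

Grades bin the accepted score range (A ≥ 0.95, B ≥ 0.85, C ≥ 0.70, else D).
The bin edges are this package's declaration — only "A is best" is
inherited from the output convention the sheet follows.

## Inputs and conventions

Reference entries come from two export dialects: a metabolite table
(`name, mz, rt, polarity` at minimum; adducts default to +H/−H by
polarity) and a LipidSearch-style lipid table, filtered to grades A–C and
m-score ≥ 5.0 before use. Pooling several unlabeled runs widens coverage;
duplicates on (name, adduct, polarity) collapse to their median m/z and RT
— a robust choice the loaders log, since exports rarely state which run's
coordinates are authoritative. RT is seconds everywhere internally;
conversion to minutes happens only inside the matcher.

Adduct mass deltas are atom-level sums that ignore the electron mass
(error < 0.001 Th at z = 1, invisible at the 2-decimal precision ion m/z
values are quoted at). With this convention the formate ions of
dipalmitoyl-PC and PC(16:0/18:1) compute to 778.56 and 804.58:

```{r}
round(ion_mz(monoisotopic_mass("C40H80NO8P"), "+HCOO"), 2)
round(ion_mz(monoisotopic_mass("C42H82NO8P"), "+HCOO"), 2)
```

The result sheet uses the fixed 17-column header (`mz1 … Grades`), with
`mz1`/`rt1` the reference coordinates and `mz2`/`rt2` the matched labeled
feature — the sheet's own definition is ambiguous about which side is
which, so this package fixes and documents that convention. An 18th
`sample_id` column is appended because the driver concatenates all labeled
samples into one sheet.

## Peak picking

The bundled picker is a deliberately simple contract, not a port of any
EIC-density algorithm: centroids pool across scans, single-linkage cluster
along m/z (break at gaps > 4 ppm), split at RT gaps > 300 s, then local
maxima expand to monotone runs which must span ≥ 3 scans, clear 3× the
trace noise (median of non-peak points) and 2× the local baseline, and
have an apex inside [10⁴, 10⁷] counts. Parameters of density-based pickers
with no analogue here are accepted in configuration for provenance and
ignored with a notice. Pre-picked feature CSVs bypass the stage entirely
and are the first-class path; peak picking is a replaceable upstream
concern. Nothing is de-isotoped at this stage — the isotopomers *are* the
signal. Picked intensity is the apex by default (`intensity_type = "area"`
switches to the summed run), since upstream tools differ and the labeling
ratio is invariant to any molecule-wide intensity convention.

## The simulator and what passing tests mean

`simulate_tracing()` plants, per molecule and sample, one feature per
envelope component at the exact theoretical rung, then perturbs it with
Gaussian m/z jitter (default 1.5 ppm SD), Gaussian RT jitter (default 2 s
SD) and lognormal intensity scatter (CV 0.1) — scales chosen to emulate
high-resolution Orbitrap acquisition with LC reproducibility in the
seconds range. Decoys are uniform in (m/z, RT); a hard-decoy mode places
them one isotope spacing off true peaks to stress tie-breaking; interferer
features reproduce the co-eluting heavier-lipid overlap at a fixed Th
offset. Randomness comes from one master seed with per-sample substreams
derived by hashing the sample id, so adding a sample never changes
existing ones.

The validation suite runs 20 seeds × 50-molecule panels with 200 decoys
per sample and requires precision ≥ 0.99 and recall ≥ 0.95, plus recovery
of every planted labeling ratio within 3·CV/√(envelope components); the
matcher is also checked for exact agreement with an exhaustive
brute-force search on 100 random instances of 200 candidates × 2000
features. These sizes keep the whole suite under a minute of matching work
while still crossing every gate boundary.

What the simulation does *not* model: chromatographic peak shape beyond
single features (the matcher consumes feature lists, so shape only matters
to the picker, which is tested separately), correlated RT drift across a
run, detector saturation, and the natural-abundance envelope (available
conceptually but not required — the package performs no natural-abundance
correction, matching its quantification definitions). Passing tests
therefore demonstrate correctness of the search and quantification
arithmetic under realistic jitter, not robustness to every artifact of
real chromatography.

The random panels emulate a *deduplicated* identification list: unique
formulas, and near-isobaric ions forced apart in RT. Real exports satisfy
this by construction — identification software reports one entry per
resolved (m/z, RT) species — and without it "ground truth" would be
ill-defined: two co-eluting ions of identical formula are genuinely
indistinguishable to any m/z–RT method.

## Numerical choices and degenerate inputs

* Atomic masses are IUPAC monoisotopic values hard-coded to 7 decimals; no
  runtime lookups.
* Score ties (exactly equal floats) break by intensity then |Δm/z|; the
  brute-force oracle in the test suite implements the same rules
  independently and must agree exactly.
* A sample with zero features yields zero hits and a warning, not an
  error; a molecule with no hits in a sample is absent from summaries
  (undefined), never zero-filled.
* Heavy isotopomers with no matched M+0 give labeling ratio 1.0 with an
  explicit `m0_missing` flag — fully labeled pools can extinguish M+0, and
  dropping such molecules would bias exactly the most-labeled species.
* Trace noise is floored at 1 count so signal-to-noise is defined for
  noise-free synthetic traces.
* Run manifests carry the resolved configuration, its MD5 and input MD5s,
  and no timestamp: identical runs are byte-identical, manifest included.

## Limitations

Only ¹³C spacing is built in (a ¹⁵N constant could be added through the
adduct/config machinery but is untested). There is no cross-sample RT
alignment, no FDR statistic (decoy evaluation exists only as a
simulation-side metric), no natural-abundance correction, and no
metabolic-network flux fitting — the output is the per-molecule labeling
evidence such downstream models consume.
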