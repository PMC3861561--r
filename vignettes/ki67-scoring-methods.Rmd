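---
title: "Methods: marker-based Ki-67 scoring and breast-carcinoma stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based Ki-67 scoring and breast-carcinoma stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67score)
```

## The measurement model

The Ki-67 proliferation index of a tumor is estimated by counting
nuclei on a small number of calibrated ×40 digital fields chosen in the
*hotspot* — the region with the densest Ki-67-positive staining,
typically near the tumor invasion front. On each field a pathologist
places one point marker per tumor nucleus, labelled positive
(immunostained) or negative. The per-field index is

$$\mathrm{IK}_j = 100 \cdot \frac{k_j}{n_j},$$

with $k_j$ positive of $n_j$ counted nuclei, and the case-level result
is the **unweighted mean of the per-field indices**,
$\overline{\mathrm{IK}} = \tfrac{1}{m}\sum_j \mathrm{IK}_j$. This is
the protocol's own estimator; the pooled ratio
$100\,\Sigma k_j / \Sigma n_j$ is always computed alongside as a
diagnostic because the two diverge when field totals are unequal
(e.g. fields of 1/10 and 90/100 give a mean of 50% but a pooled value
of 82.7%). The package never silently substitutes one for the other.

A case is considered reliably scored when at least 1,000 nuclei have
been counted in total. `aggregate_case()` flags and warns on a
shortfall rather than failing, so partial cases remain inspectable;
`images_needed()` plans the number of fields as
$\lceil \text{minimum} / \text{nuclei-per-field} \rceil$ — 7 fields at
the typical median of 151 nuclei/field, 2 for dense fields of >500.
(At the *mean* of 173 nuclei/field the ceiling gives 6; the protocol's
reported average of seven fields reflects its median-driven practice,
and the planner exposes both without forcing agreement.)

### Field calibration

All coordinates are micrometres with origin at the field's top-left
corner; pixel-unit annotations are converted through a `um_per_px`
calibration scale and are refused without one. The reference ×40 field
is 310.3 µm × 232.72 µm = 0.072213 mm², giving nuclear densities
(count/area) of 1149, 2091 and 8101 nuclei/mm² at the observed
minimum/median/maximum per-field counts of 83, 151 and 585. The
published cohort's *mean* density (2451/mm²) is arithmetically
inconsistent with its mean count at fixed area (173/0.072213 ≈ 2396);
this package reproduces only the internally consistent cells and uses
2396/mm² wherever a mean-count-equivalent density is needed. Markers
exactly on the field border are in-bounds (closed interval): clicked
nuclei may straddle edges, and the original protocol does not state a
policy, so the inclusive choice — which never discards a click — was
adopted. Near-duplicate clicks are *flagged* (`flag_near_duplicates()`,
strictly-closer-than semantics), never merged: the human click is
ground truth.

## Classification rules

All thresholds below are fixed by the underlying scoring conventions;
none are tunable.

* **Receptor levels** (`receptor_level()`): negative ≤ 1% < low ≤ 50% <
  high. Positivity (for luminal typing) is >1%.
* **HER2** (`her2_score()`): 0 when staining is absent or in <10% of
  cells; 1+ weak & discontinuous in >10%; 2+ weak-to-moderate &
  continuous in >10%, or intense & continuous in ≤30%; 3+ intense &
  continuous in >30%. Only 3+ is positive. The rule table has genuine
  gaps (exactly 10%, and discontinuous staining that is not weak);
  those raise a classed `ki67_her2_unscorable` error instead of a
  silent default, because scoring systems with reflex testing treat
  such cases out-of-band. A precomputed 0–3 score may be supplied to
  bypass the rule engine for cohorts scored elsewhere.
* **IK classes** (`ik_class()`): the printed bands "≤15 / 16–30 / >30"
  leave (15, 16) undefined for continuous IK values; the package uses
  half-open bands anchored at the printed edges —
  low ≤ 15 < moderate ≤ 30 < high — so the classes partition [0, 100].
  The alternate `luminalB14` scheme is the binary 14% luminal-A/B cut;
  the 15/30 scheme is the default because it is the one the cohort
  tables use.
* **NPI** (`npi_value()`, `npi_group()`): 0.2·size(cm) + node score +
  grade; the moderate band 3.4–5.4 is closed on both ends, GPG strictly
  below, PPG strictly above. Node score: 1 with no positive nodes, 2
  with 1–3, 3 with ≥4 or a positive apical node. Grade is consumed as
  an input (1/2/3); `sbr_to_grade()` offers the standard
  Elston–Ellis component-sum mapping (3–5 → G1, 6–7 → G2, 8–9 → G3)
  for convenience, but mitosis/tubule/pleomorphism scoring itself is
  out of scope.

Percentages in cross-tabulations are rounded half-up to one decimal
(`round_half_up()`); counts are always authoritative, since published
tables occasionally carry rounding inconsistencies.

## The synthetic generator

`simulate_field()` is a statistical stand-in for clicked fields, not a
histology simulation: the nucleus count is Poisson with mean
density × area (default 2396/mm², i.e. λ ≈ 173 in the reference field,
emulating the observed 83–585 spread), positions are uniform in the
field, and labels are independent Bernoulli draws at the local positive
probability. The `hotspot_gradient` pattern ramps the positive
probability linearly along the long axis,
$p(x) = p\,[1 + g\,(2x/W - 1)]$ clipped to [0, 1] — a minimal spatial
model chosen because no spatial statistics for nucleus clustering are
available; uniform placement is otherwise assumed. A positive
`min_separation_um` is enforced by simple sequential inhibition with a
bounded retry budget (100 attempts per point), erroring on infeasible
packing rather than looping forever. A fixed-count mode (`n_nuclei`)
exists for exact tests.

`simulate_case()` reproduces the capture policy (fields until the
cumulative count reaches the minimum, or a fixed number), and
`simulate_cohort()` adds receptor profiles and clinical covariates with
ground truth retained. Cohort defaults were chosen once to mirror an
81-case invasive-ductal series: 18/81 receptor-negative (non-luminal),
grade mix 9/45/27, 51/81 node-positive, sizes log-normal around a mean
of 2.8 cm (clamped to 1–8), true IK ~ Beta(2, 4.6) (mean ≈ 0.30) for
luminal and Beta(8, 4.5) for non-luminal tumors (whose proliferation
runs uniformly high). Seeding: one root seed; per-field and per-case
streams are derived by a deterministic affine map, so any case can be
regenerated without replaying the whole cohort.

What passing tests on synthetic data do *not* show: real fields have
spatially correlated nuclei, uneven staining intensity (the protocol
deliberately scores without intensity grading), segmentation ambiguity
at high density, and hotspot-selection variability between observers.
The generator validates the *arithmetic and classification pipeline*,
not the human annotation step.

## Numerical and design choices

* The mean-of-fields estimator is unweighted by design; field area is
  constant in this protocol, so area weighting is a non-goal.
* Median of an even number of fields = mean of the two central values.
* IK is reported to one decimal; full precision is kept internally.
* Validation is row-exact: accepted + rejected rows always partition an
  input annotation table (`validate_marker_rows()`), and errors carry
  classed conditions (`ki67_validation_error`, `ki67_io_error`) that
  the CLI maps to exit codes 1 and 2.
* Cross-tab factor orderings are fixed (high/moderate/low, GPG/MPG/PPG)
  so outputs are diffable; known factors keep empty levels as
  explicit `0.0 (0)` cells.

### Problem sizes in the checks

The statistical checks run at sizes chosen to keep the suite quick
while leaving comfortable statistical margins: parameter recovery uses
200 seeded replicates of 7 Poisson fields at true p = 0.25 (realised
n ≈ 1,210 nuclei/replicate; observed |bias| well under 0.5 percentage
points and ~95% CI coverage), and the stopping rule is exercised over
1,000 seeded trials. `scripts/acceptance.R` recomputes the same
quantities end to end.

## Known limitations

* No pixel-level nucleus detection, stain deconvolution, or slide
  mosaics: the input is human point annotations plus calibration.
* Group-mean IK values of a real cohort cannot be recomputed from
  published tables alone (they depend on the raw slides); the package
  reproduces count-derived quantities only.
* HER2 2+ ("questionable") cases are *not* treated as positive and no
  reflex-test (FISH) pathway is modelled; positivity is strictly 3+.
* The rendered field images (`render_field_image()`) are documentation
  fixtures — brown/blue disks on white — not synthetic histology.
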