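---
title: "Methods: untargeted screening of plastic migrants with migrantscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted screening of plastic migrants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrantscreen)
```

# The screening problem

Recycled food-contact polymers carry intentionally added substances
(antioxidants, UV filters, slip agents), their reaction and degradation
products, and accidental contaminants from previous use. Migration
testing asks which of these transfer into food simulants. LC-HRMS in
data-independent acquisition covers the non-volatile fraction, but the
raw output — thousands of aligned features per polarity — is dominated
by redundancy (adducts, dimers, in-source fragments, isotopologues) and
background. `migrantscreen` implements the downstream workflow: clean
the feature table, collapse redundancy, annotate compounds with
library and structure-database evidence, and confirm per-sample
presence by pseudo-MRM.

# Mass and adduct arithmetic

All mass computation rests on a static table of lightest-isotope exact
masses and isotope abundances (IUPAC/CODATA values) embedded in the
package, so results never depend on an external resource. The element
set is C, H, O, N, P, S, F, Cl plus the adduct cations Na and K — the
set that covers organic packaging chemistry.

An adduct is the transform *m/z* = (n·M + Δ)/|z|, with Δ carrying the
electron correction so computed values are true ion *m/z*. The shipped
registry holds the fourteen electrospray adducts routinely produced by
this chromatography — [M+H]⁺, [M+NH₄]⁺, [M+Na]⁺, [M+K]⁺ and their 2M
forms in positive mode; [M−H]⁻, formate [M+FA−H]⁻, acetate [M+Hac−H]⁻
and their 2M forms in negative mode — plus the in-source water-loss ion
[M+H−H₂O]⁺, which hydroxy- and carboxy-compounds (e.g. monoesters of
diacids) commonly show as their detected form. The registry is a plain
data frame and user-extensible (`adduct_registry(extra = ...)`). Only
singly charged species are modelled; multiply charged ions are not
observed for this compound class.

Isotope patterns are built by iterated convolution of per-element
isotope distributions. After each convolution step, isotopologues are
aggregated on a 1 mDa grid (probability-weighted centroid per bin) —
matching what a QTOF can actually resolve — with a very fine internal
retention floor (1e−10 of total probability) so that the user-facing
prune threshold (default 1e−4) is applied only once, to the final
pattern, and does not bias retained abundances. The base peak is
normalized to 1.

Formula enumeration from accurate mass is an exhaustive depth-first
search over element counts, heaviest element first, with hydrogen
resolved last from the residual mass. Candidates must have integral
ring-plus-double-bond equivalents within [0, 40] (even-electron neutral
molecules) and H/C ≤ 4 when carbon is present; both limits are
arguments. Per-element ceilings default to the target mass divided by
the element mass and can be tightened via `bounds`; for masses above
roughly 500 Da a restricted element set or tighter bounds keeps the
search fast.

# Library compilation

Public MSP libraries disagree on header spellings, so parsing is
case-insensitive over a synonym table (PRECURSORMZ / PrecursorMZ /
Precursor m/z; PRECURSORTYPE / Precursor_type / ADDUCT; RT /
RETENTIONTIME; ...), peak lines split on whitespace with trailing
annotations ignored, and unknown keys preserved in a pass-through map.
Harmonization normalizes adduct labels to registry spelling,
canonicalizes formulas to Hill order, rescales intensities to base
peak 100, and *flags* rather than rejects inconsistencies (precursor
more than 0.01 Da from the formula+adduct value, fragments above the
precursor, ion mode contradicting the adduct) — curation decisions
belong to the user, not the parser.

Record identity for deduplication is the first InChIKey block (the 2D
skeleton) when available, else the compound name, combined with the
adduct and the collision-energy string (exact match; no numeric
binning). The survivor is chosen by source priority, then peak count,
then lower precursor m/z, then name; compilation therefore gives the
same result regardless of input order. These conflict rules are
repository policy — upstream library compilers do not document theirs —
and every tie-break in the package resolves to lower m/z then
lexicographic name so that golden files are stable.

Transition export takes the `top_n = 5` most intense product ions
(ties to lower m/z), normalized so the largest is 100; a record with
fewer peaks exports them all, and a missing reference retention time is
flagged but exported.

# Feature cleaning

Four filters with the workflow's standard thresholds, all strict
subsets of their input and idempotent:

| filter | statistic | default | action |
|---|---|---|---|
| minimum height | max over sample columns | 3000 counts | keep if ≥ |
| sample/blank | max(sample) / max(blank) | 5 | keep if > |
| blank/QC | mean(blank) / mean(QC) | 0.5 | remove if > |
| QC RSD | 100·sd(QC)/mean(QC) | 30% | remove if > |

The blank/QC ratio uses role-group *means* (the documented behaviour
class of feature-cleaning tools; configurable), a blank maximum of zero
falls back to a floor of 1 count (division-by-zero policy), and a
zero-mean QC removes the feature with a logged reason. Because the four
statistics are independent and the inequalities strict, the filters
commute — verified property-style in the tests.

Clustering connects co-eluting features (|Δrt| ≤ 0.025 min) whose
intensity profiles across sample-role columns reach Pearson r ≥ 0.8 at
p ≤ 0.05. The p-value is the standard t-transform test with n−2 degrees
of freedom (`cor.test`); intensities are used untransformed, matching
the defaults of the established cleaning tools. Edges are annotated by
mass difference against the registry: adduct pairs (difference of two
charge-carrier deltas within 0.005 Da), dimer relations, and in-source
fragments (the lower m/z appears in the higher feature's MS2 within
tolerance). Isotopologue spacings (k·1.00336 Da) can be annotated but
are off by default, since upstream alignment software normally removes
isotopologues before export. Connected components are built by
union-find; from each cluster the most intense and the most connected
members are kept for structural elucidation (ties to lower m/z).
Features without a usable MS2 — fewer than 3 fragments above 5% of the
base peak — are removed before elucidation, as noise-only spectra
cannot support it.

Positive/negative merging infers each feature's neutral mass from its
assigned adduct (default ion [M+H]⁺ / [M−H]⁻ otherwise) and merges
features agreeing within 0.005 Da and 0.025 min; ambiguous
many-to-many cases resolve to the closest mass pairing and the rest
pass through unmerged. The 0.005/0.025 pair is interpreted as Da for
mass and minutes for retention time.

# Identification

Library matching scores candidates whose precursor lies within 0.01 Da
as 100·(0.5·cosine + 0.25·reverse cosine + 0.25·matched-reference-peak
fraction), with fragments paired greedily by mass distance within
0.025 Da, each peak used at most once. The component weights are
package policy (the vendor software does not publish its exact
formula) and are arguments to `spectral_score()`. Only candidates at or
above the 80% cutoff are reported.

Structure-database search is precursor-oriented: for each adduct
hypothesis, entries whose theoretical adduct m/z falls within 0.005 Da
are scored on the *available* evidence — mass error (1 − |Δ|/tol),
isotope agreement (1 − mean absolute difference of the A+1/A+2 relative
abundances, clamped to [0, 1], missing peaks counting as 0), and
fragment explanation. Missing evidence is excluded from the mean rather
than zeroed, because features are legitimately annotated without a full
evidence set. The base score is that mean scaled to 10 (the in-silico
scoring display convention); the final score multiplies in the database
weight (multiplicative combination assumed; the combination rule is not
documented upstream). Ties resolve to the higher-weight database, then
name. A library match at or above the cutoff always beats database
candidates; otherwise the top database candidate annotates the feature,
otherwise it is `unknown`.

The fragment score is a deliberate stand-in for bond-disconnection
in-silico fragmentation: a peak is "explained" if some sub-formula of
the candidate (RDBE ≥ −0.5) plus the adduct's charge carrier matches it
within 0.025 Da, and the score is the explained fraction of total MS2
intensity — invariant to intensity rescaling. This asks whether
fragments are *elementally consistent* with the candidate rather than
whether the bonds exist; it reproduces formula-level decisions without
structure files, and SMILES are retained in the data model for a future
structure-aware fragmenter. Scores from tools with trained priors are
not comparable number-for-number and are not reproduction targets here.

# Pseudo-MRM screening

DIA chromatograms (single wide all-ion window by default, the MS^E
acquisition model) are searched for each library compound's transitions
within 0.025 Da; when several extracted traces match a product ion, the
closest m/z wins, with ties preferring a trace covering the compound's
reference RT. Peak detection applies a moving average of window
2·level + 1 (default level 1), local-maximum detection, a minimum
contiguous width at half height of 5 *data points* (the parameter is a
point count, matching the "minimum peak width 5" convention), a minimum
apex height of 100 counts, and trapezoidal area over the descent to the
local baseline.

The presence score replaces the upstream trained posterior model — a
probabilistic classifier we cannot retrain desk-side — with a
documented composite of the same four components, at the same
thresholds: retention time (1 − |Δrt|/0.1 min, clamped; 1 when no
reference RT exists), ion-ratio agreement (1 − mean relative deviation
of observed vs reference transition ratios / 0.15, clamped; "amplitude
tolerance" is read as ion-ratio tolerance, with apex-height deviation
selectable instead), peak shape (mean pairwise correlation of
transition traces over the union peak span) and coelution (fraction of
apexes within the RT tolerance of the group median). The posterior is
100 × the mean of the available components; a compound is *present*
when the posterior reaches 60% and its summed transition area is at
least 3× the largest blank area (floor 1 for empty blanks). Presence is
monotone in both inputs, which the suite checks property-style.

# What the synthetic data emulates

The generators produce the structure the statistics under test assume:
log-normal latent abundances per compound and sample; features of one
compound (adducts, planted in-source fragments) sharing that abundance
under multiplicative log-normal noise, so their cross-sample profiles
correlate; pooled QC as the sample mean under small noise; blanks at a
configurable contamination fraction; Gaussian chromatographic peaks
with configurable S/N, RT jitter and blank carry-over; fragments drawn
from true sub-formula masses. Defaults are chosen as typical of a
well-behaved QTOF batch: noise CV 5%, blank contamination 1% of mean
sample signal for tables, S/N 20 and 10% blank carry-over for DIA
batches, peak σ 0.03 min sampled at 0.01 min.

They deliberately do **not** simulate chromatographic tailing, mass
calibration drift, detector saturation, co-eluting isobaric
interference or profile-mode raw data. Passing tests therefore
demonstrate that the arithmetic, ranking and decision rules are
correct under the model the methods assume — not that the workflow is
robust to every pathology of real instrument data. The published
study-level counts (how many compounds a real extract yields) depend on
the actual samples and are not reproducible desk-side; the suite
replaces them with property checks at matched thresholds.

Test and acceptance problem sizes — libraries of 6–30 compounds,
tables of 40–60 features, DIA batches of 20 compounds × 10 samples + 2
blanks — were chosen as the smallest sizes at which the estimated
statistics (correlations, RSDs, recall/precision) are stable across
seeds.

# Degenerate inputs and numerical choices

- Constant intensity vectors have undefined correlation: no edge,
  logged.
- Blank max of zero in ratio filters: floor of 1 count; QC mean of
  zero: feature removed, logged.
- Traces shorter than the smoothing window: no peaks, logged.
- Compounds whose precursor falls outside every DIA window: flagged
  and skipped.
- All tie-breaks resolve to lower m/z, then name, for deterministic
  outputs.
- Isotope aggregation granularity 1 mDa, prune threshold 1e−4;
  enumeration RDBE range [0, 40], H/C ≤ 4 — all configurable.

# Known limitations

- The fragment score accepts any elementally consistent sub-formula;
  it cannot distinguish structural isomers (a database entry with the
  same formula ties).
- Retention-time transfer across food simulants is unreliable (aqueous
  vs organic injection solvents shift RT), so RT is never used as
  identification evidence, only as a pseudo-MRM screening component
  against batch-internal references.
- The shape score compares traces by index over the peak span and
  assumes transitions share a sampling grid, as DIA extractions do.
- Quantification (calibration, LOD/LOQ) and risk-level classification
  are out of scope.
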