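---
title: "Designing and validating surrogate internal-standard peptide assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating surrogate internal-standard peptide assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surropep)
library(dplyr)
```

## The problem

Targeted protein quantitation by LC-MS/MS normally relies on stable
isotope-labeled internal standards (SIL-IS): synthetic peptides identical to
the analyte peptide but mass-shifted by heavy isotopes, spiked at known
amount after digestion. SIL peptides are expensive, slow to procure, and —
because they are added *after* proteolysis — blind to sample-to-sample
differences in digestion efficiency.

An alternative is to co-digest the sample with an undiluted nonhuman matrix
(fetal bovine serum is cheap and ubiquitous) and use the *homologous* bovine
tryptic peptides as internal standards. For a well-chosen peptide pair the
surrogate is near-identical in length, hydrophobicity and retention
behavior, is species specific on both sides, and — critically — passes
through the same digestion as the analyte, so per-sample digestion
variability cancels from the peak-area ratio.

`surropep` implements both halves of this strategy:

* an **in-silico designer** that digests the two orthologous proteins,
  screens peptides for species specificity and isobaric interference, maps
  homology-anchored candidate pairs through a global protein alignment, and
  ranks them by physicochemical similarity; and
* a **validation engine** that fits calibration curves from peak-area
  ratios, estimates lower assay limits, back-calculates concentrations,
  applies FDA/ICH-style acceptance rules, and compares two IS strategies
  per sample with rank tests.

A seeded simulator generates calibration plates and study samples with the
exact statistical structure the method assumes, so the normalization claim
is testable end to end without instrument data.

## The design half

### Tryptic digestion

Cleavage is the classic trypsin rule: C-terminal to K or R unless the next
residue is P; the protein C-terminus always closes a peptide. `digest()`
emits every peptide with up to `max_missed` internal missed-cleavage sites
whose length lies in `[min_len, max_len]`, with 1-based inclusive spans.

Defaults are `max_missed = 0`, `min_len = 5`, `max_len = 30`. Quantotypic
panel peptides are typically 7–13 residues and fully cleaved; a lower bound
of 5 admits short peptides such as TSALSAK while discarding uninformative
fragments. The zero missed-cleavage default for candidate generation is a
deliberate design choice: partially cleaved species make poor quantotypic
peptides, and missed-cleavage behavior is better handled as a per-sample
efficiency scalar (see the simulator) than as extra candidates.

### Masses, m/z and hydrophobicity

`monoisotopic_mass()` sums standard residue monoisotopic masses plus one
water (18.010565 Da); the proton mass is 1.007276 Da. No fixed modifications
are applied by default — none of the curated panel peptides contains
cysteine — but `fixed_mods` accepts per-residue deltas (e.g.
carbamidomethyl-C, +57.021464 Da). Precursor m/z is `(M + z·1.007276)/z`;
y-ion neutral mass is the C-terminal residue sum plus water and b-ion
neutral mass the N-terminal residue sum, each charged the same way.

For display against unit-resolution MRM tables, `round_half_away()` rounds
half away from zero (1 dp for m/z, 2 dp for GRAVY); base R's half-to-even
rule can differ exactly at the printed precision.

GRAVY — the grand average of hydropathy — is the mean Kyte–Doolittle
hydropathy over the residues. It stands in for retention-time similarity
when scoring pairs: the package fits no retention model. Note that
hydrophobicity indices quoted elsewhere for some of these peptides derive
from other scales and do not match Kyte–Doolittle GRAVY (TSALSDK, for
example, is −0.59 under Kyte–Doolittle); when cross-checking against
external tables, confirm the scale first. Similarly, external transition
tables occasionally quote a product ion whose printed m/z corresponds to a
different fragment index or to a 2+ product; `surropep` always recomputes
ion m/z from the sequence, and the product charge set is configurable
(`transitions$product_charges`, default `{1}`).

### Selection and exclusion criteria

A candidate pair must satisfy, in pipeline order:

1. **Species specificity** (`check_species_specificity()`): the peptide
   occurs exactly once in its own species' panel digest (proteotypic) and
   never in the other species' digest. This is absolute — a shared peptide
   cannot serve as either analyte or surrogate.
2. **No fatal isobaric interference** (`detect_isobaric_conflicts()`): a
   transition conflicts when another peptide in the assay background has a
   precursor within `precursor_tol` *and* any b/y product within
   `product_tol` (defaults 0.7 Da each, the width of a unit-resolution
   quadrupole window). A peptide is excluded only if *no* conflict-free
   transition remains; individual conflicted transitions are simply dropped
   and logged. The default screening background is the union of both
   species' panel digests; a full matrix-proteome FASTA can be digested and
   appended when a wider screen is wanted.
3. **Instrument response** is accepted as a pluggable ranking hook
   (`design_panel(instrument_response = ...)`) and is a no-op by default:
   empirical response ranking depends on instrument and spectral-library
   tooling outside this package's scope.
4. **Sequence similarity**: candidates are ranked by
   `score = w_len·|Δlength| + w_gravy·|ΔGRAVY| + w_sub·substitutions`
   (defaults 1, 1, 0.25; lower is better), with deterministic tie-breaks by
   substitution count then surrogate start position.

Homology anchoring uses a global (end-gap penalized) protein alignment,
BLOSUM62 with gap open 10 and gap extension 0.5, via
`Biostrings::pairwiseAlignment()`. A surrogate peptide is a candidate for a
target peptide when at least `overlap_threshold` (default 0.5) of the
target's positions align inside the surrogate's span: the threshold admits
small indel shifts while rejecting positionally unrelated peptides, which
is the intent of requiring "corresponding positions" without demanding
exact coordinate equality. Identity percentages are aligner- and
version-dependent; the package reports identical and similar positions
(similar = aligned, non-identical, positive BLOSUM62 score) for the chosen
scoring rather than promising agreement with any specific aligner.

## The validation half

### Calibration model

Calibration fits are ordinary least squares of the peak-area ratio
(analyte/IS) on nominal concentration, with replicate ratios entering as
individual observations. Fitting on replicate means is available
(`use_means = TRUE`) since plots are conventionally drawn through means,
but individual observations are the default because the lower-limit
formulas need an honest intercept dispersion. `1/x` and `1/x²` weighting
are selectable; unweighted is the default, as bioanalytical practice varies
and the simulated noise model is multiplicative either way.

### Lower limits

With σ the standard deviation (n−1 denominator) of the y-intercepts across
replicate analyses and S the mean slope:

* LLOD = 3.3·σ/S
* LLOQ = 10·σ/S

`lower_limits()` requires at least `min_fits = 3` analyses and guarantees
`lloq/llod = 10/3.3` by construction. A residual-based σ mode
(`sigma_mode = "residual"`) is provided as an alternative but is not the
default: the intercept-dispersion definition is the one the ICH-style
formula names.

### Acceptance rules

Per calibrator level, from the back-calculated replicate concentrations
`(ratio − intercept)/S`:

* mean % recovery = 100 · mean(back-calculated)/nominal,
* precision = %CV of the back-calculated replicates,
* accuracy = % relative error of the mean.

A level passes when all three lie within ±15%, widened to ±20% at the
LLOQ-level calibrator only. An analysis passes overall when at least six
nonzero levels pass. QCs use the ±15% band at every level. There is no
automatic calibrator-dropping/refit loop: failures are reported and the
gate is evaluated on the full set, so a failing plate looks like a failing
plate.

### Method comparison

`compare_methods()` runs a two-sided Wilcoxon test per sample on the
replicate concentrations from the two IS strategies. The rank-sum
(Mann–Whitney) form for independent groups is the default — the compared
replicates are independent preparations, and triplicate groups are too
small for a paired signed-rank test to reach significance at all — with a
paired signed-rank mode available. The exact distribution is used for
combined n ≤ 20 without ties; otherwise the normal approximation with
continuity and tie correction. Significance is flagged at 0.05 and 0.01;
no multiple-testing correction is applied.

## The simulator

`simulation_config()` fixes the study conditions: a nine-point calibration
series (0.49, 0.98, 1.95, 3.91, 15.63, 62.50, 250, 500, 1000), triplicate
measurement in four analyses, QCs at 32/125/600, multiplicative
measurement noise `exp(N(0, noise_cv))` with `noise_cv = 0.05`, and a
per-sample digestion efficiency `exp(N(digestion_mu, digestion_cv))` with
`digestion_cv = 0.15` and `digestion_mu = 0`. Peak areas are positive and
assay dispersion is conventionally reported as relative (CV), which is why
the noise is lognormal; the generating line defaults to slope 0.01 and
intercept 0.02 in ratio units, putting the top calibrator at a ratio of
about 10 — a realistic dynamic range for an IS spiked near mid-curve. The
digestion-efficiency dispersion has no measured counterpart here; 15% is a
plausible bench value chosen once for property testing, not an estimate of
any real workflow, and `digestion_mu = log(0.7)` models systematically
incomplete digestion.

The crucial structural assumption is *where* the efficiency factor enters:
the analyte area always carries it (the sample is digested either way); the
co-digested matrix IS carries the *same* factor, so it cancels from the
ratio replicate by replicate; a post-digestion SIL spike does not carry it,
so SIL ratios inherit the full digestion variance and, when mean efficiency
is below 1, a downward bias with closed-form magnitude
`E[conc] ≈ ((S·c + b)·E[e]·exp(noise_cv²) − b)/S`.

What the simulator does **not** emulate: chromatography, ionization
suppression, carryover, adduct formation, heteroscedastic integration
error at the noise floor, or correlation between digestion efficiency and
protein identity. Passing tests therefore demonstrate that the statistics
behave as designed under the stated noise model, not that any particular
wet-lab assay will validate.

Every generator call derives all randomness from the mandatory config seed
(distinct fixed offsets for the calibration, QC and sample streams) and
leaves the session's RNG state untouched.

## Numerical and degenerate-input choices

* Perfectly linear (noise-free) input gives R² = 1 exactly; the coefficient
  of determination is computed directly from weighted residual and total
  sums of squares rather than through `summary.lm()`, which warns on exact
  fits.
* A calibration with fewer than two distinct nonzero levels is a
  degenerate-design error; zero-nominal rows are excluded from fits and
  verdicts (the zero calibrator is a blank check, not a calibrator).
* Back-calculated concentrations may legitimately be negative near the
  noise floor and are reported as-is, flagged against LLOD when limits are
  supplied.
* Transition role assignment breaks ties deterministically (y series, then
  longer fragment, then lower product charge, then product m/z), and
  `design_panel()` output is reproducible bit for bit for fixed inputs and
  config. The alignment layer inherits `pairwiseAlignment`'s deterministic
  tie-break among co-optimal alignments; scores, and all gap-free
  correspondences the panel relies on, are tie-break invariant.
* Alignment gap costs follow the `open + extend·length` convention per gap
  run, end gaps included.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to exercise the statistics
with comfortable margins: brute-force digestion oracles on 60-residue
random proteins; fragment identities on 1000 random peptides; all-pairs
isobaric screening against a 200-peptide background; exact Wilcoxon
enumeration up to combined n = 10; 500 simulated plates for slope/LLOD
recovery (slopes checked against the analytic expectation
`S·exp(noise_cv²/2)` — multiplicative lognormal noise shifts the mean
response by that factor, which is a property of the generator, not
estimator bias — and LLOD against the analytic intercept-dispersion
propagation including the small-sample `c4(4) ≈ 0.921` SD correction); and
200-seed ensembles at `digestion_cv ∈ {0.05, 0.15, 0.3}` for the
matrix-vs-SIL CV contrast, asserted on the ensemble (near
`digestion_cv ≈ noise_cv` a single 20-sample seed is within Monte-Carlo
noise of a tie, so a per-seed strict test would test the sample size, not
the claim).

## Known limitations

* No retention-time model, spectral-library intensity ranking, collision
  energy prediction, or vendor method export; collision energies are
  user-supplied metadata.
* Proteotypicity is assessed within the supplied FASTA set. For genuine
  whole-proteome uniqueness, supply the whole proteome.
* PTM-aware quantotypicity screening is limited to the residue-alphabet
  filter; variable-modification motifs are not screened.
* Units are explicit labels; the package never converts between prepared
  concentration and on-column amount.
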