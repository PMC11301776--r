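# surropep

Design and validation of **surrogate internal-standard (IS) peptide assays**
for targeted proteomics (MRM/SRM LC-MS/MS).

## The problem

Quantifying a human protein by bottom-up LC-MS/MS needs an internal
standard for every monitored peptide. Stable isotope-labeled (SIL) peptides
are the gold standard but are costly, slow to procure, and — being spiked
*after* proteolysis — cannot correct for sample-to-sample digestion
variability. A cheap alternative co-digests the sample with an undiluted
nonhuman matrix (e.g. fetal bovine serum) and uses the homologous bovine
tryptic peptide as the IS: it experiences the same digestion as the analyte,
so the efficiency factor cancels from the peak-area ratio.

`surropep` is for assay developers who want to build and validate such
panels in silico:

* **Design**: tryptic digestion (cleave after K/R, not before P), peptide
  monoisotopic mass / precursor and b/y fragment m/z / Kyte–Doolittle GRAVY,
  species-specificity screening, homology-anchored target/surrogate pairing
  through a BLOSUM62 global alignment, isobaric-conflict screening at
  quadrupole-resolution tolerances, similarity scoring
  `w_len·|Δlen| + w_gravy·|ΔGRAVY| + w_sub·substitutions`, and MRM
  transition lists with quantifier/qualifier roles.
* **Validation**: calibration fits of peak-area ratio *r* on nominal
  concentration *x* (`r = S·x + b`, optionally 1/x or 1/x² weighted), lower
  assay limits **LLOD = 3.3·σ/S** and **LLOQ = 10·σ/S** (σ = SD of the
  regression y-intercepts across analyses, S = mean slope), back-calculated
  concentrations `(r − b)/S`, ±15 %/±20 %(LLOQ) recovery–CV–RE acceptance
  rules with the ≥6-calibrator gate, and per-sample Wilcoxon comparison of
  two IS strategies.
* **Simulation**: seeded calibration plates, QC sets and study samples with
  multiplicative lognormal noise and a per-sample digestion-efficiency
  factor shared by analyte and co-digested matrix IS but not by a SIL
  spike — the structure that makes the co-digestion normalization claim
  testable.

Everything is data-frame first: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` views,
and a thin CLI (`exec/surropep`: `digest`, `design`, `validate`,
`simulate`) wraps the same functions for shell use.

## Worked example

Design a panel from the bundled two-species fixtures and inspect the
curated pairs:

```r
library(surropep)
library(dplyr)

plasma_panel() |>
  peptide_properties(sequence = "human_peptide") |>
  transmute(protein, human_peptide, bovine_peptide,
            mz_2plus = round_half_away(mz_2plus, 1),
            gravy = round_half_away(gravy, 2))
#> # A tibble: 7 × 5
#>   protein  human_peptide bovine_peptide mz_2plus gravy
#>   <chr>    <chr>         <chr>             <dbl> <dbl>
#> 1 ALB      LVNEVTEFAK    LVNELTEFAK         575.  0.17
#> 2 ALB      QTALVELVK     QTALVELLK          501.  0.69
#> 3 DBP      TSALSAK       TSALSDK            339.  0.17
#> 4 DBP      VLEPTLK       ILESTLK            400.  0.3
#> 5 SERPING1 FQPTLLTLPR    FHPTHLTMPR         593.  0.16
#> 6 ANXA1    GVDEATIIDILTK GVDEATIIEILTK      694.  0.55
#> 7 PRKDC    DQNILLGTTYR   DHHVLLGTTYR        647. -0.55
```

`mz_2plus` is the doubly protonated precursor m/z of the human peptide
(e.g. 575.3 for LVNEVTEFAK) and `gravy` its mean Kyte–Doolittle hydropathy;
close GRAVY values between partners proxy similar retention. The full
pipeline — digestion, specificity, homology mapping, isobaric screen,
scoring — runs with:

```r
fa <- panel_fasta_paths()
design <- design_panel(define_panel(read_fasta(fa["human"], "human"),
                                    read_fasta(fa["bovine"], "bovine")))
design
#> <panel_design> 7 candidate pair(s), 7 accepted, 0 excluded
```

Simulate a four-analysis plate, fit weighted calibration curves, and apply
the acceptance rules:

```r
cfg  <- simulation_config(seed = 20)
cal  <- calibration_ratios(simulate_calibration(cfg))
fits <- fit_calibrations(cal, weighting = "1/x^2")
tidy(lower_limits(fits))
#> # A tibble: 1 × 5
#>      sigma       S  llod  lloq n_analyses
#>      <dbl>   <dbl> <dbl> <dbl>      <int>
#> 1 0.000997 0.00997 0.330 1.000          4

v <- assess_calibrators(fits[["analysis_1"]],
                        filter(cal, analysis_id == "analysis_1"))
glance(v)
#> # A tibble: 1 × 3
#>   n_levels n_passing overall_pass
#>      <int>     <int> <lgl>
#> 1        9         7 TRUE
```

The intercept dispersion across the four analyses (σ ≈ 0.001 ratio units)
against the mean slope (≈ 0.01 per concentration unit) puts the detection
limit at 0.33 and the quantitation limit at 1.0 concentration units; seven
of nine calibrator levels meet the ±15 %/±20 % recovery, precision and
accuracy rules, clearing the six-calibrator gate. `autoplot(fits[[1]])`
draws the curve, `plot_recovery(v)` the acceptance band, and
`compare_methods()` contrasts matrix-IS vs SIL-IS concentrations per
sample.

See the methods vignette (`vignettes/surrogate-is-assays.Rmd`) for the
model, parameter rationale, and what the simulator does and does not
emulate.

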