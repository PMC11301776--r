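# Curated reference panel: species-specific human quantotypic peptides for
# five plasma proteins with their bovine surrogate-IS counterparts, as used
# throughout the examples and the bundled synthetic mini-proteome FASTA
# fixtures (inst/extdata/*_panel_synthetic.fasta, which embed these peptides
# in minimal concatenated "mini-proteins").

#' Curated human/bovine surrogate peptide panel
#'
#' Seven target/surrogate peptide pairs covering serum albumin (ALB),
#' vitamin D binding protein (DBP), plasma protease C1 inhibitor (SERPING1),
#' annexin A1 (ANXA1) and DNA-dependent protein kinase catalytic subunit
#' (PRKDC). Each human peptide is proteotypic and absent from the bovine
#' proteome and vice versa; the bovine peptide sits at the homologous
#' position of the bovine ortholog. `quantifier_ion` gives the y-ion used
#' for quantitation of the lower-abundance analytes.
#'
#' @return Tibble: `protein`, `human_peptide`, `bovine_peptide`,
#'   `quantifier_series`, `quantifier_index`.
#' @examples
#' plasma_panel() |> peptide_properties(sequence = "human_peptide")
#' @export
plasma_panel <- function() {
  tibble::tribble(
    ~protein,   ~human_peptide,   ~bovine_peptide,  ~quantifier_series, ~quantifier_index,
    "ALB",      "LVNEVTEFAK",     "LVNELTEFAK",     "y", 6L,
    "ALB",      "QTALVELVK",      "QTALVELLK",      "y", 6L,
    "DBP",      "TSALSAK",        "TSALSDK",        "y", 5L,
    "DBP",      "VLEPTLK",        "ILESTLK",        "y", 5L,
    "SERPING1", "FQPTLLTLPR",     "FHPTHLTMPR",     "y", 4L,
    "ANXA1",    "GVDEATIIDILTK",  "GVDEATIIEILTK",  "y", 8L,
    "PRKDC",    "DQNILLGTTYR",    "DHHVLLGTTYR",    "y", 5L
  )
}

#' Paths to the bundled synthetic panel FASTA fixtures
#'
#' Minimal two-species mini-proteomes: each record concatenates the
#' [plasma_panel()] peptides of one protein so that tryptic digestion
#' recovers exactly those peptides. Synthetic constructions for examples and
#' tests, not UniProt sequences.
#'
#' @return Named character vector with elements `human` and `bovine`.
#' @export
panel_fasta_paths <- function() {
  c(
    human = system.file("extdata", "human_panel_synthetic.fasta",
                        package = "surropep"),
    bovine = system.file("extdata", "bovine_panel_synthetic.fasta",
                         package = "surropep")
  )
}
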