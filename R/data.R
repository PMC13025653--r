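# Bundled example data: the published 17-run corn-protein hydrolysis
# optimization experiment and its three candidate peptides.

#' Factor specification of the corn hydrolysis optimization
#'
#' The three hydrolysis factors varied in the bundled Box-Behnken
#' experiment: alkaline-protease dosage (1.0/1.25/1.5 % w/w), hydrolysis
#' time (1.5/2.25/3.0 h) and solid-liquid ratio (20/27.5/35 % w/v).
#'
#' @return A [bbd_factors()] object.
#' @export
corn_hydrolysis_factors <- function() {
  bbd_factors(c("enzyme_dosage", "hydrolysis_time", "solid_liquid_ratio"),
              low = c(1.0, 1.5, 20), high = c(1.5, 3.0, 35))
}

#' The corn hydrolysis Box-Behnken experiment
#'
#' The 17-run (12 edge + 5 center) design with four measured responses:
#' degree of hydrolysis `DH` (%), DPPH radical scavenging rate `DPPH` (%),
#' alcohol-dehydrogenase activation rate `ADH` (%) and xanthine-oxidase
#' inhibition rate `XOD` (%), as published for alkaline-protease hydrolysis
#' of corn germ meal.
#'
#' @return A `bbd_design` data.frame with 17 rows, the factor columns of
#'   [corn_hydrolysis_factors()] and the four response columns.
#' @examples
#' d <- corn_hydrolysis_design()
#' fit <- fit_quadratic(d, "DH")
#' anova(fit)
#' @export
corn_hydrolysis_design <- function() {
  path <- system.file("extdata", "corn_hydrolysis_bbd.tsv",
                      package = "peptriact", mustWork = TRUE)
  read_design_table(path, corn_hydrolysis_factors(), strict = TRUE)
}

#' The three candidate corn peptides
#'
#' Identification records of the peptides LMFP, FEGLFR and QLPSYR that
#' emerged from the published screening funnel: reported mass (Da),
#' retention time (min), relative peak area, external bioactivity score,
#' toxicity label and solubility label. No ALC value was reported for
#' these records, so the `alc` column is `NA`; screen them with the
#' lenient missing-data policy.
#'
#' @return A data.frame of 3 peptide records.
#' @export
corn_candidate_peptides <- function() {
  path <- system.file("extdata", "corn_candidate_peptides.csv",
                      package = "peptriact", mustWork = TRUE)
  read_peptide_table(path)
}
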