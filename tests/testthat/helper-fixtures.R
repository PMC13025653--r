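# shared fixtures built in code

corn_design <- corn_hydrolysis_design()
corn_factors <- corn_hydrolysis_factors()
corn_fits <- lapply(c("DH", "DPPH", "ADH", "XOD"),
                    function(r) fit_quadratic(corn_design, r))
names(corn_fits) <- c("DH", "DPPH", "ADH", "XOD")

# coded image of the published optimum (1.35 %, 2.30 h, 27.44 %)
opt_coded <- code_point(corn_factors, c(1.35, 2.30, 27.44))

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}
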