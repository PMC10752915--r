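# Small in-code fixtures shared across test files.

# cohort file with the canonical header and the given data lines
write_cohort_lines <- function(lines = character()) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- paste("sample_id", "sex", "age_years", "histology",
                  "localization", "methylation_class", "classifier_score",
                  "alteration", "detection_method", sep = "\t")
  writeLines(c(header, lines), path)
  path
}

cohort_line <- function(id, sex = "F", age = "5",
                        histology = "Pilocytic astrocytoma",
                        localization = "Posterior fossa",
                        methylation = "PA_PF (V11b4)", score = "0.99",
                        alteration = "KIAA1549:BRAF-fusion",
                        method = "DNA-methylation") {
  paste(id, sex, age, histology, localization, methylation, score,
        alteration, method, sep = "\t")
}

# a well with exact expected counts (rounded binomial means), useful when a
# test wants a near-noise-free measurement without randomness
exact_well <- function(tcf, assay = c("MUTATION", "DUPLICATION"),
                       n_droplets = 20000, g = 800,
                       v = plggtcf::DEFAULT_DROPLET_VOLUME_UL) {
  assay <- match.arg(assay)
  concs <- mixture_concentrations(tcf, assay, g)
  ks <- round(n_droplets * (1 - exp(-concs * v)))
  droplet_well("exact",
               assay = if (assay == "MUTATION") "MUT_DUPLEX" else "CNV_DUPLEX",
               positives = ks, total = n_droplets)
}

# four-stage trajectory with the given final TCF, transduced
classified_ready_trajectory <- function(final_tcf, sample_id = "S1",
                                        medium = "ABM") {
  build_trajectory(sample_id, medium, dplyr::bind_rows(
    culture_timepoint("P0", 0L, "NONE", 0.5),
    culture_timepoint("P1", 1L, medium, 0.5),
    culture_timepoint("TRANSDUCED", 3L, medium, 0.6),
    culture_timepoint("FINAL", 12L, medium, final_tcf)
  ))
}
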