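#' Patient cohort table (transcribed demographics)
#'
#' The packaged 11-patient mitochondrial-disease cohort: genetic diagnosis
#' (m.3243A>G, m.8344A>G or biallelic POLG variants), reported tissue
#' heteroplasmy (metadata only), sex, and age at death. Used for the
#' descriptive cohort statistics (mean age with t-based 95% CI) and the
#' sex-distribution comparison against the 16-subject control group
#' (5 female / 11 male).
#'
#' @return Tibble with columns `patient`, `genetic_diagnosis`,
#'   `heteroplasmy`, `sex`, `age_at_death`.
#' @examples
#' mean_ci_t(patient_cohort()$age_at_death)
#' @export
patient_cohort <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "mitophen",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Control-group sex counts for the cohort comparison
#'
#' 2x2 contingency table (rows: patient/control, columns: female/male) of
#' the study cohorts: 2 F / 9 M patients vs 5 F / 11 M controls.
#'
#' @return 2x2 integer matrix.
#' @export
cohort_sex_table <- function() {
  cohort <- patient_cohort()
  patients <- c(F = sum(cohort$sex == "F"), M = sum(cohort$sex == "M"))
  controls <- c(F = 5L, M = 11L)
  m <- rbind(patient = patients, control = controls)
  colnames(m) <- c("female", "male")
  m
}
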