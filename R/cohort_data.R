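#' Published characteristics of the study cohort
#'
#' The descriptive table of the twelve participants (age, body mass, stature,
#' BMI as printed, sport practiced, weekly training days) that the
#' synthetic-data generator's anthropometric defaults are anchored to.
#'
#' @return A data frame with one row per subject.
#' @export
#' @examples
#' sc <- subject_characteristics()
#' round(mean(sc$age_yr), 1)     # 22.7
#' round(mean(sc$body_mass_kg), 1)  # 77.5
subject_characteristics <- function() {
  path <- system.file("extdata", "subject_characteristics.tsv",
                      package = "primetrial")
  if (!nzchar(path)) {
    # fall back for un-installed source layouts (tests via pkgload)
    path <- file.path("inst", "extdata", "subject_characteristics.tsv")
  }
  utils::read.delim(path, check.names = FALSE)
}

#' Recompute BMI from mass and stature
#'
#' @param mass_kg Body mass in kg.
#' @param stature_cm Stature in cm.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(mass_kg, stature_cm) mass_kg / (stature_cm / 100)^2
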