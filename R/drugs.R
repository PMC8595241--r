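#' Packaged stimulant drug models
#'
#' Published dosing, bioavailability and target-profile values for the
#' lisdexamfetamine (LDX) and methylphenidate (MPH) formulations of the
#' ADHD case study:
#' \itemize{
#'   \item \code{ldx_adult}: LDX 70 mg, immediate release, F = 0.964.
#'   \item \code{ldx_pediatric}: LDX 50 mg, immediate release, F = 0.964.
#'   \item \code{mph_adult}: modified-release MPH 60 mg, F = 0.30,
#'     approximated as two administrations of half the dose 4 h apart.
#'   \item \code{mph_pediatric}: osmotic-release MPH 36 mg, F = 0.32,
#'     approximated as three administrations of one third 4 h apart.
#' }
#' LDX targets: TAAR1 (+1), SLC18A2, SLC6A3, SLC6A2, SLC6A4, MAOA, MAOB
#' (all -1). MPH targets: SLC6A3, SLC6A2 (-1), HTR1A (+1). EC50 values are
#' not published; the catalog leaves them \code{NA} for the user to supply
#' (or uses \code{defaultEC50} when given).
#'
#' @param name catalog entry name.
#' @param defaultEC50 EC50 (mg/L) applied to every target when supplied.
#' @return A [DrugModel-class].
#' @export
drugCatalog <- function(name = c("ldx_adult", "ldx_pediatric", "mph_adult",
                                 "mph_pediatric"),
                        defaultEC50 = NA_real_) {
  name <- match.arg(name)
  ldxTargets <- data.frame(
    protein = c("TAAR1", "SLC18A2", "SLC6A3", "SLC6A2", "SLC6A4", "MAOA", "MAOB"),
    effect = c(1, -1, -1, -1, -1, -1, -1))
  mphTargets <- data.frame(
    protein = c("SLC6A3", "SLC6A2", "HTR1A"),
    effect = c(-1, -1, 1))
  spec <- switch(name,
    ldx_adult = list(drug = "LDX", dose = 70, F = 0.964,
                     release = "immediate", targets = ldxTargets),
    ldx_pediatric = list(drug = "LDX", dose = 50, F = 0.964,
                         release = "immediate", targets = ldxTargets),
    mph_adult = list(drug = "MPH", dose = 60, F = 0.30,
                     release = "split2", targets = mphTargets),
    mph_pediatric = list(drug = "MPH", dose = 36, F = 0.32,
                         release = "split3", targets = mphTargets))
  spec$targets$ec50 <- defaultEC50
  drugModel(spec$drug, spec$dose, spec$F, spec$release, 4, spec$targets)
}
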