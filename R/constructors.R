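#' Build a demographic reference
#'
#' @param age,height,weight,bmi numeric length-2 vectors \code{c(mean, sd)},
#'   or \code{NULL} when the reference trial does not report the variable
#'   (its moments are then filled from a standard population table at
#'   generation time).
#' @param sexFemaleFraction proportion of females in [0, 1].
#' @param nReference reference population size.
#' @param label provenance label.
#' @return A [DemographicReference-class] object.
#' @examples
#' demographicReference(age = c(36.58, 10.10), height = c(171.7, 9.4),
#'                      weight = c(78.75, 17.20), sexFemaleFraction = 0.416,
#'                      nReference = 511)
#' @export
demographicReference <- function(age = NULL, height = NULL, weight = NULL,
                                 bmi = NULL, sexFemaleFraction,
                                 nReference = NA_real_, label = "") {
  given <- list(age = age, height = height, weight = weight, bmi = bmi)
  rows <- lapply(ANTHRO_VARS, function(v) {
    x <- given[[v]]
    if (is.null(x)) {
      data.frame(name = v, mean = NA_real_, sd = NA_real_, available = FALSE)
    } else {
      stopifnot(length(x) == 2L, is.finite(x))
      data.frame(name = v, mean = x[1], sd = x[2], available = TRUE)
    }
  })
  new("DemographicReference", variables = do.call(rbind, rows),
      sexFemaleFraction = sexFemaleFraction,
      nReference = as.numeric(nReference), label = label)
}

#' Build a growth reference from a long-format table
#'
#' @param table data.frame with columns \code{age} (integer years),
#'   \code{sex} ("F"/"M"), \code{variable} ("height"/"weight"),
#'   \code{mean}, \code{sd}.
#' @return A [GrowthReference-class] object.
#' @seealso [readGrowthReference()] to load from a tab-separated file,
#'   [synthGrowthReference()] for the bundled synthetic grid.
#' @export
growthReference <- function(table) new("GrowthReference", table = table)

#' Look up one age-sex cell of a growth reference
#'
#' Ages are matched to the nearest covered integer age.
#'
#' @param growth a [GrowthReference-class].
#' @param age age in years (any real value; rounded to the nearest covered
#'   integer).
#' @param sex "F" or "M".
#' @param variable "height" or "weight".
#' @return list with \code{mean} and \code{sd}.
#' @export
growthLookup <- function(growth, age, sex, variable) {
  t <- growth@table
  sub <- t[t$sex == sex & t$variable == variable, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("growth table does not cover sex ", sex, ", variable ", variable)
  a <- sub$age[which.min(abs(sub$age - round(age)))]
  if (abs(a - age) > 1)
    stop("growth table has a coverage gap near age ", round(age, 2))
  row <- sub[sub$age == a, , drop = FALSE][1L, ]
  list(mean = row$mean, sd = row$sd)
}

#' Build a drug model
#'
#' @param drug drug identifier.
#' @param doseMg total dose (mg).
#' @param bioavailability oral bioavailability F in (0, 1].
#' @param release "immediate", "split2" or "split3" (repeated lower-dose
#'   approximation of an extended-release formulation).
#' @param doseIntervalH interval between split administrations (h).
#' @param targets data.frame with columns \code{protein}, \code{effect}
#'   (+1/-1) and optionally \code{ec50} (mg/L).
#' @return A [DrugModel-class] object.
#' @export
drugModel <- function(drug, doseMg, bioavailability, release = "immediate",
                      doseIntervalH = 4, targets = data.frame()) {
  new("DrugModel", drug = drug, doseMg = doseMg,
      bioavailability = bioavailability, release = release,
      doseIntervalH = doseIntervalH, targets = targets)
}

#' Build a disease definition
#'
#' @param name condition name.
#' @param proteins data.frame with columns \code{protein} and \code{sign}
#'   (+1/-1), or a named numeric vector of signs.
#' @return A [DiseaseDefinition-class] object.
#' @export
diseaseDefinition <- function(name, proteins) {
  if (is.numeric(proteins) && !is.null(names(proteins)))
    proteins <- data.frame(protein = names(proteins), sign = unname(proteins))
  new("DiseaseDefinition", name = name, proteins = proteins)
}

#' Build a protein network from an edge list
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (+1/-1), \code{weight} (> 0).
#' @param nodes optional node universe; defaults to the union of endpoints.
#' @return A [ProteinNetwork-class] object.
#' @export
proteinNetwork <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  new("ProteinNetwork", nodes = as.character(nodes), edges = edges)
}

#' Build a training set
#'
#' @param ... entries, each a \code{list(drug =, condition =, direction =)}.
#' @return A [TrainingSet-class] object.
#' @export
trainingSet <- function(...) new("TrainingSet", entries = list(...))

#' Build a dosing scheme
#'
#' @param drug drug identifier.
#' @param times event times (h), non-decreasing.
#' @param amounts event amounts (mg).
#' @param route "gut", "blood" or "skin".
#' @return A [DosingScheme-class] object.
#' @export
dosingScheme <- function(drug, times, amounts, route = "gut") {
  new("DosingScheme", route = route, drug = drug,
      events = data.frame(time_h = times, amount_mg = amounts))
}

## ---- accessors ----

#' @describeIn VirtualPopulation-class patient table accessor
#' @param object,x a \code{VirtualPopulation}
#' @export
patients <- function(x) {
  stopifnot(is(x, "VirtualPopulation"))
  x@patients
}

#' Number of patients / solutions in a container
#' @param x a \code{VirtualPopulation} or \code{SolutionEnsemble}.
#' @export
setMethod("length", "VirtualPopulation", function(x) nrow(x@patients))

#' @rdname length-VirtualPopulation-method
#' @export
setMethod("length", "SolutionEnsemble", function(x) ncol(x@activities))

#' Activity matrix accessor (proteins x solutions)
#' @param x a \code{SolutionEnsemble}.
#' @export
activities <- function(x) {
  stopifnot(is(x, "SolutionEnsemble"))
  x@activities
}

#' Per-solution training-set accuracy accessor
#' @param x a \code{SolutionEnsemble}.
#' @export
solutionAccuracies <- function(x) {
  stopifnot(is(x, "SolutionEnsemble"))
  x@accuracy
}

## ---- show methods ----

setMethod("show", "DemographicReference", function(object) {
  v <- object@variables
  cat(sprintf("DemographicReference%s (n = %s, %.1f%% F)\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              format(object@nReference), 100 * object@sexFemaleFraction))
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-7s %s\n", v$name[i],
                if (v$available[i]) sprintf("%.2f +/- %.2f", v$mean[i], v$sd[i])
                else "(fill from standard table)"))
})

setMethod("show", "VirtualPopulation", function(object) {
  p <- object@patients
  cat(sprintf("VirtualPopulation: %d %s patients (seed %d)\n",
              nrow(p), object@populationKind, object@seed))
  cat(sprintf("  age %.2f +/- %.2f y; height %.1f +/- %.1f cm; weight %.1f +/- %.1f kg; %.1f%% F\n",
              mean(p$age), stats::sd(p$age), mean(p$height_cm), stats::sd(p$height_cm),
              mean(p$weight_kg), stats::sd(p$weight_kg), 100 * mean(p$sex == "F")))
  if (any(nzchar(p$arm_id)))
    cat("  arms:", paste(sprintf("%s(%d)", names(table(p$arm_id)),
                                 as.vector(table(p$arm_id))), collapse = " "), "\n")
})

setMethod("show", "ProteinNetwork", function(object) {
  cat(sprintf("ProteinNetwork: %d proteins, %d signed edges (%d activating, %d inhibiting)\n",
              length(object@nodes), nrow(object@edges),
              sum(object@edges$sign > 0), sum(object@edges$sign < 0)))
})

setMethod("show", "SolutionEnsemble", function(object) {
  cat(sprintf("SolutionEnsemble: patient %s, drug %s, %d solutions over %d proteins\n",
              object@patientId, object@drugId, ncol(object@activities),
              nrow(object@activities)))
  cat(sprintf("  accuracy %.1f-%.1f%%; %d candidates rejected\n",
              min(object@accuracy), max(object@accuracy), object@rejections))
})

setMethod("show", "ConcentrationProfile", function(object) {
  cat(sprintf("ConcentrationProfile: %d timepoints over %.1f h, %d compartments\n",
              length(object@time), max(object@time), ncol(object@concentrations)))
  cb <- object@concentrations[, "blood"]
  cat(sprintf("  blood Cmax %.4g mg/L at t = %.1f h\n",
              max(cb), object@time[which.max(cb)]))
})

setMethod("show", "PowerCurve", function(object) {
  cat(sprintf("PowerCurve: %d sample sizes (n = %d..%d), %d reps each, max accuracy %.3f\n",
              nrow(object@grid), min(object@grid$n), max(object@grid$n),
              object@reps, object@maxAccuracy))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult: k = %d over %d solutions (silhouette %.3f, Hopkins %.3f)\n",
              object@k, length(object@labels),
              object@indices$silhouette, object@indices$hopkins))
})

setMethod("show", "TrimmedDefinition", function(object) {
  cat(sprintf("TrimmedDefinition: %d proteins retained, rho %.3f (full-set rho %.3f)\n",
              nrow(object@definition@proteins), object@rho, object@rhoFull))
})
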