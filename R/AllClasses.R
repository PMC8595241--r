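#' @import methods
NULL

ANTHRO_VARS <- c("age", "height", "weight", "bmi")

#' Reference demographic summary of a trial population
#'
#' Summary statistics (mean, SD per anthropometric variable, and the female
#' sex fraction) of the real population a virtual population should mimic.
#' Variables are any of \code{age} (years), \code{height} (cm),
#' \code{weight} (kg) and \code{bmi} (kg/m^2); a variable can be flagged
#' unavailable, in which case moments are filled from a standard
#' population table at generation time.
#'
#' @slot variables data.frame with columns \code{name}, \code{mean},
#'   \code{sd}, \code{available}.
#' @slot sexFemaleFraction proportion of females in [0, 1].
#' @slot nReference size of the reference population.
#' @slot label free-text provenance label.
#' @export
setClass("DemographicReference",
  representation(variables = "data.frame", sexFemaleFraction = "numeric",
                 nReference = "numeric", label = "character"),
  prototype(label = ""))

setValidity("DemographicReference", function(object) {
  v <- object@variables
  msg <- character()
  if (!all(c("name", "mean", "sd", "available") %in% names(v)))
    msg <- c(msg, "variables needs columns name, mean, sd, available")
  else {
    if (!all(v$name %in% ANTHRO_VARS))
      msg <- c(msg, sprintf("variable names must be among %s",
                            paste(ANTHRO_VARS, collapse = ", ")))
    if (anyDuplicated(v$name)) msg <- c(msg, "duplicated variable names")
    av <- v[v$available, , drop = FALSE]
    if (nrow(av) == 0L) msg <- c(msg, "at least one variable must be available")
    if (any(!is.finite(av$mean)) || any(!is.finite(av$sd)) || any(av$sd < 0))
      msg <- c(msg, "available variables need finite mean and sd >= 0")
  }
  f <- object@sexFemaleFraction
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    msg <- c(msg, "sexFemaleFraction must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Age- and sex-conditional growth reference
#'
#' Long-format table of morphometric means and SDs by integer age and sex,
#' in the style of WHO growth references. Used as the standard population
#' distribution for pediatric-adolescent population generation.
#'
#' @slot table data.frame with columns \code{age}, \code{sex} ("F"/"M"),
#'   \code{variable}, \code{mean}, \code{sd}.
#' @export
setClass("GrowthReference", representation(table = "data.frame"))

setValidity("GrowthReference", function(object) {
  t <- object@table
  need <- c("age", "sex", "variable", "mean", "sd")
  if (!all(need %in% names(t))) return("table needs age, sex, variable, mean, sd")
  if (any(t$sd <= 0)) return("growth sd must be > 0")
  for (s in c("F", "M")) for (v in unique(t$variable)) {
    ages <- t$age[t$sex == s & t$variable == v]
    if (!all(6:17 %in% ages))
      return(sprintf("growth table must cover ages 6-17 for sex %s, variable %s", s, v))
  }
  TRUE
})

#' A virtual population
#'
#' Set of virtual patients with joint demographics matching a reference,
#' plus arm assignment and comorbidity tags once allocated.
#'
#' @slot patients data.frame with columns \code{id}, \code{sex},
#'   \code{age}, \code{height_cm}, \code{weight_kg}, \code{bmi},
#'   \code{arm_id}, \code{tags} (comma-separated condition names).
#' @slot populationKind "adult" (age > 18) or "pediatric" (6-17).
#' @slot seed integer seed the generator consumed.
#' @slot provenance list: reference label, validation table, generator
#'   settings.
#' @export
setClass("VirtualPopulation",
  representation(patients = "data.frame", populationKind = "character",
                 seed = "integer", provenance = "list"),
  prototype(provenance = list()))

setValidity("VirtualPopulation", function(object) {
  p <- object@patients
  need <- c("id", "sex", "age", "height_cm", "weight_kg", "bmi", "arm_id", "tags")
  msg <- character()
  if (!all(need %in% names(p))) return(paste("patients needs columns:",
                                             paste(need, collapse = ", ")))
  if (nrow(p) == 0L) msg <- c(msg, "population is empty")
  if (!object@populationKind %in% c("adult", "pediatric"))
    msg <- c(msg, "populationKind must be 'adult' or 'pediatric'")
  if (nrow(p) > 0L) {
    if (any(p$height_cm <= 0) || any(p$weight_kg <= 0))
      msg <- c(msg, "height and weight must be positive")
    bmi <- p$weight_kg / (p$height_cm / 100)^2
    if (any(abs(bmi - p$bmi) > 1e-6 * pmax(bmi, 1)))
      msg <- c(msg, "bmi must equal weight/(height/100)^2 within 1e-6 relative")
    if (object@populationKind == "adult" && any(p$age <= 18))
      msg <- c(msg, "adult population requires age > 18")
    if (object@populationKind == "pediatric" && any(p$age < 6 | p$age > 17))
      msg <- c(msg, "pediatric population requires ages in [6, 17]")
    if (!all(p$sex %in% c("F", "M"))) msg <- c(msg, "sex must be 'F' or 'M'")
  }
  if (length(msg)) msg else TRUE
})

#' Drug model: dosing, bioavailability and molecular target profile
#'
#' Everything the pipeline needs to know about one drug: total oral dose,
#' bioavailability, release formulation (how an extended-release product is
#' approximated by repeated lower doses), and the signed target profile
#' with per-target EC50s for the exposure-to-modulation step.
#'
#' @slot drug drug identifier.
#' @slot doseMg total dose per administration cycle (mg).
#' @slot bioavailability oral bioavailability F in (0, 1].
#' @slot release one of "immediate", "split2" (two administrations of half
#'   the dose) or "split3" (three administrations of one third).
#' @slot doseIntervalH interval between split administrations (h).
#' @slot targets data.frame with columns \code{protein},
#'   \code{effect} (+1 activation / -1 inhibition), \code{ec50} (mg/L).
#' @export
setClass("DrugModel",
  representation(drug = "character", doseMg = "numeric",
                 bioavailability = "numeric", release = "character",
                 doseIntervalH = "numeric", targets = "data.frame"),
  prototype(release = "immediate", doseIntervalH = 4))

setValidity("DrugModel", function(object) {
  msg <- character()
  if (!(object@bioavailability > 0 && object@bioavailability <= 1))
    msg <- c(msg, "bioavailability must be in (0, 1]")
  if (!object@release %in% c("immediate", "split2", "split3"))
    msg <- c(msg, "release must be immediate, split2 or split3")
  if (object@doseMg <= 0) msg <- c(msg, "doseMg must be > 0")
  t <- object@targets
  if (nrow(t) > 0L) {
    if (!all(c("protein", "effect") %in% names(t)))
      msg <- c(msg, "targets needs protein and effect columns")
    else if (!all(t$effect %in% c(-1, 1)))
      msg <- c(msg, "target effects must be +1 or -1")
  }
  if (length(msg)) msg else TRUE
})

#' Dosing scheme: administration events for one drug
#'
#' @slot route "gut" (oral), "blood" (intravenous) or "skin" (subcutaneous).
#' @slot events data.frame with columns \code{time_h}, \code{amount_mg}.
#' @slot drug drug identifier.
#' @export
setClass("DosingScheme",
  representation(route = "character", events = "data.frame", drug = "character"))

setValidity("DosingScheme", function(object) {
  msg <- character()
  if (!object@route %in% c("gut", "blood", "skin"))
    msg <- c(msg, "route must be gut, blood or skin")
  e <- object@events
  if (!all(c("time_h", "amount_mg") %in% names(e)))
    msg <- c(msg, "events needs time_h and amount_mg")
  else {
    if (any(e$amount_mg <= 0)) msg <- c(msg, "amounts must be > 0")
    if (is.unsorted(e$time_h)) msg <- c(msg, "event times must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated per-compartment concentration profile
#'
#' @slot time output time grid (h).
#' @slot concentrations matrix, time x compartment, mg/L.
#' @slot cleared matrix, time x clearance site, cumulative cleared mg.
#' @slot depot amount not yet absorbed at each time (mg).
#' @slot params the \code{PBPKParams} used.
#' @slot scheme the \code{DosingScheme} simulated.
#' @export
setClass("ConcentrationProfile",
  representation(time = "numeric", concentrations = "matrix",
                 cleared = "matrix", depot = "numeric",
                 params = "ANY", scheme = "ANY"))

setValidity("ConcentrationProfile", function(object) {
  msg <- character()
  if (min(object@concentrations) < -1e-9) msg <- c(msg, "negative concentrations")
  if (nrow(object@concentrations) != length(object@time))
    msg <- c(msg, "concentration rows must match time grid")
  d <- apply(object@cleared, 2, function(x) min(diff(x)))
  if (length(d) && min(d) < -1e-9) msg <- c(msg, "cumulative clearance must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Individualized PBPK parameter set
#'
#' @slot volumes named numeric, compartment volumes (L).
#' @slot flows named numeric, blood flow to each peripheral compartment (L/h).
#' @slot cardiacOutput total cardiac output (L/h).
#' @slot ka first-order absorption rate constant (1/h).
#' @slot clearance named numeric, first-order clearance rate constants (1/h)
#'   at the gut, liver and kidney sites (applied to blood-borne drug).
#' @slot bioavailability F in (0, 1].
#' @slot bloodVolAdj multiplier readjusting blood volume to the compound's
#'   volume of distribution.
#' @export
setClass("PBPKParams",
  representation(volumes = "numeric", flows = "numeric",
                 cardiacOutput = "numeric", ka = "numeric",
                 clearance = "numeric", bioavailability = "numeric",
                 bloodVolAdj = "numeric"),
  prototype(bloodVolAdj = 1))

setValidity("PBPKParams", function(object) {
  msg <- character()
  if (any(object@volumes <= 0)) msg <- c(msg, "volumes must be > 0")
  if (any(object@flows < 0)) msg <- c(msg, "flows must be >= 0")
  if (sum(object@flows) > object@cardiacOutput * (1 + 1e-8))
    msg <- c(msg, "sum of organ flows exceeds cardiac output")
  if (!(object@bioavailability > 0 && object@bioavailability <= 1))
    msg <- c(msg, "bioavailability must be in (0, 1]")
  if (!"blood" %in% names(object@volumes)) msg <- c(msg, "volumes must include blood")
  if (length(msg)) msg else TRUE
})

#' Signed, weighted protein functional network
#'
#' Directed network over protein identifiers; each edge carries a sign
#' (+1 activating, -1 inhibiting) and a positive weight. Backs the
#' activity-propagation surrogate for mechanism-of-action modeling.
#'
#' @slot nodes protein identifiers.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign}, \code{weight}.
#' @export
setClass("ProteinNetwork",
  representation(nodes = "character", edges = "data.frame"))

setValidity("ProteinNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("source", "target", "sign", "weight") %in% names(e)))
    return("edges needs source, target, sign, weight")
  if (nrow(e) > 0L) {
    if (!all(e$sign %in% c(-1, 1))) msg <- c(msg, "edge signs must be +1/-1")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      msg <- c(msg, "edge weights must be finite and > 0")
    if (any(e$source == e$target)) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$source, e$target) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Signed disease protein definition
#'
#' The molecular definition of a disease or comorbidity: the proteins whose
#' activity characterizes the condition, each with its pathological sign
#' v_i (+1 abnormally active, -1 abnormally inactive). The tSignal efficacy
#' statistic is evaluated over this set.
#'
#' @slot name condition name.
#' @slot proteins data.frame with columns \code{protein}, \code{sign}.
#' @export
setClass("DiseaseDefinition",
  representation(name = "character", proteins = "data.frame"))

setValidity("DiseaseDefinition", function(object) {
  p <- object@proteins
  if (!all(c("protein", "sign") %in% names(p)))
    return("proteins needs protein and sign columns")
  if (nrow(p) == 0L) return("definition must be non-empty")
  if (anyDuplicated(p$protein)) return("duplicate proteins in definition")
  if (!all(p$sign %in% c(-1, 1))) return("signs must be +1 or -1")
  TRUE
})

#' Training set of drug-pathophysiology relationships
#'
#' Known directional relationships used to gate solution quality: each
#' entry says that stimulating the network with a drug's target profile
#' should move the tSignal of a condition in a stated direction.
#'
#' @slot entries list of lists with elements \code{drug} (a
#'   \code{DrugModel}), \code{condition} (a \code{DiseaseDefinition}) and
#'   \code{direction} (+1 expected tSignal increase, -1 decrease).
#' @export
setClass("TrainingSet", representation(entries = "list"))

setValidity("TrainingSet", function(object) {
  if (length(object@entries) == 0L) return("training set must be non-empty")
  ok <- vapply(object@entries, function(e)
    is(e$drug, "DrugModel") && is(e$condition, "DiseaseDefinition") &&
      e$direction %in% c(-1, 1), logical(1))
  if (!all(ok)) return("each entry needs drug, condition, direction in {-1, +1}")
  TRUE
})

#' Ensemble of protein-activity solutions for one patient and drug
#'
#' One mathematical solution is a protein -> activity map with values in
#' (-1, 1); an ensemble of at least \code{ensembleMin} solutions, each with
#' training-set accuracy at or above the accuracy floor, represents the
#' intra-patient variability of the mechanism-of-action model.
#'
#' @slot patientId patient identifier.
#' @slot drugId drug identifier.
#' @slot activities matrix, proteins x solutions, each value in (-1, 1).
#' @slot accuracy per-solution training-set accuracy, percent.
#' @slot modulation named per-target modulation used as the stimulus.
#' @slot rejections number of candidate solutions discarded by the gate.
#' @slot converged per-solution propagation convergence flag.
#' @export
setClass("SolutionEnsemble",
  representation(patientId = "character", drugId = "character",
                 activities = "matrix", accuracy = "numeric",
                 modulation = "numeric", rejections = "numeric",
                 converged = "logical"))

setValidity("SolutionEnsemble", function(object) {
  msg <- character()
  a <- object@activities
  if (ncol(a) < 1L) msg <- c(msg, "ensemble must hold at least one solution")
  if (length(a) && (max(a) >= 1 || min(a) <= -1))
    msg <- c(msg, "activities must lie strictly inside (-1, 1)")
  if (length(object@accuracy) != ncol(a))
    msg <- c(msg, "one accuracy per solution required")
  if (length(msg)) msg else TRUE
})

#' Progressive-sampling power curve
#'
#' Accuracy of a two-feature linear classifier as a function of (total,
#' balanced) sample size, with normal-approximation power quantiles
#' expressed as a percentage of the maximum achievable accuracy.
#'
#' @slot grid data.frame with columns \code{n} (total samples),
#'   \code{mean_acc}, \code{sd_acc}, \code{pct_of_max_power95},
#'   \code{pct_of_max_power99}.
#' @slot maxAccuracy ceiling accuracy from the full data set.
#' @slot reps repetitions per sample size.
#' @export
setClass("PowerCurve",
  representation(grid = "data.frame", maxAccuracy = "numeric", reps = "numeric"))

setValidity("PowerCurve", function(object) {
  g <- object@grid
  need <- c("n", "mean_acc", "sd_acc", "pct_of_max_power95", "pct_of_max_power99")
  if (!all(need %in% names(g))) return(paste("grid needs:", paste(need, collapse = ", ")))
  if (nrow(g) && g$n[1] != 8) return("sample-size grid must start at 8")
  TRUE
})

#' Trimmed disease definition after correlation-driven optimization
#'
#' @slot definition the retained \code{DiseaseDefinition}.
#' @slot rho achieved Pearson correlation between per-drug mean tSignal and
#'   clinical efficacy.
#' @slot rhoFull correlation of the untrimmed definition.
#' @slot trace data.frame logging each removal (protein, rho after removal).
#' @export
setClass("TrimmedDefinition",
  representation(definition = "DiseaseDefinition", rho = "numeric",
                 rhoFull = "numeric", trace = "data.frame"))

setValidity("TrimmedDefinition", function(object) {
  if (abs(object@rho) < abs(object@rhoFull) - 1e-12)
    return("trimming must not decrease |rho|")
  TRUE
})

#' Linear mapping from tSignal to the clinical efficacy scale
#'
#' @slot intercept,slope OLS coefficients of ADHD-RS-IV change ~ tSignal.
#' @slot rho Pearson correlation of the fit.
#' @slot residualSd residual standard deviation.
#' @slot n number of paired points.
#' @export
setClass("EfficacyMapping",
  representation(intercept = "numeric", slope = "numeric", rho = "numeric",
                 residualSd = "numeric", n = "numeric"))

#' Clustering result with validation indices
#'
#' @slot k selected number of clusters.
#' @slot labels per-row cluster labels in 1..k.
#' @slot scores PCA score matrix used for clustering.
#' @slot explainedVariance per-component explained-variance fractions.
#' @slot indices list with elements \code{hopkins}, \code{silhouette},
#'   \code{jaccard} (per-cluster stability).
#' @slot perK data.frame of candidate-k diagnostics (k, silhouette,
#'   min/max size ratio, kept flag).
#' @export
setClass("ClusteringResult",
  representation(k = "numeric", labels = "integer", scores = "matrix",
                 explainedVariance = "numeric", indices = "list",
                 perK = "data.frame"))

setValidity("ClusteringResult", function(object) {
  ev <- object@explainedVariance
  if (any(ev > 1 + 1e-9) || is.unsorted(rev(ev)))
    return("explained-variance fractions must be <= 1 and non-increasing")
  if (length(object@labels) && !all(object@labels %in% seq_len(object@k)))
    return("labels must be in 1..k")
  TRUE
})
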