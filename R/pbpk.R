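#' Default 14-compartment model structure
#'
#' Hub-and-spoke whole-body structure: blood is the unique central
#' compartment exchanging with every organ; dosing can enter at the gut
#' (oral), blood (intravenous) or skin (subcutaneous); clearance is
#' restricted to the gut, liver and kidneys.
#'
#' @return list with \code{compartments}, \code{dosingSites},
#'   \code{clearanceSites}.
#' @export
pbpkCompartments <- function() {
  list(compartments = c("blood", "gut", "liver", "kidneys", "brain", "heart",
                        "lungs", "muscle", "adipose", "skin", "bone",
                        "spleen", "pancreas", "rest"),
       dosingSites = c("gut", "blood", "skin"),
       clearanceSites = c("gut", "liver", "kidneys"))
}

#' Default allometric scaling table
#'
#' Organ volumes as fixed fractions of body weight (L/kg) and organ blood
#' flows as fractions of cardiac output. The fractions are standard-order
#' physiological values assembled for this package (the model treats the
#' table as configurable data, not code); flow fractions sum to 1.
#'
#' @return data.frame with columns \code{compartment},
#'   \code{volume_per_kg}, \code{flow_fraction}.
#' @export
defaultAllometricTable <- function() {
  data.frame(
    compartment = c("blood", "gut", "liver", "kidneys", "brain", "heart",
                    "lungs", "muscle", "adipose", "skin", "bone", "spleen",
                    "pancreas", "rest"),
    volume_per_kg = c(0.075, 0.017, 0.026, 0.004, 0.020, 0.005, 0.008,
                      0.400, 0.190, 0.037, 0.086, 0.0026, 0.0014, 0.050),
    flow_fraction = c(NA, 0.15, 0.065, 0.19, 0.12, 0.04, 0.025, 0.17,
                      0.05, 0.05, 0.05, 0.03, 0.01, 0.05))
}

cardiacFrequency <- function(age, sex) {
  base <- if (age < 10) 90 else if (age <= 18) 80 else 70   # beats/min
  base + if (sex == "F") 5 else 0
}

#' Individualize PBPK parameters from patient demographics
#'
#' Volumes scale linearly with body weight through the allometric table
#' (the adipose compartment additionally scales with BMI relative to a
#' BMI of 24); flows are fractions of cardiac output, computed as cardiac
#' frequency (age- and sex-banded) times a weight-proportional stroke
#' volume (1 mL/kg). Bioavailability comes from the drug model.
#'
#' @param patient one-row patient data.frame (columns \code{sex},
#'   \code{age}, \code{height_cm}, \code{weight_kg}, \code{bmi}) or a
#'   list with those elements.
#' @param drug a [DrugModel-class].
#' @param allometric allometric table, see [defaultAllometricTable()].
#' @param ka absorption rate constant (1/h), typically from
#'   [fitAbsorptionClearance()].
#' @param clearance named clearance rate constants (1/h) for gut, liver,
#'   kidneys.
#' @param bloodVolAdj blood-volume multiplier fitting the compound's
#'   volume of distribution.
#' @return A [PBPKParams-class].
#' @export
individualizeParameters <- function(patient, drug,
                                    allometric = defaultAllometricTable(),
                                    ka = 1.0,
                                    clearance = c(gut = 0, liver = 0,
                                                  kidneys = 0.3),
                                    bloodVolAdj = 1) {
  p <- as.list(patient)
  stopifnot(!is.null(p$age), !is.null(p$weight_kg), !is.null(p$sex))
  if (p$age < 0 || p$age > 120) stop("age outside the allometric table coverage")
  bmi <- if (!is.null(p$bmi)) p$bmi else p$weight_kg / (p$height_cm / 100)^2
  vol <- allometric$volume_per_kg * p$weight_kg
  names(vol) <- allometric$compartment
  vol["adipose"] <- vol["adipose"] * bmi / 24
  hr <- cardiacFrequency(p$age, p$sex)
  co <- hr * 60 * (1.0 * p$weight_kg) / 1000          # L/h, SV = 1 mL/kg
  fl <- allometric$flow_fraction * co
  names(fl) <- allometric$compartment
  fl <- fl[!is.na(fl)]
  cl <- c(gut = 0, liver = 0, kidneys = 0)
  cl[names(clearance)] <- clearance
  new("PBPKParams", volumes = vol, flows = fl, cardiacOutput = co, ka = ka,
      clearance = cl, bioavailability = drug@bioavailability,
      bloodVolAdj = bloodVolAdj)
}

#' Expand a drug's release type into a dosing scheme
#'
#' Extended-release formulations are approximated by repeated
#' administration of lower doses: "split2" gives two administrations of
#' half the dose, "split3" three administrations of one third, separated
#' by the drug's dose interval (default 4 h); "immediate" gives a single
#' administration at t = 0.
#'
#' @param drug a [DrugModel-class].
#' @param totalDose total dose (mg); defaults to the drug's dose.
#' @return A [DosingScheme-class] (oral route).
#' @examples
#' conc36 <- drugModel("MPH-oros", 36, 0.32, release = "split3")
#' expandExtendedRelease(conc36)  # 12 mg at 0, 4 and 8 h
#' @export
expandExtendedRelease <- function(drug, totalDose = drug@doseMg) {
  stopifnot(totalDose > 0)
  k <- switch(drug@release, immediate = 1L, split2 = 2L, split3 = 3L,
              stop("unknown release type: ", drug@release))
  dosingScheme(drug@drug, times = drug@doseIntervalH * (seq_len(k) - 1L),
               amounts = rep(totalDose / k, k))
}

#' Simulate the whole-body concentration profile
#'
#' Integrates the linear ODE system of the 14-compartment model: oral or
#' subcutaneous doses enter a first-order absorption depot (scaled by
#' bioavailability) feeding blood; blood exchanges with each organ by
#' flow-limited transport (unit partition coefficients by default); drug
#' is eliminated first-order from blood-borne drug at the gut, liver and
#' kidney sites, bookkept per site. Intravenous doses enter blood
#' directly. Mass balance (depot + compartment amounts + cleared =
#' bioavailable administered dose) holds within integration tolerance at
#' all times.
#'
#' @param params a [PBPKParams-class].
#' @param scheme a [DosingScheme-class].
#' @param tEnd end of simulation (h), at or after the last dose.
#' @param dt output grid step (h).
#' @param spec compartment structure, see [pbpkCompartments()].
#' @param partition named partition coefficients (default 1 everywhere).
#' @param rtol,atol integration tolerances.
#' @return A [ConcentrationProfile-class].
#' @export
simulatePBPK <- function(params, scheme, tEnd, dt = 0.1,
                         spec = pbpkCompartments(), partition = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  ev <- scheme@events
  if (nrow(ev) && tEnd < max(ev$time_h))
    stop("tEnd must be at or after the last dosing event")
  comps <- spec$compartments
  periph <- setdiff(comps, "blood")
  sites <- spec$clearanceSites
  if (!scheme@route %in% spec$dosingSites)
    stop("dosing route must be one of: ", paste(spec$dosingSites, collapse = ", "))
  Kp <- stats::setNames(rep(1, length(periph)), periph)
  if (!is.null(partition)) Kp[names(partition)] <- partition
  vols <- params@volumes[comps]
  vols["blood"] <- vols["blood"] * params@bloodVolAdj
  if (any(is.na(vols))) stop("params lack volumes for some compartments")
  Q <- stats::setNames(rep(0, length(periph)), periph)
  Q[names(params@flows)] <- params@flows
  kcl <- stats::setNames(rep(0, length(sites)), sites)
  kcl[names(params@clearance)] <- params@clearance

  state <- stats::setNames(rep(0, 1 + length(comps) + length(sites)),
                           c("depot", comps, paste0("cleared_", sites)))
  deriv <- function(t, y, parms) {
    cb <- y["blood"] / vols["blood"]
    cp <- y[periph] / vols[periph]
    exch <- Q * (cb - cp / Kp[periph])          # blood -> organ net flux
    elim <- kcl * unname(y["blood"])            # per-site first-order on blood
    d <- numeric(length(y))
    names(d) <- names(y)
    d["depot"] <- -params@ka * y["depot"]
    d[periph] <- exch
    d["blood"] <- params@ka * y["depot"] - sum(exch) - sum(elim)
    d[paste0("cleared_", sites)] <- elim
    list(unname(d))
  }

  times <- sort(unique(c(seq(0, tEnd, by = dt), ev$time_h, tEnd)))
  F <- if (scheme@route == "blood") 1 else params@bioavailability
  events <- NULL
  if (nrow(ev) > 0) {
    var <- if (scheme@route == "blood") "blood" else "depot"
    events <- list(data = data.frame(var = var, time = ev$time_h,
                                     value = F * ev$amount_mg, method = "add"))
  }
  sol <- deSolve::lsoda(state, times, deriv, parms = NULL, rtol = rtol,
                        atol = atol, events = events)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  sol <- as.data.frame(sol)
  amounts <- as.matrix(sol[comps])
  if (min(amounts) < -1e-6) stop("integration produced negative amounts")
  amounts[amounts < 0] <- 0
  conc <- sweep(amounts, 2, vols[comps], "/")
  cleared <- as.matrix(sol[paste0("cleared_", sites)])
  colnames(cleared) <- sites
  new("ConcentrationProfile", time = sol$time, concentrations = conc,
      cleared = cleared, depot = pmax(sol$depot, 0), params = params,
      scheme = scheme)
}

#' Verify mass balance of a simulated profile
#'
#' At every output time, depot + sum of compartment amounts + cumulative
#' cleared must equal the bioavailable fraction of the dose administered
#' so far.
#'
#' @param profile a [ConcentrationProfile-class].
#' @return maximum relative deviation over the grid (fraction of the total
#'   bioavailable dose).
#' @export
massBalanceError <- function(profile) {
  params <- profile@params
  scheme <- profile@scheme
  vols <- params@volumes[colnames(profile@concentrations)]
  vols["blood"] <- vols["blood"] * params@bloodVolAdj
  inSystem <- profile@depot +
    rowSums(sweep(profile@concentrations, 2, vols, "*")) +
    rowSums(profile@cleared)
  F <- if (scheme@route == "blood") 1 else params@bioavailability
  ## solver output at an event time is the pre-bolus state, so a dose only
  ## counts as administered strictly after its event time
  administered <- vapply(profile@time, function(t)
    F * sum(scheme@events$amount_mg[scheme@events$time_h < t - 1e-9]),
    numeric(1))
  total <- F * sum(scheme@events$amount_mg)
  if (total == 0) return(max(abs(inSystem)))
  max(abs(inSystem - administered)) / total
}

#' Interpolate tissue concentrations at arbitrary times
#'
#' Linear interpolation on the solver output grid.
#'
#' @param profile a [ConcentrationProfile-class].
#' @param compartment compartment name.
#' @param times query times within the simulated range.
#' @return concentrations (mg/L) at \code{times}.
#' @export
tissueTimepoints <- function(profile, compartment, times) {
  if (!compartment %in% colnames(profile@concentrations))
    stop("unknown compartment: ", compartment)
  if (any(times < min(profile@time) - 1e-9 | times > max(profile@time) + 1e-9))
    stop("query times outside the simulated range")
  stats::approx(profile@time, profile@concentrations[, compartment],
                xout = times, rule = 2)$y
}

#' Fit absorption, clearance and blood-volume adjustment to observed PK
#'
#' Least-squares fit of the blood concentration predicted by
#' [simulatePBPK()] to observed datapoints, over (ka, renal clearance,
#' blood-volume adjustment) on the log scale (Levenberg-Marquardt, fixed
#' starting point, hence deterministic). A near-flat objective (relative
#' parameter uncertainty above 10^3) is flagged with a degeneracy warning
#' carried in the result.
#'
#' @param params a [PBPKParams-class] template (its ka, clearance
#'   and bloodVolAdj slots are overwritten by the fit).
#' @param scheme a [DosingScheme-class].
#' @param obs data.frame with columns \code{time_h}, \code{conc_mg_per_L};
#'   at least 4 points.
#' @param start starting values \code{c(ka =, cl =, adj =)}.
#' @param clearanceSite which site carries the fitted clearance.
#' @param logScale fit residuals on the log-concentration scale; the right
#'   choice when observation noise is multiplicative (constant CV), as in
#'   most PK assays. Default FALSE (plain concentration-scale residuals).
#' @param dt simulation output step during fitting.
#' @return list with \code{estimates} (ka, cl, adj), \code{params} (the
#'   updated parameter set), \code{rmse}, \code{r2}, \code{degenerate}.
#' @export
fitAbsorptionClearance <- function(params, scheme, obs,
                                   start = c(ka = 1, cl = 0.2, adj = 1),
                                   clearanceSite = "kidneys",
                                   logScale = FALSE, dt = 0.1) {
  stopifnot(nrow(obs) >= 4)
  if (all(obs$conc_mg_per_L <= 0) || stats::sd(obs$conc_mg_per_L) == 0)
    stop("observations carry no signal to fit")
  tEnd <- max(obs$time_h, scheme@events$time_h)
  predict_ <- function(theta) {
    p <- params
    p@ka <- exp(theta[1])
    p@clearance[clearanceSite] <- exp(theta[2])
    p@bloodVolAdj <- exp(theta[3])
    prof <- simulatePBPK(p, scheme, tEnd, dt = dt)
    tissueTimepoints(prof, "blood", obs$time_h)
  }
  resid_ <- if (logScale) {
    if (any(obs$conc_mg_per_L <= 0))
      stop("log-scale fitting requires strictly positive observations")
    function(theta) log(pmax(predict_(theta), 1e-12)) - log(obs$conc_mg_per_L)
  } else function(theta) predict_(theta) - obs$conc_mg_per_L
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_,
                            control = minpack.lm::nls.lm.control(maxiter = 100))
  est <- exp(fit$par)
  names(est) <- c("ka", "cl", "adj")
  res <- predict_(fit$par) - obs$conc_mg_per_L
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sum((obs$conc_mg_per_L - mean(obs$conc_mg_per_L))^2)
  sv <- svd(fit$hessian)$d
  degenerate <- min(sv) < 1e-8 * max(sv)
  pOut <- params
  pOut@ka <- est["ka"]
  pOut@clearance[clearanceSite] <- est["cl"]
  pOut@bloodVolAdj <- est["adj"]
  if (degenerate)
    warning("fit objective is nearly flat in at least one parameter direction")
  list(estimates = est, params = pOut, rmse = rmse, r2 = r2,
       degenerate = degenerate, niter = fit$niter)
}
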