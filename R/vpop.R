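#' Standard population fill values
#'
#' Moments used to fill demographic variables the reference trial does not
#' report, in the role of a standard (e.g. European survey) population
#' distribution. The bundled values are synthetic round numbers of the
#' right order for a European adult population; replace with survey-derived
#' values for production use.
#'
#' @param kind "adult" or "pediatric".
#' @return data.frame with columns \code{name}, \code{mean}, \code{sd}.
#' @export
standardFillTable <- function(kind = c("adult", "pediatric")) {
  kind <- match.arg(kind)
  if (kind == "adult")
    data.frame(name = ANTHRO_VARS,
               mean = c(42, 170, 75, 25.8), sd = c(13, 9.5, 15, 4.6))
  else
    data.frame(name = ANTHRO_VARS,
               mean = c(11.5, 147, 42, 19.0), sd = c(3.3, 16, 15, 3.3))
}

resolveMoments <- function(reference, fill) {
  v <- reference@variables
  out <- data.frame(name = ANTHRO_VARS, mean = NA_real_, sd = NA_real_,
                    filled = FALSE)
  for (i in seq_along(ANTHRO_VARS)) {
    nm <- ANTHRO_VARS[i]
    row <- v[v$name == nm, , drop = FALSE]
    if (nrow(row) == 1L && row$available) {
      out$mean[i] <- row$mean; out$sd[i] <- row$sd
    } else if (!is.null(fill) && nm %in% fill$name) {
      j <- match(nm, fill$name)
      out$mean[i] <- fill$mean[j]; out$sd[i] <- fill$sd[j]
      out$filled[i] <- TRUE
    } else {
      stop("variable '", nm, "' is available neither in the reference nor ",
           "in the fill table")
    }
  }
  out
}

#' Build the multivariate normal specification for population sampling
#'
#' Assembles the mean vector and covariance matrix of the multivariate
#' normal distribution (MVND) whose marginals carry the reference means and
#' SDs. Variables the reference does not report are filled from the
#' standard-distribution table and flagged. BMI is never sampled (it is
#' derived from height and weight downstream) but its moments are resolved
#' here so downstream validation can target it.
#'
#' @param reference a [DemographicReference-class].
#' @param fill standard fill table (see [standardFillTable()]); \code{NULL}
#'   allowed when the reference reports every variable.
#' @param heightWeightCor correlation imposed between height and weight
#'   (the reference tables report no covariances).
#' @return list with elements \code{mean} (named, over age/height/weight),
#'   \code{cov} (symmetric positive semi-definite, diagonal = sd^2),
#'   \code{moments} (all four variables incl. BMI with \code{filled}
#'   flags).
#' @export
buildMVND <- function(reference, fill = NULL, heightWeightCor = 0.5) {
  m <- resolveMoments(reference, fill)
  samp <- c("age", "height", "weight")
  mu <- stats::setNames(m$mean[match(samp, m$name)], samp)
  sd <- stats::setNames(m$sd[match(samp, m$name)], samp)
  R <- diag(3)
  dimnames(R) <- list(samp, samp)
  R["height", "weight"] <- R["weight", "height"] <- heightWeightCor
  S <- diag(sd) %*% R %*% diag(sd)
  dimnames(S) <- list(samp, samp)
  list(mean = mu, cov = S, moments = m)
}

## truncated MVN draw: resample rows violating the plausibility bounds
drawAdults <- function(k, mvnd) {
  lo <- c(age = 18 + 1e-6, height = 100, weight = 25)
  out <- matrix(NA_real_, 0, 3, dimnames = list(NULL, names(mvnd$mean)))
  while (nrow(out) < k) {
    x <- MASS::mvrnorm(max(2L * (k - nrow(out)), 10L), mvnd$mean, mvnd$cov)
    if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(mvnd$mean)))
    keep <- x[, "age"] > lo["age"] & x[, "height"] > lo["height"] &
      x[, "weight"] > lo["weight"]
    out <- rbind(out, x[keep, , drop = FALSE])
  }
  out[seq_len(k), , drop = FALSE]
}

## standardized moment-mismatch cost over the targeted variables
momentCost <- function(X, moments) {
  cost <- 0
  bmi <- X[, "weight"] / (X[, "height"] / 100)^2
  vals <- cbind(X, bmi = bmi)
  for (i in seq_len(nrow(moments))) {
    nm <- moments$name[i]
    if (moments$filled[i] && nm == "bmi") next  # filled BMI is not a target
    x <- vals[, nm]
    s <- moments$sd[i]
    if (s == 0) next
    cost <- cost + ((mean(x) - moments$mean[i]) / s)^2
    if (nrow(vals) > 1L) cost <- cost + ((stats::sd(x) - s) / s)^2
  }
  cost
}

quotaFemales <- function(n, frac) as.integer(floor(n * frac + 0.5))

finishPopulation <- function(X, sexes, kind, seed, reference, val, extra = list()) {
  n <- nrow(X)
  patients <- data.frame(
    id = sprintf("%s-%04d", substr(kind, 1, 2), seq_len(n)),
    sex = sexes,
    age = X[, "age"],
    height_cm = X[, "height"],
    weight_kg = X[, "weight"],
    bmi = X[, "weight"] / (X[, "height"] / 100)^2,
    arm_id = "",
    tags = "",
    stringsAsFactors = FALSE)
  prov <- c(list(reference = reference@label,
                 validation = val), extra)
  new("VirtualPopulation", patients = patients, populationKind = kind,
      seed = as.integer(seed), provenance = prov)
}

#' Generate an adult virtual population
#'
#' Samples candidate patients from the reference-derived multivariate
#' normal distribution (truncated to adult ages > 18 and positive
#' anthropometry), then runs a simulated-annealing refinement that
#' repeatedly proposes replacing one patient with a fresh draw to minimize
#' the standardized mismatch of sample means and SDs against the reference.
#' A candidate population is only returned if every targeted variable
#' passes the one-sample z-test acceptance rule (p > alpha); otherwise the
#' generator restarts with a fresh sample.
#'
#' Sex is a quota variable (round-half-up on the reference female
#' fraction), not part of the MVND. BMI is derived from height and weight,
#' never sampled; when the reference reports BMI it enters the annealing
#' cost through the derived values.
#'
#' @param reference a [DemographicReference-class].
#' @param fill standard fill table for unreported variables.
#' @param n number of patients (>= 1).
#' @param seed integer seed; identical inputs and seed reproduce the
#'   population exactly.
#' @param annealIter annealing iterations per restart.
#' @param coolRate geometric cooling factor per iteration.
#' @param restarts maximum restarts before giving up.
#' @param alpha acceptance level of the z-test gate.
#' @param heightWeightCor see [buildMVND()].
#' @return A [VirtualPopulation-class]; its provenance carries the
#'   validation table and the number of restarts used.
#' @examples
#' ref <- synthReferencePopulation("adult")$reference
#' pop <- generateAdultVpop(ref, n = 100, seed = 7)
#' validatePopulation(pop, ref)
#' @export
generateAdultVpop <- function(reference, fill = standardFillTable("adult"),
                              n, seed, annealIter = 200, coolRate = 0.95,
                              restarts = 20, alpha = 0.05,
                              heightWeightCor = 0.5) {
  stopifnot(n >= 1)
  mvnd <- buildMVND(reference, fill, heightWeightCor)
  degenerate <- all(mvnd$moments$sd == 0)
  bestCost <- Inf
  res <- NULL
  withSeed(childSeed(seed, "adult-vpop"), {
    for (r in seq_len(restarts)) {
      X <- if (degenerate)
        matrix(rep(mvnd$mean, each = n), n, dimnames = list(NULL, names(mvnd$mean)))
      else drawAdults(n, mvnd)
      cost <- momentCost(X, mvnd$moments)
      temp <- max(cost, 1e-3)
      if (!degenerate) {
        for (it in seq_len(annealIter)) {
          i <- sample.int(n, 1L)
          cand <- X
          cand[i, ] <- drawAdults(1L, mvnd)
          newCost <- momentCost(cand, mvnd$moments)
          if (newCost < cost || stats::runif(1) < exp((cost - newCost) / temp)) {
            X <- cand; cost <- newCost
          }
          temp <- temp * coolRate
        }
      }
      nF <- quotaFemales(n, reference@sexFemaleFraction)
      sexes <- rep("M", n)
      sexes[sample.int(n, nF)] <- "F"
      val <- zTestTable(X, mvnd$moments, n)
      if (all(val$pass)) {
        res <- list(X = X, sexes = sexes, val = val, restarts = r)
        break
      }
      if (cost < bestCost) bestCost <- cost
    }
  })
  if (is.null(res))
    stop(sprintf(paste0("adult population failed z-test validation after %d ",
                        "restarts (best cost %.4g)"), restarts, bestCost))
  finishPopulation(res$X, res$sexes, "adult", seed, reference, res$val,
                   list(restarts = res$restarts))
}

zTestTable <- function(X, moments, n, alpha = 0.05) {
  bmi <- X[, "weight"] / (X[, "height"] / 100)^2
  vals <- cbind(X, bmi = bmi)
  rows <- lapply(seq_len(nrow(moments)), function(i) {
    nm <- moments$name[i]
    if (moments$filled[i]) return(NULL)  # only reference-reported variables are targeted
    x <- vals[, nm]
    mu <- moments$mean[i]; s <- moments$sd[i]
    z <- if (s == 0) { if (abs(mean(x) - mu) < 1e-12) 0 else Inf }
         else (mean(x) - mu) / (s / sqrt(n))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(variable = nm, mean = mean(x), ref_mean = mu, ref_sd = s,
               z = z, p = p, pass = p > alpha)
  })
  do.call(rbind, rows)
}

#' Validate a virtual population against its reference
#'
#' One-sample z-test per targeted variable: z = (xbar - mu) / (sigma /
#' sqrt(n)) with the reference SD as sigma, two-sided p from the standard
#' normal. A population passes when every variable has p > alpha.
#'
#' @param pop a [VirtualPopulation-class] (or a patient data.frame).
#' @param reference a [DemographicReference-class].
#' @param alpha significance level of the acceptance rule.
#' @return data.frame with columns \code{variable}, \code{mean},
#'   \code{ref_mean}, \code{ref_sd}, \code{z}, \code{p}, \code{pass};
#'   attribute \code{overall} carries the all-variables verdict.
#' @export
validatePopulation <- function(pop, reference, alpha = 0.05) {
  p <- if (is(pop, "VirtualPopulation")) pop@patients else pop
  if (nrow(p) == 0L) stop("cannot validate an empty population")
  X <- cbind(age = p$age, height = p$height_cm, weight = p$weight_kg)
  m <- reference@variables
  moments <- data.frame(name = m$name, mean = m$mean, sd = m$sd,
                        filled = !m$available)
  out <- zTestTable(X, moments, nrow(p), alpha)
  attr(out, "overall") <- all(out$pass)
  out
}

#' Generate a pediatric-adolescent virtual population
#'
#' Ages are drawn exactly from the reference age marginal truncated to
#' 6-17 years; height and weight are then sampled by parallel
#' Metropolis-Hastings chains (one per patient, vectorized) conditional on
#' each patient's age and sex. The conditional target combines the
#' reference marginals of every reported variable (including derived BMI)
#' with the growth-reference conditional density for unreported variables,
#' and constrains height and weight to lie within 4 SD of their age- and
#' sex-conditional growth cell. Sex is assigned by quota beforehand and
#' conditions the growth lookups. Like the adult generator, a candidate
#' population is only returned once every targeted variable passes the
#' z-test acceptance rule; otherwise the sampler restarts.
#'
#' @param reference a [DemographicReference-class].
#' @param growth a [GrowthReference-class] covering ages 6-17.
#' @param n number of patients.
#' @param seed integer seed.
#' @param burnin Metropolis-Hastings burn-in steps.
#' @param thin post-burn-in steps between the chains' retained state and
#'   the final state actually kept.
#' @param stepFrac random-walk step as a fraction of each variable's SD.
#' @param restarts maximum restarts of the whole sampler.
#' @param alpha z-test acceptance level.
#' @return A [VirtualPopulation-class].
#' @examples
#' fx <- synthReferencePopulation("pediatric")
#' pop <- generatePediatricVpop(fx$reference, fx$growth, n = 100, seed = 7)
#' @export
generatePediatricVpop <- function(reference, growth, n, seed,
                                  burnin = 1000, thin = 10, stepFrac = 0.5,
                                  restarts = 20, alpha = 0.05) {
  stopifnot(n >= 1)
  m <- reference@variables
  avail <- function(v) { r <- m[m$name == v, ]; nrow(r) == 1L && r$available }
  mom <- function(v) { r <- m[m$name == v, ]; c(r$mean, r$sd) }

  gt <- growth@table
  for (v in c("height", "weight")) for (s in c("F", "M"))
    if (!nrow(gt[gt$variable == v & gt$sex == s, ]))
      stop("growth table must cover variable ", v, " for sex ", s)
  ## growth lookup matrices indexed by [age - 5, sex]
  gmat <- function(variable, field) {
    sapply(c("F", "M"), function(s) {
      sub <- gt[gt$sex == s & gt$variable == variable, ]
      sub[[field]][match(6:17, sub$age)]
    })
  }
  ghM <- gmat("height", "mean"); ghS <- gmat("height", "sd")
  gwM <- gmat("weight", "mean"); gwS <- gmat("weight", "sd")
  lookup <- function(M, age, sexIdx) M[cbind(pmin(pmax(round(age), 6), 17) - 5L, sexIdx)]

  ## conditional target for (height, weight) given age and sex: reference
  ## marginals for reported variables (incl. derived BMI), growth-conditional
  ## densities for unreported ones, and hard 4-SD growth windows
  logTarget <- function(age, h, w, sexIdx) {
    lt <- rep(0, length(h))
    bad <- h <= 0 | w <= 0
    mh <- lookup(ghM, age, sexIdx); sh <- lookup(ghS, age, sexIdx)
    mw <- lookup(gwM, age, sexIdx); sw <- lookup(gwS, age, sexIdx)
    bad <- bad | abs(h - mh) > 4 * sh | abs(w - mw) > 4 * sw
    lt <- lt + if (avail("height")) {
      a <- mom("height"); stats::dnorm(h, a[1], a[2], log = TRUE)
    } else stats::dnorm(h, mh, sh, log = TRUE)
    lt <- lt + if (avail("weight")) {
      a <- mom("weight"); stats::dnorm(w, a[1], a[2], log = TRUE)
    } else stats::dnorm(w, mw, sw, log = TRUE)
    if (avail("bmi")) {
      a <- mom("bmi")
      lt <- lt + stats::dnorm(w / (h / 100)^2, a[1], a[2], log = TRUE)
    }
    lt[bad] <- -Inf
    lt
  }

  ## ages are drawn exactly from the truncated reference marginal; coupling
  ## them into the MH state would let the growth windows tilt the age
  ## marginal away from the reference
  drawAges <- function(n, mu, sd) {
    if (sd == 0) return(rep(mu, n))
    lo <- stats::pnorm(6, mu, sd); hi <- stats::pnorm(17, mu, sd)
    stats::qnorm(stats::runif(n, lo, hi), mu, sd)
  }

  refAge <- if (avail("age")) mom("age") else c(11.5, 3.3)
  stepH <- stepFrac * (if (avail("height")) mom("height")[2] else mean(ghS))
  stepW <- stepFrac * (if (avail("weight")) mom("weight")[2] else mean(gwS))

  nF <- quotaFemales(n, reference@sexFemaleFraction)
  res <- NULL
  withSeed(childSeed(seed, "pediatric-vpop"), {
    for (r in seq_len(restarts)) {
      sexes <- rep("M", n)
      sexes[sample.int(n, nF)] <- "F"
      sexIdx <- ifelse(sexes == "F", 1L, 2L)
      age <- drawAges(n, refAge[1], refAge[2])
      h <- lookup(ghM, age, sexIdx)
      w <- lookup(gwM, age, sexIdx)
      lt <- logTarget(age, h, w, sexIdx)
      degenerate <- all(c(stepH, stepW) == 0)
      nSteps <- if (degenerate) 0L else burnin + thin
      for (s in seq_len(nSteps)) {
        ph <- h + stats::rnorm(n, 0, stepH)
        pw <- w + stats::rnorm(n, 0, stepW)
        plt <- logTarget(age, ph, pw, sexIdx)
        acc <- log(stats::runif(n)) < plt - lt
        h[acc] <- ph[acc]; w[acc] <- pw[acc]
        lt[acc] <- plt[acc]
      }
      X <- cbind(age = age, height = h, weight = w)
      moments <- data.frame(name = m$name, mean = m$mean, sd = m$sd,
                            filled = !m$available)
      val <- zTestTable(X, moments, n, alpha)
      if (all(val$pass)) {
        res <- list(X = X, sexes = sexes, val = val, restarts = r)
        break
      }
    }
  })
  if (is.null(res))
    stop("pediatric population failed z-test validation after ", restarts,
         " restarts")
  finishPopulation(res$X, res$sexes, "pediatric", seed, reference, res$val,
                   list(restarts = res$restarts))
}

#' Describe one trial arm
#'
#' @param armId arm identifier.
#' @param size number of patients in the arm.
#' @param comorbidities condition names tagged onto the arm's patients
#'   (empty = disease-only arm).
#' @return list usable by [assignArms()].
#' @export
armSpec <- function(armId, size, comorbidities = character()) {
  stopifnot(size > 0)
  list(armId = armId, size = as.integer(size),
       comorbidities = as.character(comorbidities))
}

#' Randomly allocate a population to trial arms
#'
#' Random partition without replacement; arm sizes must sum to the
#' population size. Comorbidity tags are copied from the arm specs.
#'
#' @param pop a [VirtualPopulation-class].
#' @param arms list of [armSpec()] entries.
#' @param seed integer seed.
#' @return The population with \code{arm_id} and \code{tags} set.
#' @export
assignArms <- function(pop, arms, seed) {
  n <- nrow(pop@patients)
  sizes <- vapply(arms, `[[`, integer(1), "size")
  if (sum(sizes) != n)
    stop("arm sizes sum to ", sum(sizes), " but the population has ", n,
         " patients")
  ord <- withSeed(childSeed(seed, "arms"), sample.int(n))
  armId <- rep(vapply(arms, `[[`, character(1), "armId"), sizes)
  tags <- rep(vapply(arms, function(a) paste(a$comorbidities, collapse = ","),
                     character(1)), sizes)
  pop@patients$arm_id[ord] <- armId
  pop@patients$tags[ord] <- tags
  pop
}

#' Standard nine-arm design of one population
#'
#' One disease-only arm of 500 patients plus eight comorbidity arms of 100
#' patients each (1,300 patients per population; 2,600 over the adult and
#' pediatric-adolescent populations together).
#'
#' @param comorbidities names of the eight comorbidity arms.
#' @param mainSize,comorbiditySize arm sizes.
#' @return list of [armSpec()] entries.
#' @export
nineArmDesign <- function(comorbidities = c("depression", "anxiety",
                                            "bipolar", "tics", "binge_eating",
                                            "depression+anxiety",
                                            "anxiety+tics",
                                            "depression+binge_eating"),
                          mainSize = 500, comorbiditySize = 100) {
  stopifnot(length(comorbidities) == 8L)
  c(list(armSpec("adhd_only", mainSize)),
    lapply(seq_along(comorbidities), function(i)
      armSpec(paste0("comorbid_", i), comorbiditySize,
              strsplit(comorbidities[i], "+", fixed = TRUE)[[1]])))
}
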