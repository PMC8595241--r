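test_that("parameter individualization scales with anthropometry", {
  drug <- drugCatalog("ldx_adult")
  expect_equal(drug@bioavailability, 0.964)
  p1 <- individualizeParameters(standardAdult(), drug)
  p2 <- individualizeParameters(standardAdult(), drug)
  expect_identical(p1, p2)
  # doubling body weight doubles every volume (adipose also scales with BMI,
  # so compare at fixed BMI)
  heavy <- standardAdult()
  heavy$weight_kg <- 140; heavy$bmi <- standardAdult()$bmi
  ph <- individualizeParameters(heavy, drug)
  expect_equal(unname(ph@volumes), unname(2 * p1@volumes))
  expect_true(all(p1@volumes > 0))
  expect_lte(sum(p1@flows), p1@cardiacOutput * (1 + 1e-9))
  expect_error(individualizeParameters(list(sex = "M", age = 130,
                                            weight_kg = 70, height_cm = 170),
                                       drug), "coverage")
})

test_that("extended-release expansion follows the split rules", {
  conc <- drugModel("MPH", 36, 0.32, release = "split3")
  sch <- expandExtendedRelease(conc)
  expect_equal(sch@events$time_h, c(0, 4, 8))
  expect_equal(sch@events$amount_mg, rep(12, 3))
  medi <- drugModel("MPH", 20, 0.30, release = "split2")
  sch2 <- expandExtendedRelease(medi)
  expect_equal(sch2@events$time_h, c(0, 4))
  expect_equal(sch2@events$amount_mg, rep(10, 2))
  imm <- drugModel("LDX", 70, 0.964)
  expect_equal(expandExtendedRelease(imm)@events,
               data.frame(time_h = 0, amount_mg = 70))
  bad <- imm; bad@release <- "weird"
  expect_error(expandExtendedRelease(bad), "unknown release")
})

test_that("zero dose gives an all-zero profile", {
  p <- oneCompartmentParams()
  sch <- new("DosingScheme", route = "gut", drug = "x",
             events = data.frame(time_h = numeric(), amount_mg = numeric()))
  prof <- simulatePBPK(p, sch, tEnd = 5)
  expect_equal(max(abs(prof@concentrations)), 0)
})

test_that("one-compartment limit reproduces the Bateman closed form", {
  ka <- 1.2; ke <- 0.3; F <- 0.964; dose <- 70
  p <- oneCompartmentParams(ka, ke, F)
  prof <- simulatePBPK(p, dosingScheme("x", 0, dose), tEnd = 24)
  tt <- seq(0.2, 24, by = 0.2)
  num <- tissueTimepoints(prof, "blood", tt)
  ana <- batemanConcentration(tt, ka, ke, F, dose, unname(p@volumes["blood"]))
  expect_lt(max(abs(num - ana)) / max(ana), 0.005)
})

test_that("mass balance, non-negativity and clearance monotonicity hold", {
  drug <- drugCatalog("mph_pediatric")
  child <- list(sex = "M", age = 8, height_cm = 130, weight_kg = 30,
                bmi = 30 / 1.3^2)
  p <- individualizeParameters(child, drug, ka = 1.5,
                               clearance = c(kidneys = 0.4, liver = 0.2))
  prof <- simulatePBPK(p, expandExtendedRelease(drug), tEnd = 24)
  expect_lt(massBalanceError(prof), 0.001)
  expect_gte(min(prof@concentrations), 0)
  expect_true(all(diff(prof@cleared[, "kidneys"]) >= -1e-12))
  expect_true(all(diff(prof@cleared[, "liver"]) >= -1e-12))
})

test_that("the system is linear: dose doubling and superposition", {
  drug <- drugCatalog("ldx_adult")
  p <- individualizeParameters(standardAdult(), drug, ka = 1.2,
                               clearance = c(kidneys = 0.3))
  prof1 <- simulatePBPK(p, dosingScheme("x", 0, 35), tEnd = 16)
  prof2 <- simulatePBPK(p, dosingScheme("x", 0, 70), tEnd = 16)
  expect_equal(prof2@concentrations, 2 * prof1@concentrations,
               tolerance = 1e-6)
  # repeated doses superpose single-dose solutions
  prof12 <- simulatePBPK(p, dosingScheme("x", c(0, 4), c(35, 35)), tEnd = 16)
  shifted <- tissueTimepoints(prof1, "blood", pmax(seq(0, 16, 0.1) - 4, 0)) *
    (seq(0, 16, 0.1) > 4)
  direct <- tissueTimepoints(prof1, "blood", seq(0, 16, 0.1))
  combo <- tissueTimepoints(prof12, "blood", seq(0, 16, 0.1))
  expect_lt(max(abs(combo - direct - shifted)) / max(combo), 0.005)
})

test_that("tissue timepoint lookup is linear interpolation on the grid", {
  p <- oneCompartmentParams()
  prof <- simulatePBPK(p, dosingScheme("x", 0, 70), tEnd = 10)
  expect_equal(tissueTimepoints(prof, "blood", 0), 0)
  i <- 31
  expect_identical(tissueTimepoints(prof, "blood", prof@time[i]),
                   unname(prof@concentrations[i, "blood"]))
  mid <- (prof@time[i] + prof@time[i + 1]) / 2
  expect_equal(tissueTimepoints(prof, "blood", mid),
               mean(prof@concentrations[i:(i + 1), "blood"]),
               tolerance = 1e-12)
  expect_error(tissueTimepoints(prof, "bladder", 1), "unknown compartment")
  expect_error(tissueTimepoints(prof, "blood", 99), "outside")
})

test_that("absorption/clearance fitting recovers known parameters", {
  ka <- 1.2; ke <- 0.3; F <- 0.964; dose <- 70
  template <- oneCompartmentParams(ka = 1, ke = 0.2, F = F)
  V <- unname(template@volumes["blood"])
  times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  obs <- synthPKObservations(ka, ke, F, dose, V, times, noise = 0)
  fit <- suppressWarnings(
    fitAbsorptionClearance(template, dosingScheme("x", 0, dose), obs))
  expect_lt(abs(fit$estimates["ka"] - ka) / ka, 0.01)
  expect_lt(abs(fit$estimates["cl"] - ke) / ke, 0.01)
  expect_gt(fit$r2, 0.999)
  # determinism
  fit2 <- suppressWarnings(
    fitAbsorptionClearance(template, dosingScheme("x", 0, dose), obs))
  expect_identical(fit$estimates, fit2$estimates)
  # degenerate input
  flat <- data.frame(time_h = times, conc_mg_per_L = 0)
  expect_error(fitAbsorptionClearance(template, dosingScheme("x", 0, dose),
                                      flat), "no signal")
})

test_that("noisy-data recovery stays within 10% median error over seeds", {
  ka <- 1.2; ke <- 0.3; F <- 0.964; dose <- 70
  template <- oneCompartmentParams(ka = 1, ke = 0.2, F = F)
  V <- unname(template@volumes["blood"])
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24)
  err <- vapply(1:20, function(s) {
    obs <- synthPKObservations(ka, ke, F, dose, V, times, noise = 0.05,
                               seed = s)
    fit <- suppressWarnings(
      fitAbsorptionClearance(template, dosingScheme("x", 0, dose), obs,
                             logScale = TRUE))
    max(abs(fit$estimates["ka"] - ka) / ka, abs(fit$estimates["cl"] - ke) / ke)
  }, numeric(1))
  expect_lt(median(err), 0.10)
})
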