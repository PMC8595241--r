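test_that("Emax target modulation follows the half-maximal identities", {
  tgt <- data.frame(protein = "T1", effect = -1, ec50 = 2)
  expect_equal(unname(targetModulation(rep(0, 5), tgt)), 0)
  expect_equal(unname(targetModulation(rep(2, 4), tgt)), -0.5)
  tgt$effect <- 1
  expect_equal(unname(targetModulation(c(2, 6), tgt)), (0.5 + 0.75) / 2)
  tgt$ec50 <- NA
  expect_error(targetModulation(1, tgt), "EC50")
})

test_that("propagation fixes zero input at zero and respects edge signs", {
  net <- chainNetwork()
  z <- propagateActivity(net, numeric(0), noise = 0)
  expect_true(z$converged)
  expect_equal(unname(z$activity), rep(0, 4))
  up <- propagateActivity(net, c(A = 0.8), noise = 0)
  expect_gt(up$activity["B"], 0)                       # A -> B activating
  expect_equal(unname(sign(up$activity["B"])), unname(sign(up$activity["A"])))
  expect_lt(up$activity["C"], 0)                       # B -| C inhibiting
  expect_equal(unname(up$activity["D"]), 0)            # disconnected
  # odd map: flipping the stimulus flips every activity
  dn <- propagateActivity(net, c(A = -0.8), noise = 0)
  expect_equal(dn$activity, -up$activity, tolerance = 1e-9)
  expect_true(all(abs(up$activity) < 1))
})

test_that("tSignal algebraic identities hold exactly", {
  d <- diseaseDefinition("d", c(A = 1, B = -1, C = 1))
  # disease fully expressed: y = v
  expect_equal(as.numeric(computeTSignal(c(A = 1, B = -1, C = 1), d)), -1,
               tolerance = 1e-12)
  # neutral state
  expect_equal(as.numeric(computeTSignal(c(A = 0, B = 0, C = 0), d)), 0,
               tolerance = 1e-12)
  # hand-computed mixed case: -(1/3)(0.5 - 0.5 - 1.0) = 1/3
  expect_equal(as.numeric(computeTSignal(c(A = 0.5, B = 0.5, C = -1), d)),
               1 / 3, tolerance = 1e-12)
  # full reversion: y = -v
  expect_equal(as.numeric(computeTSignal(c(A = -1, B = 1, C = -1), d)), 1,
               tolerance = 1e-12)
  expect_error(computeTSignal(c(A = 1), diseaseDefinition("e",
    data.frame(protein = character(), sign = numeric()))), "non-empty")
})

test_that("tSignal is linear in the solution and bounded", {
  set.seed(4)
  d <- diseaseDefinition("d", setNames(sample(c(-1, 1), 6, TRUE),
                                       paste0("P", 1:6)))
  for (r in 1:20) {
    y <- setNames(runif(6, -0.999, 0.999), paste0("P", 1:6))
    ts <- as.numeric(computeTSignal(y, d))
    expect_true(ts >= -1 && ts <= 1)
    a <- runif(1)
    expect_equal(as.numeric(computeTSignal(a * y, d)), a * ts,
                 tolerance = 1e-12)
  }
  # missing proteins count as neutral, keeping n fixed
  half <- computeTSignal(c(P1 = 1), diseaseDefinition("d", c(P1 = -1, P2 = 1)))
  expect_equal(as.numeric(half), 0.5)
  expect_equal(attr(half, "missing"), "P2")
})

test_that("solution accuracy counts satisfied training relationships", {
  fx <- synthNetworkWithDefinitions(seed = 7)
  noiseless <- propagateActivity(fx$network,
                                 mechtrial:::drugStimulus(fx$drugs[[1]]),
                                 noise = 0)
  expect_equal(solutionAccuracy(noiseless, fx$training, fx$network), 100)
  # invert one expectation: 1 of 2 relationships now fails
  flipped <- fx$training
  flipped@entries[[2]]$direction <- -flipped@entries[[2]]$direction
  expect_equal(solutionAccuracy(noiseless, flipped, fx$network), 50)
})

test_that("ensembles respect the size and accuracy gates", {
  fx <- synthNetworkWithDefinitions(seed = 7)
  ens <- sampleEnsemble("p1", fx$drugs[[1]], fx$network, fx$training,
                        seed = 11)
  expect_gte(length(ens), 50)
  expect_true(all(solutionAccuracies(ens) >= 85))
  expect_true(all(abs(activities(ens)) < 1))
  expect_true(all(ens@converged))
  # noiseless sampling yields identical solutions at accuracy 100
  ens0 <- sampleEnsemble("p1", fx$drugs[[1]], fx$network, fx$training,
                         noise = 0, ensembleMin = 5, seed = 1)
  expect_equal(max(apply(activities(ens0), 1, var)), 0)
  expect_true(all(solutionAccuracies(ens0) == 100))
  # impossible floor
  expect_error(sampleEnsemble("p1", fx$drugs[[1]], fx$network, fx$training,
                              accuracyFloor = 101, ensembleMin = 5,
                              maxAttempts = 20, seed = 1),
               "best accuracy")
})

test_that("ensemble mean tSignal is seed-stable within Monte-Carlo error", {
  fx <- synthNetworkWithDefinitions(seed = 7)
  ts <- vapply(1:4, function(s)
    ensembleTSignal(sampleEnsemble("p", fx$drugs[[1]], fx$network,
                                   fx$training, seed = s),
                    fx$definition), numeric(1))
  sols <- sampleEnsemble("p", fx$drugs[[1]], fx$network, fx$training,
                         seed = 99)
  perSol <- apply(activities(sols), 2, function(y)
    as.numeric(computeTSignal(y, fx$definition)))
  se <- sd(perSol) / sqrt(length(perSol))
  expect_lt(max(ts) - min(ts), 8 * se)
})

test_that("opposite target profiles give opposite-signed tSignals", {
  fx <- synthNetworkWithDefinitions(seed = 3)
  s1 <- propagateActivity(fx$network, mechtrial:::drugStimulus(fx$drugs[[1]]),
                          noise = 0)
  s2 <- propagateActivity(fx$network, mechtrial:::drugStimulus(fx$drugs[[2]]),
                          noise = 0)
  t1 <- as.numeric(computeTSignal(s1$activity, fx$definition))
  t2 <- as.numeric(computeTSignal(s2$activity, fx$definition))
  expect_gt(t1, 0)                       # constructed to revert the disease
  expect_equal(t2, -t1, tolerance = 1e-9)
  # empty target set leaves the network at rest
  none <- drugModel("none", 1, 0.5,
                    targets = data.frame(protein = character(),
                                         effect = numeric()))
  s0 <- propagateActivity(fx$network, mechtrial:::drugStimulus(none),
                          noise = 0)
  expect_equal(as.numeric(computeTSignal(s0$activity, fx$definition)), 0)
})

test_that("comorbidity definitions act as weak persistent stimuli", {
  fx <- synthNetworkWithDefinitions(seed = 7)
  com <- diseaseDefinition("comorbid",
                           fx$definition@proteins[1:2, , drop = FALSE])
  e1 <- sampleEnsemble("p", fx$drugs[[1]], fx$network, fx$training,
                       ensembleMin = 10, noise = 0, seed = 1)
  e2 <- sampleEnsemble("p", fx$drugs[[1]], fx$network, fx$training,
                       comorbidities = list(com), ensembleMin = 10,
                       noise = 0, seed = 1)
  expect_false(isTRUE(all.equal(activities(e1), activities(e2))))
})
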