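test_that("buildMVND carries reference moments and fills missing variables", {
  ref <- adultRef()   # BMI unreported
  mv <- buildMVND(ref, standardFillTable("adult"))
  expect_equal(unname(mv$mean), c(36.58, 171.7, 78.75))
  expect_equal(unname(diag(mv$cov)), c(10.10, 9.4, 17.20)^2)
  expect_true(isSymmetric(mv$cov))
  expect_true(all(eigen(mv$cov, only.values = TRUE)$values >= -1e-9))
  expect_true(mv$moments$filled[mv$moments$name == "bmi"])
  fillRow <- standardFillTable("adult")
  expect_equal(mv$moments$mean[mv$moments$name == "bmi"],
               fillRow$mean[fillRow$name == "bmi"])
  # unresolvable variable
  expect_error(buildMVND(ref, fill = NULL), "available neither")
})

test_that("one-sample z-test validation matches the closed form", {
  # constant population pinned at specific means; sigma is the reference SD
  pats <- constantPatients(500, age = 37.5, height = 171.7, weight = 78.75)
  val <- validatePopulation(pats, fullRef())
  age <- val[val$variable == "age", ]
  expect_equal(age$z, (37.5 - 36.58) / (10.10 / sqrt(500)), tolerance = 1e-12)
  expect_equal(age$z, 2.0368, tolerance = 1e-4)
  expect_equal(age$p, 0.0417, tolerance = 1e-2)
  expect_false(age$pass)
  others <- val[val$variable != "age", ]
  expect_true(all(others$z == 0) && all(others$p == 1) && all(others$pass))
  expect_error(validatePopulation(constantPatients(1, 30, 170, 70)[0, ],
                                  fullRef()), "empty")
})

test_that("adult generator matches its reference and derives BMI exactly", {
  ref <- adultRef()
  pop <- generateAdultVpop(ref, n = 500, seed = 11)
  p <- patients(pop)
  expect_equal(nrow(p), 500)
  expect_true(all(p$age > 18))
  expect_equal(p$bmi, p$weight_kg / (p$height_cm / 100)^2, tolerance = 1e-9)
  val <- validatePopulation(pop, ref)
  expect_true(attr(val, "overall"))
  # sex quota, round-half-up
  expect_equal(sum(p$sex == "F"), floor(500 * 0.416 + 0.5))
  # realized mean age is a draw near the reference target
  expect_lt(abs(mean(p$age) - 36.58), 3 * 10.10 / sqrt(500))
})

test_that("zero-variance reference yields patients pinned at the means", {
  ref <- demographicReference(age = c(40, 0), height = c(170, 0),
                              weight = c(70, 0), sexFemaleFraction = 0,
                              nReference = 1)
  pop <- generateAdultVpop(ref, n = 1, seed = 1)
  p <- patients(pop)
  expect_equal(p$age, 40)
  expect_equal(p$height_cm, 170)
  expect_equal(p$weight_kg, 70)
  pop5 <- generateAdultVpop(ref, n = 5, seed = 2)
  expect_equal(unique(patients(pop5)$age), 40)
})

test_that("generators are byte-deterministic in (inputs, seed)", {
  ref <- adultRef()
  a <- generateAdultVpop(ref, n = 60, seed = 5)
  b <- generateAdultVpop(ref, n = 60, seed = 5)
  expect_identical(patients(a), patients(b))
  fx <- pedRef()
  c1 <- generatePediatricVpop(fx$reference, fx$growth, n = 60, seed = 5)
  c2 <- generatePediatricVpop(fx$reference, fx$growth, n = 60, seed = 5)
  expect_identical(patients(c1), patients(c2))
  expect_false(identical(patients(a),
                         patients(generateAdultVpop(ref, n = 60, seed = 6))))
})

test_that("acceptance loop keeps sample means inside the z-band (Monte Carlo)", {
  ref <- demographicReference(age = c(40, 5), height = c(170, 8),
                              weight = c(72, 12), sexFemaleFraction = 0.5,
                              nReference = 200)
  hits <- vapply(1:100, function(s) {
    p <- patients(generateAdultVpop(ref, n = 200, seed = s))
    abs(mean(p$age) - 40) < 3 * 5 / sqrt(200)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("pediatric generator respects age bounds and growth windows", {
  fx <- pedRef()
  pop <- generatePediatricVpop(fx$reference, fx$growth, n = 400, seed = 9)
  p <- patients(pop)
  expect_true(all(p$age >= 6 & p$age <= 17))
  expect_true(attr(validatePopulation(pop, fx$reference), "overall"))
  for (i in seq_len(nrow(p))) {
    gh <- growthLookup(fx$growth, p$age[i], p$sex[i], "height")
    gw <- growthLookup(fx$growth, p$age[i], p$sex[i], "weight")
    expect_lt(abs(p$height_cm[i] - gh$mean), 4 * gh$sd + 1e-9)
    expect_lt(abs(p$weight_kg[i] - gw$mean), 4 * gw$sd + 1e-9)
  }
  # age marginal follows the truncated reference distribution (Kolmogorov)
  mu <- 10.9; sd <- 2.8
  lo <- pnorm(6, mu, sd); hi <- pnorm(17, mu, sd)
  trunc_cdf <- function(x) (pnorm(x, mu, sd) - lo) / (hi - lo)
  ks <- suppressWarnings(ks.test(p$age, trunc_cdf))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("growth table gaps are rejected", {
  fx <- pedRef()
  gt <- fx$growth@table
  expect_error(growthReference(gt[gt$age != 12, ]), "cover ages 6-17")
  expect_error(growthLookup(fx$growth, 25, "M", "height"), "coverage gap")
})

test_that("arm assignment partitions exactly and copies tags", {
  ref <- adultRef()
  pop <- generateAdultVpop(ref, n = 130, seed = 3)
  arms <- c(list(armSpec("adhd_only", 50)),
            lapply(1:8, function(i) armSpec(paste0("c", i), 10,
                                            comorbidities = paste0("cond", i))))
  out <- assignArms(pop, arms, seed = 1)
  tab <- table(patients(out)$arm_id)
  expect_equal(unname(tab["adhd_only"]), 50)
  expect_true(all(tab[paste0("c", 1:8)] == 10))
  expect_equal(sum(tab), 130)
  expect_true(all(patients(out)$tags[patients(out)$arm_id == "c3"] == "cond3"))
  # different seeds: different partition, identical size histogram
  out2 <- assignArms(pop, arms, seed = 2)
  expect_false(identical(patients(out)$arm_id, patients(out2)$arm_id))
  expect_equal(table(patients(out2)$arm_id), tab)
  # size mismatch
  expect_error(assignArms(pop, list(armSpec("a", 10)), 1), "sum to")
  # single arm = identity assignment
  one <- assignArms(pop, list(armSpec("all", 130)), 1)
  expect_true(all(patients(one)$arm_id == "all"))
})

test_that("population class enforces its invariants", {
  p <- constantPatients(3, 30, 170, 70)
  expect_s4_class(new("VirtualPopulation", patients = p,
                      populationKind = "adult", seed = 1L), "VirtualPopulation")
  bad <- p; bad$bmi <- bad$bmi + 1
  expect_error(new("VirtualPopulation", patients = bad,
                   populationKind = "adult", seed = 1L), "bmi")
  young <- p; young$age <- 10
  expect_error(new("VirtualPopulation", patients = young,
                   populationKind = "adult", seed = 1L), "age > 18")
})
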