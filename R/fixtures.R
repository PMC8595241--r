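## Seeded synthetic-data generators. Every generator is a pure function of
## its arguments and seed, so the rest of the toolkit is testable offline.

#' Bundled synthetic growth reference grid
#'
#' A smooth, WHO-style grid of height and weight means and SDs by integer
#' age (6-17) and sex. The values are synthetic: they follow realistic
#' growth shapes and are calibrated so that, aggregated over the packaged
#' pediatric reference age distribution, the implied joint of height,
#' weight and BMI is coherent with that reference's summary moments (mean
#' height near 149 cm, BMI profile rising from about 17 to 21 kg/m^2).
#' They are not measured percentile data.
#'
#' @return A [GrowthReference-class].
#' @export
synthGrowthReference <- function() {
  ages <- 6:17
  hM <- c(119, 125, 131, 137, 143, 149, 155, 161, 167, 172, 176, 178)
  hF <- c(118, 124, 130, 136, 143, 149, 155, 159, 161, 162, 163, 163)
  hS <- c(6, 6, 6.5, 6.5, 7, 7.5, 8, 8.5, 8, 7.5, 7, 7)
  bmiProfile <- 17 + 0.35 * (ages - 6)
  wM <- bmiProfile * (hM / 100)^2
  wF <- bmiProfile * (hF / 100)^2
  tab <- rbind(
    data.frame(age = ages, sex = "M", variable = "height", mean = hM, sd = hS),
    data.frame(age = ages, sex = "F", variable = "height", mean = hF, sd = hS),
    data.frame(age = ages, sex = "M", variable = "weight", mean = wM,
               sd = 0.2 * wM),
    data.frame(age = ages, sex = "F", variable = "weight", mean = wF,
               sd = 0.2 * wF))
  growthReference(tab)
}

#' Packaged reference populations
#'
#' The adult reference carries the published adult trial demographic
#' summary (age 36.58 +/- 10.10 years, height 171.7 +/- 9.4 cm, weight
#' 78.75 +/- 17.20 kg, 41.6% female, n = 511; BMI unreported). The
#' pediatric reference carries the pediatric-adolescent summary (age 10.90
#' +/- 2.80 years, weight 43.60 +/- 15.10 kg, BMI 19.1 +/- 3.4 kg/m^2,
#' 20.0% female, n = 111; height unreported) together with the bundled
#' synthetic growth grid.
#'
#' @param kind "adult" or "pediatric".
#' @return list with \code{reference} (a
#'   [DemographicReference-class]) and, for pediatric, \code{growth}
#'   (a [GrowthReference-class]).
#' @export
synthReferencePopulation <- function(kind = c("adult", "pediatric")) {
  kind <- match.arg(kind)
  if (kind == "adult") {
    list(reference = demographicReference(
      age = c(36.58, 10.10), height = c(171.7, 9.4), weight = c(78.75, 17.20),
      sexFemaleFraction = 0.416, nReference = 511, label = "adult-trial-reference"))
  } else {
    list(reference = demographicReference(
      age = c(10.90, 2.80), weight = c(43.60, 15.10), bmi = c(19.1, 3.4),
      sexFemaleFraction = 0.20, nReference = 111,
      label = "pediatric-trial-reference"),
      growth = synthGrowthReference())
  }
}

#' Synthetic gene-expression counts with a planted case/control effect
#'
#' Log-normal baseline counts; the first \code{nInformative} genes are
#' shifted by \code{d} within-gene SDs (on the log scale) in cases.
#'
#' @param nControl,nCase cohort sizes.
#' @param nGenes total genes.
#' @param nInformative genes carrying the effect.
#' @param d effect size in within-gene SD units.
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples matrix),
#'   \code{labels} ("control"/"case") and \code{informative} (gene names).
#' @export
synthExpression <- function(nControl, nCase, nGenes = 200, nInformative = 20,
                            d = 1, seed = 1) {
  stopifnot(nInformative <= nGenes)
  withSeed(childSeed(seed, "expression"), {
    n <- nControl + nCase
    labels <- rep(c("control", "case"), c(nControl, nCase))
    baseMean <- stats::runif(nGenes, 3, 8)        # log2 scale
    sdLog <- stats::runif(nGenes, 0.3, 0.8)
    logx <- matrix(stats::rnorm(nGenes * n, baseMean, sdLog), nGenes, n)
    if (nInformative > 0)
      logx[seq_len(nInformative), labels == "case"] <-
        logx[seq_len(nInformative), labels == "case"] +
        d * sdLog[seq_len(nInformative)]
    counts <- round(2^logx)
    dimnames(counts) <- list(sprintf("gene%03d", seq_len(nGenes)),
                             sprintf("s%03d", seq_len(n)))
    list(counts = counts, labels = labels,
         informative = rownames(counts)[seq_len(nInformative)])
  })
}

#' Synthetic signed protein network with a satisfiable training set
#'
#' Builds a connected random signed, weighted, directed network; defines a
#' drug target profile on a few upstream nodes; runs the noiseless activity
#' propagation of that drug; and picks the most-responsive nodes as the
#' disease definition with signs opposite to the drug's noiseless effect.
#' By construction the drug reverses the disease signature, so the single
#' training relationship (drug raises tSignal) is satisfiable with accuracy
#' 100 for the noiseless solution. A second drug with the opposite target
#' signs is included.
#'
#' @param nNodes,nEdges network size.
#' @param nEffectors disease-definition size.
#' @param nTargets drug target count.
#' @param seed integer seed.
#' @return list with \code{network}, \code{definition}, \code{drugs} (list
#'   of two [DrugModel-class]), \code{training} (a
#'   [TrainingSet-class]).
#' @export
synthNetworkWithDefinitions <- function(nNodes = 40, nEdges = 100,
                                        nEffectors = 10, nTargets = 3,
                                        seed = 1) {
  stopifnot(nEffectors < nNodes, nTargets < nNodes)
  withSeed(childSeed(seed, "network"), {
    prot <- sprintf("P%03d", seq_len(nNodes))
    ## connected backbone (random spanning tree) + random extra edges
    perm <- sample(prot)
    backbone <- data.frame(source = perm[pmax(1, sapply(2:nNodes, function(i)
      sample.int(i - 1L, 1L)))], target = perm[2:nNodes])
    extra <- data.frame(source = prot[sample.int(nNodes, nEdges, replace = TRUE)],
                        target = prot[sample.int(nNodes, nEdges, replace = TRUE)])
    e <- rbind(backbone, extra)
    e <- e[e$source != e$target, ]
    e <- e[!duplicated(e[c("source", "target")]), ]
    e$sign <- sample(c(-1, 1), nrow(e), replace = TRUE, prob = c(0.3, 0.7))
    e$weight <- stats::runif(nrow(e), 0.5, 1.5)
    g <- igraph::graph_from_data_frame(e[c("source", "target")],
                                       vertices = prot)
    stopifnot(igraph::is_connected(g, mode = "weak"))
    net <- proteinNetwork(e, prot)

    targets <- sample(prot, nTargets)
    effects <- sample(c(-1, 1), nTargets, replace = TRUE)
    t1 <- data.frame(protein = targets, effect = effects, ec50 = 0.05)
    drug1 <- drugModel("drugA", doseMg = 50, bioavailability = 0.9, targets = t1)
    t2 <- t1; t2$effect <- -t2$effect
    drug2 <- drugModel("drugB", doseMg = 50, bioavailability = 0.9, targets = t2)

    base <- propagateActivity(net, stats::setNames(effects * 0.8, targets),
                              noise = 0, seed = 1)
    y <- base$activity
    y <- y[setdiff(names(y), targets)]
    eff <- names(sort(abs(y), decreasing = TRUE))[seq_len(nEffectors)]
    if (min(abs(y[eff])) < 1e-8)
      stop("fixture network too sparse: effector activities vanish")
    defn <- diseaseDefinition("synthetic-condition",
                              stats::setNames(-sign(y[eff]), eff))
    training <- trainingSet(
      list(drug = drug1, condition = defn, direction = +1),
      list(drug = drug2, condition = defn, direction = -1))
    list(network = net, definition = defn, drugs = list(drug1, drug2),
         training = training)
  })
}

#' Synthetic one-compartment pharmacokinetic observations
#'
#' Points on the closed-form Bateman curve for a single oral dose, with
#' optional multiplicative log-normal noise.
#'
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @param F bioavailability.
#' @param dose dose (mg).
#' @param V volume of distribution (L).
#' @param times sampling times (h), strictly increasing.
#' @param noise SD of the log-normal multiplicative noise (0 = exact).
#' @param seed integer seed.
#' @return data.frame with \code{time_h}, \code{conc_mg_per_L}.
#' @export
synthPKObservations <- function(ka, ke, F, dose, V, times, noise = 0, seed = 1) {
  stopifnot(ka > 0, ke > 0, ka != ke, dose > 0, V > 0)
  conc <- batemanConcentration(times, ka, ke, F, dose, V)
  if (noise > 0)
    conc <- withSeed(childSeed(seed, "pkobs"),
                     conc * exp(stats::rnorm(length(conc), 0, noise)))
  data.frame(time_h = times, conc_mg_per_L = conc)
}

#' Closed-form one-compartment oral concentration curve
#'
#' The Bateman function F D ka (exp(-ke t) - exp(-ka t)) / (V (ka - ke)),
#' used as the limiting-case oracle for the full compartment model.
#'
#' @param t times (h).
#' @param ka,ke absorption and elimination rate constants (1/h).
#' @param F bioavailability.
#' @param dose dose (mg).
#' @param V volume of distribution (L).
#' @return concentrations (mg/L).
#' @export
batemanConcentration <- function(t, ka, ke, F, dose, V) {
  F * dose * ka * (exp(-ke * t) - exp(-ka * t)) / (V * (ka - ke))
}
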