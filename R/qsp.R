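#' Convert target-tissue exposure into drug-target modulation
#'
#' Applies the Emax (EC50) relationship to a set of target-tissue
#' concentration timepoints: for each target the unsigned modulation is the
#' mean over timepoints of c^h / (c^h + EC50^h), signed by the drug's
#' effect on the target (+1 activation, -1 inhibition). With constant
#' exposure equal to the EC50 this is half-maximal (0.5).
#'
#' @param concentrations target-tissue concentration timepoints (mg/L).
#' @param drug a [DrugModel-class] whose targets carry \code{ec50},
#'   or a data.frame with columns \code{protein}, \code{effect},
#'   \code{ec50}.
#' @param hill Hill coefficient (default 1, plain hyperbolic Emax).
#' @param aggregate how timepoints are pooled: "mean" (default) or "max".
#' @return named numeric vector of signed per-target modulations in
#'   (-1, 1).
#' @export
targetModulation <- function(concentrations, drug, hill = 1,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  t <- if (is(drug, "DrugModel")) drug@targets else drug
  stopifnot(all(concentrations >= 0))
  if (!"ec50" %in% names(t) || any(!is.finite(t$ec50)) || any(t$ec50 <= 0))
    stop("every target needs a positive EC50")
  vapply(seq_len(nrow(t)), function(i) {
    frac <- concentrations^hill / (concentrations^hill + t$ec50[i]^hill)
    t$effect[i] * if (aggregate == "mean") mean(frac) else max(frac)
  }, numeric(1)) |> stats::setNames(t$protein)
}

## Row-normalized signed adjacency: W[i, j] = sign * weight of edge j -> i,
## scaled so every absolute row sum is <= 1. With damping lambda < 1 the
## iteration x <- tanh(lambda * W x + s) is then a contraction.
networkMatrix <- function(network) {
  n <- length(network@nodes)
  W <- matrix(0, n, n, dimnames = list(network@nodes, network@nodes))
  e <- network@edges
  W[cbind(match(e$target, network@nodes), match(e$source, network@nodes))] <-
    e$sign * e$weight
  rs <- pmax(1, rowSums(abs(W)))
  W / rs
}

fullStimulus <- function(network, modulation) {
  s <- stats::setNames(rep(0, length(network@nodes)), network@nodes)
  if (length(modulation)) {
    if (!all(names(modulation) %in% network@nodes))
      stop("modulation targets missing from the network: ",
           paste(setdiff(names(modulation), network@nodes), collapse = ", "))
    s[names(modulation)] <- modulation
  }
  s
}

propagateCore <- function(W, s, lambda, maxIter, tol, clamp = NULL) {
  x <- rep(0, nrow(W))
  names(x) <- rownames(W)
  if (!is.null(clamp)) x[names(clamp)] <- clamp
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    xn <- tanh(lambda * as.vector(W %*% x) + s)
    names(xn) <- names(x)
    if (!is.null(clamp)) xn[names(clamp)] <- clamp
    if (max(abs(xn - x)) < tol) { x <- xn; converged <- TRUE; break }
    x <- xn
  }
  list(activity = x, converged = converged, iterations = it)
}

#' Propagate a drug stimulus into bounded protein activities
#'
#' Damped signed network propagation: starting from rest, iterate
#' \code{x <- tanh(lambda * W x + s)} with the row-normalized signed
#' adjacency W and the stimulus vector s (per-target modulation plus any
#' persistent comorbidity inputs) until the state changes by less than
#' \code{tol}, or \code{maxIter} iterations. All activities stay strictly
#' inside (-1, 1). A seeded Gaussian perturbation of the stimulus
#' (\code{noise} > 0) produces distinct solutions from the same inputs,
#' which is how intra-patient variability is modeled.
#'
#' This propagation is a transparent surrogate for proprietary
#' supervised-trained mechanism-of-action modeling: it reproduces the
#' published interface and constraints (bounded activities, solution
#' ensembles, training-set accuracy gate), not the proprietary training.
#'
#' @param network a [ProteinNetwork-class].
#' @param modulation named stimulus vector (targets and strengths).
#' @param noise SD of the Gaussian stimulus perturbation.
#' @param seed integer seed for the perturbation.
#' @param lambda damping factor in (0, 1).
#' @param maxIter,tol iteration controls.
#' @param clamp optional named values to hold fixed during propagation
#'   (used by the sensitivity sweep).
#' @return list with \code{activity} (named vector in (-1, 1)),
#'   \code{converged}, \code{iterations}, \code{perturbation}.
#' @export
propagateActivity <- function(network, modulation, noise = 0, seed = 1,
                              lambda = 0.9, maxIter = 200, tol = 1e-6,
                              clamp = NULL) {
  stopifnot(lambda > 0, lambda < 1)
  W <- networkMatrix(network)
  s <- fullStimulus(network, modulation)
  eps <- if (noise > 0)
    withSeed(childSeed(seed, "propagate"),
             stats::rnorm(length(s), 0, noise))
  else rep(0, length(s))
  res <- propagateCore(W, s + eps, lambda, maxIter, tol, clamp)
  res$perturbation <- stats::setNames(eps, names(s))
  if (!res$converged)
    warning("propagation did not converge within ", maxIter, " iterations")
  res
}

#' tSignal: signed-definition efficacy statistic
#'
#' tSignal = -(1/n) * sum_i v_i y_i over the n proteins of a disease
#' definition, where v_i is the protein's pathological sign and y_i the
#' modeled activity. +1 means complete reversion of the disease signature
#' (y_i = -v_i for all i), -1 a fully expressed signature. Definition
#' proteins absent from the solution contribute y_i = 0 (neutral) and are
#' reported in the \code{missing} attribute, keeping n fixed.
#'
#' @param solution named activity vector, or the list returned by
#'   [propagateActivity()].
#' @param definition a [DiseaseDefinition-class].
#' @return tSignal in [-1, 1], with attribute \code{missing}.
#' @examples
#' d <- diseaseDefinition("demo", c(A = 1, B = -1, C = 1))
#' computeTSignal(c(A = 0.5, B = 0.5, C = -1), d)  # 1/3
#' @export
computeTSignal <- function(solution, definition) {
  if (is.list(solution) && !is.null(solution$activity))
    solution <- solution$activity
  p <- definition@proteins
  if (nrow(p) == 0L) stop("tSignal is undefined for an empty definition")
  y <- stats::setNames(rep(0, nrow(p)), p$protein)
  present <- intersect(p$protein, names(solution))
  y[present] <- solution[present]
  out <- -sum(p$sign * y) / nrow(p)
  attr(out, "missing") <- setdiff(p$protein, names(solution))
  out
}

drugStimulus <- function(drug, strength = 0.8) {
  t <- drug@targets
  stats::setNames(t$effect * strength, t$protein)
}

#' Training-set accuracy of one solution
#'
#' A solution is one perturbed parametrization of the network model (the
#' stimulus perturbation drawn for it). Its accuracy is the percentage of
#' training relationships it reproduces: for each (drug, condition,
#' expected direction) entry, the entry's drug stimulus is propagated
#' under the solution's perturbation and the sign of the resulting tSignal
#' change relative to baseline is compared with the expected direction.
#'
#' @param solution result of [propagateActivity()] (its
#'   \code{perturbation} is reused), or a named perturbation vector.
#' @param training a [TrainingSet-class].
#' @param network a [ProteinNetwork-class].
#' @param baseline named baseline activity vector (default: untreated rest
#'   state, all zero).
#' @param targetStrength stimulus magnitude per target used for training
#'   stimuli.
#' @param lambda,maxIter,tol propagation controls.
#' @return accuracy percentage in [0, 100].
#' @export
solutionAccuracy <- function(solution, training, network, baseline = NULL,
                             targetStrength = 0.8, lambda = 0.9,
                             maxIter = 200, tol = 1e-6) {
  if (length(training@entries) == 0L) stop("training set is empty")
  eps <- if (is.list(solution)) solution$perturbation else solution
  if (is.null(eps)) eps <- stats::setNames(rep(0, length(network@nodes)),
                                           network@nodes)
  W <- networkMatrix(network)
  ok <- vapply(training@entries, function(e) {
    s <- fullStimulus(network, drugStimulus(e$drug, targetStrength))
    res <- propagateCore(W, s + eps[rownames(W)], lambda, maxIter, tol)
    base <- if (is.null(baseline))
      stats::setNames(rep(0, length(network@nodes)), network@nodes)
    else baseline
    delta <- as.numeric(computeTSignal(res$activity, e$condition)) -
      as.numeric(computeTSignal(base, e$condition))
    sign(delta) == e$direction
  }, logical(1))
  100 * mean(ok)
}

#' Sample a gated ensemble of solutions for one patient and drug
#'
#' Draws seeded stimulus perturbations, propagates each into an activity
#' solution, scores its training-set accuracy, and retains it only when
#' the accuracy reaches the floor. Sampling continues until the ensemble
#' holds at least \code{ensembleMin} retained solutions (default 50, each
#' with accuracy >= 85) or the attempt budget is exhausted, in which case
#' an error reports the best accuracy seen.
#'
#' @param patientId,drug patient identifier and a [DrugModel-class].
#' @param network a [ProteinNetwork-class].
#' @param training a [TrainingSet-class].
#' @param modulation named signed per-target stimulus (from
#'   [targetModulation()]); defaults to the drug's target signs at
#'   \code{targetStrength}.
#' @param comorbidities optional list of [DiseaseDefinition-class]
#'   objects added as weak persistent inputs.
#' @param comorbidityWeight stimulus weight of comorbidity proteins.
#' @param ensembleMin minimum retained solutions.
#' @param accuracyFloor minimum per-solution accuracy (percent).
#' @param noise stimulus perturbation SD.
#' @param maxAttempts attempt budget.
#' @param seed integer seed.
#' @param targetStrength,lambda,maxIter,tol propagation controls.
#' @return A [SolutionEnsemble-class].
#' @export
sampleEnsemble <- function(patientId, drug, network, training,
                           modulation = NULL, comorbidities = list(),
                           comorbidityWeight = 0.25, ensembleMin = 50,
                           accuracyFloor = 85, noise = 0.05,
                           maxAttempts = 40L * ensembleMin, seed = 1,
                           targetStrength = 0.8, lambda = 0.9,
                           maxIter = 200, tol = 1e-6) {
  if (is.null(modulation)) modulation <- drugStimulus(drug, targetStrength)
  stim <- fullStimulus(network, modulation)
  for (cm in comorbidities) {
    p <- cm@proteins
    keep <- p$protein %in% network@nodes
    stim[p$protein[keep]] <- stim[p$protein[keep]] +
      comorbidityWeight * p$sign[keep]
  }
  W <- networkMatrix(network)
  nNode <- length(stim)
  sols <- list(); accs <- numeric(); conv <- logical()
  rejected <- 0L; bestAcc <- -Inf
  withSeed(childSeed(seed, paste0("ensemble-", patientId, "-", drug@drug)), {
    for (a in seq_len(max(maxAttempts, ensembleMin))) {
      eps <- if (noise > 0) stats::rnorm(nNode, 0, noise) else rep(0, nNode)
      names(eps) <- names(stim)
      res <- propagateCore(W, stim + eps, lambda, maxIter, tol)
      acc <- solutionAccuracy(eps, training, network,
                              targetStrength = targetStrength,
                              lambda = lambda, maxIter = maxIter, tol = tol)
      bestAcc <- max(bestAcc, acc)
      if (acc >= accuracyFloor) {
        sols[[length(sols) + 1L]] <- res$activity
        accs <- c(accs, acc)
        conv <- c(conv, res$converged)
        if (length(sols) >= ensembleMin) break
      } else rejected <- rejected + 1L
    }
  })
  if (length(sols) < ensembleMin)
    stop(sprintf(paste0("could not assemble %d solutions with accuracy >= %g ",
                        "within %d attempts (best accuracy seen: %.1f)"),
                 ensembleMin, accuracyFloor, maxAttempts, bestAcc))
  A <- do.call(cbind, sols)
  colnames(A) <- sprintf("sol%03d", seq_len(ncol(A)))
  new("SolutionEnsemble", patientId = as.character(patientId),
      drugId = drug@drug, activities = A, accuracy = accs,
      modulation = modulation, rejections = as.numeric(rejected),
      converged = conv)
}

#' Mean tSignal of an ensemble
#'
#' @param ensemble a [SolutionEnsemble-class].
#' @param definition a [DiseaseDefinition-class].
#' @return mean tSignal over the ensemble's solutions.
#' @export
ensembleTSignal <- function(ensemble, definition) {
  mean(apply(ensemble@activities, 2, function(y)
    as.numeric(computeTSignal(y, definition))))
}
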