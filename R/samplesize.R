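#' Normalize raw expression counts
#'
#' Library-size normalization (TMM factors) followed by a
#' log2-counts-per-million transform with a 0.5 prior count, via
#' \pkg{edgeR}. All-zero samples are removed with a warning. The result is
#' deterministic.
#'
#' @param counts non-negative matrix, genes x samples.
#' @param labels cohort labels per sample, "control" or "case".
#' @return A \linkS4class{SummarizedExperiment} with assay \code{logcpm}
#'   and column data \code{cohort}.
#' @export
normalizeExpression <- function(counts, labels) {
  counts <- as.matrix(counts)
  stopifnot(min(counts) >= 0, ncol(counts) == length(labels))
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    warning("removing ", sum(libsize == 0), " all-zero sample(s)")
    counts <- counts[, libsize > 0, drop = FALSE]
    labels <- labels[libsize > 0]
  }
  if (!all(labels %in% c("control", "case")))
    stop("labels must be 'control' or 'case'")
  if (!all(c("control", "case") %in% labels))
    stop("both cohorts must be non-empty")
  d <- edgeR::calcNormFactors(edgeR::DGEList(counts))
  logcpm <- edgeR::cpm(d, log = TRUE, prior.count = 0.5)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(logcpm = logcpm),
    colData = S4Vectors::DataFrame(cohort = labels))
}

exprMatrix <- function(dataset, genes = NULL) {
  X <- SummarizedExperiment::assay(dataset, "logcpm")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(X))
    if (length(missing)) stop("genes absent from the dataset: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  list(X = t(X),   # samples x genes
       y = SummarizedExperiment::colData(dataset)$cohort == "case")
}

## two-class linear discriminant on a feature matrix (samples x features)
ldaFit <- function(X, y) {
  m0 <- colMeans(X[!y, , drop = FALSE]); m1 <- colMeans(X[y, , drop = FALSE])
  S <- (crossprod(sweep(X[!y, , drop = FALSE], 2, m0)) +
        crossprod(sweep(X[y, , drop = FALSE], 2, m1))) /
    max(1, nrow(X) - 2)
  S <- S + diag(1e-8, ncol(X))
  w <- solve(S, m1 - m0)
  list(w = w, c = sum(w * (m0 + m1)) / 2)
}

ldaPredict <- function(fit, X) as.vector(X %*% fit$w) > fit$c

## vectorized two-sample t statistics per feature
tScreen <- function(X, y) {
  n1 <- sum(y); n0 <- sum(!y)
  m1 <- colMeans(X[y, , drop = FALSE]); m0 <- colMeans(X[!y, , drop = FALSE])
  v1 <- apply(X[y, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[!y, , drop = FALSE], 2, stats::var)
  abs(m1 - m0) / sqrt(pmax(v1 / n1 + v0 / n0, 1e-12))
}

## choose the best feature pair: t-statistic screen to nScreen candidates,
## then exhaustive pair search by resubstitution accuracy
selectPair <- function(X, y, nScreen = 6) {
  cand <- order(tScreen(X, y), decreasing = TRUE)[seq_len(min(nScreen, ncol(X)))]
  pairs <- utils::combn(cand, 2)
  acc <- apply(pairs, 2, function(pr) {
    f <- ldaFit(X[, pr, drop = FALSE], y)
    mean(ldaPredict(f, X[, pr, drop = FALSE]) == y)
  })
  pairs[, which.max(acc)]
}

## stratified k-fold CV of the pair classifier; the feature pair is
## re-selected inside every training fold so the estimate is unbiased
cvPairAccuracy <- function(X, y, k = 10, nScreen = 6) {
  n <- nrow(X)
  k <- max(2L, min(k, sum(y), sum(!y)))
  fold <- integer(n)
  fold[y] <- rep_len(seq_len(k), sum(y))[sample.int(sum(y))]
  fold[!y] <- rep_len(seq_len(k), sum(!y))[sample.int(sum(!y))]
  hits <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    pr <- selectPair(X[tr, , drop = FALSE], y[tr], nScreen)
    fit <- ldaFit(X[tr, pr, drop = FALSE], y[tr])
    hits <- hits + sum(ldaPredict(fit, X[!tr, pr, drop = FALSE]) == y[!tr])
  }
  hits / n
}

#' Maximum achievable control-vs-case accuracy
#'
#' Ceiling accuracy of the two-feature linear classifier on the full
#' dataset, estimated by stratified 10-fold cross-validation with the
#' feature-pair selection (univariate-t screen plus best-pair search)
#' nested inside every fold.
#'
#' @param dataset output of [normalizeExpression()].
#' @param genes optional gene subset (disease-definition genes).
#' @param seed integer seed (fold assignment).
#' @param nScreen screened candidate features before the pair search.
#' @return accuracy in [0, 1].
#' @export
maxAccuracy <- function(dataset, genes = NULL, seed = 1, nScreen = 6) {
  d <- exprMatrix(dataset, genes)
  if (sum(d$y) < 10 || sum(!d$y) < 10)
    stop("each cohort must hold at least 10 samples")
  withSeed(childSeed(seed, "maxacc"), cvPairAccuracy(d$X, d$y, 10, nScreen))
}

#' Progressive-sampling power curve
#'
#' For each total sample size n on the grid (even numbers from 8 up to
#' twice the smallest cohort), draws \code{reps} balanced 1:1 subsets
#' without replacement, trains the two-feature linear classifier on each
#' and estimates its accuracy by stratified 10-fold cross-validation. A
#' normal distribution is fitted to the per-n accuracies (sample mean and
#' SD); the curves reported at 95% and 99% statistical power are the
#' one-sided lower quantiles (mean - 1.645 sd and mean - 2.326 sd),
#' expressed as a percentage of the maximum achievable accuracy.
#'
#' @param dataset output of [normalizeExpression()].
#' @param genes optional gene subset.
#' @param reps repetitions per sample size (default 100).
#' @param seed integer seed.
#' @param nScreen screened candidates for pair selection.
#' @param maxAcc precomputed ceiling accuracy; computed via
#'   [maxAccuracy()] when NULL.
#' @return A [PowerCurve-class].
#' @export
progressiveCurve <- function(dataset, genes = NULL, reps = 100, seed = 1,
                             nScreen = 6, maxAcc = NULL) {
  d <- exprMatrix(dataset, genes)
  nSmall <- min(sum(d$y), sum(!d$y))
  if (nSmall < 8) stop("smallest cohort must hold at least 8 samples")
  if (is.null(maxAcc)) maxAcc <- maxAccuracy(dataset, genes, seed, nScreen)
  grid <- seq(8L, 2L * nSmall, by = 2L)
  idx1 <- which(d$y); idx0 <- which(!d$y)
  rows <- withSeed(childSeed(seed, "progressive"), {
    lapply(grid, function(n) {
      half <- n %/% 2L
      accs <- vapply(seq_len(reps), function(r) {
        take <- c(sample(idx0, half), sample(idx1, half))
        cvPairAccuracy(d$X[take, , drop = FALSE], d$y[take],
                       k = min(10, n), nScreen = nScreen)
      }, numeric(1))
      data.frame(n = n, mean_acc = mean(accs), sd_acc = stats::sd(accs))
    })
  })
  g <- do.call(rbind, rows)
  z95 <- stats::qnorm(0.95); z99 <- stats::qnorm(0.99)
  g$pct_of_max_power95 <- 100 * (g$mean_acc - z95 * g$sd_acc) / maxAcc
  g$pct_of_max_power99 <- 100 * (g$mean_acc - z99 * g$sd_acc) / maxAcc
  new("PowerCurve", grid = g, maxAccuracy = maxAcc, reps = reps)
}

#' Required sample size from a power curve
#'
#' Smallest grid sample size whose power-quantile percentage of the
#' maximum accuracy reaches the threshold.
#'
#' @param curve a [PowerCurve-class].
#' @param threshold required percentage of maximum accuracy.
#' @param power statistical power, 95 or 99.
#' @return list with \code{total} (NA when not achievable),
#'   \code{perCohort} and \code{achievable}.
#' @export
requiredSampleSize <- function(curve, threshold = 85, power = 95) {
  stopifnot(power %in% c(95, 99))
  col <- paste0("pct_of_max_power", power)
  g <- curve@grid
  ok <- which(g[[col]] >= threshold)
  if (length(ok) == 0L)
    return(list(total = NA_integer_, perCohort = NA_integer_,
                achievable = FALSE))
  n <- g$n[min(ok)]
  list(total = as.integer(n), perCohort = as.integer(n / 2),
       achievable = TRUE)
}
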