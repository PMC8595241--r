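#' One-at-a-time local sensitivity of the tSignal response
#'
#' For each queried protein, its activity is clamped to each grid value in
#' (-1, 1), the network propagation is re-run with the clamp held, and the
#' tSignal over the disease definition is recomputed. The sensitivity is
#' the mean absolute tSignal difference from the unclamped model,
#' expressed as a percentage of the maximal possible tSignal variation,
#' taken as 2 (the width of (-1, 1)) minus the original tSignal.
#'
#' This is a local one-at-a-time sweep over the model parameters (protein
#' activities), not a variance-decomposition index.
#'
#' @param network a [ProteinNetwork-class].
#' @param modulation named stimulus vector of the model under study.
#' @param definition a [DiseaseDefinition-class].
#' @param proteins proteins to sweep (default: all network nodes).
#' @param grid activity grid, at least 5 points strictly inside (-1, 1).
#' @param lambda,maxIter,tol propagation controls.
#' @return data.frame with columns \code{protein}, \code{sensitivity_pct}
#'   (in [0, 100]) and \code{impact} (TRUE when > 15).
#' @export
localSensitivity <- function(network, modulation, definition,
                             proteins = network@nodes,
                             grid = seq(-0.99, 0.99, length.out = 21),
                             lambda = 0.9, maxIter = 200, tol = 1e-6) {
  stopifnot(length(grid) >= 5, all(grid > -1 & grid < 1))
  missing <- setdiff(proteins, network@nodes)
  if (length(missing))
    stop("proteins not in the network: ", paste(missing, collapse = ", "))
  W <- networkMatrix(network)
  s <- fullStimulus(network, modulation)
  base <- propagateCore(W, s, lambda, maxIter, tol)
  baseTS <- as.numeric(computeTSignal(base$activity, definition))
  denom <- 2 - baseTS
  pct <- vapply(proteins, function(pr) {
    deltas <- vapply(grid, function(g) {
      res <- propagateCore(W, s, lambda, maxIter, tol,
                           clamp = stats::setNames(g, pr))
      abs(as.numeric(computeTSignal(res$activity, definition)) - baseTS)
    }, numeric(1))
    min(100, 100 * mean(deltas) / denom)
  }, numeric(1))
  data.frame(protein = proteins, sensitivity_pct = unname(pct),
             impact = unname(pct) > 15, row.names = NULL)
}

#' Rank proteins by sensitivity
#'
#' Descending by sensitivity percentage with a deterministic lexicographic
#' tie-break on protein id; proteins above the impact threshold are
#' flagged.
#'
#' @param results output of [localSensitivity()].
#' @param topM keep only the first \code{topM} rows (default: all).
#' @param threshold impact threshold in percent.
#' @return reordered data.frame with refreshed \code{impact} flags.
#' @export
rankSensitiveProteins <- function(results, topM = NULL, threshold = 15) {
  if (nrow(results) == 0L) stop("empty sensitivity results")
  ord <- order(-results$sensitivity_pct, results$protein)
  out <- results[ord, , drop = FALSE]
  out$impact <- out$sensitivity_pct > threshold
  rownames(out) <- NULL
  if (!is.null(topM)) out <- utils::head(out, topM)
  out
}

#' Hopkins statistic of clustering tendency
#'
#' Standard Hopkins statistic: nearest-neighbor distances from uniform
#' reference points drawn in the data bounding box (u) versus from
#' sampled data points to the remaining data (w), combined as
#' sum(u^d) / (sum(u^d) + sum(w^d)). Spatially uniform data give values
#' near 0.5; clustered data approach 1. Zero-range dimensions are dropped
#' with a warning.
#'
#' @param data numeric matrix (>= 10 rows).
#' @param sampleFraction fraction of rows sampled as probes.
#' @param seed integer seed.
#' @return Hopkins statistic in [0, 1].
#' @export
hopkinsStatistic <- function(data, sampleFraction = 0.1, seed = 1) {
  X <- as.matrix(data)
  if (nrow(X) < 10L) stop("need at least 10 rows")
  rng <- apply(X, 2, range)
  keep <- rng[2, ] - rng[1, ] > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-range dimension(s)")
    X <- X[, keep, drop = FALSE]
    rng <- rng[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-degenerate dimensions left")
  n <- nrow(X); d <- ncol(X)
  m <- max(1L, round(sampleFraction * n))
  withSeed(childSeed(seed, "hopkins"), {
    probes <- sample.int(n, m)
    U <- sapply(seq_len(d), function(j) stats::runif(m, rng[1, j], rng[2, j]))
    if (m == 1L) U <- matrix(U, 1)
    nn <- function(P, ref) apply(P, 1, function(p)
      sqrt(min(colSums((t(ref) - p)^2))))
    u <- nn(U, X)
    w <- vapply(probes, function(i)
      sqrt(min(colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2))), numeric(1))
    sum(u^d) / (sum(u^d) + sum(w^d))
  })
}

#' Mean silhouette index of a clustering
#'
#' Standard silhouette widths via \pkg{cluster}; singleton clusters score
#' 0.
#'
#' @param data numeric matrix.
#' @param labels integer cluster labels (k >= 2).
#' @return mean silhouette width in [-1, 1].
#' @export
silhouetteIndex <- function(data, labels) {
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined for a single cluster")
  sil <- cluster::silhouette(as.integer(labels), stats::dist(data))
  mean(sil[, "sil_width"])
}

#' Bootstrap Jaccard stability of a clustering
#'
#' For each of B bootstrap resamples the data are reclustered with k-means
#' (same k), and each original cluster is matched to the bootstrap cluster
#' with the greatest Jaccard overlap (computed over the distinct rows
#' present in the resample). Stability is the per-cluster mean best-match
#' Jaccard over the B resamples.
#'
#' @param data numeric matrix.
#' @param labels integer cluster labels.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return named numeric, per-cluster stability in [0, 1].
#' @export
jaccardBootstrap <- function(data, labels, B = 100, seed = 1) {
  X <- as.matrix(data)
  k <- length(unique(labels))
  if (k < 2L) stop("need at least 2 clusters")
  orig <- split(seq_len(nrow(X)), labels)
  withSeed(childSeed(seed, "jaccard"), {
    acc <- matrix(0, B, k)
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      km <- tryCatch(stats::kmeans(X[idx, , drop = FALSE], k, nstart = 5),
                     error = function(e) NULL)
      if (is.null(km)) { acc[b, ] <- NA; next }
      boot <- split(unique(idx), vapply(split(km$cluster, idx)[as.character(unique(idx))],
                                        function(v) v[1], numeric(1)))
      ## boot: distinct original rows grouped by their bootstrap cluster
      acc[b, ] <- vapply(seq_len(k), function(ci) {
        A <- intersect(orig[[ci]], unique(idx))
        if (length(A) == 0L) return(NA_real_)
        max(vapply(boot, function(Bset)
          length(intersect(A, Bset)) / length(union(A, Bset)), numeric(1)))
      }, numeric(1))
    }
    stats::setNames(colMeans(acc, na.rm = TRUE), paste0("cluster", seq_len(k)))
  })
}

#' Cluster solutions and select the number of clusters
#'
#' Projects the feature matrix onto its first \code{pcaDims} principal
#' components, runs k-means (25 restarts) for each candidate k, discards
#' candidates whose smallest/largest cluster-size ratio falls below
#' \code{sizeRatioMin} (heavily unbalanced groups), and selects the k with
#' the highest mean silhouette, breaking ties by mean bootstrap Jaccard
#' stability. Hopkins, silhouette and Jaccard indices of the winner are
#' reported.
#'
#' @param data numeric matrix, rows = solutions, columns = features
#'   (typically final activities of the definition's effector proteins).
#' @param kRange candidate cluster counts.
#' @param pcaDims number of principal components retained.
#' @param seed integer seed.
#' @param sizeRatioMin minimum smallest/largest cluster-size ratio.
#' @param B bootstrap resamples for the Jaccard index.
#' @return A [ClusteringResult-class].
#' @export
selectOptimalK <- function(data, kRange = 2:7, pcaDims = 5, seed = 1,
                           sizeRatioMin = 0.05, B = 100) {
  X <- as.matrix(data)
  if (nrow(X) < 2L * max(kRange))
    stop("need at least ", 2L * max(kRange), " rows")
  if (all(apply(X, 2, stats::var) < 1e-24))
    stop("no valid clustering: rows are identical")
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  dims <- min(pcaDims, ncol(pca$x))
  scores <- pca$x[, seq_len(dims), drop = FALSE]
  ev <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(dims)]
  fits <- list()
  perK <- data.frame()
  withSeed(childSeed(seed, "kmeans"), {
    for (k in kRange) {
      km <- stats::kmeans(scores, k, nstart = 25, iter.max = 100)
      ratio <- min(km$size) / max(km$size)
      kept <- ratio >= sizeRatioMin
      sil <- if (kept) silhouetteIndex(scores, km$cluster) else NA_real_
      fits[[as.character(k)]] <- km
      perK <- rbind(perK, data.frame(k = k, silhouette = sil,
                                     size_ratio = ratio, kept = kept))
    }
  })
  cand <- perK[perK$kept, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no valid clustering: every k was filtered")
  best <- cand[abs(cand$silhouette - max(cand$silhouette)) < 1e-12, ]
  if (nrow(best) > 1L) {
    jac <- vapply(best$k, function(k)
      mean(jaccardBootstrap(scores, fits[[as.character(k)]]$cluster, B, seed)),
      numeric(1))
    best <- best[which.max(jac), , drop = FALSE]
  }
  kStar <- best$k[1]
  km <- fits[[as.character(kStar)]]
  idx <- list(hopkins = hopkinsStatistic(scores, seed = seed),
              silhouette = silhouetteIndex(scores, km$cluster),
              jaccard = jaccardBootstrap(scores, km$cluster, B, seed))
  new("ClusteringResult", k = as.numeric(kStar),
      labels = as.integer(km$cluster), scores = scores,
      explainedVariance = ev, indices = idx, perK = perK)
}

#' Compare variables across clusters
#'
#' Per variable: an overall one-way test across clusters (ANOVA, or
#' Kruskal-Wallis when any cluster has fewer than 30 members) plus a
#' per-cluster two-sided test of each cluster against the pooled rest
#' (Student's t, or Mann-Whitney under the same small-sample rule).
#' Benjamini-Hochberg adjustment is applied within each variable's family
#' of per-cluster tests. Variables with zero within-group variance are
#' flagged as test-undefined.
#'
#' @param data data.frame of variables (one row per solution or patient).
#' @param labels cluster labels.
#' @param alpha significance level.
#' @return list with \code{overall} (variable, test, statistic, p) and
#'   \code{perCluster} (variable, cluster, test, p, q, significant).
#' @export
compareClusters <- function(data, labels, alpha = 0.05) {
  data <- as.data.frame(data)
  labels <- as.factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 clusters with at least 2 members each")
  nonpar <- any(tab < 30)
  overall <- data.frame(); perCluster <- data.frame()
  for (v in names(data)) {
    x <- data[[v]]
    groups <- split(x, labels)
    if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1)))) {
      overall <- rbind(overall, data.frame(variable = v, test = "undefined",
                                           statistic = NA, p = NA))
      next
    }
    if (nonpar) {
      kt <- stats::kruskal.test(x, labels)
      overall <- rbind(overall, data.frame(variable = v, test = "kruskal",
                                           statistic = unname(kt$statistic),
                                           p = kt$p.value))
    } else {
      av <- stats::oneway.test(x ~ labels, var.equal = TRUE)
      overall <- rbind(overall, data.frame(variable = v, test = "anova",
                                           statistic = unname(av$statistic),
                                           p = av$p.value))
    }
    ps <- vapply(levels(labels), function(l) {
      a <- x[labels == l]; b <- x[labels != l]
      if (stats::var(a) == 0 && stats::var(b) == 0) return(NA_real_)
      if (nonpar) stats::wilcox.test(a, b, exact = FALSE)$p.value
      else stats::t.test(a, b)$p.value
    }, numeric(1))
    q <- stats::p.adjust(ps, "BH")
    perCluster <- rbind(perCluster, data.frame(
      variable = v, cluster = levels(labels),
      test = if (nonpar) "wilcox" else "t", p = unname(ps), q = unname(q),
      significant = !is.na(q) & q < alpha))
  }
  list(overall = overall, perCluster = perCluster)
}
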