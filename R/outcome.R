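#' Per-drug mean tSignal
#'
#' Averages tSignal over solutions within each ensemble, then over the
#' ensembles (patients) of each drug.
#'
#' @param ensembles list of [SolutionEnsemble-class] objects.
#' @param definition a [DiseaseDefinition-class].
#' @return named numeric, mean tSignal per drug id.
#' @export
drugLevelTSignal <- function(ensembles, definition) {
  if (length(ensembles) == 0L) stop("no ensembles to aggregate")
  drugs <- vapply(ensembles, function(e) e@drugId, character(1))
  per <- vapply(ensembles, ensembleTSignal, numeric(1), definition)
  tapply(per, drugs, mean) |> c()
}

#' Pearson correlation between per-drug tSignal and clinical efficacy
#'
#' Clinical efficacy records (ADHD-RS-IV change from baseline; negative =
#' improvement) of the same drug are pooled by plain averaging before
#' correlating. Since higher tSignal means more reversion of the disease
#' signature, the expected correlation is negative; a positive value is
#' reported with a warning, not an error.
#'
#' @param tsignals named per-drug tSignal values.
#' @param records data.frame with columns \code{drug},
#'   \code{adhd_rs_change} (and optionally \code{trial_id},
#'   \code{population}).
#' @return Pearson correlation over drugs present in both inputs.
#' @export
efficacyCorrelation <- function(tsignals, records) {
  eff <- tapply(records$adhd_rs_change, records$drug, mean)
  common <- intersect(names(tsignals), names(eff))
  if (length(common) < 3L)
    stop("need at least 3 drugs with both tSignal and efficacy")
  x <- tsignals[common]; y <- eff[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  rho <- stats::cor(x, y)
  if (rho > 0)
    warning("positive tSignal-efficacy correlation; check sign conventions")
  rho
}

## per-drug tSignal restricted to a protein subset, from per-drug mean
## activity vectors (proteins x drugs matrix)
subsetTSignals <- function(meanAct, proteins, signs) {
  -colSums(meanAct[proteins, , drop = FALSE] * signs) / length(proteins)
}

#' Trim a disease definition against clinical efficacy data
#'
#' Greedy backward elimination: repeatedly remove the single protein whose
#' removal most increases the absolute Pearson correlation between the
#' per-drug mean tSignal (restricted to the retained set) and the pooled
#' clinical efficacy values. Stops when no removal improves the absolute
#' correlation by more than \code{tolImprove}, or when the retained set
#' would shrink below \code{floorFrac} of the original definition. Ties
#' break lexicographically on protein id, so the trace replays
#' deterministically.
#'
#' @param definition a [DiseaseDefinition-class].
#' @param ensembles list of [SolutionEnsemble-class] (several drugs).
#' @param records clinical efficacy records, see [efficacyCorrelation()].
#' @param tolImprove minimum |rho| improvement to keep trimming.
#' @param floorFrac smallest retained fraction of the original definition.
#' @return A [TrimmedDefinition-class].
#' @export
trimDefinition <- function(definition, ensembles, records,
                           tolImprove = 1e-4, floorFrac = 0.5) {
  p <- definition@proteins
  if (nrow(p) < 2L) stop("definition must hold at least 2 proteins")
  drugs <- vapply(ensembles, function(e) e@drugId, character(1))
  ## per-drug mean activity over solutions then patients, rows = proteins
  meanAct <- sapply(sort(unique(drugs)), function(d) {
    rowMeans(sapply(ensembles[drugs == d], function(e) rowMeans(e@activities)))
  })
  missing <- setdiff(p$protein, rownames(meanAct))
  if (length(missing)) {
    pad <- matrix(0, length(missing), ncol(meanAct),
                  dimnames = list(missing, colnames(meanAct)))
    meanAct <- rbind(meanAct, pad)
  }
  eff <- tapply(records$adhd_rs_change, records$drug, mean)
  common <- intersect(colnames(meanAct), names(eff))
  if (length(common) < 3L) stop("need at least 3 drugs to correlate")
  eff <- eff[common]
  rhoOf <- function(keep) {
    ts <- subsetTSignals(meanAct[, common, drop = FALSE], p$protein[keep],
                         p$sign[keep])
    if (stats::sd(ts) == 0) return(NA_real_)
    stats::cor(ts, eff)
  }
  keep <- rep(TRUE, nrow(p))
  rhoFull <- rhoOf(keep)
  if (is.na(rhoFull)) stop("correlation undefined on the full definition")
  rho <- rhoFull
  floorN <- max(2L, ceiling(floorFrac * nrow(p)))
  trace <- data.frame(protein = character(), rho = numeric())
  ord <- order(p$protein)  # lexicographic candidate order fixes tie-breaks
  repeat {
    if (sum(keep) <= floorN) break
    best <- NULL; bestRho <- rho
    for (i in ord[keep[ord]]) {
      cand <- keep; cand[i] <- FALSE
      r <- rhoOf(cand)
      if (!is.na(r) && abs(r) > abs(bestRho) + tolImprove) {
        best <- i; bestRho <- r
      }
    }
    if (is.null(best)) break
    keep[best] <- FALSE
    rho <- bestRho
    trace <- rbind(trace, data.frame(protein = p$protein[best], rho = rho))
  }
  new("TrimmedDefinition",
      definition = diseaseDefinition(paste0(definition@name, "-trimmed"),
                                     p[keep, , drop = FALSE]),
      rho = rho, rhoFull = rhoFull, trace = trace)
}

#' Fit the linear mapping from tSignal to the clinical scale
#'
#' Ordinary least squares of pooled ADHD-RS-IV change on per-drug mean
#' tSignal.
#'
#' @param tsignals named per-drug tSignal values.
#' @param records clinical efficacy records.
#' @return An [EfficacyMapping-class].
#' @export
fitEfficacyMapping <- function(tsignals, records) {
  eff <- tapply(records$adhd_rs_change, records$drug, mean)
  common <- intersect(names(tsignals), names(eff))
  if (length(common) < 3L) stop("need at least 3 paired points")
  x <- tsignals[common]; y <- eff[common]
  if (stats::sd(x) == 0) stop("rank-deficient fit: tSignal has no variance")
  fit <- stats::lm(y ~ x)
  new("EfficacyMapping", intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]), rho = stats::cor(x, y),
      residualSd = stats::sd(stats::residuals(fit)), n = length(common))
}

#' Predict clinical efficacy from tSignal
#'
#' @param mapping an [EfficacyMapping-class].
#' @param tsignal tSignal value(s).
#' @return predicted ADHD-RS-IV change from baseline.
#' @export
predictEfficacy <- function(mapping, tsignal) {
  mapping@intercept + mapping@slope * tsignal
}
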