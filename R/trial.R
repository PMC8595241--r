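## End-to-end trial driver: population generation -> PBPK exposure ->
## target modulation -> gated solution ensembles -> tSignal -> analyses.

## small content fingerprint for provenance (multiplicative rolling hash)
fnvHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Demo trial configuration
#'
#' A desk-scale configuration of the two-drug crossover protocol on the
#' packaged synthetic network fixture: one population kind, a scaled-down
#' arm design, and spec-default ensemble gates (at least
#' \code{ensembleMin} solutions per patient, accuracy floor 85).
#'
#' @param kind population kind.
#' @param nPatients population size.
#' @param seed global trial seed.
#' @param ensembleMin retained solutions per patient and drug.
#' @param tEnd simulated exposure window (h).
#' @return configuration list consumed by [runTrial()].
#' @export
demoTrialConfig <- function(kind = "adult", nPatients = 10, seed = 1,
                            ensembleMin = 50, tEnd = 24) {
  list(kind = kind, nPatients = nPatients, seed = seed,
       ensembleMin = ensembleMin, accuracyFloor = 85, noise = 0.05,
       tEnd = tEnd, ec50 = 0.02,
       arms = list(armSpec("adhd_only", nPatients)))
}

#' Run the three-phase in silico trial protocol
#'
#' Phase I: molecular setup (network, disease definition, two drug target
#' profiles and training set from the synthetic fixture generator).
#' Phase II: virtual population generation and arm allocation, per-patient
#' PBPK simulation of each drug's dosing scheme, brain-exposure Emax
#' modulation, and gated solution ensembles. Both drugs are applied to the
#' same cloned baseline state per patient (two-period crossover with zero
#' carryover). Phase III: tSignal scoring, clustering of effector
#' activities with validation indices, local sensitivity of the most
#' relevant proteins, and cluster comparison statistics.
#'
#' @param config configuration list, see [demoTrialConfig()], or a path to
#'   a YAML file holding one.
#' @param outDir optional directory; when given, per-phase artifacts
#'   (population table, tSignal table, JSON summary) are written with the
#'   config hash in their provenance.
#' @return trial bundle: list with \code{population}, \code{profiles},
#'   \code{ensembles}, \code{tsignals}, \code{clustering},
#'   \code{sensitivity}, \code{comparison}, \code{configHash}.
#' @export
runTrial <- function(config = demoTrialConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed
  hash <- fnvHash(config)

  ## Phase I: molecular characterization (synthetic stand-ins)
  fx <- synthNetworkWithDefinitions(seed = childSeed(seed, "molecular"))
  drugs <- fx$drugs

  ## Phase II: populations, exposure, QSP ensembles
  refs <- synthReferencePopulation(config$kind)
  pop <- if (config$kind == "adult")
    generateAdultVpop(refs$reference, n = config$nPatients, seed = seed)
  else
    generatePediatricVpop(refs$reference, refs$growth, n = config$nPatients,
                          seed = seed)
  pop <- assignArms(pop, config$arms, seed)
  pts <- patients(pop)

  sampleTimes <- seq(0.5, config$tEnd, by = 0.5)
  profiles <- list(); ensembles <- list()
  tsRows <- list()
  for (i in seq_len(nrow(pts))) {
    for (d in drugs) {
      params <- individualizeParameters(pts[i, ], d)
      scheme <- expandExtendedRelease(d)
      prof <- simulatePBPK(params, scheme, tEnd = config$tEnd)
      brain <- tissueTimepoints(prof, "brain", sampleTimes)
      tgt <- d@targets
      tgt$ec50 <- config$ec50
      mod <- targetModulation(brain, tgt)
      ens <- sampleEnsemble(pts$id[i], d, fx$network, fx$training,
                            modulation = mod,
                            ensembleMin = config$ensembleMin,
                            accuracyFloor = config$accuracyFloor,
                            noise = config$noise,
                            seed = childSeed(seed, paste0(pts$id[i], d@drug)))
      key <- paste(pts$id[i], d@drug, sep = ".")
      profiles[[key]] <- prof
      ensembles[[key]] <- ens
      tsRows[[key]] <- data.frame(
        patient = pts$id[i], drug = d@drug,
        tsignal = ensembleTSignal(ens, fx$definition),
        accuracy = mean(solutionAccuracies(ens)))
    }
  }
  tsignals <- do.call(rbind, c(tsRows, list(make.row.names = FALSE)))

  ## Phase III: analysis on pooled effector activities
  eff <- fx$definition@proteins$protein
  feat <- t(do.call(cbind, lapply(ensembles, function(e)
    activities(e)[eff, , drop = FALSE])))
  drugOfRow <- rep(vapply(ensembles, function(e) e@drugId, character(1)),
                   vapply(ensembles, length, integer(1)))
  patientOfRow <- rep(vapply(ensembles, function(e) e@patientId, character(1)),
                      vapply(ensembles, length, integer(1)))
  clustering <- tryCatch(
    selectOptimalK(feat, seed = childSeed(seed, "cluster")),
    error = function(e) e)
  sens <- localSensitivity(fx$network, drugStimulus(drugs[[1]]),
                           fx$definition)
  sens <- rankSensitiveProteins(sens)
  comparison <- NULL
  if (is(clustering, "ClusteringResult")) {
    solTs <- vapply(seq_len(nrow(feat)), function(r)
      as.numeric(computeTSignal(feat[r, ], fx$definition)), numeric(1))
    demo <- pts[match(patientOfRow, pts$id),
                c("age", "height_cm", "weight_kg", "bmi")]
    df <- cbind(tsignal = solTs, demo)
    comparison <- tryCatch(compareClusters(df, clustering@labels),
                           error = function(e) e)
  }
  bundle <- list(population = pop, profiles = profiles, ensembles = ensembles,
                 tsignals = tsignals, clustering = clustering,
                 sensitivity = sens, comparison = comparison,
                 definition = fx$definition, configHash = hash,
                 config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeVirtualPopulation(pop, file.path(outDir, "population.tsv"))
    utils::write.table(tsignals, file.path(outDir, "tsignals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = seed,
           mean_tsignal = as.list(tapply(tsignals$tsignal, tsignals$drug, mean)),
           k = if (is(clustering, "ClusteringResult")) clustering@k else NA),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Summarize a trial bundle
#'
#' @param bundle output of [runTrial()].
#' @param topM sensitivity rows reported.
#' @return report list (per-drug tSignal summary, cluster summary, top
#'   sensitivity table); printed compactly.
#' @export
summarizeTrial <- function(bundle, topM = 30) {
  need <- c("tsignals", "sensitivity")
  missing <- setdiff(need, names(bundle)[!vapply(bundle, is.null, logical(1))])
  ts <- bundle$tsignals
  perDrug <- do.call(rbind, lapply(split(ts, ts$drug), function(d)
    data.frame(drug = d$drug[1], mean_tsignal = mean(d$tsignal),
               sd_tsignal = stats::sd(d$tsignal),
               mean_accuracy = mean(d$accuracy))))
  report <- list(
    perDrug = perDrug,
    cluster = if (is(bundle$clustering, "ClusteringResult")) {
      list(k = bundle$clustering@k, indices = bundle$clustering@indices)
    } else NULL,
    sensitivityTop = utils::head(bundle$sensitivity, topM),
    incomplete = missing)
  if (length(missing))
    warning("partial report; missing stages: ", paste(missing, collapse = ", "))
  cat("In silico trial summary (config ", bundle$configHash, ")\n", sep = "")
  print(report$perDrug, row.names = FALSE)
  if (!is.null(report$cluster))
    cat(sprintf("clusters: k = %d, silhouette %.3f, Hopkins %.3f\n",
                report$cluster$k, report$cluster$indices$silhouette,
                report$cluster$indices$hopkins))
  cat(sprintf("top sensitive proteins reported: %d\n",
              nrow(report$sensitivityTop)))
  invisible(report)
}
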