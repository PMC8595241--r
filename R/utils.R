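## Deterministic seed fan-out: every stage draws its own substream seed so a
## single trial seed reproduces the whole pipeline without stages sharing RNG
## state. Kept below 2^31 - R integers are 32-bit.
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563) + 1L
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read a growth reference from a tab-separated file
#'
#' Expected columns: \code{age}, \code{sex}, \code{variable}, \code{mean},
#' \code{sd}.
#'
#' @param path file path.
#' @return A [GrowthReference-class] object.
#' @export
readGrowthReference <- function(path) {
  growthReference(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a signed protein network from a tab-separated edge list
#'
#' Expected columns: \code{source}, \code{target}, \code{sign},
#' \code{weight} (weight defaults to 1 when absent).
#'
#' @param path file path.
#' @return A [ProteinNetwork-class] object.
#' @export
readProteinNetwork <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"weight" %in% names(e)) e$weight <- 1
  proteinNetwork(e)
}

#' Read a disease definition from a tab-separated (protein, sign) table
#'
#' @param path file path.
#' @param name condition name; defaults to the file base name.
#' @return A [DiseaseDefinition-class] object.
#' @export
readDiseaseDefinition <- function(path, name = NULL) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  diseaseDefinition(name, p)
}

#' Read observed pharmacokinetic datapoints
#'
#' Expected columns: \code{time_h}, \code{conc_mg_per_L}.
#'
#' @param path delimiter-separated file path.
#' @param sep field separator.
#' @return data.frame with strictly increasing times.
#' @export
readPKObservations <- function(path, sep = "\t") {
  obs <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "conc_mg_per_L") %in% names(obs)))
  if (any(diff(obs$time_h) <= 0)) stop("observation times must be strictly increasing")
  if (any(obs$conc_mg_per_L < 0)) stop("observed concentrations must be >= 0")
  obs
}

#' Write a virtual population to disk
#'
#' Writes the patient table as a tab-separated file plus a JSON provenance
#' sidecar (seed, reference label, validation p-values).
#'
#' @param pop a [VirtualPopulation-class].
#' @param path output table path; the sidecar gets a \code{.json} suffix.
#' @return \code{path}, invisibly.
#' @export
writeVirtualPopulation <- function(pop, path) {
  utils::write.table(pop@patients, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- c(list(seed = pop@seed, kind = pop@populationKind), pop@provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
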