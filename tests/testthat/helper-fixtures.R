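# Shared fixture builders; everything is generated in code, seeded.

adultRef <- function() synthReferencePopulation("adult")$reference

pedRef <- function() synthReferencePopulation("pediatric")

# a reference with all three sampled variables reported, handy for z-test
# arithmetic
fullRef <- function(ageSd = 10.10) {
  demographicReference(age = c(36.58, ageSd), height = c(171.7, 9.4),
                       weight = c(78.75, 17.20), sexFemaleFraction = 0.5,
                       nReference = 500)
}

constantPatients <- function(n, age, height, weight) {
  data.frame(id = as.character(seq_len(n)), sex = "M", age = age,
             height_cm = height, weight_kg = weight,
             bmi = weight / (height / 100)^2, arm_id = "", tags = "")
}

# standard adult used in PBPK tests (male, 40 y, 175 cm, 70 kg)
standardAdult <- function() {
  list(sex = "M", age = 40, height_cm = 175, weight_kg = 70,
       bmi = 70 / 1.75^2)
}

# one-compartment configuration: no organ exchange, renal elimination only
oneCompartmentParams <- function(ka = 1.2, ke = 0.3, F = 0.964) {
  p <- individualizeParameters(standardAdult(), drugModel("x", 70, F),
                               ka = ka, clearance = c(kidneys = ke))
  p@flows[] <- 0
  p
}

# tiny hand-built network: A -> B (+), B -> C (-), D isolated
chainNetwork <- function() {
  proteinNetwork(data.frame(source = c("A", "B"), target = c("B", "C"),
                            sign = c(1, -1), weight = 1),
                 nodes = c("A", "B", "C", "D"))
}

blobData <- function(seed, n = 60, d = 5, sep = 4) {
  set.seed(seed)
  rbind(matrix(rnorm(n * d), n, d),
        matrix(rnorm(n * d, sep), n, d),
        matrix(rnorm(n * d, -sep), n, d))
}
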