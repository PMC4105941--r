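## Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (!exists(name, envir = .fixtures))
        assign(name, build(), envir = .fixtures)
    get(name, envir = .fixtures)
}

model1 <- function() fixture("model1", function() assembleModel(1))
model5 <- function() fixture("model5", function() assembleModel(5))
model8 <- function() fixture("model8", function() assembleModel(8))

longProtocol <- function() StimulusProtocol(dose = 2, exposure = "long")
shortProtocol <- function() StimulusProtocol(dose = 2, exposure = "short",
                                             tWash = 30)

## default synthetic bundle (Model 8 truth, cv = 0.2, n = 3, seed 42)
defaultBundle <- function() fixture("bundle42", function()
    generateBundle("8", seed = 42))

noiselessBundle <- function(truth = "1")
    fixture(paste0("nfbundle", truth), function()
        generateBundle(truth, noise = NoiseModel(cv = 0, cvElisa = 0,
                                                 replicates = 1),
                       seed = 7))

## tiny 3-species toy: A + B -> C (k1), C -> A + B (k2)
toyBindingNetwork <- function() {
    ReactionNetwork(
        species = data.frame(name = c("A", "B", "C"),
                             compartment = "cytoplasm",
                             initial = c(5, 3, 0), constant = FALSE),
        reactions = c("A + B -> C @ k1", "C -> A + B @ k2"),
        parameters = c(k1 = 0.7, k2 = 0.2))
}

## hand-written derivatives for the toy binding network (independent of
## buildRHS)
toyBindingDeriv <- function(y) {
    v1 <- 0.7 * y["A"] * y["B"]
    v2 <- 0.2 * y["C"]
    c(A = unname(-v1 + v2), B = unname(-v1 + v2), C = unname(v1 - v2))
}
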