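#' @import methods
NULL

#' Compartmental mass-action reaction network
#'
#' The executable representation of one model variant: species with
#' compartments and initial concentrations, irreversible mass-action
#' reactions, and a named parameter vector.  Concentrations are in nM and
#' time in minutes throughout; species assigned to the nucleus are stored as
#' cytoplasm-volume-relative concentrations, so stoichiometry-weighted sums
#' over compartments (conserved totals, lysate-style observables) are
#' directly additive.
#'
#' @slot species data.frame with columns \code{name}, \code{compartment}
#'   (one of extracellular, cytoplasm, early_endosome, caveolae, nucleus),
#'   \code{initial} (nM, non-negative) and \code{constant} (logical;
#'   buffered species such as Smad7 in the HaCaT models).
#' @slot reactions list of reaction records; each record is a list with
#'   \code{id}, \code{reactants} (character, 0--2 names), \code{products}
#'   (character), \code{rate} (parameter name), \code{modifier} (a species
#'   whose concentration multiplies the rate without being consumed, or
#'   \code{NA}), and \code{source} (where the reaction came from:
#'   \code{"prior_model"}, \code{"effect_block"} or \code{"this_work"}).
#' @slot parameters named numeric vector of rate constants (1/min,
#'   1/(nM min) or nM/min according to reaction order).
#' @slot provenance named character vector, one of \code{"literature"},
#'   \code{"fixed_prior_model"}, \code{"estimated"} per parameter.
#' @slot volumeRatio cytoplasm-to-nucleus volume ratio; used only when
#'   translating literature per-volume shuttling rates into the relative
#'   concentration convention, never inside the right-hand side.
#' @export
setClass("ReactionNetwork",
         slots = c(species = "data.frame",
                   reactions = "list",
                   parameters = "numeric",
                   provenance = "character",
                   volumeRatio = "numeric"))

setValidity("ReactionNetwork", function(object) {
    msgs <- character()
    sp <- object@species
    need <- c("name", "compartment", "initial", "constant")
    if (!all(need %in% names(sp)))
        return(paste("species must have columns",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(sp$name))
        msgs <- c(msgs, "duplicated species names")
    if (any(sp$initial < 0))
        msgs <- c(msgs, "negative initial concentrations")
    comps <- c("extracellular", "cytoplasm", "early_endosome", "caveolae",
               "nucleus")
    if (!all(sp$compartment %in% comps))
        msgs <- c(msgs, "unknown compartment")
    for (rx in object@reactions) {
        if (length(rx$reactants) > 2)
            msgs <- c(msgs, sprintf("reaction %s has >2 reactants", rx$id))
        refs <- c(rx$reactants, rx$products,
                  if (!is.na(rx$modifier)) rx$modifier)
        if (!all(refs %in% sp$name))
            msgs <- c(msgs, sprintf("reaction %s references unknown species",
                                    rx$id))
        if (!rx$rate %in% names(object@parameters))
            msgs <- c(msgs, sprintf("reaction %s references unknown parameter %s",
                                    rx$id, rx$rate))
    }
    if (any(object@parameters < 0))
        msgs <- c(msgs, "negative rate constants")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Model variant: a network plus its negative-regulation effect flags
#'
#' @slot modelId character, one of "1".."8", "S1", "S2", "S3".
#' @slot effects character vector of effect flags present in this variant.
#' @slot network the assembled \linkS4class{ReactionNetwork}.
#' @slot estimated names of the free parameters exposed to the fitter
#'   (the effect-specific rate constants of the variant).
#' @slot fixed names of parameters held at their default values.
#' @export
setClass("ModelVariant",
         slots = c(modelId = "character",
                   effects = "character",
                   network = "ReactionNetwork",
                   estimated = "character",
                   fixed = "character"))

setValidity("ModelVariant", function(object) {
    pn <- names(object@network@parameters)
    if (!all(object@estimated %in% pn))
        return("estimated parameters not present in network")
    TRUE
})

#' Stimulation/perturbation protocol
#'
#' @slot dose TGF-beta dose in ng/ml.
#' @slot exposure "long" (continuous) or "short" (ligand washout plus
#'   receptor-kinase inhibition at \code{tWash}).
#' @slot tWash washout time in minutes (short exposure only).
#' @slot perturbations character subset of \code{c("MG132","CYCLOHEXIMIDE")},
#'   applied as parameter overrides before simulation.
#' @slot horizon simulation horizon in minutes.
#' @export
setClass("StimulusProtocol",
         slots = c(dose = "numeric",
                   exposure = "character",
                   tWash = "numeric",
                   perturbations = "character",
                   horizon = "numeric"))

setValidity("StimulusProtocol", function(object) {
    msgs <- character()
    if (object@dose < 0) msgs <- c(msgs, "dose must be >= 0")
    if (!object@exposure %in% c("long", "short"))
        msgs <- c(msgs, "exposure must be 'long' or 'short'")
    if (object@exposure == "short" && object@tWash >= object@horizon)
        msgs <- c(msgs, "tWash must be < horizon")
    bad <- setdiff(object@perturbations, c("MG132", "CYCLOHEXIMIDE"))
    if (length(bad))
        msgs <- c(msgs, paste("unknown perturbation:", paste(bad, collapse = ",")))
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Solver output on a time grid plus derived observables
#'
#' @slot times numeric vector, minutes.
#' @slot state numeric matrix, time x species (nM; nuclear species in
#'   cytoplasm-volume-relative units).
#' @slot observables data.frame (time_min, name, value) with the
#'   lysate-style stoichiometry-weighted totals.
#' @slot modelId model the trajectory came from.
#' @slot protocol the \linkS4class{StimulusProtocol} used.
#' @export
setClass("Trajectory",
         slots = c(times = "numeric",
                   state = "matrix",
                   observables = "data.frame",
                   modelId = "character",
                   protocol = "StimulusProtocol"))

#' Tidy time-course dataset
#'
#' Records of (protocol_id, time, observable, replicate, value, weight) as
#' produced by the synthetic generator or read from CSV, plus the
#' normalization convention of the values.
#'
#' @slot data data.frame with columns protocol_id, time, observable,
#'   replicate, value, weight.
#' @slot normalization one of "absolute_nM", "relative_to_max",
#'   "relative_to_t0".
#' @export
setClass("TimeSeriesDataset",
         slots = c(data = "data.frame",
                   normalization = "character"))

setValidity("TimeSeriesDataset", function(object) {
    need <- c("protocol_id", "time", "observable", "replicate", "value",
              "weight")
    if (!all(need %in% names(object@data)))
        return(paste("data must have columns", paste(need, collapse = ", ")))
    if (any(object@data$time < 0)) return("times must be >= 0")
    if (!object@normalization %in%
        c("absolute_nM", "relative_to_max", "relative_to_t0"))
        return("unknown normalization")
    TRUE
})

#' Multistart fit result
#'
#' @slot estimates named numeric, best-fit parameters on the natural scale.
#' @slot logEstimates the same on log10 scale (the optimization scale).
#' @slot sse winning sum of squared errors.
#' @slot sseByDataset named numeric, per-channel SSE decomposition.
#' @slot restarts list of per-start records (start, sse, convergence).
#' @slot winner index of the winning restart.
#' @slot seed RNG seed used for start generation.
#' @export
setClass("FitResult",
         slots = c(estimates = "numeric",
                   logEstimates = "numeric",
                   sse = "numeric",
                   sseByDataset = "numeric",
                   restarts = "list",
                   winner = "integer",
                   seed = "integer"))

setValidity("FitResult", function(object) {
    if (length(object@sse) && object@sse < 0) return("SSE must be >= 0")
    TRUE
})

#' Synthetic experimental bundle
#'
#' One \linkS4class{TimeSeriesDataset} per measurement channel, together
#' with the ground truth that generated it.
#'
#' @slot channels named list of \linkS4class{TimeSeriesDataset}
#'   (pSmad2_short, pSmad2_long, T1R, Smad2_total, PPM1A).
#' @slot truthModel model id of the generating truth.
#' @slot truthParams named numeric parameters of the truth.
#' @slot seed RNG seed; bundles are exactly regenerable from (truth, seed).
#' @export
setClass("SyntheticBundle",
         slots = c(channels = "list",
                   truthModel = "character",
                   truthParams = "numeric",
                   seed = "integer"))

setMethod("show", "ReactionNetwork", function(object) {
    cat(sprintf("ReactionNetwork: %d species, %d reactions, %d parameters\n",
                nrow(object@species), length(object@reactions),
                length(object@parameters)))
    tab <- table(object@species$compartment)
    cat("  species by compartment:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  constant (buffered) species: %s\n",
                paste(object@species$name[object@species$constant],
                      collapse = ", ")))
})

setMethod("show", "ModelVariant", function(object) {
    cat(sprintf("ModelVariant '%s'\n", object@modelId))
    cat("  effects:", if (length(object@effects))
        paste(object@effects, collapse = ", ") else "(none)", "\n")
    cat(sprintf("  network: %d species, %d reactions\n",
                nrow(object@network@species), length(object@network@reactions)))
    cat("  estimated parameters:",
        paste(object@estimated, collapse = ", "), "\n")
})

setMethod("show", "StimulusProtocol", function(object) {
    cat(sprintf("StimulusProtocol: %g ng/ml, %s exposure%s, horizon %g min\n",
                object@dose, object@exposure,
                if (object@exposure == "short")
                    sprintf(" (washout at %g min)", object@tWash) else "",
                object@horizon))
    if (length(object@perturbations))
        cat("  perturbations:", paste(object@perturbations, collapse = ", "),
            "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory of model %s: %d times (%g..%g min), %d species\n",
                object@modelId, length(object@times), min(object@times),
                max(object@times), ncol(object@state)))
    cat("  observables:",
        paste(unique(object@observables$name), collapse = ", "), "\n")
})

setMethod("show", "TimeSeriesDataset", function(object) {
    cat(sprintf("TimeSeriesDataset: %d records, %d observables, normalization %s\n",
                nrow(object@data), length(unique(object@data$observable)),
                object@normalization))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: SSE %.6g over %d restart(s), winner #%d\n",
                object@sse, length(object@restarts), object@winner))
    print(signif(object@estimates, 4))
})

setMethod("show", "SyntheticBundle", function(object) {
    cat(sprintf("SyntheticBundle from model %s truth (seed %d)\n",
                object@truthModel, object@seed))
    for (nm in names(object@channels))
        cat(sprintf("  %-14s %d records (%s)\n", nm,
                    nrow(object@channels[[nm]]@data),
                    object@channels[[nm]]@normalization))
})
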