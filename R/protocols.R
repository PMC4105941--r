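#' Create a stimulation protocol
#'
#' @param dose TGF-beta dose in ng/ml (2 ng/ml is the standard saturating
#'   dose; 80 pM under the 25-kDa mass assumption).
#' @param exposure "long" for continuous stimulation, "short" for washout
#'   plus receptor-kinase inhibition at \code{tWash}.
#' @param tWash washout time, minutes (default 30).
#' @param perturbations character subset of
#'   \code{c("MG132", "CYCLOHEXIMIDE")}.
#' @param horizon simulation horizon, minutes (default 24 h).
#' @return a \linkS4class{StimulusProtocol}.
#' @export
StimulusProtocol <- function(dose = 2, exposure = c("long", "short"),
                             tWash = 30, perturbations = character(),
                             horizon = 1440) {
    exposure <- match.arg(exposure)
    new("StimulusProtocol", dose = dose, exposure = exposure,
        tWash = tWash, perturbations = perturbations, horizon = horizon)
}

#' Convert a TGF-beta dose from ng/ml to pM
#'
#' 2 ng/ml of the 25-kDa mature TGF-beta dimer corresponds to 80 pM.
#'
#' @param dose_ng_per_ml dose in ng/ml (>= 0).
#' @param molecular_mass_kDa molecular mass (default 25).
#' @return dose in pM.
#' @export
doseConvert <- function(dose_ng_per_ml, molecular_mass_kDa = 25) {
    if (any(dose_ng_per_ml < 0)) stop("dose must be >= 0")
    if (molecular_mass_kDa <= 0) stop("molecular mass must be positive")
    ## ng/ml = 1e-6 g/L; divide by g/mol, report in pM (1e12 pmol/mol)
    dose_ng_per_ml * 1e-6 / (molecular_mass_kDa * 1e3) * 1e12
}

## Extracellular ligand is booked in cytoplasm-volume-relative nM so that
## receptor binding depletes it with integer stoichiometry.  With the
## default medium-to-cell volume factor of 1000, an 80 pM dose maps to
## 80 nM relative.
LIGAND_VOLUME_FACTOR <- 1000

doseToRelativeNM <- function(dose_ng_per_ml,
                             volumeFactor = LIGAND_VOLUME_FACTOR) {
    doseConvert(dose_ng_per_ml) * 1e-3 * volumeFactor
}

## Stiff-capable integration of a network from a given state.  Returns the
## deSolve matrix (time column first).  Integration failures raise an error
## naming the last good time unless silent = TRUE (the fitter converts
## failures into a large finite penalty instead).
integrateNetwork <- function(network, y0, times, rtol = 1e-8, atol = 1e-8) {
    rhs <- buildRHS(network)
    func <- function(t, y, parms) list(rhs(y, t))
    out <- deSolve::lsoda(y = y0, times = times, func = func, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    attr_diag <- attributes(out)$istate
    if (nrow(out) < length(times))
        stop(sprintf("integration failed at t=%.2f min (last good time)",
                     out[nrow(out), 1]))
    out
}

#' Apply a chemical perturbation to a model
#'
#' MG132 (proteasome inhibition) sets the proteasomal P-Smad degradation
#' rate to zero, leaving every other degradation rate untouched.
#' Cycloheximide (translation inhibition) halves every zeroth-order
#' synthesis rate (receptor, Smad, Smad7 and PPM1A production).  Returns a
#' modified copy; the input is untouched.
#'
#' @param model a \linkS4class{ModelVariant}.
#' @param perturbation "MG132" or "CYCLOHEXIMIDE".
#' @return modified \linkS4class{ModelVariant}.
#' @export
applyPerturbation <- function(model, perturbation) {
    perturbation <- match.arg(perturbation, c("MG132", "CYCLOHEXIMIDE"))
    net <- model@network
    if (perturbation == "MG132") {
        uses <- any(vapply(net@reactions, function(rx)
            rx$rate == "kdeg_pSmad2", logical(1)))
        if (!uses) {
            warning("MG132 is a no-op for model ", model@modelId,
                    " (no proteasomal P-Smad degradation reaction)")
            return(model)
        }
        model@network@parameters["kdeg_pSmad2"] <- 0
    } else {
        synth <- unique(vapply(
            Filter(function(rx) length(rx$reactants) == 0, net@reactions),
            `[[`, "", "rate"))
        model@network@parameters[synth] <-
            model@network@parameters[synth] * 0.5
    }
    model
}

#' Simulate a model under a stimulation protocol
#'
#' Integrates from the model's (equilibrated) initial state with the
#' extracellular ligand set to the protocol dose at t = 0.  Short exposure
#' implements washout at \code{tWash} as a hard integration restart:
#' extracellular TGF-beta is set to zero and the receptor kinase is
#' disabled (the washout compound is a type-I receptor kinase inhibitor,
#' so pre-formed ligand-receptor complexes stop phosphorylating Smad2).
#' Chemical perturbations in the protocol are applied as parameter
#' overrides before integration.
#'
#' @param model a \linkS4class{ModelVariant} with equilibrated initials.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param times output grid in minutes (default: 1-min resolution over the
#'   protocol horizon).
#' @param rtol,atol integrator tolerances (default 1e-8).
#' @return a \linkS4class{Trajectory}.
#' @export
simulateModel <- function(model, protocol, times = NULL, rtol = 1e-8,
                          atol = 1e-8) {
    stopifnot(is(model, "ModelVariant"), is(protocol, "StimulusProtocol"))
    validObject(protocol)
    if (is.null(times)) times <- seq(0, protocol@horizon, by = 1)
    if (max(times) > protocol@horizon)
        stop("output times exceed protocol horizon")
    for (p in protocol@perturbations)
        model <- applyPerturbation(model, p)
    net <- model@network
    y0 <- initialState(net)
    y0["TGFb"] <- doseToRelativeNM(protocol@dose)

    if (protocol@exposure == "long" || protocol@dose == 0) {
        grid <- sort(unique(c(0, times)))
        sol <- integrateNetwork(net, y0, grid, rtol, atol)
        state <- sol[match(times, sol[, 1]), -1, drop = FALSE]
    } else {
        tw <- protocol@tWash
        pre <- sort(unique(c(0, times[times <= tw], tw)))
        sol1 <- integrateNetwork(net, y0, pre, rtol, atol)
        yw <- sol1[nrow(sol1), -1]
        yw["TGFb"] <- 0
        netOff <- setParameters(net, c(kphos = 0))
        post <- sort(unique(c(tw, times[times > tw])))
        sol2 <- integrateNetwork(netOff, yw, post, rtol, atol)
        state <- rbind(
            sol1[match(times[times <= tw], sol1[, 1]), -1, drop = FALSE],
            sol2[match(times[times > tw], sol2[, 1]), -1, drop = FALSE])
    }
    rownames(state) <- NULL
    obs <- computeObservables(model, state, times)
    new("Trajectory", times = as.numeric(times), state = state,
        observables = obs, modelId = model@modelId, protocol = protocol)
}

## Stoichiometry-weighted observable table for a state matrix.
computeObservables <- function(model, state, times) {
    defs <- observableDefinitions(model)
    recs <- lapply(names(defs), function(nm) {
        w <- defs[[nm]]
        vals <- as.vector(state[, names(w), drop = FALSE] %*% w)
        data.frame(time_min = times, name = nm, value = vals)
    })
    do.call(rbind, recs)
}

#' Extract an observable time series from a trajectory
#'
#' Lysate-style observables are stoichiometry-weighted totals over all
#' matching species in all compartments.  Western-blot style normalization
#' is available: to the series' own maximum or to its t = 0 value.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param observable registered observable name (see
#'   \code{\link{observableDefinitions}}).
#' @param normalize "none" (nM), "max" or "t0".
#' @return data.frame (time_min, value).
#' @export
observe <- function(trajectory, observable,
                    normalize = c("none", "max", "t0")) {
    normalize <- match.arg(normalize)
    obs <- trajectory@observables
    if (!observable %in% obs$name)
        stop("unknown observable '", observable, "'; available: ",
             paste(unique(obs$name), collapse = ", "))
    sub <- obs[obs$name == observable, c("time_min", "value")]
    rownames(sub) <- NULL
    if (normalize == "max") {
        m <- max(sub$value)
        if (m > 0) sub$value <- sub$value / m
    } else if (normalize == "t0") {
        v0 <- sub$value[which.min(sub$time_min)]
        if (v0 > 0) sub$value <- sub$value / v0
    }
    sub
}

#' Tidy export of a trajectory
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @return data.frame (time_min, name, value, kind) with both raw species
#'   and derived observables.
#' @export
trajectoryTable <- function(trajectory) {
    sp <- data.frame(
        time_min = rep(trajectory@times, ncol(trajectory@state)),
        name = rep(colnames(trajectory@state), each = length(trajectory@times)),
        value = as.vector(trajectory@state),
        kind = "species")
    ob <- trajectory@observables
    names(ob) <- c("time_min", "name", "value")
    ob$kind <- "observable"
    rbind(sp, ob)
}

#' Experimental comparison time grid (minutes)
#'
#' The sampling grid used for comparison with the western/ELISA time
#' courses: 0, 15, 30, 45 min, then 1, 2, 4, 6, 8, 12, 24 hr.
#' @return numeric vector.
#' @export
experimentalGrid <- function() {
    c(0, 15, 30, 45, 60, 120, 240, 360, 480, 720, 1440)
}
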