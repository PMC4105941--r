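#' Receptor-degradation rate sweep
#'
#' Fixes the Smad7-driven receptor-degradation rate (klid) at each grid
#' value, refits the proteasomal P-Smad degradation rate (kdeg_pSmad2) to
#' the phospho-Smad2 channels, and reports the total type-I receptor level
#' at 24 hr per grid point together with Spearman correlations between
#' the receptor level, klid and the fitted degradation rate.  Refit
#' failures flag the point and the sweep continues.
#'
#' @param model a Model 5 style variant (must include receptor and P-Smad
#'   degradation).
#' @param channels phospho-Smad2 fitting channels (list with
#'   pSmad2_short, pSmad2_long).
#' @param grid klid values, strictly increasing (default
#'   \code{10^seq(-6, -2, by = 0.5)}).
#' @param seed RNG seed for the refits.
#' @param nStarts restarts per refit.
#' @return list with \code{points} (data.frame klid, kdeg_pSmad2, T1R_24hr,
#'   T1R_decrease_pct, sse, ok) and \code{correlations} (Spearman).
#' @export
klidSweep <- function(model, channels, grid = 10^seq(-6, -2, by = 0.5),
                      seed = 1, nStarts = 2) {
    stopifnot(all(diff(grid) > 0))
    pts <- vector("list", length(grid))
    for (i in seq_along(grid)) {
        mi <- setParameters(model, c(klid = grid[i]))
        rec <- tryCatch({
            fit <- fitMultistart(mi, channels, nStarts = nStarts,
                                 seed = seed, free = "kdeg_pSmad2")
            mfit <- setParameters(mi, fit@estimates)
            tr <- simulateModel(mfit, StimulusProtocol(dose = 2),
                                times = c(0, 1440), rtol = 1e-6,
                                atol = 1e-6)
            t1r <- observe(tr, "T1R_total")
            data.frame(klid = grid[i],
                       kdeg_pSmad2 = unname(fit@estimates["kdeg_pSmad2"]),
                       T1R_24hr = t1r$value[2],
                       T1R_decrease_pct = 100 * (1 - t1r$value[2] /
                                                     t1r$value[1]),
                       sse = fit@sse, ok = TRUE)
        }, error = function(e)
            data.frame(klid = grid[i], kdeg_pSmad2 = NA, T1R_24hr = NA,
                       T1R_decrease_pct = NA, sse = NA, ok = FALSE))
        pts[[i]] <- rec
    }
    points <- do.call(rbind, pts)
    okp <- points[points$ok, ]
    correlations <- c(
        T1R_vs_klid = stats::cor(okp$T1R_24hr, okp$klid,
                                 method = "spearman"),
        T1R_vs_kdeg = stats::cor(okp$T1R_24hr, okp$kdeg_pSmad2,
                                 method = "spearman"),
        klid_vs_kdeg = stats::cor(okp$klid, okp$kdeg_pSmad2,
                                  method = "spearman"))
    list(points = points, correlations = correlations)
}

#' Relative phospho-Smad2 change under proteasome inhibition
#'
#' change(t) = (P-Smad2 with MG132 - P-Smad2 without) / (P-Smad2 without),
#' simulated under a given exposure duration; positive values mean
#' proteasome inhibition raises phospho-Smad2.  Near-zero control levels
#' (below \code{maskFrac} of the control peak) are masked with a warning.
#'
#' @param model a \linkS4class{ModelVariant} with a proteasomal P-Smad
#'   degradation reaction.
#' @param exposure "short" (washout at 30 min) or "long" (continuous
#'   8-hr stimulation).
#' @param times evaluation times in minutes (default 1, 2, 4, 6 hr).
#' @param maskFrac detection-limit mask: control levels below this
#'   fraction of the control peak (default 0.05, a western-blot style
#'   detection floor) are treated as unquantifiable and masked.
#' @return data.frame (time_min, control, treated, change).
#' @export
mg132Change <- function(model, exposure = c("short", "long"),
                        times = c(60, 120, 240, 360), maskFrac = 0.05) {
    exposure <- match.arg(exposure)
    if (!"kdeg_pSmad2" %in%
        vapply(model@network@reactions, `[[`, "", "rate"))
        stop("model ", model@modelId,
             " has no proteasomal P-Smad degradation rate")
    horizon <- max(480, max(times))
    proto <- if (exposure == "short")
        StimulusProtocol(dose = 2, exposure = "short", tWash = 30,
                         horizon = horizon)
    else StimulusProtocol(dose = 2, exposure = "long", horizon = horizon)
    grid <- sort(unique(c(0, times, seq(0, horizon, by = 5))))
    ctrl <- observe(simulateModel(model, proto, times = grid),
                    "PSmad2_total")
    trt <- observe(simulateModel(applyPerturbation(model, "MG132"), proto,
                                 times = grid), "PSmad2_total")
    c0 <- ctrl$value[match(times, ctrl$time_min)]
    t0 <- trt$value[match(times, trt$time_min)]
    change <- (t0 - c0) / c0
    mask <- c0 < maskFrac * max(ctrl$value)
    if (any(mask)) {
        warning("control level near zero at t = ",
                paste(times[mask], collapse = ", "),
                " min; change masked")
        change[mask] <- NA
    }
    data.frame(time_min = times, control = c0, treated = t0,
               change = change)
}

#' Sensitivity of trajectories to one rate constant
#'
#' Scales the named rate by each fold of the grid, simulates 24 hr of
#' continuous stimulation, and summarizes the response per species as the
#' relative change of the trajectory integral against the unperturbed
#' run.  Integration failures at extreme folds are masked cells.
#'
#' @param model a \linkS4class{ModelVariant}.
#' @param rateName rate constant to perturb.
#' @param foldGrid fold factors (default \code{10^(-4:2)}).
#' @param species species to report (default all).
#' @return species x fold matrix of relative integral changes.
#' @export
sensitivityHeatmap <- function(model, rateName, foldGrid = 10^(-4:2),
                               species = NULL) {
    p0 <- networkParameters(model)
    if (!rateName %in% names(p0)) stop("unknown rate '", rateName, "'")
    if (is.null(species)) species <- speciesNames(model)
    times <- seq(0, 1440, by = 10)
    base <- simulateModel(model, StimulusProtocol(dose = 2),
                          times = times, rtol = 1e-6, atol = 1e-6)
    integ <- function(tr) {
        y <- tr@state[, species, drop = FALSE]
        dt <- diff(tr@times)
        colSums((y[-1, , drop = FALSE] + y[-nrow(y), , drop = FALSE]) / 2 *
                dt)
    }
    I0 <- integ(base)
    out <- matrix(NA_real_, nrow = length(species), ncol = length(foldGrid),
                  dimnames = list(species, sprintf("%g", foldGrid)))
    for (j in seq_along(foldGrid)) {
        pj <- stats::setNames(p0[rateName] * foldGrid[j], rateName)
        trj <- tryCatch(
            simulateModel(setParameters(model, pj),
                          StimulusProtocol(dose = 2), times = times,
                          rtol = 1e-6, atol = 1e-6),
            error = function(e) NULL)
        if (is.null(trj)) next
        Ij <- integ(trj)
        out[, j] <- (Ij - I0) / pmax(I0, 1e-9)
    }
    out
}

#' Adaptation index of a response time series
#'
#' (peak - final) / peak for a non-negative series: 0 for a flat
#' (non-adapting) response, 1 for a response that returns exactly to
#' zero by the horizon.
#'
#' @param values numeric series (e.g. phospho-Smad2 over time).
#' @return dimensionless index in [0, 1] for non-negative series.
#' @export
adaptationIndex <- function(values) {
    pk <- max(values)
    if (pk <= 0) stop("adaptation index undefined for a non-positive series")
    (pk - values[length(values)]) / pk
}

#' Effect-contribution decomposition of the full feedback model
#'
#' Removes the negative-regulation effects one after another from the
#' full model -- proteasomal P-Smad degradation, then PTEN-mediated PPM1A
#' stabilization, then dephosphorylation (leaving no negative regulation)
#' -- by zeroing their rate constants without re-equilibration, and
#' simulates phospho-Smad2 over the horizon for each nested removal.
#'
#' @param model8 the full model (Model 8).
#' @param horizon minutes (default 24 hr).
#' @param times output grid (default 2-min resolution).
#' @return list of data.frames (time_min, value), named "full",
#'   "minus_PSmadDegradation", "minus_PPM1AStabilization",
#'   "minus_Dephosphorylation".
#' @export
effectContribution <- function(model8, horizon = 1440, times = NULL) {
    if (is.null(times)) times <- seq(0, horizon, by = 2)
    proto <- StimulusProtocol(dose = 2, horizon = horizon)
    removals <- list(
        full = c(),
        minus_PSmadDegradation = c(kdeg_pSmad2 = 0),
        minus_PPM1AStabilization = c(kdeg_pSmad2 = 0, kon_T = 0,
                                     kon_TP = 0),
        minus_Dephosphorylation = c(kdeg_pSmad2 = 0, kon_T = 0,
                                    kon_TP = 0, kcat_P = 0, kon_P = 0,
                                    kdephos = 0))
    lapply(removals, function(z) {
        m <- if (length(z)) setParameters(model8, z) else model8
        observe(simulateModel(m, proto, times = times), "PSmad2_total")
    })
}

#' Dose-response of phospho-Smad2
#'
#' Simulates the model across a TGF-beta dose grid and reads out total
#' phospho-Smad2 at 45 min and 24 hr, plus the fraction of extracellular
#' ligand remaining at 24 hr (low doses are depleted by receptor
#' binding).
#'
#' @param model a \linkS4class{ModelVariant}.
#' @param doses ng/ml grid (default the 0.025--2 ng/ml doubling series).
#' @return data.frame (dose_ng_ml, dose_pM, pSmad2_45min, pSmad2_24hr,
#'   ligand_fraction_remaining).
#' @export
doseResponse <- function(model,
                         doses = c(0.025, 0.0625, 0.125, 0.25, 0.5, 1, 2)) {
    rows <- lapply(doses, function(d) {
        tr <- simulateModel(model, StimulusProtocol(dose = d),
                            times = c(0, 45, 1440))
        ps <- observe(tr, "PSmad2_total")
        lig0 <- doseToRelativeNM(d)
        ligT <- tr@state[tr@times == 1440, "TGFb"]
        data.frame(dose_ng_ml = d, dose_pM = doseConvert(d),
                   pSmad2_45min = ps$value[ps$time_min == 45],
                   pSmad2_24hr = ps$value[ps$time_min == 1440],
                   ligand_fraction_remaining =
                       if (lig0 > 0) ligT / lig0 else NA_real_)
    })
    do.call(rbind, rows)
}
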