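#' Multiplicative replicate-noise model
#'
#' Densitometry-style measurements are strictly positive with a roughly
#' constant coefficient of variation, so replicates are drawn as
#' value x exp(N(-s^2/2, s)) with s = sqrt(log(1 + cv^2)), which has mean
#' equal to the noiseless value and coefficient of variation cv.
#'
#' @param cv coefficient of variation for western-style channels
#'   (default 0.2).
#' @param cvElisa coefficient of variation for ELISA channels
#'   (default 0.1).
#' @param replicates replicates per time point (default 3).
#' @return a list of class "NoiseModel".
#' @export
NoiseModel <- function(cv = 0.2, cvElisa = 0.1, replicates = 3) {
    stopifnot(cv >= 0, cvElisa >= 0, replicates >= 1)
    structure(list(cv = cv, cvElisa = cvElisa,
                   replicates = as.integer(replicates)),
              class = "NoiseModel")
}

applyNoise <- function(values, cv, replicates) {
    if (cv == 0)
        return(rep(values, each = replicates))
    s <- sqrt(log(1 + cv^2))
    n <- length(values) * replicates
    rep(values, each = replicates) * exp(stats::rnorm(n, -s^2 / 2, s))
}

## Channel layout of the default experimental emulation: sampling grids
## (minutes), observables, protocols and normalizations.
bundleLayout <- function() {
    list(
        pSmad2_short = list(protocol = "short",
                            observable = "PSmad2_total",
                            times = c(0, 15, 30, 45, 60, 120, 180, 240),
                            normalization = "relative_to_max",
                            noise = "western"),
        pSmad2_long = list(protocol = "long",
                           observable = "PSmad2_total",
                           times = experimentalGrid(),
                           normalization = "relative_to_max",
                           noise = "western"),
        T1R = list(protocol = "long",
                   observable = "T1R_total",
                   times = c(0, 15, 30, 45, 60, 120, 240, 480, 1440),
                   normalization = "relative_to_t0",
                   noise = "western"),
        Smad2_total = list(protocol = "long",
                           observable = "Smad2_total",
                           times = c(0, 60, 120, 240, 480, 720, 1440),
                           normalization = "absolute_nM",
                           noise = "elisa"),
        PPM1A = list(protocol = "long",
                     observable = "PPM1A_total",
                     times = c(0, 15, 30, 60, 120, 240, 480),
                     normalization = "relative_to_max",
                     noise = "western"))
}

#' Generate a synthetic experimental bundle
#'
#' Simulates a ground-truth model under the short- and long-exposure
#' protocols, samples the observables on the experimental grids
#' (phospho-Smad2 under both exposures; type-I receptor, total Smad2 and
#' -- when the truth models it -- total PPM1A under continuous
#' stimulation), applies each channel's normalization (relative-to-max
#' for western-style channels, nM for ELISA) and adds multiplicative
#' lognormal replicate noise.  Bundles are bit-identical given the same
#' truth and seed.
#'
#' @param truthModel model id of the generating truth (default "8").
#' @param truthParams optional named parameter overrides for the truth.
#' @param noise a \code{\link{NoiseModel}}.
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticBundle}.
#' @export
generateBundle <- function(truthModel = "8", truthParams = NULL,
                           noise = NoiseModel(), seed = 42) {
    truthModel <- as.character(truthModel)
    model <- assembleModel(truthModel, parameters = truthParams)
    layout <- bundleLayout()
    available <- names(observableDefinitions(model))
    layout <- Filter(function(l) l$observable %in% available, layout)
    protos <- standardProtocols()
    simTimes <- lapply(protos, function(p) {
        tt <- unlist(lapply(Filter(function(l)
            l$protocol == p@exposure, layout), `[[`, "times"))
        sort(unique(c(0, tt)))
    })
    names(simTimes) <- names(protos)
    sims <- list(short = simulateModel(model, protos$short,
                                       times = simTimes$short),
                 long = simulateModel(model, protos$long,
                                      times = simTimes$long))
    channels <- withLocalSeed(seed, {
        lapply(layout, function(l) {
            sim <- observe(sims[[l$protocol]], l$observable)
            vals <- normalizeSeries(sim$value, sim$time_min,
                                    l$normalization)
            atT <- vals[match(l$times, sim$time_min)]
            cv <- if (l$noise == "elisa") noise$cvElisa else noise$cv
            noisy <- applyNoise(atT, cv, noise$replicates)
            TimeSeriesDataset(
                data.frame(protocol_id = l$protocol,
                           time = rep(l$times, each = noise$replicates),
                           observable = l$observable,
                           replicate = rep(seq_len(noise$replicates),
                                           times = length(l$times)),
                           value = noisy, weight = 1),
                normalization = l$normalization)
        })
    })
    new("SyntheticBundle", channels = channels, truthModel = truthModel,
        truthParams = networkParameters(model), seed = as.integer(seed))
}

#' Parameter-recovery / cross-model experiment
#'
#' Generates \code{nTrials} synthetic bundles from a known truth and fits
#' a model to each; for self-recovery the report carries per-trial
#' relative errors of the estimates, for cross-model fits it carries the
#' per-channel SSE decomposition used by the rejection workflow.
#'
#' @param truthModel truth model id.
#' @param fitModel model id to fit (same as truth for self-recovery).
#' @param noise a \code{\link{NoiseModel}}.
#' @param nTrials number of Monte-Carlo trials.
#' @param seed base seed; trial i uses seed + i.
#' @param nStarts restarts per fit.
#' @param free parameters to fit (default: the fit model's estimated set).
#' @return list with \code{errors} (trials x parameters relative errors,
#'   self-recovery only), \code{summary} (bias and RMSE per parameter),
#'   \code{sse} (per-trial per-channel SSE) and \code{fits}.
#' @export
recoveryExperiment <- function(truthModel = "1", fitModel = truthModel,
                               noise = NoiseModel(), nTrials = 3,
                               seed = 1, nStarts = 3, free = NULL) {
    truthModel <- as.character(truthModel)
    fitModel <- as.character(fitModel)
    fits <- vector("list", nTrials)
    errs <- list(); sses <- list()
    truthPars <- networkParameters(assembleModel(truthModel,
                                                 equilibrated = FALSE))
    for (i in seq_len(nTrials)) {
        bundle <- generateBundle(truthModel, noise = noise,
                                 seed = seed + i)
        model <- assembleModel(fitModel)
        fit <- fitMultistart(model,
                             bundle@channels[c("pSmad2_short",
                                               "pSmad2_long")],
                             nStarts = nStarts, seed = seed + i,
                             free = free)
        fits[[i]] <- fit
        if (identical(truthModel, fitModel))
            errs[[i]] <- fit@estimates / truthPars[names(fit@estimates)] - 1
        sses[[i]] <- fit@sseByDataset
    }
    errors <- if (length(errs)) do.call(rbind, errs) else NULL
    summary <- if (!is.null(errors))
        data.frame(parameter = colnames(errors),
                   bias = colMeans(errors),
                   rmse = sqrt(colMeans(errors^2)))
    else NULL
    list(errors = errors, summary = summary, sse = sses, fits = fits)
}
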