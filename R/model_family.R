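## Model family: a shared Smad-signalling skeleton (receptor trafficking in
## the Klipp lineage, nucleocytoplasmic shuttling in the Schmierer lineage)
## plus toggleable negative-regulation effect blocks.  Each reaction records
## where it came from ("prior_model" for skeleton reactions reconstructed
## from the cited prior models, "effect_block" for the negative-regulation
## additions).

#' Negative-regulation effect flags
#'
#' @return character vector of the recognised effect flags.
#' @export
effectFlags <- function() {
    c("DEPHOSPHORYLATION", "RECEPTOR_DEGRADATION", "PSMAD_DEGRADATION",
      "ENDOGENOUS_SMAD_TURNOVER", "PPM1A_STABILIZATION", "ISMAD_FEEDBACK",
      "PPM1A_EXPRESSION")
}

#' Effect composition of every model variant
#'
#' The +/- pattern of negative-regulation effects across Models 1--8 (with
#' the supplementary variants S1--S3).  Models 1--8 differ only in which
#' effect blocks are switched on over the shared skeleton.
#'
#' @return named list mapping model id to its character vector of effect
#'   flags.
#' @export
modelEffectsTable <- function() {
    list(
        "1"  = c("DEPHOSPHORYLATION"),
        "2"  = c("DEPHOSPHORYLATION", "RECEPTOR_DEGRADATION"),
        "3"  = c("RECEPTOR_DEGRADATION"),
        "4"  = c("PSMAD_DEGRADATION"),
        "5"  = c("DEPHOSPHORYLATION", "RECEPTOR_DEGRADATION",
                 "PSMAD_DEGRADATION"),
        "6"  = c("DEPHOSPHORYLATION", "PSMAD_DEGRADATION"),
        "7"  = c("DEPHOSPHORYLATION", "PSMAD_DEGRADATION",
                 "ENDOGENOUS_SMAD_TURNOVER"),
        "8"  = c("DEPHOSPHORYLATION", "PSMAD_DEGRADATION",
                 "ENDOGENOUS_SMAD_TURNOVER", "PPM1A_STABILIZATION"),
        "S1" = c("DEPHOSPHORYLATION", "RECEPTOR_DEGRADATION",
                 "PSMAD_DEGRADATION", "ISMAD_FEEDBACK"),
        "S2" = c("DEPHOSPHORYLATION", "PSMAD_DEGRADATION",
                 "ENDOGENOUS_SMAD_TURNOVER", "PPM1A_EXPRESSION"),
        "S3" = c("DEPHOSPHORYLATION", "PPM1A_STABILIZATION"))
}

## Total relative concentrations of Smad2 and Smad4 in HaCaT (nM).
TOTAL_SMAD2 <- 571.43
TOTAL_SMAD4 <- 1333.33

#' Default rate constants of the model family
#'
#' Units are 1/min for first-order, 1/(nM min) for second-order and nM/min
#' for zeroth-order constants.  Skeleton trafficking/shuttling rates carry
#' provenance "fixed_prior_model" or "literature"; effect-block rates are
#' "estimated" (they are the free parameters of the fitter, with defaults
#' calibrated once against the qualitative HaCaT behaviour the models must
#' reproduce).
#'
#' @return named numeric vector.
#' @export
defaultParameters <- function() {
    c(
        ## receptor module (Klipp-lineage trafficking)
        ka1       = 0.05,    # TGFb + T2R association, 1/(nM min)
        kd1       = 0.03,    # TGFb:T2R dissociation, 1/min
        ka2       = 0.3,     # TGFb:T2R + T1R -> LRC, 1/(nM min)
        ki_EE     = 0.33,    # LRC internalization to early endosome
        ki_Cave   = 0.33,    # LRC internalization to caveolae
        kr_EE     = 0.033,   # LRC recycling from EE (receptors returned,
                             # ligand degraded)
        kr_Cave   = 0.03,    # LRC recycling from caveolae to surface
        kcd       = 0.0025,  # shared constitutive turnover of all
                             # receptor-containing species
        pT1R      = 0.0025,  # T1R production, nM/min
        pT2R      = 0.0075,  # T2R production, nM/min
        ## Smad module (Schmierer-lineage shuttling)
        kphos     = 0.035,   # Smad2 phosphorylation by endosomal LRC
        kon_Smad  = 5e-3,    # Smad complex association (homo = hetero)
        koff_Smad = 0.18,    # Smad complex dissociation
        kimp_S2   = 0.156,   # Smad2 nuclear import
        kexp_S2   = 0.32,    # Smad2 nuclear export
        kimp_S4   = 0.156,
        kexp_S4   = 0.32,
        kimp_cplx = 0.9,     # Smad-complex import (faster than monomer)
        ## effect blocks
        kdephos     = 0.35,   # one-step nuclear dephosphorylation
        klid        = 1e-4,   # Smad7-driven LRC degradation, 1/(nM min)
        kdeg_pSmad2 = 0.06,   # proteasomal degradation of nuclear P-Smad
        ksyn_S2     = 1.7143, # endogenous Smad2 synthesis, nM/min
        kdeg_S2     = 3e-3,   # endogenous Smad2 degradation
        ## I-Smad feedback (Model S1)
        ksyn_S7_0  = 1.0,     # basal Smad7 synthesis, nM/min
        ksyn_S7    = 0.01,    # Smad-complex-driven Smad7 synthesis
        kdeg_S7    = 0.01,
        kon_S7     = 1e-4,    # Smad7-LRC association
        kdp_S7LRC  = 0.01,    # dephosphorylation branch (receptors returned)
        kdeg_S7LRC = 0.005,   # degradation branch
        ## explicit PPM1A (Models 8, S2, S3)
        ksyn_P   = 0.5,     # basal cytoplasmic PPM1A synthesis, nM/min
        kdeg_P   = 0.05,    # degradation of unbound PPM1A
        kimp_P   = 0.5,     # PPM1A nuclear import (high)
        kon_P    = 0.05,    # PPM1A-substrate association
        koff_P   = 1.0,
        kcat_P   = 3.0,     # catalytic dephosphorylation step
        ksyn_P_ind = 0.02,  # complex-driven PPM1A synthesis (Model S2)
        ## PTEN-mediated stabilization (Models 8, S3)
        kon_T    = 0.1,     # pSmad2 + PTEN association (cytoplasm)
        koff_T   = 0.1,
        kon_TP   = 1.0,     # ternary complex formation with PPM1A
        koff_TP  = 0.1,
        krel_TP  = 0.5,     # ternary releases pSmad2 + PTEN:PPM1A
        kimp_TP  = 0.01,    # PTEN:PPM1A nuclear import (slow; delayed
                            # nuclear availability)
        kdiss_TP = 0.002,   # nuclear PTEN:PPM1A dissociation
        kexp_T   = 0.05     # nuclear PTEN export
    )
}

parameterProvenance <- function() {
    prior <- c("ka1", "kd1", "ka2", "ki_EE", "ki_Cave", "kr_EE", "kr_Cave",
               "kcd", "pT1R", "pT2R")
    lit <- c("kimp_S2", "kexp_S2", "kimp_S4", "kexp_S4", "kimp_cplx",
             "kon_Smad", "koff_Smad")
    p <- defaultParameters()
    prov <- stats::setNames(rep("estimated", length(p)), names(p))
    prov[prior] <- "fixed_prior_model"
    prov[lit] <- "literature"
    prov
}

## Master observable weight registry: species -> stoichiometric weight per
## lysate-style observable.  Restricted to the species a variant contains.
observableWeightsRegistry <- function() {
    list(
        PSmad2_total = c(pSmad2c = 1, pSmad2n = 1, pS2S4c = 1, pS2S4n = 1,
                         pS2pS2c = 2, pS2pS2n = 2, PpS2n = 1, TPpS2n = 1,
                         pS2PTEN_c = 1, pS2PTENP_c = 1),
        Smad2_total = c(Smad2c = 1, Smad2n = 1, pSmad2c = 1, pSmad2n = 1,
                        pS2S4c = 1, pS2S4n = 1, pS2pS2c = 2, pS2pS2n = 2,
                        PpS2n = 1, TPpS2n = 1, pS2PTEN_c = 1,
                        pS2PTENP_c = 1),
        Smad4_total = c(Smad4c = 1, Smad4n = 1, pS2S4c = 1, pS2S4n = 1),
        T1R_total = c(T1R = 1, LRC_surf = 1, LRC_EE = 1, LRC_Cave = 1,
                      S7LRC_EE = 1, S7LRC_Cave = 1),
        T2R_total = c(T2R = 1, TGFbT2R = 1, LRC_surf = 1, LRC_EE = 1,
                      LRC_Cave = 1, S7LRC_EE = 1, S7LRC_Cave = 1),
        PPM1A_total = c(PPM1A_c = 1, PPM1A_n = 1, PpS2n = 1, TPpS2n = 1,
                        pS2PTENP_c = 1, PTENPPM1A_c = 1, PTENPPM1A_n = 1),
        PTEN_total = c(PTEN_c = 1, PTEN_n = 1, pS2PTEN_c = 1,
                       pS2PTENP_c = 1, PTENPPM1A_c = 1, PTENPPM1A_n = 1,
                       TPpS2n = 1),
        PTEN_PPM1A_complex = c(pS2PTENP_c = 1, PTENPPM1A_c = 1,
                               PTENPPM1A_n = 1, TPpS2n = 1),
        Smad7_total = c(Smad7 = 1, S7LRC_EE = 1, S7LRC_Cave = 1))
}

#' Observable weight vectors for a network
#'
#' @param network a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @return named list of stoichiometric weight vectors, restricted to
#'   species present in the network.
#' @export
observableDefinitions <- function(network) {
    if (is(network, "ModelVariant")) network <- network@network
    sp <- network@species$name
    reg <- observableWeightsRegistry()
    out <- lapply(reg, function(w) w[names(w) %in% sp])
    out[vapply(out, length, 1L) > 0]
}

#' Conserved-moiety weight vectors for a network
#'
#' Smad2, Smad4, T1R, T2R, PPM1A and PTEN moieties with stoichiometric
#' weights (the phospho-Smad2 homomeric complex counts twice for Smad2).
#'
#' @param network a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @return named list of weight vectors.
#' @export
moietyDefinitions <- function(network) {
    defs <- observableDefinitions(network)
    keep <- intersect(c("Smad2_total", "Smad4_total", "T1R_total",
                        "T2R_total", "PPM1A_total", "PTEN_total"),
                      names(defs))
    out <- defs[keep]
    names(out) <- sub("_total$", "", names(out))
    out
}

skeletonSpecies <- function() {
    data.frame(
        name = c("TGFb", "T2R", "T1R", "TGFbT2R", "LRC_surf", "LRC_EE",
                 "LRC_Cave", "Smad2c", "pSmad2c", "Smad4c", "pS2S4c",
                 "pS2pS2c", "Smad2n", "pSmad2n", "Smad4n", "pS2S4n",
                 "pS2pS2n", "Smad7"),
        compartment = c("extracellular", "cytoplasm", "cytoplasm",
                        "cytoplasm", "cytoplasm", "early_endosome",
                        "caveolae", "cytoplasm", "cytoplasm", "cytoplasm",
                        "cytoplasm", "cytoplasm", "nucleus", "nucleus",
                        "nucleus", "nucleus", "nucleus", "cytoplasm"),
        initial = 0,
        constant = FALSE)
}

skeletonReactions <- function() {
    rx <- c(
        "TGFb + T2R -> TGFbT2R @ ka1",
        "TGFbT2R -> TGFb + T2R @ kd1",
        "TGFbT2R + T1R -> LRC_surf @ ka2",
        "LRC_surf -> LRC_EE @ ki_EE",
        "LRC_surf -> LRC_Cave @ ki_Cave",
        "LRC_EE -> T1R + T2R @ kr_EE",
        "LRC_Cave -> LRC_surf @ kr_Cave",
        "0 -> T1R @ pT1R",
        "0 -> T2R @ pT2R",
        "T1R -> 0 @ kcd",
        "T2R -> 0 @ kcd",
        "TGFbT2R -> 0 @ kcd",
        "LRC_surf -> 0 @ kcd",
        "LRC_EE -> 0 @ kcd",
        "LRC_Cave -> 0 @ kcd",
        "Smad2c -> pSmad2c @ kphos [LRC_EE]",
        "pSmad2c + Smad4c -> pS2S4c @ kon_Smad",
        "pS2S4c -> pSmad2c + Smad4c @ koff_Smad",
        "pSmad2c + pSmad2c -> pS2pS2c @ kon_Smad",
        "pS2pS2c -> pSmad2c + pSmad2c @ koff_Smad",
        "Smad2c -> Smad2n @ kimp_S2",
        "Smad2n -> Smad2c @ kexp_S2",
        "pSmad2c -> pSmad2n @ kimp_S2",
        "Smad4c -> Smad4n @ kimp_S4",
        "Smad4n -> Smad4c @ kexp_S4",
        "pS2S4c -> pS2S4n @ kimp_cplx",
        "pS2pS2c -> pS2pS2n @ kimp_cplx",
        "pS2S4n -> pSmad2n + Smad4n @ koff_Smad",
        "pSmad2n + Smad4n -> pS2S4n @ kon_Smad",
        "pS2pS2n -> pSmad2n + pSmad2n @ koff_Smad",
        "pSmad2n + pSmad2n -> pS2pS2n @ kon_Smad")
    lapply(seq_along(rx), function(i)
        parseReaction(rx[i], id = sprintf("sk%02d", i),
                      source = "prior_model"))
}

effectReactions <- function(effects) {
    lines <- character()
    if ("RECEPTOR_DEGRADATION" %in% effects)
        lines <- c(lines, "LRC_Cave -> 0 @ klid [Smad7]")
    ppm1aExplicit <- any(c("PPM1A_STABILIZATION", "PPM1A_EXPRESSION") %in%
                         effects)
    if ("DEPHOSPHORYLATION" %in% effects && !ppm1aExplicit)
        lines <- c(lines, "pSmad2n -> Smad2n @ kdephos")
    if ("PSMAD_DEGRADATION" %in% effects)
        lines <- c(lines, "pSmad2n -> 0 @ kdeg_pSmad2")
    if ("ENDOGENOUS_SMAD_TURNOVER" %in% effects)
        lines <- c(lines,
                   "0 -> Smad2c @ ksyn_S2",
                   "Smad2c -> 0 @ kdeg_S2",
                   "Smad2n -> 0 @ kdeg_S2",
                   "pSmad2c -> 0 @ kdeg_S2",
                   "pSmad2n -> 0 @ kdeg_S2")
    if ("ISMAD_FEEDBACK" %in% effects)
        lines <- c(lines,
                   "0 -> Smad7 @ ksyn_S7_0",
                   "0 -> Smad7 @ ksyn_S7 [pS2S4n]",
                   "0 -> Smad7 @ ksyn_S7 [pS2pS2n]",
                   "Smad7 -> 0 @ kdeg_S7",
                   "Smad7 + LRC_Cave -> S7LRC_Cave @ kon_S7",
                   "Smad7 + LRC_EE -> S7LRC_EE @ kon_S7",
                   "S7LRC_Cave -> Smad7 + T1R + T2R @ kdp_S7LRC",
                   "S7LRC_EE -> Smad7 + T1R + T2R @ kdp_S7LRC",
                   "S7LRC_Cave -> 0 @ kdeg_S7LRC",
                   "S7LRC_EE -> 0 @ kdeg_S7LRC")
    if ("PPM1A_EXPRESSION" %in% effects)
        lines <- c(lines,
                   "0 -> PPM1A_n @ ksyn_P",
                   "PPM1A_n -> 0 @ kdeg_P",
                   "0 -> PPM1A_n @ ksyn_P_ind [pS2S4n]",
                   "0 -> PPM1A_n @ ksyn_P_ind [pS2pS2n]")
    if (ppm1aExplicit)        # two-step catalysis replaces one-step dephos
        lines <- c(lines,
                   "PPM1A_n + pSmad2n -> PpS2n @ kon_P",
                   "PpS2n -> PPM1A_n + pSmad2n @ koff_P",
                   "PpS2n -> PPM1A_n + Smad2n @ kcat_P")
    if ("PPM1A_STABILIZATION" %in% effects)
        lines <- c(lines,
                   "0 -> PPM1A_c @ ksyn_P",
                   "PPM1A_c -> 0 @ kdeg_P",
                   "PPM1A_n -> 0 @ kdeg_P",
                   "PPM1A_c -> PPM1A_n @ kimp_P",
                   "PTENPPM1A_n + pSmad2n -> TPpS2n @ kon_P",
                   "TPpS2n -> PTENPPM1A_n + pSmad2n @ koff_P",
                   "TPpS2n -> PTENPPM1A_n + Smad2n @ kcat_P",
                   "pSmad2c + PTEN_c -> pS2PTEN_c @ kon_T",
                   "pS2PTEN_c -> pSmad2c + PTEN_c @ koff_T",
                   "pS2PTEN_c + PPM1A_c -> pS2PTENP_c @ kon_TP",
                   "pS2PTENP_c -> pS2PTEN_c + PPM1A_c @ koff_TP",
                   "pS2PTENP_c -> pSmad2c + PTENPPM1A_c @ krel_TP",
                   "PTENPPM1A_c -> PTENPPM1A_n @ kimp_TP",
                   "PTENPPM1A_n -> PTEN_n + PPM1A_n @ kdiss_TP",
                   "PTEN_n -> PTEN_c @ kexp_T")
    lapply(seq_along(lines), function(i)
        parseReaction(lines[i], id = sprintf("ef%02d", i),
                      source = "effect_block"))
}

effectSpecies <- function(effects) {
    sp <- list()
    if ("ISMAD_FEEDBACK" %in% effects)
        sp$ismad <- data.frame(
            name = c("S7LRC_EE", "S7LRC_Cave"),
            compartment = c("early_endosome", "caveolae"),
            initial = 0, constant = FALSE)
    if ("PPM1A_EXPRESSION" %in% effects)
        sp$pexp <- data.frame(
            name = c("PPM1A_n", "PpS2n"),
            compartment = "nucleus", initial = 0, constant = FALSE)
    if ("PPM1A_STABILIZATION" %in% effects)
        sp$pstab <- data.frame(
            name = c("PPM1A_c", "PPM1A_n", "PpS2n", "PTEN_c", "PTEN_n",
                     "pS2PTEN_c", "pS2PTENP_c", "PTENPPM1A_c",
                     "PTENPPM1A_n", "TPpS2n"),
            compartment = c("cytoplasm", "nucleus", "nucleus", "cytoplasm",
                            "nucleus", "cytoplasm", "cytoplasm",
                            "cytoplasm", "nucleus", "nucleus"),
            initial = 0, constant = FALSE)
    if (!length(sp)) return(NULL)
    out <- do.call(rbind, sp)
    out[!duplicated(out$name), ]
}

## Pre-stimulus initial concentrations (analytic; polished by equilibrate).
analyticInitials <- function(species, effects, p) {
    ini <- stats::setNames(rep(0, nrow(species)), species$name)
    ini["T1R"] <- p["pT1R"] / p["kcd"]
    ini["T2R"] <- p["pT2R"] / p["kcd"]
    ## Smad distribution from shuttling balance (turnover shifts it by
    ## <0.2% at default rates; equilibrate() polishes).
    rS2 <- p["kimp_S2"] / p["kexp_S2"]
    ini["Smad2c"] <- TOTAL_SMAD2 / (1 + rS2)
    ini["Smad2n"] <- TOTAL_SMAD2 - ini["Smad2c"]
    rS4 <- p["kimp_S4"] / p["kexp_S4"]
    ini["Smad4c"] <- TOTAL_SMAD4 / (1 + rS4)
    ini["Smad4n"] <- TOTAL_SMAD4 - ini["Smad4c"]
    ini["Smad7"] <- 100
    if ("PPM1A_EXPRESSION" %in% effects)
        ini["PPM1A_n"] <- p["ksyn_P"] / p["kdeg_P"]
    if ("PPM1A_STABILIZATION" %in% effects) {
        ini["PPM1A_c"] <- p["ksyn_P"] / (p["kdeg_P"] + p["kimp_P"])
        ini["PPM1A_n"] <- p["kimp_P"] * ini["PPM1A_c"] / p["kdeg_P"]
        ini["PTEN_c"] <- 25
    }
    ini
}

effectParameterMap <- function(effects) {
    ppm1aExplicit <- any(c("PPM1A_STABILIZATION", "PPM1A_EXPRESSION") %in%
                         effects)
    out <- character()
    for (e in effects)
        out <- c(out, switch(e,
            DEPHOSPHORYLATION = if (ppm1aExplicit) "kcat_P" else "kdephos",
            RECEPTOR_DEGRADATION = "klid",
            PSMAD_DEGRADATION = "kdeg_pSmad2",
            ENDOGENOUS_SMAD_TURNOVER = c("ksyn_S2", "kdeg_S2"),
            ISMAD_FEEDBACK = c("ksyn_S7", "kon_S7", "kdp_S7LRC",
                               "kdeg_S7LRC"),
            PPM1A_EXPRESSION = "ksyn_P_ind",
            PPM1A_STABILIZATION = c("kon_T", "krel_TP", "kimp_TP")))
    unique(out)
}

#' Assemble a model variant
#'
#' Builds the shared skeleton (ligand binding, receptor trafficking through
#' early endosome and caveolae, receptor production/turnover, Smad2
#' phosphorylation by endosomal LRC, homomeric and heteromeric complex
#' formation at the same rate, nucleocytoplasmic shuttling with faster
#' complex import) and adds the variant's negative-regulation effect
#' blocks.  In variants with explicit PPM1A (8, S2, S3) dephosphorylation
#' is realized as two-step catalysis instead of the one-step reaction.
#'
#' @param modelId one of "1".."8", "S1", "S2", "S3" (integers accepted).
#' @param parameters optional named numeric overrides of
#'   \code{\link{defaultParameters}}.
#' @param equilibrated if TRUE (default) initial concentrations are set to
#'   the pre-stimulus steady state via \code{\link{equilibrate}}.
#' @return a \linkS4class{ModelVariant}.
#' @export
assembleModel <- function(modelId, parameters = NULL, equilibrated = TRUE) {
    modelId <- as.character(modelId)
    tab <- modelEffectsTable()
    if (!modelId %in% names(tab))
        stop("unknown model id '", modelId, "'; expected one of ",
             paste(names(tab), collapse = ", "))
    effects <- tab[[modelId]]
    p <- defaultParameters()
    if (!is.null(parameters)) {
        unknown <- setdiff(names(parameters), names(p))
        if (length(unknown))
            stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
        p[names(parameters)] <- parameters
    }
    species <- rbind(skeletonSpecies(), effectSpecies(effects))
    species$constant <- species$name == "Smad7" &
        !"ISMAD_FEEDBACK" %in% effects
    species$initial <- unname(analyticInitials(species, effects, p))
    reactions <- c(skeletonReactions(), effectReactions(effects))
    net <- ReactionNetwork(species, reactions, p,
                           provenance = parameterProvenance())
    est <- effectParameterMap(effects)
    model <- new("ModelVariant", modelId = modelId, effects = effects,
                 network = net, estimated = est,
                 fixed = setdiff(names(p), est))
    if (equilibrated) {
        ss <- equilibrate(model)
        model@network@species$initial <- unname(ss[speciesNames(model)])
    }
    model
}

#' Pre-stimulus steady state of a model variant
#'
#' Simulates the system without TGF-beta for \code{horizon} minutes (one
#' week by default) and returns the final state.  All variants share the
#' same steady state for the species they have in common, because only
#' production, degradation, trafficking and shuttling occur without ligand
#' and their rates are shared across variants.
#'
#' @param model a \linkS4class{ModelVariant}.
#' @param horizon equilibration horizon in minutes (default 1e4).
#' @param warnTol warn if the maximum relative rate of change at the
#'   horizon exceeds this (default 1e-8 per minute).
#' @return named numeric steady-state vector.
#' @export
equilibrate <- function(model, horizon = 1e4, warnTol = 1e-8) {
    net <- model@network
    y0 <- initialState(net)
    y0["TGFb"] <- 0
    sol <- integrateNetwork(net, y0, times = c(0, horizon))
    yss <- sol[nrow(sol), -1]
    if (any(yss > 1e9))
        stop("equilibration diverged (species above 1e9 nM) in model ",
             model@modelId)
    rhs <- buildRHS(net)
    dy <- rhs(yss)
    rel <- abs(dy) / pmax(abs(yss), 1e-6)
    if (max(rel) > warnTol)
        warning(sprintf(
            "model %s: max relative rate %.2e/min at equilibration horizon",
            model@modelId, max(rel)))
    yss
}

#' Free-parameter schema for the fitter
#'
#' The effect-specific rate constants of a variant, with log10-scale box
#' bounds for multistart estimation.
#'
#' @param modelId model id as in \code{\link{assembleModel}}.
#' @param lower,upper default bounds on the natural scale.
#' @return data.frame (name, lower, upper, scale, default).
#' @export
estimatedParameterSchema <- function(modelId, lower = 1e-8, upper = 1e3) {
    modelId <- as.character(modelId)
    effects <- modelEffectsTable()[[modelId]]
    if (is.null(effects)) stop("unknown model id '", modelId, "'")
    nm <- effectParameterMap(effects)
    data.frame(name = nm, lower = lower, upper = upper, scale = "log10",
               default = unname(defaultParameters()[nm]))
}
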