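#' Construct a reaction network
#'
#' @param species data.frame with columns name, compartment, initial,
#'   constant.
#' @param reactions list of reaction records (see
#'   \linkS4class{ReactionNetwork}) or character vector in the declarative
#'   format accepted by \code{\link{parseReaction}}.
#' @param parameters named numeric vector of rate constants.
#' @param provenance optional named character vector
#'   (literature/fixed_prior_model/estimated); defaults to "estimated".
#' @param volumeRatio cytoplasm-to-nucleus volume ratio (default 3).
#' @return a validated \linkS4class{ReactionNetwork}.
#' @export
ReactionNetwork <- function(species, reactions, parameters,
                            provenance = NULL, volumeRatio = 3) {
    if (is.character(reactions))
        reactions <- lapply(seq_along(reactions), function(i)
            parseReaction(reactions[i], id = sprintf("r%02d", i)))
    if (is.null(provenance))
        provenance <- stats::setNames(rep("estimated", length(parameters)),
                                      names(parameters))
    species$name <- as.character(species$name)
    species$compartment <- as.character(species$compartment)
    species$constant <- as.logical(species$constant)
    rownames(species) <- NULL
    new("ReactionNetwork", species = species, reactions = reactions,
        parameters = parameters, provenance = provenance,
        volumeRatio = volumeRatio)
}

#' Parse one declarative reaction line
#'
#' Accepts \code{"A + B -> C @ kname"} with an optional trailing modifier
#' annotation \code{"[mod]"} (a species whose concentration multiplies the
#' rate without being consumed) and \code{"0"} for an empty side (synthesis
#' or degradation).  Reversible reactions are written as two lines with
#' separate rate constants.
#'
#' @param text the reaction string.
#' @param id reaction identifier.
#' @param source provenance of the reaction
#'   ("prior_model"/"effect_block"/"this_work").
#' @return a reaction record list.
#' @export
parseReaction <- function(text, id = "r", source = "this_work") {
    txt <- trimws(text)
    modifier <- NA_character_
    mm <- regmatches(txt, regexec("\\[([^]]+)\\]\\s*$", txt))[[1]]
    if (length(mm)) {
        modifier <- trimws(mm[2])
        txt <- trimws(sub("\\[[^]]+\\]\\s*$", "", txt))
    }
    halves <- strsplit(txt, "@", fixed = TRUE)[[1]]
    if (length(halves) != 2)
        stop("reaction '", text, "' must contain '@ rate'")
    rate <- trimws(halves[2])
    sides <- strsplit(halves[1], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2)
        stop("reaction '", text, "' must contain '->'")
    side <- function(s) {
        s <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
        s <- s[nzchar(s)]
        s[s != "0"]
    }
    list(id = id, reactants = side(sides[1]), products = side(sides[2]),
         rate = rate, modifier = modifier, source = source)
}

#' Species names of a network
#' @param network a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @return character vector.
#' @export
speciesNames <- function(network) {
    if (is(network, "ModelVariant")) network <- network@network
    network@species$name
}

#' Parameter vector of a network or model variant
#' @param object a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @return named numeric vector.
#' @export
networkParameters <- function(object) {
    if (is(object, "ModelVariant")) object <- object@network
    object@parameters
}

#' Replace parameter values
#'
#' Returns a modified copy; unknown names are an error.
#' @param object a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @param values named numeric vector of replacements.
#' @return object of the same class with updated parameters.
#' @export
setParameters <- function(object, values) {
    stopifnot(is.numeric(values), !is.null(names(values)))
    if (is(object, "ModelVariant")) {
        object@network <- setParameters(object@network, values)
        return(object)
    }
    unknown <- setdiff(names(values), names(object@parameters))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    object@parameters[names(values)] <- values
    object
}

#' Stoichiometry matrix of a network
#'
#' Net stoichiometric change per species (rows) and reaction (columns).
#' Conserved moieties live in the left null space of this matrix.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @return numeric matrix with dimnames (species, reaction ids).
#' @export
stoichiometryMatrix <- function(network) {
    sp <- network@species$name
    nr <- length(network@reactions)
    S <- matrix(0, nrow = length(sp), ncol = nr,
                dimnames = list(sp, vapply(network@reactions, `[[`, "", "id")))
    for (j in seq_len(nr)) {
        rx <- network@reactions[[j]]
        for (r in rx$reactants) S[r, j] <- S[r, j] - 1
        for (p in rx$products) S[p, j] <- S[p, j] + 1
    }
    S
}

#' Mass-action rate of a single reaction
#'
#' rate = k times the product of reactant and modifier concentrations;
#' zeroth-order (synthesis) reactions return k.
#'
#' @param reaction a reaction record (one element of a network's reaction
#'   list, or the output of \code{\link{parseReaction}}).
#' @param state named numeric vector of concentrations (nM).
#' @param params named numeric vector of rate constants.
#' @return rate in nM/min.
#' @export
massActionRate <- function(reaction, state, params) {
    k <- params[reaction$rate]
    if (is.na(k))
        stop("unknown parameter '", reaction$rate, "' in reaction ",
             reaction$id)
    refs <- c(reaction$reactants,
              if (!is.na(reaction$modifier)) reaction$modifier)
    if (length(refs)) {
        conc <- state[refs]
        if (anyNA(conc))
            stop("unknown species '",
                 paste(refs[is.na(conc)], collapse = ", "),
                 "' in reaction ", reaction$id)
        k <- k * prod(conc)
    }
    unname(k)
}

## Precompute the index structures the compiled RHS consumes.
networkIndices <- function(network) {
    sp <- network@species$name
    nr <- length(network@reactions)
    idx <- function(name) if (is.na(name)) 0L else match(name, sp)
    r1 <- integer(nr); r2 <- integer(nr); mod <- integer(nr)
    for (j in seq_len(nr)) {
        rx <- network@reactions[[j]]
        r1[j] <- if (length(rx$reactants) >= 1) idx(rx$reactants[1]) else 0L
        r2[j] <- if (length(rx$reactants) >= 2) idx(rx$reactants[2]) else 0L
        mod[j] <- idx(rx$modifier)
    }
    list(r1 = r1, r2 = r2, mod = mod,
         S = stoichiometryMatrix(network),
         constMask = as.integer(network@species$constant),
         rateNames = vapply(network@reactions, `[[`, "", "rate"),
         speciesNames = sp)
}

#' Build the ODE right-hand side of a network
#'
#' Returns \code{function(state, time)} mapping a named (or ordered) state
#' vector to the derivative vector: d/dt of each species is the
#' stoichiometry-weighted sum of mass-action reaction rates; constant
#' (buffered) species have zero derivative.  Nuclear species are already in
#' cytoplasm-volume-relative units, so no volume scaling occurs here.
#'
#' @param network a validated \linkS4class{ReactionNetwork}.
#' @param engine "C" (compiled, default) or "R" (pure-R reference
#'   implementation; used as the independent check in the test-suite).
#' @return function(state, time = 0) -> named derivative vector.
#' @export
buildRHS <- function(network, engine = c("C", "R")) {
    engine <- match.arg(engine)
    validObject(network)
    ix <- networkIndices(network)
    k <- unname(network@parameters[ix$rateNames])
    if (engine == "C") {
        function(state, time = 0) {
            dy <- .Call(C_mass_action_deriv, as.double(state), k, ix$r1,
                        ix$r2, ix$mod, ix$S, ix$constMask)
            names(dy) <- ix$speciesNames
            dy
        }
    } else {
        function(state, time = 0) {
            y <- as.double(state)
            f1 <- ifelse(ix$r1 > 0L, y[pmax(ix$r1, 1L)], 1)
            f2 <- ifelse(ix$r2 > 0L, y[pmax(ix$r2, 1L)], 1)
            fm <- ifelse(ix$mod > 0L, y[pmax(ix$mod, 1L)], 1)
            rates <- k * f1 * f2 * fm
            dy <- as.vector(ix$S %*% rates)
            dy[ix$constMask == 1L] <- 0
            names(dy) <- ix$speciesNames
            dy
        }
    }
}

#' Conserved moiety totals
#'
#' Stoichiometry-weighted sums of concentrations; a species containing two
#' copies of a moiety (the phospho-Smad2 homomeric complex for the Smad2
#' moiety) counts twice.  Because nuclear species are stored in
#' cytoplasm-volume-relative units the sums are directly additive across
#' compartments.
#'
#' @param network a \linkS4class{ReactionNetwork} (used to check species
#'   names).
#' @param state named numeric state vector.
#' @param moieties named list; each element is a named numeric vector of
#'   stoichiometric weights over species.  Defaults to
#'   \code{\link{moietyDefinitions}} applied to the network.
#' @return named numeric vector of totals (nM).
#' @export
conservedTotals <- function(network, state, moieties = NULL) {
    if (is(network, "ModelVariant")) network <- network@network
    if (is.null(moieties)) moieties <- moietyDefinitions(network)
    out <- vapply(moieties, function(w) {
        if (!all(names(w) %in% network@species$name))
            stop("moiety references unknown species: ",
                 paste(setdiff(names(w), network@species$name),
                       collapse = ", "))
        conc <- state[names(w)]
        if (anyNA(conc))
            stop("state is missing species: ",
                 paste(names(w)[is.na(conc)], collapse = ", "))
        sum(w * conc)
    }, numeric(1))
    out
}

#' Validate a network and report findings
#'
#' Non-throwing structural checks: dangling parameters, unknown species,
#' negative initial concentrations, species never produced nor consumed,
#' parameters defined but unused.
#'
#' @param network a \linkS4class{ReactionNetwork}.
#' @return data.frame (level, what, detail); zero rows when well formed.
#' @export
validateNetwork <- function(network) {
    findings <- list()
    add <- function(level, what, detail)
        findings[[length(findings) + 1]] <<- data.frame(
            level = level, what = what, detail = detail)
    sp <- network@species
    bad <- sp$name[sp$initial < 0]
    for (s in bad) add("error", "negative_initial", s)
    used <- character(); touched <- character()
    for (rx in network@reactions) {
        refs <- c(rx$reactants, rx$products,
                  if (!is.na(rx$modifier)) rx$modifier)
        unk <- setdiff(refs, sp$name)
        for (u in unk) add("error", "unknown_species",
                          sprintf("%s in %s", u, rx$id))
        if (!rx$rate %in% names(network@parameters))
            add("error", "unknown_parameter",
                sprintf("%s in %s", rx$rate, rx$id))
        used <- c(used, rx$rate)
        touched <- c(touched, rx$reactants, rx$products)
    }
    for (p in setdiff(names(network@parameters), used))
        add("note", "unused_parameter", p)
    idle <- setdiff(sp$name[!sp$constant], touched)
    for (s in idle) add("note", "inert_species", s)
    if (length(findings)) do.call(rbind, findings)
    else data.frame(level = character(), what = character(),
                    detail = character())
}

#' Initial state vector of a network
#' @param network a \linkS4class{ReactionNetwork} or
#'   \linkS4class{ModelVariant}.
#' @return named numeric vector of initial concentrations.
#' @export
initialState <- function(network) {
    if (is(network, "ModelVariant")) network <- network@network
    stats::setNames(network@species$initial, network@species$name)
}
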