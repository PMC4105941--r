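## Standard-format I/O: SBML (Level 3 Version 1, mass-action kinetic laws
## only), tidy CSV for datasets and trajectories, YAML protocols, and JSON
## provenance manifests.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a model variant to SBML
#'
#' Writes SBML Level 3 Version 1 with one compartment per cellular
#' compartment, species with initial concentrations (nM; nuclear species
#' in the cytoplasm-volume-relative convention, recorded in the model
#' notes), global parameters (minutes/nM units) and irreversible
#' reactions whose kinetic laws are explicit mass-action MathML products.
#' Constant (buffered) species are exported with boundaryCondition
#' semantics.
#'
#' @param model a \linkS4class{ModelVariant} or
#'   \linkS4class{ReactionNetwork}.
#' @param path output file.
#' @return path, invisibly.
#' @export
sbmlExport <- function(model, path) {
    net <- if (is(model, "ModelVariant")) model@network else model
    modelId <- if (is(model, "ModelVariant"))
        paste0("model_", gsub("[^A-Za-z0-9]", "", model@modelId))
    else "network"
    doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                              version = "1")
    mdl <- xml2::xml_add_child(doc, "model", id = modelId,
                               timeUnits = "minute")
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste(
        "Units: nM, minutes. Nuclear species are stored as",
        "cytoplasm-volume-relative concentrations; compartment sizes are",
        "set to 1 so that reported amounts equal these relative",
        "concentrations."))
    locs <- xml2::xml_add_child(mdl, "listOfCompartments")
    for (cmp in unique(net@species$compartment))
        xml2::xml_add_child(locs, "compartment", id = cmp, size = "1",
                            constant = "true")
    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(net@species))) {
        s <- net@species[i, ]
        xml2::xml_add_child(los, "species", id = s$name,
                            compartment = s$compartment,
                            initialConcentration =
                                format(s$initial, digits = 17),
                            hasOnlySubstanceUnits = "false",
                            boundaryCondition =
                                if (s$constant) "true" else "false",
                            constant = "false")
    }
    lop <- xml2::xml_add_child(mdl, "listOfParameters")
    for (pn in names(net@parameters))
        xml2::xml_add_child(lop, "parameter", id = pn,
                            value = format(net@parameters[[pn]],
                                           digits = 17),
                            constant = "true")
    lor <- xml2::xml_add_child(mdl, "listOfReactions")
    for (rx in net@reactions) {
        rn <- xml2::xml_add_child(lor, "reaction", id = rx$id,
                                  reversible = "false", fast = "false")
        addRefs <- function(parent, tag, refTag, names) {
            if (!length(names)) return()
            lst <- xml2::xml_add_child(parent, tag)
            for (nm in unique(names)) {
                st <- sum(names == nm)
                if (refTag == "modifierSpeciesReference")
                    xml2::xml_add_child(lst, refTag, species = nm)
                else
                    xml2::xml_add_child(lst, refTag, species = nm,
                                        stoichiometry = as.character(st),
                                        constant = "true")
            }
        }
        addRefs(rn, "listOfReactants", "speciesReference", rx$reactants)
        addRefs(rn, "listOfProducts", "speciesReference", rx$products)
        if (!is.na(rx$modifier))
            addRefs(rn, "listOfModifiers", "modifierSpeciesReference",
                    rx$modifier)
        kl <- xml2::xml_add_child(rn, "kineticLaw")
        math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
        factors <- c(rx$rate, rx$reactants,
                     if (!is.na(rx$modifier)) rx$modifier)
        if (length(factors) == 1) {
            xml2::xml_add_child(math, "ci", factors)
        } else {
            ap <- xml2::xml_add_child(math, "apply")
            xml2::xml_add_child(ap, "times")
            for (f in factors) xml2::xml_add_child(ap, "ci", f)
        }
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' Import an SBML model with mass-action kinetics
#'
#' Reads SBML Level 2/3 files whose kinetic laws are explicit mass-action
#' products (an optional \code{<times>} apply over \code{<ci>} factors:
#' one rate parameter plus the reactant/modifier species).  Any other
#' rate law (Hill, Michaelis-Menten, explicit numerics) is rejected with
#' a clear message.
#'
#' @param path SBML file.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
sbmlImport <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    mdl <- xml2::xml_find_first(doc, ".//model")
    if (is.na(xml2::xml_name(mdl, ns = character())))
        stop("malformed SBML: no <model> element in ", path)
    spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
    if (!length(spNodes)) stop("malformed SBML: no species")
    species <- data.frame(
        name = xml2::xml_attr(spNodes, "id"),
        compartment = xml2::xml_attr(spNodes, "compartment"),
        initial = as.numeric(xml2::xml_attr(spNodes,
                                            "initialConcentration")),
        constant = xml2::xml_attr(spNodes, "boundaryCondition") %in%
            "true")
    species$initial[is.na(species$initial)] <- 0
    pNodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
    parameters <- stats::setNames(
        as.numeric(xml2::xml_attr(pNodes, "value")),
        xml2::xml_attr(pNodes, "id"))
    rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
    reactions <- lapply(rxNodes, function(rn) {
        id <- xml2::xml_attr(rn, "id")
        refs <- function(xp) {
            nodes <- xml2::xml_find_all(rn, xp)
            sp <- xml2::xml_attr(nodes, "species")
            st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
            st[is.na(st)] <- 1
            if (any(st != round(st)))
                stop("non-integer stoichiometry in reaction ", id)
            rep(sp, times = st)
        }
        reactants <- refs("./listOfReactants/speciesReference")
        products <- refs("./listOfProducts/speciesReference")
        modifiers <- xml2::xml_attr(
            xml2::xml_find_all(rn, "./listOfModifiers/modifierSpeciesReference"),
            "species")
        math <- xml2::xml_find_first(rn, "./kineticLaw/math")
        if (is.na(xml2::xml_name(math, ns = character())))
            stop("reaction ", id, " has no kinetic law")
        bad <- xml2::xml_find_all(
            math, ".//*[not(self::apply or self::times or self::ci)]")
        if (length(bad))
            stop("unsupported rate law in reaction ", id, ": <",
                 xml2::xml_name(bad[[1]]),
                 "> is not mass action (only products of concentrations ",
                 "and one rate constant are supported)")
        cis <- xml2::xml_text(xml2::xml_find_all(math, ".//ci"))
        cis <- trimws(cis)
        rate <- setdiff(cis, c(reactants, modifiers))
        if (length(rate) != 1)
            stop("kinetic law of reaction ", id,
                 " is not k * reactants * modifiers mass action")
        expected <- sort(c(rate, reactants, modifiers))
        if (!identical(sort(cis), expected))
            stop("kinetic law of reaction ", id,
                 " does not match its reactant/modifier list")
        list(id = id, reactants = reactants, products = products,
             rate = rate,
             modifier = if (length(modifiers)) modifiers[1]
                        else NA_character_,
             source = "sbml_import")
    })
    ReactionNetwork(species, reactions, parameters)
}

#' Write a tidy time-course dataset to CSV
#' @param dataset a \linkS4class{TimeSeriesDataset}.
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeTimeSeriesCSV <- function(dataset, path) {
    d <- dataset@data
    d$normalization <- dataset@normalization
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}

#' Read a tidy time-course dataset from CSV
#' @param path CSV path written by \code{\link{writeTimeSeriesCSV}} (or
#'   any CSV with the same columns).
#' @return a \linkS4class{TimeSeriesDataset}.
#' @export
readTimeSeriesCSV <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    norm <- if ("normalization" %in% names(d)) unique(d$normalization)[1]
            else "absolute_nM"
    d$normalization <- NULL
    TimeSeriesDataset(d, normalization = norm)
}

#' Write a trajectory to tidy CSV
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeTrajectoryCSV <- function(trajectory, path) {
    utils::write.csv(trajectoryTable(trajectory), path, row.names = FALSE)
    invisible(path)
}

#' Read a stimulation protocol from YAML
#'
#' Fields: dose (ng/ml), exposure (long/short), t_wash, perturbations,
#' horizon; missing fields take the \code{\link{StimulusProtocol}}
#' defaults.
#'
#' @param path YAML file.
#' @return a \linkS4class{StimulusProtocol}.
#' @export
readProtocolYAML <- function(path) {
    y <- yaml::read_yaml(path)
    StimulusProtocol(
        dose = if (!is.null(y$dose)) y$dose else 2,
        exposure = if (!is.null(y$exposure)) y$exposure else "long",
        tWash = if (!is.null(y$t_wash)) y$t_wash else 30,
        perturbations = if (!is.null(y$perturbations))
            toupper(unlist(y$perturbations)) else character(),
        horizon = if (!is.null(y$horizon)) y$horizon else 1440)
}

#' Write a stimulation protocol to YAML
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param path output YAML path.
#' @return path, invisibly.
#' @export
writeProtocolYAML <- function(protocol, path) {
    yaml::write_yaml(list(dose = protocol@dose,
                          exposure = protocol@exposure,
                          t_wash = protocol@tWash,
                          perturbations = as.list(protocol@perturbations),
                          horizon = protocol@horizon), path)
    invisible(path)
}

#' Write a provenance manifest next to a result file
#'
#' Records the configuration, seed and package version so a result file
#' can be regenerated from its manifest alone.
#'
#' @param path manifest path (JSON).
#' @param config named list of run configuration.
#' @param seed RNG seed used.
#' @return path, invisibly.
#' @export
writeManifest <- function(path, config, seed = NA) {
    jsonlite::write_json(
        list(config = config, seed = seed,
             package = "tgfsmad",
             version = as.character(utils::packageVersion("tgfsmad")),
             created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Write a model variant to the declarative network config format
#'
#' A plain-text format with species, parameter and reaction sections;
#' reactions are written as \code{"A + B -> C @ k [modifier]"}.
#'
#' @param model a \linkS4class{ModelVariant} or
#'   \linkS4class{ReactionNetwork}.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeNetworkConfig <- function(model, path) {
    net <- if (is(model, "ModelVariant")) model@network else model
    lines <- c("# tgfsmad network config", "[species]")
    for (i in seq_len(nrow(net@species))) {
        s <- net@species[i, ]
        lines <- c(lines, sprintf("%s\t%s\t%.17g\t%s", s$name,
                                  s$compartment, s$initial,
                                  if (s$constant) "constant" else "dynamic"))
    }
    lines <- c(lines, "[parameters]")
    for (pn in names(net@parameters))
        lines <- c(lines, sprintf("%s\t%.17g", pn, net@parameters[[pn]]))
    lines <- c(lines, "[reactions]")
    for (rx in net@reactions) {
        lhs <- if (length(rx$reactants))
            paste(rx$reactants, collapse = " + ") else "0"
        rhs <- if (length(rx$products))
            paste(rx$products, collapse = " + ") else "0"
        mod <- if (!is.na(rx$modifier)) paste0(" [", rx$modifier, "]")
               else ""
        lines <- c(lines, sprintf("%s: %s -> %s @ %s%s", rx$id, lhs, rhs,
                                  rx$rate, mod))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a declarative network config
#' @param path file written by \code{\link{writeNetworkConfig}}.
#' @return a \linkS4class{ReactionNetwork}.
#' @export
readNetworkConfig <- function(path) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    section <- ""
    sp <- list(); pars <- c(); rx <- list()
    for (ln in lines) {
        if (startsWith(ln, "[")) { section <- ln; next }
        if (section == "[species]") {
            f <- strsplit(ln, "\t")[[1]]
            sp[[length(sp) + 1]] <- data.frame(
                name = f[1], compartment = f[2],
                initial = as.numeric(f[3]), constant = f[4] == "constant")
        } else if (section == "[parameters]") {
            f <- strsplit(ln, "\t")[[1]]
            pars[f[1]] <- as.numeric(f[2])
        } else if (section == "[reactions]") {
            f <- strsplit(ln, ":", fixed = TRUE)[[1]]
            rx[[length(rx) + 1]] <-
                parseReaction(paste(f[-1], collapse = ":"),
                              id = trimws(f[1]))
        }
    }
    ReactionNetwork(do.call(rbind, sp), rx, pars)
}
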