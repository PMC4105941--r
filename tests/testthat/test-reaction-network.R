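test_that("mass-action rates follow the product-of-concentrations law", {
    params <- c(k = 2, kd = 0.1, ks = 1.5)
    bim <- parseReaction("A + B -> C @ k")
    expect_equal(massActionRate(bim, c(A = 3, B = 4, C = 0), params), 24)
    expect_equal(massActionRate(bim, c(A = 0, B = 4, C = 0), params), 0)
    deg <- parseReaction("X -> 0 @ kd")
    expect_equal(massActionRate(deg, c(X = 10), params), 1)
    syn <- parseReaction("0 -> X @ ks")
    expect_equal(massActionRate(syn, c(X = 99), params), 1.5)
    mod <- parseReaction("X -> 0 @ kd [M]")
    expect_equal(massActionRate(mod, c(X = 10, M = 5), params), 5)
    expect_error(massActionRate(bim, c(A = 3), params), "unknown species")
    expect_error(massActionRate(parseReaction("A -> 0 @ nope"),
                                c(A = 1), params), "unknown parameter")
})

test_that("reaction parser handles modifiers, synthesis and homodimers", {
    rx <- parseReaction("pSmad2c + pSmad2c -> pS2pS2c @ kon [LRC_EE]")
    expect_equal(rx$reactants, c("pSmad2c", "pSmad2c"))
    expect_equal(rx$products, "pS2pS2c")
    expect_equal(rx$modifier, "LRC_EE")
    syn <- parseReaction("0 -> X @ ks")
    expect_length(syn$reactants, 0)
    expect_error(parseReaction("A -> B"), "must contain '@ rate'")
})

test_that("RHS matches trivial stoichiometry and conserves closed toys", {
    net <- ReactionNetwork(
        species = data.frame(name = c("A", "B"), compartment = "cytoplasm",
                             initial = c(1, 0), constant = FALSE),
        reactions = "A -> B @ k", parameters = c(k = 1))
    rhs <- buildRHS(net)
    dy <- rhs(c(A = 1, B = 0))
    expect_equal(unname(dy), c(-1, 1))
    ## closed binding toy: total A-moiety and B-moiety constant
    toy <- toyBindingNetwork()
    rhsT <- buildRHS(toy)
    for (i in 1:5) {
        y <- stats::setNames(c(i, 2 * i, 0.5 * i), c("A", "B", "C"))
        d <- rhsT(y)
        expect_equal(unname(d["A"] + d["C"]), 0)
        expect_equal(unname(d["B"] + d["C"]), 0)
    }
})

test_that("RHS agrees with independently hand-coded derivatives", {
    toy <- toyBindingNetwork()
    rhs <- buildRHS(toy)
    set.seed(11)
    for (i in 1:100) {
        y <- stats::setNames(stats::runif(3, 0, 10), c("A", "B", "C"))
        expect_equal(rhs(y), toyBindingDeriv(y), tolerance = 1e-15)
    }
})

test_that("compiled and pure-R RHS engines agree to machine precision", {
    net <- model8()@network
    rhsC <- buildRHS(net, engine = "C")
    rhsR <- buildRHS(net, engine = "R")
    set.seed(5)
    for (i in 1:20) {
        y <- stats::setNames(stats::runif(nrow(net@species), 0, 100),
                             net@species$name)
        expect_equal(rhsC(y), rhsR(y), tolerance = 1e-14)
    }
})

test_that("constant (buffered) species have zero derivative", {
    net <- model1()@network
    rhs <- buildRHS(net)
    y <- initialState(net)
    y["TGFb"] <- 80
    y["LRC_Cave"] <- 1
    expect_equal(unname(rhs(y)["Smad7"]), 0)
})

test_that("conserved totals weight homomeric complexes by stoichiometry", {
    net <- model8()@network
    y <- initialState(net)
    y[] <- 0
    y["pS2pS2n"] <- 10
    tot <- conservedTotals(net, y)
    expect_equal(unname(tot["Smad2"]), 20)
    y["pS2S4n"] <- 3
    tot <- conservedTotals(net, y)
    expect_equal(unname(tot["Smad2"]), 23)
    expect_equal(unname(tot["Smad4"]), 3)
    expect_error(conservedTotals(net, y, moieties = list(x = c(Qx = 1))),
                 "unknown species")
})

test_that("equilibrated Model 1 carries the HaCaT Smad totals", {
    tot <- conservedTotals(model1(), initialState(model1()))
    expect_equal(unname(tot["Smad2"]), 571.43, tolerance = 1e-6)
    expect_equal(unname(tot["Smad4"]), 1333.33, tolerance = 1e-6)
})

test_that("conserved moieties lie in the left null space of S", {
    net <- model1()@network
    S <- stoichiometryMatrix(net)
    defs <- moietyDefinitions(net)
    for (m in c("Smad2", "Smad4")) {
        w <- rep(0, nrow(S)); names(w) <- rownames(S)
        w[names(defs[[m]])] <- defs[[m]]
        expect_equal(max(abs(w %*% S)), 0)
    }
})

test_that("network validation reports structural findings without throwing", {
    expect_identical(nrow(subset(validateNetwork(model1()@network),
                                 level == "error")), 0L)
    bad <- ReactionNetwork(
        species = data.frame(name = c("A", "B"), compartment = "cytoplasm",
                             initial = c(1, 0), constant = FALSE),
        reactions = "A -> B @ k", parameters = c(k = 1, k_unused = 2))
    f <- validateNetwork(bad)
    expect_true("unused_parameter" %in% f$what)
    ## findings, not errors, for a dangling parameter reference
    bad2 <- bad
    bad2@reactions[[1]]$rate <- "k_missing"
    f2 <- validateNetwork(bad2)
    expect_true(any(f2$what == "unknown_parameter" &
                    grepl("k_missing", f2$detail)))
})

test_that("parameter replacement is checked and non-destructive", {
    m <- model1()
    m2 <- setParameters(m, c(kdephos = 0.1))
    expect_equal(unname(networkParameters(m2)["kdephos"]), 0.1)
    expect_equal(unname(networkParameters(m)["kdephos"]),
                 unname(defaultParameters()["kdephos"]))
    expect_error(setParameters(m, c(bogus = 1)), "unknown parameter")
})
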