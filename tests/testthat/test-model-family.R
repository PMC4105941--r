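test_that("effect flags of Models 1-8 match the family design matrix", {
    ## hard-coded copy of the model x effect matrix
    expected <- rbind(
        DEPHOSPHORYLATION        = c(1, 1, 0, 0, 1, 1, 1, 1),
        RECEPTOR_DEGRADATION     = c(0, 1, 1, 0, 1, 0, 0, 0),
        PSMAD_DEGRADATION        = c(0, 0, 0, 1, 1, 1, 1, 1),
        ENDOGENOUS_SMAD_TURNOVER = c(0, 0, 0, 0, 0, 0, 1, 1),
        PPM1A_STABILIZATION      = c(0, 0, 0, 0, 0, 0, 0, 1))
    tab <- modelEffectsTable()
    for (m in 1:8)
        for (eff in rownames(expected))
            expect_identical(eff %in% tab[[as.character(m)]],
                             unname(expected[eff, m] == 1),
                             label = sprintf("model %d effect %s", m, eff))
})

test_that("assembled variants carry exactly their effect reactions", {
    effRates <- function(m) unique(vapply(
        Filter(function(rx) rx$source == "effect_block",
               m@network@reactions), `[[`, "", "rate"))
    expect_identical(effRates(model1()), "kdephos")
    r5 <- effRates(model5())
    expect_setequal(r5, c("klid", "kdephos", "kdeg_pSmad2"))
    expect_false("ksyn_S2" %in% r5)
    expect_setequal(model8()@effects,
                    c("DEPHOSPHORYLATION", "PSMAD_DEGRADATION",
                      "ENDOGENOUS_SMAD_TURNOVER", "PPM1A_STABILIZATION"))
    ## explicit-PPM1A variants realize dephosphorylation as catalysis
    expect_true("kcat_P" %in% effRates(model8()))
    expect_false("kdephos" %in% effRates(model8()))
    expect_error(assembleModel("42"), "unknown model id")
})

test_that("pre-stimulus equilibration gives a ligand-free steady state", {
    m <- model1()
    ss <- initialState(m)
    expect_equal(unname(ss["pSmad2n"]), 0, tolerance = 1e-10)
    expect_equal(unname(ss["TGFb"]), 0)
    ## a further week changes nothing by more than 0.1%
    ss2 <- equilibrate(m)
    nz <- ss > 1e-6
    expect_lt(max(abs(ss2[nz] / ss[nz] - 1)), 1e-3)
})

test_that("monomeric Smad distribution follows the shuttling-rate ratio", {
    ss <- initialState(model1())
    p <- networkParameters(model1())
    expect_equal(unname(ss["Smad2n"] / ss["Smad2c"]),
                 unname(p["kimp_S2"] / p["kexp_S2"]), tolerance = 1e-6)
    expect_equal(unname(ss["Smad4n"] / ss["Smad4c"]),
                 unname(p["kimp_S4"] / p["kexp_S4"]), tolerance = 1e-6)
})

test_that("all variants share the pre-stimulus steady state of common species", {
    states <- lapply(as.character(1:8), function(id)
        initialState(assembleModel(id)))
    shared <- Reduce(intersect, lapply(states, names))
    ref <- states[[1]][shared]
    for (i in 2:8) {
        cur <- states[[i]][shared]
        nz <- ref > 1e-6
        expect_lt(max(abs(cur[nz] / ref[nz] - 1)), 0.01)
    }
})

test_that("Model 8 basal PPM1A sits at the synthesis-degradation balance", {
    ss <- initialState(model8())
    p <- networkParameters(model8())
    pc <- unname(p["ksyn_P"] / (p["kdeg_P"] + p["kimp_P"]))
    expect_equal(unname(ss["PPM1A_c"]), pc, tolerance = 1e-4)
    expect_equal(unname(ss["PPM1A_n"]),
                 unname(p["kimp_P"]) * pc / unname(p["kdeg_P"]),
                 tolerance = 1e-4)
    ## no phospho-Smad, hence no PTEN scaffolding before stimulation
    expect_equal(unname(ss["PTENPPM1A_c"]), 0, tolerance = 1e-8)
    expect_equal(unname(ss["pS2PTEN_c"]), 0, tolerance = 1e-8)
})

test_that("free-parameter schema follows the effect-to-parameter mapping", {
    expect_identical(estimatedParameterSchema("1")$name, "kdephos")
    s3 <- estimatedParameterSchema("3")
    expect_true("klid" %in% s3$name)
    expect_false("kdephos" %in% s3$name)
    s4 <- estimatedParameterSchema("4")
    expect_true("kdeg_pSmad2" %in% s4$name)
    expect_false("klid" %in% s4$name)
    expect_true(all(s3$scale == "log10"))
    expect_true(all(s3$lower > 0))
})

test_that("moiety conservation holds along stimulated trajectories", {
    ## Model 1 has no Smad synthesis/degradation: Smad2 and Smad4 totals
    ## stay fixed over 24 hr of saturating ligand
    tr <- simulateModel(model1(), longProtocol(),
                        times = seq(0, 1440, by = 60))
    for (i in seq_along(tr@times)) {
        tot <- conservedTotals(model1(), tr@state[i, ])
        expect_equal(unname(tot["Smad2"]), 571.43, tolerance = 1e-6)
        expect_equal(unname(tot["Smad4"]), 1333.33, tolerance = 1e-6)
    }
})
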