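test_that("dose conversion reproduces the 2 ng/ml = 80 pM equivalence", {
    expect_identical(doseConvert(2), 80)
    expect_identical(doseConvert(0), 0)
    expect_equal(doseConvert(1), 40)
    expect_equal(doseConvert(2, molecular_mass_kDa = 50), 40)
    expect_error(doseConvert(2, molecular_mass_kDa = 0), "positive")
    expect_error(doseConvert(-1), ">= 0")
})

test_that("zero dose leaves every observable flat at steady state", {
    tr <- simulateModel(model8(), StimulusProtocol(dose = 0),
                        times = c(0, 360, 720, 1440))
    obs <- tr@observables
    for (nm in unique(obs$name)) {
        v <- obs$value[obs$name == nm]
        expect_lt(max(abs(v - v[1])), max(1e-6, 1e-6 * abs(v[1])))
    }
})

test_that("Model 1 plateaus by one hour while Model 8 keeps declining", {
    tt <- seq(0, 1440, by = 10)
    ps1 <- observe(simulateModel(model1(), longProtocol(), times = tt),
                   "PSmad2_total")
    after1h <- ps1$value[ps1$time_min >= 60]
    expect_lt((max(after1h) - after1h[length(after1h)]) / max(ps1$value),
              0.10)
    ps8 <- observe(simulateModel(model8(), longProtocol(), times = tt),
                   "PSmad2_total")
    expect_gt(1 - ps8$value[length(ps8$value)] / max(ps8$value), 0.20)
    ## peak near one hour
    expect_lt(ps8$time_min[which.max(ps8$value)], 120)
})

test_that("zeroing the slow-mode rates collapses Model 5 onto Model 1", {
    m5 <- setParameters(model5(), c(klid = 0, kdeg_pSmad2 = 0))
    tt <- seq(0, 1440, by = 30)
    ps5 <- observe(simulateModel(m5, longProtocol(), times = tt),
                   "PSmad2_total")
    ps1 <- observe(simulateModel(model1(), longProtocol(), times = tt),
                   "PSmad2_total")
    expect_equal(ps5$value, ps1$value, tolerance = 1e-6)
})

test_that("proteasome inhibition zeroes exactly one rate", {
    m5 <- applyPerturbation(model5(), "MG132")
    expect_identical(unname(networkParameters(m5)["kdeg_pSmad2"]), 0)
    diff <- networkParameters(m5) != networkParameters(model5())
    expect_identical(names(which(diff)), "kdeg_pSmad2")
    ## no P-Smad degradation reaction in Model 1: warning, no-op
    expect_warning(m1p <- applyPerturbation(model1(), "MG132"), "no-op")
    expect_identical(networkParameters(m1p), networkParameters(model1()))
    ## basal PPM1A and receptor degradation untouched in Model 8
    m8p <- applyPerturbation(model8(), "MG132")
    diff8 <- which(networkParameters(m8p) != networkParameters(model8()))
    expect_identical(names(diff8), "kdeg_pSmad2")
})

test_that("cycloheximide halves every zeroth-order synthesis rate", {
    m8c <- applyPerturbation(model8(), "CYCLOHEXIMIDE")
    p0 <- networkParameters(model8())
    p1 <- networkParameters(m8c)
    synth <- c("pT1R", "pT2R", "ksyn_S2", "ksyn_P")
    expect_equal(unname(p1[synth]), unname(p0[synth]) / 2)
    untouched <- setdiff(names(p0), synth)
    expect_equal(p1[untouched], p0[untouched])
})

test_that("washout with receptor-kinase block eliminates phospho-Smad2", {
    for (id in c("1", "2", "8")) {
        tr <- simulateModel(assembleModel(id), shortProtocol(),
                            times = c(0, 15, 30, 60, 240))
        ps <- observe(tr, "PSmad2_total")
        expect_lt(ps$value[ps$time_min == 240] / max(ps$value), 0.05,
                  label = paste("model", id, "washout"))
    }
})

test_that("observable extraction and normalization behave as labelled", {
    tr <- simulateModel(model1(), longProtocol(),
                        times = seq(0, 1440, by = 120))
    expect_error(observe(tr, "NotAThing"), "unknown observable")
    ts <- observe(tr, "Smad2_total")
    expect_equal(ts$value, rep(571.43, length(ts$value)), tolerance = 1e-6)
    psm <- observe(tr, "PSmad2_total", normalize = "max")
    expect_equal(max(psm$value), 1)
    t1r <- observe(simulateModel(model8(), longProtocol(),
                                 times = seq(0, 1440, by = 120)),
                   "T1R_total", normalize = "t0")
    expect_true(all(abs(t1r$value - 1) < 0.10))
})

test_that("trajectories stay non-negative within solver tolerance", {
    for (m in list(model1(), model8())) {
        tr <- simulateModel(m, longProtocol(), times = seq(0, 1440, by = 20))
        expect_gt(min(tr@state), -1e-7)
    }
    trw <- simulateModel(model8(), shortProtocol(),
                         times = seq(0, 1440, by = 20))
    expect_gt(min(trw@state), -1e-7)
})

test_that("protocol validation rejects inconsistent settings", {
    expect_error(StimulusProtocol(dose = -1), "dose")
    expect_error(StimulusProtocol(exposure = "short", tWash = 2000,
                                  horizon = 1440), "tWash")
    expect_error(simulateModel(model1(), longProtocol(),
                               times = c(0, 2000)), "horizon")
})
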