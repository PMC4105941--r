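test_that("proteasome-inhibition change is identically zero without the rate", {
    m8 <- setParameters(model8(), c(kdeg_pSmad2 = 0))
    ch <- suppressWarnings(mg132Change(m8, "long"))
    expect_true(all(abs(ch$change[!is.na(ch$change)]) < 1e-8))
    expect_error(mg132Change(model1(), "long"), "no proteasomal")
})

test_that("short-exposure proteasome inhibition is much weaker than long", {
    chS <- suppressWarnings(mg132Change(model8(), "short"))
    chL <- suppressWarnings(mg132Change(model8(), "long"))
    z <- function(x) { x[is.na(x)] <- 0; mean(abs(x)) }
    expect_gte(z(chL$change) / z(chS$change), 3)
    ## masked points exist in the short arm (signal below detection)
    expect_true(any(is.na(chS$change)))
})

test_that("sensitivity map is null at fold 1 and for unreachable species", {
    mat <- sensitivityHeatmap(model1(), "kdephos", foldGrid = c(0.1, 1, 10))
    expect_true(all(abs(mat[, "1"]) < 1e-6))
    ## the receptor module is upstream of dephosphorylation: unaffected
    for (sp in c("TGFb", "T1R", "T2R", "LRC_EE", "LRC_Cave"))
        expect_lt(max(abs(mat[sp, ])), 1e-6)
    ## downstream species do respond
    expect_gt(max(abs(mat["pSmad2n", ])), 0.01)
    expect_true(all(is.finite(mat)))
    expect_error(sensitivityHeatmap(model1(), "nothere"), "unknown rate")
})

test_that("adaptation index is 0 for flat, 1 for fully adapting series", {
    expect_equal(adaptationIndex(c(2, 2, 2)), 0)
    expect_equal(adaptationIndex(c(0, 5, 3, 0)), 1)
    expect_error(adaptationIndex(c(0, 0)), "undefined")
    ## the plateau model adapts less than the feedback model
    tt <- seq(0, 1440, by = 20)
    a1 <- adaptationIndex(observe(simulateModel(model1(), longProtocol(),
        times = tt), "PSmad2_total")$value)
    a8 <- adaptationIndex(observe(simulateModel(model8(), longProtocol(),
        times = tt), "PSmad2_total")$value)
    expect_lt(a1, a8)
})

test_that("removing all negative regulation unleashes phospho-Smad2", {
    ec <- fixture("contribution", function()
        effectContribution(model8(), times = seq(0, 1440, by = 10)))
    full <- ec$full; noreg <- ec$minus_Dephosphorylation
    ## removing nothing reproduces the baseline
    base <- observe(simulateModel(model8(), longProtocol(),
                                  times = full$time_min), "PSmad2_total")
    expect_equal(full$value, base$value, tolerance = 1e-8)
    ## monotone growth over the first hour, far beyond the full peak
    v1h <- noreg$value[noreg$time_min <= 60]
    expect_true(all(diff(v1h) > 0))
    expect_gte(max(noreg$value) / max(full$value), 10)
    ## each removal weakly increases the 24-hr exposure integral
    integral <- vapply(ec, function(d) sum(d$value), numeric(1))
    expect_true(all(diff(integral) > -1e-6))
    ## without stabilization the peak survives but the decline is lost
    nostab <- ec$minus_PPM1AStabilization
    declineFull <- 1 - full$value[length(full$value)] / max(full$value)
    declineNoStab <- 1 - nostab$value[length(nostab$value)] /
        max(nostab$value)
    expect_lt(declineNoStab, declineFull / 2)
})

test_that("dose response is monotone with low-dose ligand depletion", {
    dr <- fixture("doseresp", function() doseResponse(model8()))
    expect_true(all(diff(dr$pSmad2_45min) >= -1e-6))
    ## ligand is substantially depleted at the lowest dose only
    expect_lt(dr$ligand_fraction_remaining[1], 0.1)
    expect_gt(dr$ligand_fraction_remaining[nrow(dr)], 0.3)
    ## the standard dose reproduces the stock long-exposure protocol
    tr <- simulateModel(model8(), longProtocol(), times = c(0, 45, 1440))
    ps <- observe(tr, "PSmad2_total")
    expect_equal(dr$pSmad2_45min[nrow(dr)], ps$value[ps$time_min == 45],
                 tolerance = 1e-8)
})

test_that("receptor-degradation sweep reproduces the trade-off signs", {
    b <- defaultBundle()
    sw <- fixture("sweep", function()
        klidSweep(model5(), b@channels[c("pSmad2_short", "pSmad2_long")],
                  grid = 10^seq(-6, -2, by = 1), seed = 1, nStarts = 2))
    expect_true(all(sw$points$ok))
    expect_lt(sw$correlations[["T1R_vs_klid"]], 0)
    expect_gt(sw$correlations[["T1R_vs_kdeg"]], 0)
    expect_lt(sw$correlations[["klid_vs_kdeg"]], 0)
    ## smallest klid leaves the receptor pool essentially untouched
    expect_lt(sw$points$T1R_decrease_pct[1], 10)
})
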