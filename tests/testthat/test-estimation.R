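test_that("SSE objective is zero at the generating truth and additive", {
    b <- noiselessBundle("1")
    sse <- sseObjective(model1(), b@channels[c("pSmad2_short",
                                               "pSmad2_long")])
    expect_lt(as.numeric(sse), 1e-10)
    ## single record with residual 2 contributes 4
    tr <- simulateModel(model1(), longProtocol(), times = c(0, 60))
    v <- observe(tr, "PSmad2_total")$value[2]
    ch <- TimeSeriesDataset(
        data.frame(protocol_id = "long", time = 60,
                   observable = "PSmad2_total", replicate = 1,
                   value = v + 2, weight = 1),
        normalization = "absolute_nM")
    expect_equal(as.numeric(sseObjective(model1(), ch)), 4,
                 tolerance = 1e-6)
    ## record order does not matter
    b2 <- defaultBundle()
    ch1 <- b2@channels$pSmad2_long
    ch2 <- ch1
    ch2@data <- ch2@data[rev(seq_len(nrow(ch2@data))), ]
    expect_equal(as.numeric(sseObjective(model1(), ch1)),
                 as.numeric(sseObjective(model1(), ch2)))
})

test_that("multistart estimation is deterministic and finds the truth", {
    b <- noiselessBundle("1")
    fitCh <- b@channels[c("pSmad2_short", "pSmad2_long")]
    start <- setParameters(model1(), c(kdephos = 0.05))
    f1 <- fitMultistart(start, fitCh, nStarts = 2, seed = 3)
    f2 <- fitMultistart(start, fitCh, nStarts = 2, seed = 3)
    expect_identical(f1@estimates, f2@estimates)
    truth <- unname(networkParameters(model1())["kdephos"])
    expect_lt(abs(f1@estimates[["kdephos"]] / truth - 1), 0.01)
    expect_lte(f1@sse, min(vapply(f1@restarts, `[[`, 1, "sse")) + 1e-8)
    ## one start placed at the optimum stays there
    f3 <- fitMultistart(model1(), fitCh, nStarts = 1, seed = 1)
    expect_lt(f3@sse, 1e-8)
    expect_lt(abs(f3@estimates[["kdephos"]] / truth - 1), 1e-3)
})

test_that("richer nested variants fit at least as well", {
    b <- defaultBundle()
    fitCh <- b@channels[c("pSmad2_short", "pSmad2_long")]
    f2 <- fitMultistart(assembleModel(2), fitCh, nStarts = 3, seed = 1)
    f5 <- fitMultistart(assembleModel(5), fitCh, nStarts = 3, seed = 1)
    expect_lte(f5@sse, f2@sse * 1.05)
})

test_that("constrained Model 7 fit keeps total Smad2 flat", {
    b <- defaultBundle()
    fitCh <- b@channels[c("pSmad2_short", "pSmad2_long")]
    m7 <- assembleModel(7)
    fit <- constrainedFitModel7(m7, fitCh, nStarts = 2, seed = 1)
    est <- smadTurnoverTie(m7)(fit@estimates)
    ## flux balance at t = 0: synthesis equals degradation of the
    ## monomeric pool
    ss <- initialState(m7)
    expect_equal(unname(est["ksyn_S2"]),
                 unname(est["kdeg_S2"]) * sum(ss[c("Smad2c", "Smad2n")]))
    tr <- simulateModel(setParameters(m7, est), longProtocol(),
                        times = seq(0, 1440, by = 60))
    ts <- observe(tr, "Smad2_total")
    expect_lt(max(abs(ts$value / ts$value[1] - 1)), 0.05)
})

test_that("integration failure inside the objective returns a finite penalty", {
    ## an absurd parameter vector that blows the system up
    ch <- defaultBundle()@channels["pSmad2_long"]
    res <- channelResiduals(setParameters(model8(), c(kphos = 1e8)),
                            ch)
    expect_true(all(is.finite(res)))
})
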