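test_that("bundles are exactly regenerable and noise-free in the cv->0 limit", {
    b1 <- generateBundle("1", seed = 99)
    b2 <- generateBundle("1", seed = 99)
    for (nm in names(b1@channels))
        expect_identical(b1@channels[[nm]]@data, b2@channels[[nm]]@data)
    b3 <- generateBundle("1", seed = 100)
    expect_false(identical(b1@channels$pSmad2_long@data,
                           b3@channels$pSmad2_long@data))
    ## cv = 0: every replicate equals the noiseless simulation
    nf <- generateBundle("1", noise = NoiseModel(cv = 0, cvElisa = 0,
                                                 replicates = 3),
                         seed = 1)
    d <- nf@channels$pSmad2_long@data
    spread <- tapply(d$value, d$time, function(v) diff(range(v)))
    expect_true(all(spread == 0))
})

test_that("channel layout matches the experimental design it emulates", {
    b <- defaultBundle()
    expect_setequal(names(b@channels),
                    c("pSmad2_short", "pSmad2_long", "T1R", "Smad2_total",
                      "PPM1A"))
    expect_identical(unique(b@channels$pSmad2_short@data$protocol_id),
                     "short")
    expect_identical(b@channels$Smad2_total@normalization, "absolute_nM")
    expect_identical(b@channels$pSmad2_long@normalization,
                     "relative_to_max")
    ## three replicates per time point
    expect_identical(max(b@channels$PPM1A@data$replicate), 3L)
    ## ELISA channel lives on the nM scale of the HaCaT Smad2 pool
    expect_gt(mean(b@channels$Smad2_total@data$value), 400)
    ## a truth without explicit PPM1A has no PPM1A channel
    b1 <- generateBundle("1", seed = 5)
    expect_false("PPM1A" %in% names(b1@channels))
})

test_that("the Model-8 truth shows the PPM1A upregulation signature", {
    nf <- generateBundle("8", noise = NoiseModel(cv = 0, cvElisa = 0,
                                                 replicates = 1),
                         seed = 1)
    d <- nf@channels$PPM1A@data
    fold1h <- d$value[d$time == 60] / d$value[d$time == 0]
    expect_gte(fold1h, 2)
})

test_that("noise-free self-recovery is exact to within one percent", {
    rec <- recoveryExperiment("1", noise = NoiseModel(cv = 0, cvElisa = 0,
                                                      replicates = 1),
                              nTrials = 1, seed = 3, nStarts = 2)
    expect_lt(max(abs(rec$errors)), 0.01)
})

test_that("fitting the plateau model to feedback-truth data leaves a signed misfit", {
    b <- defaultBundle()
    fit <- fitMultistart(model1(), b@channels[c("pSmad2_short",
                                                "pSmad2_long")],
                         nStarts = 2, seed = 1)
    fitted <- setParameters(model1(), fit@estimates)
    res <- channelMeanResiduals(fitted, b@channels$pSmad2_long)
    ## systematic run of same-sign residuals: plateau cannot track the
    ## late decline
    expect_gte(longestSignRun(res), 4)
})
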