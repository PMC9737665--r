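test_that("buildLibrary returns the amino acids plus seeded background", {
    lib0 <- buildLibrary(0, seed = 3)
    expect_equal(nrow(lib0), 20L)
    expect_true("glutamate" %in% lib0$name)
    expect_equal(lib0$formula[lib0$name == "glutamate"], "C5H9NO4")

    lib <- buildLibrary(300, seed = 7)
    expect_equal(nrow(lib), 320L)
    lib2 <- buildLibrary(300, seed = 7)
    expect_identical(lib, lib2)
    expect_false(identical(lib, buildLibrary(300, seed = 8)))
})

test_that("background metabolites avoid known substrate/product ions", {
    lib <- buildLibrary(300, seed = 7)
    bg <- lib[grepl("^bg_", lib$name), ]
    pairs <- knownDecarboxylationPairs()
    guard <- formulaMass(unique(c(pairs$substrate_formula,
                                  pairs$product_formula)))
    for (adduct in c("[M+H]+", "[M-H]-")) {
        bg_mz <- ionMz(formulaMass(bg$formula), adduct)
        for (g in ionMz(guard, adduct))
            expect_true(all(abs(ppmError(bg_mz, g)) >= 25))
    }
    # in particular nothing shadows the GABA [M+H]+ ion near 104.0706
    expect_true(all(abs(ppmError(ionMz(formulaMass(bg$formula), "[M+H]+"),
                                 104.0706)) >= 20))
})

test_that("simulateRun reproduces analytic Gaussian areas when noiseless", {
    lib <- buildLibrary(0, seed = 1)[14, ]   # one metabolite
    spec <- noiselessRunSpec()
    run <- simulateRun(lib, 1, spec, seed = 5)
    pts <- do.call(rbind, lapply(scans(run), function(s)
        if (length(s)) data.frame(rt = rtime(s), intensity = intensity(s))))
    # trapezoidal sum over the emitted trace vs closed-form Gaussian area
    o <- order(pts$rt)
    area <- sum(diff(pts$rt[o]) *
                (head(pts$intensity[o], -1) + tail(pts$intensity[o], -1)) / 2)
    expect_equal(area, gaussian_area(lib$base_intensity, spec$peak_sigma),
                 tolerance = 0.01)
})

test_that("zero concentrations leave only baseline noise", {
    lib <- buildLibrary(0, seed = 1)
    run <- simulateRun(lib, 0, runSpec(), seed = 2)
    # baseline-only: nothing remotely approaching metabolite peak heights
    top <- max(vapply(scans(run), function(s)
        if (length(s)) max(intensity(s)) else 0, numeric(1)))
    expect_lt(top, 2000)
    # and a noiseless all-zero run is completely empty
    run0 <- simulateRun(lib, 0, noiselessRunSpec(), seed = 2)
    expect_equal(sum(vapply(scans(run0), length, integer(1))), 0L)
})

test_that("simulateRun is deterministic and seed-sensitive", {
    lib <- buildLibrary(5, seed = 1)
    a <- simulateRun(lib, 1, runSpec(), seed = 9)
    b <- simulateRun(lib, 1, runSpec(), seed = 9)
    expect_identical(a, b)
    c <- simulateRun(lib, 1, runSpec(), seed = 10)
    expect_false(identical(a, c))
    expect_error(simulateRun(lib[0, ], 1, runSpec()), "empty")
})

test_that("simulateExperiment encodes the constructed depletion exactly", {
    lib <- buildLibrary(0, seed = 4)
    eff <- gad65Effect(depletion_factor = 10)
    exp <- simulateExperiment(lib, eff, n_replicates = 1,
                              spec = noiselessRunSpec(), seed = 11)
    glu_mz <- ionMz(formulaMass("C5H9NO4"), "[M+H]+")
    raw_area <- function(run) {
        tot <- 0
        rts <- rtime(run)
        y <- vapply(scans(run), function(s) {
            i <- which(abs(ppmError(mz(s), glu_mz)) < 25)
            if (length(i)) sum(intensity(s)[i]) else 0
        }, numeric(1))
        sum(diff(rts) * (head(y, -1) + tail(y, -1)) / 2)
    }
    r <- raw_area(exp$runs$vector_1) / raw_area(exp$runs$enzyme_1)
    expect_equal(r, 10, tolerance = 0.01)
})

test_that("a unit effect leaves the two groups identical up to noise", {
    lib <- buildLibrary(0, seed = 4)
    eff <- enzymeEffect("glutamate", 1)
    exp <- simulateExperiment(lib, eff, n_replicates = 1,
                              spec = noiselessRunSpec(), seed = 3)
    # noiseless and depletion 1: scan content identical between groups
    expect_equal(lapply(scans(exp$runs$vector_1), mz),
                 lapply(scans(exp$runs$enzyme_1), mz))
})

test_that("the GAD65 preset emits the product at the GABA ion", {
    lib <- buildLibrary(0, seed = 4)
    exp <- simulateExperiment(lib, gad65Effect(), n_replicates = 1,
                              spec = runSpec(), seed = 6)
    gaba <- 104.0706
    hits <- unlist(lapply(scans(exp$runs$enzyme_1), function(s)
        mz(s)[abs(ppmError(mz(s), gaba)) < 25]))
    expect_gt(length(hits), 5)
    expect_lt(abs(ppmError(median(hits), gaba)), 25)
    # absent from the vector group (above the baseline-noise regime)
    v <- unlist(lapply(scans(exp$runs$vector_1), function(s) {
        i <- abs(ppmError(mz(s), gaba)) < 25 & intensity(s) > 1000
        mz(s)[i]
    }))
    expect_length(v, 0)
})

test_that("effect validation rejects bad substrate or non-CO2 products", {
    lib <- buildLibrary(0, seed = 4)
    expect_error(
        simulateExperiment(lib, enzymeEffect("nonexistent", 10),
                           spec = noiselessRunSpec()),
        "not in library")
    bad <- enzymeEffect("glutamate", 10, "oops", "C3H6O2")
    expect_error(simulateExperiment(lib, bad, spec = noiselessRunSpec()),
                 "not a decarboxylation")
})

test_that("experiment fixtures carry MS2 spectra and MRM traces", {
    lib <- buildLibrary(0, seed = 4)
    exp <- simulateExperiment(lib, gad65Effect(), n_replicates = 2,
                              spec = noiselessRunSpec(), seed = 6)
    expect_setequal(names(exp$ms2), c("glutamate", "GABA"))
    expect_equal(precursorMz(exp$ms2$GABA),
                 ionMz(formulaMass("C4H9NO2"), "[M+H]+"), tolerance = 1e-6)
    expect_true(all(c("analyte", "run_id", "group", "rt", "intensity")
                    %in% names(exp$mrm)))
    # every panel analyte present in the library gets a trace in all 4 runs
    # (cystine is on the panel but not in the amino-acid library)
    expect_setequal(unique(exp$mrm$analyte),
                    intersect(loadTransitions()$analyte,
                              exp$library$name))
    expect_equal(length(unique(exp$mrm$run_id)), 4L)
})
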