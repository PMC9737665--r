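test_that("the built-in transition panel matches the acquisition method", {
    tr <- loadTransitions()
    expect_equal(nrow(tr), 19L)
    expect_false("glycine" %in% tr$analyte)
    glu <- tr[tr$analyte == "glutamate", ]
    expect_equal(glu$q1, 148.1)
    expect_equal(glu$q3, 84.1)
    expect_equal(glu$ce, 17)
    expect_true(all(tr$q3 < tr$q1 + 0.1))
})

test_that("printed Q1 values agree with formula-derived nominal masses", {
    tr <- loadTransitions()
    for (nm in list(c("glutamate", "C5H9NO4"),
                    c("phenylalanine", "C9H11NO2"),
                    c("histidine", "C6H9N3O2"))) {
        theo <- round(formulaMass(nm[2]) + 1.00728, 1)
        expect_equal(tr$q1[tr$analyte == nm[1]], theo,
                     info = nm[1])
    }
})

test_that("transition files round-trip and validate", {
    tr <- loadTransitions()
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(tr, path, row.names = FALSE)
    expect_equal(loadTransitions(path), tr)
    bad <- tr
    bad$q1[bad$analyte == "glutamate"] <- 149.0   # 0.9 off nominal
    path2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(bad, path2, row.names = FALSE)
    expect_warning(loadTransitions(path2), "glutamate")
})

test_that("integrateTrace matches the analytic Gaussian area", {
    rt <- seq(3, 7, by = 1 / 60)
    y <- 5e4 * exp(-(rt - 5)^2 / (2 * 0.05^2))
    tr <- data.frame(rt = rt, intensity = y)
    res <- integrateTrace(tr, c(4.5, 5.5))
    expect_equal(res$area, gaussian_area(5e4, 0.05), tolerance = 0.02)
    expect_equal(res$rt_apex, 5, tolerance = 1 / 60)
    # flat trace integrates to zero after baseline subtraction
    flat <- data.frame(rt = rt, intensity = rep(777, length(rt)))
    expect_equal(integrateTrace(flat, c(4, 6))$area, 0)
    # window that excludes the peak: essentially nothing
    expect_lt(integrateTrace(tr, c(3.0, 4.0))$area,
              1e-4 * gaussian_area(5e4, 0.05))
})

test_that("integrateTrace is additive and baseline-offset invariant", {
    rt <- seq(0, 10, by = 1 / 60)
    y <- 1e4 * exp(-(rt - 3)^2 / (2 * 0.05^2)) +
         2e4 * exp(-(rt - 7)^2 / (2 * 0.05^2))
    tr <- data.frame(rt = rt, intensity = y)
    a1 <- integrateTrace(tr, c(2, 4))$area
    a2 <- integrateTrace(tr, c(6, 8))$area
    both <- integrateTrace(tr, c(2, 8))$area
    expect_equal(a1 + a2, both, tolerance = 0.001)
    off <- data.frame(rt = rt, intensity = y + 5000)
    expect_equal(integrateTrace(off, c(2, 4))$area, a1, tolerance = 1e-6)
})

test_that("panelCompare flags exactly the GAD65 substrate", {
    lib <- buildLibrary(0, seed = 4)
    exp <- simulateExperiment(lib, gad65Effect(), n_replicates = 3,
                              spec = noiselessRunSpec(), seed = 12)
    ref <- setNames(exp$library$rt, exp$library$name)
    panel <- panelCompare(exp$mrm, reference_rt = ref)
    expect_true(panel$depleted[panel$analyte == "glutamate"])
    expect_false(any(panel$depleted[panel$analyte != "glutamate"]))
    # without the pseudocount the constructed 10-fold depletion is exact
    raw <- panelCompare(exp$mrm, reference_rt = ref, pseudocount = 0)
    expect_equal(raw$ratio[raw$analyte == "glutamate"], 10,
                 tolerance = 0.02)
    # report ordered by ratio descending
    expect_equal(panel$analyte[1], "glutamate")
    expect_true(all(diff(panel$ratio) <= 0))
})

test_that("panelCompare reproduces the AADC substrate preference", {
    lib <- buildLibrary(0, seed = 4)
    exp <- simulateExperiment(lib, aadcEffect(), n_replicates = 3,
                              spec = noiselessRunSpec(), seed = 13)
    ref <- setNames(exp$library$rt, exp$library$name)
    panel <- panelCompare(exp$mrm, reference_rt = ref)
    flagged <- panel$analyte[panel$depleted]
    expect_setequal(flagged,
                    c("phenylalanine", "tryptophan", "tyrosine"))
    r <- setNames(panel$ratio, panel$analyte)
    expect_gt(r["phenylalanine"], r["tyrosine"])
    expect_gt(r["tryptophan"], r["tyrosine"])
})

test_that("identical groups produce no depletion flags", {
    lib <- buildLibrary(0, seed = 4)
    exp <- simulateExperiment(lib, enzymeEffect("glutamate", 1),
                              n_replicates = 2,
                              spec = noiselessRunSpec(), seed = 14)
    ref <- setNames(exp$library$rt, exp$library$name)
    panel <- panelCompare(exp$mrm, reference_rt = ref)
    expect_false(any(panel$depleted))
    expect_equal(panel$ratio, rep(1, nrow(panel)), tolerance = 1e-9)
})

test_that("panelCompare shares the differential module's ratio rule", {
    traces <- rbind(
        data.frame(analyte = "glutamate", run_id = "v1", group = "vector",
                   rt = seq(1, 3, by = 0.01),
                   intensity = 1e4 * exp(-(seq(1, 3, by = 0.01) - 2)^2 /
                                             (2 * 0.05^2))),
        data.frame(analyte = "glutamate", run_id = "e1", group = "enzyme",
                   rt = seq(1, 3, by = 0.01), intensity = 0))
    panel <- panelCompare(traces, pseudocount = 50)
    area <- gaussian_area(1e4, 0.05)
    expect_equal(panel$ratio, (area + 50) / 50, tolerance = 0.02)
    expect_error(panelCompare(traces[traces$group == "vector", ]),
                 "no trace in the enzyme")
})
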