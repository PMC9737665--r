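test_that("detectMasses drops centroids below the noise floor", {
    s <- CentroidSpectrum(1.0, c(100.0, 200.0), c(50, 150))
    out <- detectMasses(s, 100)
    expect_equal(mz(out), 200.0)
    expect_equal(intensity(out), 150)
    # floor 0 is the identity
    expect_identical(detectMasses(s, 0), s)
    # all peaks below the floor: empty spectrum, not an error
    empty <- detectMasses(s, 1e6)
    expect_length(mz(empty), 0)
    expect_s4_class(empty, "CentroidSpectrum")
})

test_that("buildEics recovers a single Gaussian trace as one EIC", {
    run <- gaussian_run(mz0 = 150.05, rt0 = 5, height = 1e5)
    eics <- buildEics(run)
    expect_length(eics, 1L)
    tol <- max(0.002, 20e-6 * 150.05)
    expect_lt(abs(mzCenter(eics[[1]]) - 150.05), tol)
    # the full emitted trace (about 29 scans) survives
    expect_gte(length(eics[[1]]), 25L)
})

test_that("buildEics enforces the minimum group size of 5 scans", {
    # 4-scan trace at high intensity: rejected
    scans <- lapply(1:10, function(i) {
        if (i %in% 3:6) CentroidSpectrum(i / 60, 200.0, 5000)
        else CentroidSpectrum(i / 60, numeric(), numeric())
    })
    run <- MsRun(scans)
    expect_length(buildEics(run), 0L)
    # 5-scan trace: accepted
    scans5 <- lapply(1:10, function(i) {
        if (i %in% 3:7) CentroidSpectrum(i / 60, 200.0, 5000)
        else CentroidSpectrum(i / 60, numeric(), numeric())
    })
    expect_length(buildEics(MsRun(scans5)), 1L)
})

test_that("buildEics enforces the group intensity threshold of 200", {
    scans <- lapply(1:20, function(i) CentroidSpectrum(i / 60, 150.0, 150))
    expect_length(buildEics(MsRun(scans)), 0L)
    scans2 <- lapply(1:20, function(i)
        CentroidSpectrum(i / 60, 150.0, if (i == 10) 250 else 150))
    expect_length(buildEics(MsRun(scans2)), 1L)
})

test_that("co-eluting analytes 0.05 Da apart give two disjoint EICs", {
    # 0.05 Da > max(0.002 Da, 20 ppm x 150 = 0.003 Da)
    rt <- seq(4.8, 5.2, by = 1 / 60)
    scans <- lapply(rt, function(t) {
        y <- 1e4 * exp(-(t - 5)^2 / (2 * 0.05^2))
        CentroidSpectrum(t, c(150.00, 150.05), c(y, 0.8 * y))
    })
    eics <- buildEics(MsRun(scans))
    expect_length(eics, 2L)
    centers <- sort(vapply(eics, mzCenter, numeric(1)))
    expect_equal(centers, c(150.00, 150.05), tolerance = 1e-6)
    # disjoint: every point in exactly one EIC
    n_pts <- sum(vapply(eics, length, integer(1)))
    expect_equal(n_pts, 2L * length(rt))
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
    mk <- function(y) new("Eic", mzCenter = 100, runId = "r",
                          polarity = "positive",
                          points = data.frame(scan = seq_along(y),
                                              rt = seq_along(y) / 60,
                                              mz = 100, intensity = y))
    const <- mk(rep(500, 21))
    expect_equal(chromPoints(smoothEic(const))$intensity, rep(500, 21))
    x <- seq(-1, 1, length.out = 21)
    quad <- mk(1000 + 200 * x + 300 * x^2)
    expect_equal(chromPoints(smoothEic(quad, 7, 2))$intensity,
                 1000 + 200 * x + 300 * x^2, tolerance = 1e-9)
    # shorter than the window: returned unchanged
    short <- mk(c(1, 5, 2))
    expect_identical(smoothEic(short), short)
    expect_error(smoothEic(const, window = 6), "odd")
    expect_error(smoothEic(const, window = 3, poly_order = 4), "odd|order")
})

test_that("smoothing strictly reduces the residual of a noisy Gaussian", {
    set.seed(42)
    rt <- seq(4.6, 5.4, by = 1 / 60)
    truth <- 1e4 * exp(-(rt - 5)^2 / (2 * 0.08^2))
    noisy <- truth * (1 + 0.08 * rnorm(length(rt)))
    eic <- new("Eic", mzCenter = 150, runId = "r", polarity = "positive",
               points = data.frame(scan = seq_along(rt), rt = rt,
                                   mz = 150, intensity = noisy))
    sm <- smoothEic(eic)
    rms <- function(y) sqrt(mean((y - truth)^2))
    expect_lt(rms(chromPoints(sm)$intensity), rms(noisy))
})

test_that("resolveFeatures integrates a clean Gaussian to 2%", {
    eic <- gaussian_eic(height = 1e5, sigma = 0.05)
    feats <- resolveFeatures(eic)
    expect_equal(nrow(feats), 1L)
    expect_equal(feats$area, gaussian_area(1e5, 0.05), tolerance = 0.02)
    expect_equal(feats$rt_apex, 5, tolerance = 1 / 60)
    expect_equal(feats$height, 1e5, tolerance = 0.01)
    # scan span lies within the parent EIC
    expect_gte(feats$scan_first, min(chromPoints(eic)$scan))
    expect_lte(feats$scan_last, max(chromPoints(eic)$scan))
})

test_that("resolveFeatures splits two Gaussians at the valley minimum", {
    rt <- seq(4.5, 6.0, by = 1 / 60)
    y <- 1e5 * exp(-(rt - 5)^2 / (2 * 0.05^2)) +
         8e4 * exp(-(rt - 5.5)^2 / (2 * 0.05^2))
    eic <- new("Eic", mzCenter = 150, runId = "r", polarity = "positive",
               points = data.frame(scan = seq_along(rt), rt = rt,
                                   mz = 150, intensity = y))
    feats <- resolveFeatures(eic)
    expect_equal(nrow(feats), 2L)
    expect_equal(sort(feats$rt_apex), c(5, 5.5), tolerance = 0.02)
    # non-overlapping scan spans
    feats <- feats[order(feats$scan_first), ]
    expect_lt(feats$scan_last[1], feats$scan_first[2])
})

test_that("a plateau with top/edge ratio 1.2 yields no feature", {
    # triangle rising 1000 -> 1200 -> 1000: apex/edge = 1.2 < 1.7
    y <- c(seq(1000, 1200, length.out = 11), seq(1180, 1000,
                                                 length.out = 10))
    eic <- new("Eic", mzCenter = 150, runId = "r", polarity = "positive",
               points = data.frame(scan = seq_along(y),
                                   rt = seq_along(y) / 60, mz = 150,
                                   intensity = y))
    expect_equal(nrow(resolveFeatures(eic)), 0L)
})

test_that("feature calling scales with intensity when thresholds scale", {
    eic <- gaussian_eic(height = 1e4)
    p1 <- featureParams()
    f1 <- resolveFeatures(eic, p1)
    sc <- chromPoints(eic)
    sc$intensity <- sc$intensity * 10
    eic10 <- new("Eic", mzCenter = mzCenter(eic), runId = "r",
                 polarity = "positive", points = sc)
    p10 <- featureParams(noise_level = 1000,
                         group_intensity_threshold = 2000)
    f10 <- resolveFeatures(eic10, p10)
    expect_equal(nrow(f1), nrow(f10))
    expect_equal(f10$area, 10 * f1$area, tolerance = 1e-9)
})

test_that("noiseless extraction recovers every library peak accurately", {
    lib <- buildLibrary(10, seed = 21)
    spec <- noiselessRunSpec()
    run <- simulateRun(lib, 1, spec, seed = 1)
    feats <- extractFeatures(run)
    ion <- ionMz(formulaMass(lib$formula), "[M+H]+")
    # leucine/isoleucine share a formula: count distinct (mz, rt) targets
    for (i in seq_len(nrow(lib))) {
        hit <- which(abs(ppmError(feats$mz, ion[i])) < 20 &
                         abs(feats$rt_apex - lib$rt[i]) < 0.1)
        expect_length(hit, 1L)
        expect_equal(feats$area[hit],
                     gaussian_area(lib$base_intensity[i], spec$peak_sigma),
                     tolerance = 0.01)
    }
})
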