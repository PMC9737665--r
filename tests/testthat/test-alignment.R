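toy_features <- function(mz, rt, area = NULL, run = "r1") {
    data.frame(run_id = run, mz = mz, rt_apex = rt,
               height = if (is.null(area)) rep(1e4, length(mz)) else area,
               area = if (is.null(area)) rep(1e3, length(mz)) else area,
               scan_first = 1L, scan_last = 10L,
               n_points = 10L, polarity = "positive",
               stringsAsFactors = FALSE)
}

two_groups <- function(runs) {
    setNames(rep(c("vector", "enzyme"), length.out = length(runs)), runs)
}

test_that("identical feature lists align into fully detected rows", {
    f <- toy_features(c(150.0, 200.0, 250.0), c(2, 4, 6),
                      area = c(10, 20, 30))
    tab <- joinAlign(list(r1 = f, r2 = f), two_groups(c("r1", "r2")))
    expect_equal(nrow(tab), 3L)
    expect_true(all(statusMatrix(tab) == "detected"))
    expect_equal(unname(intensityMatrix(tab)[, "r1"]),
                 unname(intensityMatrix(tab)[, "r2"]))
})

test_that("features beyond the RT tolerance go to separate rows", {
    a <- toy_features(150.0, 2.0)
    b <- toy_features(150.0, 2.5)   # 0.5 min > 0.2 min tolerance
    tab <- joinAlign(list(r1 = a, r2 = b), two_groups(c("r1", "r2")))
    expect_equal(nrow(tab), 2L)
    expect_equal(sum(statusMatrix(tab) == "detected"), 2L)
    # just inside the tolerance: one row
    b2 <- toy_features(150.0, 2.15)
    tab2 <- joinAlign(list(r1 = a, r2 = b2), two_groups(c("r1", "r2")))
    expect_equal(nrow(tab2), 1L)
    expect_equal(featureRt(tab2), mean(c(2.0, 2.15)))
})

test_that("alignment conserves every input feature exactly once", {
    set.seed(11)
    fl <- lapply(c("r1", "r2", "r3"), function(r)
        toy_features(runif(8, 100, 500), runif(8, 1, 9),
                     area = runif(8, 1e3, 1e5), run = r))
    names(fl) <- c("r1", "r2", "r3")
    tab <- joinAlign(fl, setNames(c("vector", "vector", "enzyme"),
                                  names(fl)))
    n_in <- sum(vapply(fl, nrow, integer(1)))
    expect_equal(sum(statusMatrix(tab) == "detected"), n_in)
    # every detected cell's area equals some input feature's area
    for (r in names(fl))
        expect_setequal(
            intensityMatrix(tab)[statusMatrix(tab)[, r] == "detected", r],
            fl[[r]]$area)
})

test_that("joinAlign matches the exhaustive assignment oracle on toys", {
    for (seed in 1:25) {
        set.seed(seed)
        n_runs <- sample(2:3, 1)
        n_true <- sample(3:5, 1)
        true_mz <- runif(n_true, 100, 500)
        true_rt <- runif(n_true, 1, 9)
        fl <- list()
        for (r in seq_len(n_runs)) {
            seen <- which(runif(n_true) < 0.8)
            if (!length(seen)) seen <- 1L
            fl[[paste0("r", r)]] <- toy_features(
                true_mz[seen] + runif(length(seen), -4e-4, 4e-4),
                true_rt[seen] + runif(length(seen), -0.04, 0.04),
                area = runif(length(seen), 1e3, 1e4),
                run = paste0("r", r))
        }
        got <- table_grouping(
            joinAlign(fl, two_groups(names(fl))), fl)
        expect_identical(got, oracle_align(fl),
                         info = paste("seed", seed))
    }
})

test_that("gapFill recovers a peak dropped in one run", {
    lib <- buildLibrary(0, seed = 4)[c(14, 17), ]   # glutamate + one more
    spec <- noiselessRunSpec()
    r1 <- simulateRun(lib, 1, spec, run_id = "r1", seed = 1)
    r2 <- simulateRun(lib, 1, spec, run_id = "r2", seed = 2)
    f1 <- extractFeatures(r1)
    f2 <- extractFeatures(r2)
    # drop glutamate from run 2's list as if the builder had lost it
    glu <- which.min(abs(f2$mz - ionMz(formulaMass("C5H9NO4"), "[M+H]+")))
    f2_dropped <- f2[-glu, , drop = FALSE]
    tab <- joinAlign(list(r1 = f1, r2 = f2_dropped),
                     two_groups(c("r1", "r2")))
    expect_equal(sum(statusMatrix(tab) == "missing"), 1L)
    filled <- gapFill(tab, list(r1 = r1, r2 = r2))
    st <- statusMatrix(filled)
    expect_equal(sum(st == "gap_filled"), 1L)
    i <- which(st[, "r2"] == "gap_filled")
    # within 20% of the sister run's detected area (noiseless fixture)
    expect_equal(intensityMatrix(filled)[i, "r2"],
                 intensityMatrix(filled)[i, "r1"], tolerance = 0.2)
    # detected cells untouched; no cell decreased
    det <- st == "detected"
    expect_identical(intensityMatrix(filled)[det],
                     intensityMatrix(tab)[det])
    expect_true(all(intensityMatrix(filled) >= intensityMatrix(tab)))
})

test_that("gapFill leaves signal-free cells at zero and is idempotent", {
    f1 <- toy_features(c(150.0, 300.0), c(2, 8), area = c(10, 20))
    f2 <- toy_features(150.0, 2.0, area = c(12))
    # empty raw runs: nothing to fill from
    mk_empty <- function(id) MsRun(lapply(seq(0, 10, by = 1 / 60),
        function(t) CentroidSpectrum(t, numeric(), numeric())), runId = id)
    runs <- list(r1 = mk_empty("r1"), r2 = mk_empty("r2"))
    tab <- joinAlign(list(r1 = f1, r2 = f2), two_groups(c("r1", "r2")))
    filled <- gapFill(tab, runs)
    st <- statusMatrix(filled)
    expect_equal(sum(st == "missing"), 1L)
    expect_equal(intensityMatrix(filled)[st == "missing"], 0)
    # an already-complete table passes through unchanged
    tab_full <- joinAlign(list(r1 = f1, r2 = f1),
                          two_groups(c("r1", "r2")))
    expect_identical(intensityMatrix(gapFill(tab_full, runs)),
                     intensityMatrix(tab_full))
})

test_that("filterDuplicates collapses twin rows and is idempotent", {
    f1 <- toy_features(c(150.0000, 150.0005, 200.0), c(2.00, 2.05, 5),
                       area = c(100, 40, 70))
    tab <- joinAlign(list(r1 = f1[1, ], r2 = f1[2, ], r3 = f1[3, ]),
                     setNames(c("vector", "enzyme", "vector"),
                              c("r1", "r2", "r3")))
    # rows 1 and 2 are within both tolerances -> collapse keeps higher total
    expect_equal(nrow(tab), 2L)   # aligned already merges these two
    # force duplicates by aligning runs whose features just straddle the
    # greedy merge but fall within tolerance as consensus rows
    fA <- toy_features(c(150.0000, 150.0004), c(2.00, 2.01),
                       area = c(100, 90), run = "rA")
    tabA <- joinAlign(list(rA = fA), setNames("vector", "rA"))
    # one run cannot merge its own two features -> two rows within tol
    expect_equal(nrow(tabA), 2L)
    expect_error(filterDuplicates(tabA), NA)
    dedup <- filterDuplicates(tabA)
    expect_equal(nrow(dedup), 1L)
    expect_equal(sum(intensityMatrix(dedup)), 100)
    expect_identical(intensityMatrix(filterDuplicates(dedup)),
                     intensityMatrix(dedup))
})

test_that("rows separated by more than the m/z tolerance both survive", {
    # 0.01 Da apart at m/z 150 > max(0.002, 0.003)
    fA <- toy_features(c(150.00, 150.01), c(2.0, 2.0), area = c(50, 60),
                       run = "rA")
    tabA <- joinAlign(list(rA = fA), setNames("vector", "rA"))
    expect_equal(nrow(filterDuplicates(tabA)), 2L)
})
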