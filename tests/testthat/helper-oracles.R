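# Independent brute-force oracles and tiny fixture builders shared across
# test files. Oracles are deliberately naive and share no code with the
# implementation paths they check.

# Gaussian ion trace as an Eic object on a uniform scan grid.
gaussian_eic <- function(mz0 = 150, rt0 = 5, height = 1e5, sigma = 0.05,
                         dt = 1 / 60, span = 4, run = "r1",
                         polarity = "positive") {
    rt <- seq(rt0 - span * sigma, rt0 + span * sigma, by = dt)
    y <- height * exp(-(rt - rt0)^2 / (2 * sigma^2))
    new("Eic", mzCenter = mz0, runId = run, polarity = polarity,
        points = data.frame(scan = seq_along(rt), rt = rt,
                            mz = rep(mz0, length(rt)), intensity = y))
}

gaussian_area <- function(height, sigma) height * sigma * sqrt(2 * pi)

# One-metabolite run: a Gaussian trace embedded in otherwise empty scans.
gaussian_run <- function(mz0 = 150, rt0 = 5, height = 1e5, sigma = 0.05,
                         dt = 1 / 60, duration = 10, floor = 1,
                         polarity = "positive", run = "r1") {
    rt <- seq(0, duration, by = dt)
    scans <- lapply(rt, function(t) {
        y <- height * exp(-(t - rt0)^2 / (2 * sigma^2))
        if (y >= floor)
            CentroidSpectrum(t, mz0, y, polarity)
        else
            CentroidSpectrum(t, numeric(), numeric(), polarity)
    })
    MsRun(scans, runId = run, polarity = polarity)
}

# Exhaustive per-run assignment oracle for join alignment: runs are merged
# sequentially (same master-list semantics as the implementation), but each
# run's feature-to-row assignment is found by exhaustive enumeration —
# maximum number of features assigned, then minimum total score. Consensus
# coordinates are means over members.
oracle_align <- function(per_run_features, mz_tol_da = 0.002,
                         mz_tol_ppm = 20, rt_tol = 0.2) {
    tol_of <- function(m) pmax(mz_tol_da, mz_tol_ppm * 1e-6 * m)
    rows <- list()   # each: list(mz_sum, rt_sum, n, members = list(run=idx))
    for (k in seq_along(per_run_features)) {
        f <- per_run_features[[k]]
        if (!nrow(f)) next
        cons_mz <- vapply(rows, function(r) r$mz_sum / r$n, numeric(1))
        cons_rt <- vapply(rows, function(r) r$rt_sum / r$n, numeric(1))
        cand <- lapply(seq_len(nrow(f)), function(i) {
            if (!length(rows)) return(integer(0))
            tol <- tol_of(cons_mz)
            which(abs(f$mz[i] - cons_mz) <= tol &
                      abs(f$rt_apex[i] - cons_rt) <= rt_tol)
        })
        score <- function(i, r)
            abs(f$mz[i] - cons_mz[r]) / tol_of(cons_mz[r]) +
            abs(f$rt_apex[i] - cons_rt[r]) / rt_tol
        best <- NULL
        recurse <- function(i, used, asg, n_asg, tot) {
            if (i > nrow(f)) {
                if (is.null(best) || n_asg > best$n ||
                    (n_asg == best$n && tot < best$tot))
                    best <<- list(asg = asg, n = n_asg, tot = tot)
                return(invisible())
            }
            recurse(i + 1L, used, c(asg, NA_integer_), n_asg, tot)
            for (r in setdiff(cand[[i]], used))
                recurse(i + 1L, c(used, r), c(asg, r), n_asg + 1L,
                        tot + score(i, r))
        }
        recurse(1L, integer(0), integer(0), 0L, 0)
        for (i in seq_len(nrow(f))) {
            r <- best$asg[i]
            if (is.na(r)) {
                rows[[length(rows) + 1L]] <- list(
                    mz_sum = f$mz[i], rt_sum = f$rt_apex[i], n = 1L,
                    members = setNames(list(i),
                                       names(per_run_features)[k]))
            } else {
                rows[[r]]$mz_sum <- rows[[r]]$mz_sum + f$mz[i]
                rows[[r]]$rt_sum <- rows[[r]]$rt_sum + f$rt_apex[i]
                rows[[r]]$n <- rows[[r]]$n + 1L
                rows[[r]]$members[[names(per_run_features)[k]]] <- i
            }
        }
    }
    # canonical form: per row, the set of (run, feature mz) members
    grouping <- lapply(rows, function(r)
        sort(paste(names(r$members), unlist(r$members), sep = ":")))
    sort(vapply(grouping, paste, character(1), collapse = "|"))
}

# Canonical grouping of a FeatureTable for comparison with oracle_align:
# which input features ended up in the same row.
table_grouping <- function(table, per_run_features) {
    st <- statusMatrix(table)
    ints <- intensityMatrix(table)
    out <- character(0)
    for (i in seq_len(nrow(table))) {
        members <- character(0)
        for (r in colnames(table)) {
            if (st[i, r] != "detected") next
            f <- per_run_features[[r]]
            j <- which(abs(f$area - ints[i, r]) < 1e-9)
            members <- c(members, paste(r, j[1], sep = ":"))
        }
        out <- c(out, paste(sort(members), collapse = "|"))
    }
    sort(out)
}

# Exhaustive cosine oracle: maximum normalized dot product over all valid
# one-to-one fragment matchings within the tolerance.
oracle_cosine <- function(a, b, frag_tol = 0.02) {
    ma <- mz(a); mb <- mz(b)
    ia <- intensity(a); ib <- intensity(b)
    na2 <- sum(ia^2); nb2 <- sum(ib^2)
    if (na2 == 0 || nb2 == 0) return(0)
    best <- 0
    recurse <- function(i, used_b, acc) {
        if (i > length(ma)) {
            best <<- max(best, acc)
            return(invisible())
        }
        recurse(i + 1L, used_b, acc)           # leave fragment i unmatched
        for (j in setdiff(which(abs(ma[i] - mb) <= frag_tol), used_b))
            recurse(i + 1L, c(used_b, j), acc + ia[i] * ib[j])
    }
    recurse(1L, integer(0), 0)
    min(1, best / sqrt(na2 * nb2))
}

# Random MS2 spectrum pair with a controlled number of shared fragments;
# distinct fragments are kept >= 0.2 apart so matchings are unambiguous.
random_ms2_pair <- function(n_a = 5, n_b = 5, n_shared = 3, seed = 1) {
    set.seed(seed)
    base <- 60 + 0.2 * seq_len(n_a + n_b) + runif(n_a + n_b, 0, 0.05)
    shared <- base[seq_len(n_shared)]
    only_a <- base[n_shared + seq_len(n_a - n_shared)]
    only_b <- base[n_a + seq_len(n_b - n_shared)]
    mk <- function(mzv) Ms2Spectrum(500, mzv, runif(length(mzv), 10, 100))
    list(a = mk(c(shared, only_a)),
         b = mk(c(shared + runif(n_shared, -0.005, 0.005), only_b)))
}
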