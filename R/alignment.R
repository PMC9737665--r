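.make_feature_table <- function(mz, rt, intensity, status, runs, groups,
                                polarity, params) {
    o <- order(mz)
    intensity <- intensity[o, , drop = FALSE]
    status <- status[o, , drop = FALSE]
    rn <- sprintf("FT%04d", seq_along(mz))
    dimnames(intensity) <- list(rn, runs)
    dimnames(status) <- list(rn, runs)
    se <- SummarizedExperiment(
        assays = list(intensity = intensity, status = status),
        rowData = S4Vectors::DataFrame(mz = mz[o], rt = rt[o],
                                       row.names = rn),
        colData = S4Vectors::DataFrame(run = runs,
                                       group = unname(groups[runs]),
                                       row.names = runs),
        metadata = list(polarity = polarity, params = params))
    new("FeatureTable", se)
}

#' Join-align per-run feature lists into a feature table
#'
#' Sequential master-list alignment: runs are merged in input order into a
#' growing set of consensus rows. A feature joins the candidate row (within
#' both the m/z tolerance and the RT tolerance) with the best combined
#' score `w_mz * (dmz / mz_tol) + w_rt * (drt / rt_tol)` — scores are
#' normalized by their tolerances so the two unit weights are comparable —
#' and starts a new row when no candidate exists. Within one run,
#' feature-row assignments are made in ascending score order and each row
#' accepts at most one feature per run. Consensus m/z and RT are the means
#' over member features.
#'
#' @param per_run_features named list (by run id) of feature data.frames as
#'   returned by [extractFeatures()].
#' @param groups named character vector mapping run ids to `"vector"` /
#'   `"enzyme"`.
#' @param params a [featureParams()].
#' @return a [FeatureTable-class]; cells without a member feature have
#'   intensity 0 and status `"missing"`.
#' @export
joinAlign <- function(per_run_features, groups, params = featureParams()) {
    stopifnot(length(per_run_features) >= 1, !is.null(names(per_run_features)))
    runs <- names(per_run_features)
    polarity <- "positive"
    for (f in per_run_features)
        if (nrow(f)) { polarity <- f$polarity[1]; break }
    cons_mz_sum <- numeric(0); cons_rt_sum <- numeric(0)
    cons_n <- integer(0)
    area <- matrix(numeric(0), 0, length(runs))
    n_rows <- 0L
    for (k in seq_along(runs)) {
        f <- per_run_features[[k]]
        if (!nrow(f)) next
        cons_mz <- if (n_rows) cons_mz_sum / cons_n else numeric(0)
        cons_rt <- if (n_rows) cons_rt_sum / cons_n else numeric(0)
        cand <- list()
        if (n_rows) {
            for (i in seq_len(nrow(f))) {
                dmz <- abs(f$mz[i] - cons_mz)
                drt <- abs(f$rt_apex[i] - cons_rt)
                tol <- .mz_tol(cons_mz, params)
                ok <- which(dmz <= tol & drt <= params$rt_tol)
                if (length(ok))
                    cand[[length(cand) + 1L]] <- data.frame(
                        feat = i, row = ok,
                        score = params$w_mz * dmz[ok] / tol[ok] +
                                params$w_rt * drt[ok] / params$rt_tol)
            }
        }
        assigned_f <- logical(nrow(f))
        assigned_r <- logical(n_rows)
        if (length(cand)) {
            cand <- do.call(rbind, cand)
            cand <- cand[order(cand$score), , drop = FALSE]
            for (j in seq_len(nrow(cand))) {
                fi <- cand$feat[j]; ri <- cand$row[j]
                if (assigned_f[fi] || assigned_r[ri]) next
                assigned_f[fi] <- TRUE; assigned_r[ri] <- TRUE
                area[ri, k] <- f$area[fi]
                cons_mz_sum[ri] <- cons_mz_sum[ri] + f$mz[fi]
                cons_rt_sum[ri] <- cons_rt_sum[ri] + f$rt_apex[fi]
                cons_n[ri] <- cons_n[ri] + 1L
            }
        }
        new_i <- which(!assigned_f)
        if (length(new_i)) {
            add <- matrix(NA_real_, length(new_i), length(runs))
            add[, k] <- f$area[new_i]
            area <- rbind(area, add)
            cons_mz_sum <- c(cons_mz_sum, f$mz[new_i])
            cons_rt_sum <- c(cons_rt_sum, f$rt_apex[new_i])
            cons_n <- c(cons_n, rep(1L, length(new_i)))
            n_rows <- n_rows + length(new_i)
        }
    }
    status <- matrix(ifelse(is.na(area), "missing", "detected"),
                     nrow(area), ncol(area))
    area[is.na(area)] <- 0
    .make_feature_table(cons_mz_sum / cons_n, cons_rt_sum / cons_n,
                        area, status, runs, groups, polarity, params)
}

## Flatten a run to mz-sorted point vectors once, for fast window queries.
.flatten_run <- function(run) {
    rts <- rtime(run)
    n_per <- vapply(run@scans, function(s) length(s@mz), integer(1))
    mzv <- unlist(lapply(run@scans, function(s) s@mz), use.names = FALSE)
    iv <- unlist(lapply(run@scans, function(s) s@intensity),
                 use.names = FALSE)
    rtv <- rep.int(rts, n_per)
    scv <- rep.int(seq_along(rts), n_per)
    o <- order(mzv)
    list(mz = mzv[o], intensity = iv[o], rt = rtv[o], scan = scv[o],
         dt = if (length(rts) > 1) median(diff(rts)) else 0)
}

#' Fill missing feature-table cells from the raw runs
#'
#' For every `"missing"` cell, raw data points within the row's m/z
#' tolerance and RT window (`rt +/- rt_tol`) are collected (nearest point
#' per scan), a peak is grown outward from the most intense point, and the
#' cell is filled with its trapezoidal area. Growing to either side stops
#' once a point's intensity rises more than `(1 + gap_intensity_tol)`-fold
#' above the running minimum on that side, so a neighbouring peak is not
#' swallowed. A fill needs at least `gap_min_points` points (a one-point
#' fill is valued as intensity times the scan interval); cells with no
#' signal in the window stay 0 with status `"missing"`. Detected cells are
#' never modified.
#'
#' @param table a [FeatureTable-class] from [joinAlign()].
#' @param runs named list of the raw [MsRun-class] objects that produced
#'   the table.
#' @param params a [featureParams()].
#' @return the gap-filled [FeatureTable-class].
#' @export
gapFill <- function(table, runs, params = featureParams()) {
    stopifnot(is(table, "FeatureTable"))
    if (!all(colnames(table) %in% names(runs)))
        stop("runs must cover every table column")
    ints <- intensityMatrix(table)
    st <- statusMatrix(table)
    mzv <- featureMz(table)
    rtv <- featureRt(table)
    for (cn in colnames(table)) {
        miss <- which(st[, cn] == "missing")
        if (!length(miss)) next
        fl <- .flatten_run(runs[[cn]])
        for (i in miss) {
            tol <- .mz_tol(mzv[i], params)
            lo <- findInterval(mzv[i] - tol, fl$mz) + 1L
            hi <- findInterval(mzv[i] + tol, fl$mz)
            if (hi < lo) next
            sel <- lo:hi
            sel <- sel[abs(fl$rt[sel] - rtv[i]) <= params$rt_tol]
            if (!length(sel)) next
            ## nearest-in-m/z point per scan, RT-ordered
            d <- abs(fl$mz[sel] - mzv[i])
            sel <- sel[order(fl$scan[sel], d)]
            sel <- sel[!duplicated(fl$scan[sel])]
            sel <- sel[order(fl$rt[sel])]
            y <- fl$intensity[sel]
            x <- fl$rt[sel]
            apex <- which.max(y)
            keep_l <- apex; runmin <- y[apex]
            j <- apex - 1L
            while (j >= 1L) {
                if (y[j] > (1 + params$gap_intensity_tol) * runmin) break
                runmin <- min(runmin, y[j]); keep_l <- j; j <- j - 1L
            }
            keep_r <- apex; runmin <- y[apex]
            j <- apex + 1L
            while (j <= length(y)) {
                if (y[j] > (1 + params$gap_intensity_tol) * runmin) break
                runmin <- min(runmin, y[j]); keep_r <- j; j <- j + 1L
            }
            seg <- keep_l:keep_r
            if (length(seg) < params$gap_min_points) next
            val <- if (length(seg) == 1L) y[seg] * fl$dt
                   else .trapz(x[seg], y[seg])
            if (val > 0) {
                ints[i, cn] <- val
                st[i, cn] <- "gap_filled"
            }
        }
    }
    assay(table, "intensity") <- ints
    assay(table, "status") <- st
    table
}

#' Collapse duplicate feature-table rows
#'
#' Rows lying within both the m/z tolerance and the RT tolerance of each
#' other are duplicates of one feature; only the row with the greater total
#' intensity is kept (ties broken by lower m/z). The operation is
#' deterministic and idempotent.
#'
#' @param table a [FeatureTable-class].
#' @param params a [featureParams()].
#' @return the filtered [FeatureTable-class].
#' @export
filterDuplicates <- function(table, params = featureParams()) {
    stopifnot(is(table, "FeatureTable"))
    if (!nrow(table)) return(table)
    mzv <- featureMz(table)
    rtv <- featureRt(table)
    tot <- rowSums(intensityMatrix(table))
    pref <- order(-tot, mzv)
    keep <- logical(nrow(table))
    kept <- integer(0)
    for (i in pref) {
        if (length(kept)) {
            dmz <- abs(mzv[i] - mzv[kept])
            drt <- abs(rtv[i] - rtv[kept])
            tol <- .mz_tol(pmax(mzv[i], mzv[kept]), params)
            if (any(dmz <= tol & drt <= params$rt_tol)) next
        }
        keep[i] <- TRUE
        kept <- c(kept, i)
    }
    table[keep, ]
}
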