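#' Untargeted processing parameters
#'
#' All numeric parameters of the untargeted stack in one place. Defaults
#' are the processing values used throughout this workflow: detection noise
#' level 100 counts; m/z tolerance "0.002 m/z or 20 ppm" (read as the larger
#' of the two at a given mass); chromatogram-building group intensity
#' threshold 200 with a minimum group size of 5 scans; Savitzky-Golay
#' smoothing (window 7, order 2); local-minimum resolver with
#' chromatographic threshold 0.85 (an intensity quantile, see
#' [resolveFeatures()]), minimum top/edge ratio 1.7 and minimum 5 data
#' points; join-aligner RT tolerance 0.2 min with unit m/z and RT weights;
#' gap-filling intensity tolerance 1.0 with minimum 1 data point.
#'
#' @param noise_level mass-detection intensity floor, counts.
#' @param mz_tol_da,mz_tol_ppm combined m/z tolerance: at mass m the
#'   tolerance is `max(mz_tol_da, mz_tol_ppm * 1e-6 * m)`.
#' @param min_group_size minimum EIC length, scans.
#' @param group_intensity_threshold an EIC is kept only if at least one
#'   point reaches this intensity.
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   order.
#' @param chrom_threshold resolver intensity quantile below which candidate
#'   apexes are rejected, in `[0, 1)`.
#' @param min_top_edge_ratio minimum apex/edge intensity ratio.
#' @param min_points minimum data points per resolved feature.
#' @param rt_tol join-aligner (and gap-filling) RT tolerance, minutes.
#' @param w_mz,w_rt join-aligner score weights.
#' @param gap_intensity_tol gap-filling edge-extension tolerance: extension
#'   outward stops once intensity rises more than `(1 + tol)`-fold above the
#'   running minimum on that side.
#' @param gap_min_points minimum raw points for a filled value.
#' @return a list of class `"FeatureParams"`.
#' @export
featureParams <- function(noise_level = 100, mz_tol_da = 0.002,
                          mz_tol_ppm = 20, min_group_size = 5,
                          group_intensity_threshold = 200,
                          sg_window = 7, sg_order = 2,
                          chrom_threshold = 0.85,
                          min_top_edge_ratio = 1.7, min_points = 5,
                          rt_tol = 0.2, w_mz = 1, w_rt = 1,
                          gap_intensity_tol = 1.0, gap_min_points = 1) {
    structure(as.list(environment()), class = "FeatureParams")
}

.mz_tol <- function(mz, params)
    pmax(params$mz_tol_da, params$mz_tol_ppm * 1e-6 * mz)

.trapz <- function(x, y) {
    n <- length(x)
    if (n < 2L) return(0)
    sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Centroid mass detection
#'
#' Removes all centroids below the intensity noise level, the first step of
#' the untargeted stack.
#'
#' @param spectrum a [CentroidSpectrum-class].
#' @param noise_level intensity floor (counts, >= 0); peaks strictly below
#'   it are dropped.
#' @return the filtered [CentroidSpectrum-class] (possibly empty).
#' @export
detectMasses <- function(spectrum, noise_level = 100) {
    stopifnot(is(spectrum, "CentroidSpectrum"), noise_level >= 0)
    keep <- spectrum@intensity >= noise_level
    if (all(keep)) return(spectrum)
    new("CentroidSpectrum", rtime = spectrum@rtime,
        polarity = spectrum@polarity, mz = spectrum@mz[keep],
        intensity = spectrum@intensity[keep])
}

#' Build extracted ion chromatograms by intensity-seeded grouping
#'
#' ADAP-style construction: all data points of a run are pooled and visited
#' in order of decreasing intensity; each still-unassigned point seeds a new
#' trace, and for every scan the nearest unassigned point within the m/z
#' tolerance of the running intensity-weighted center is appended. A trace
#' is kept only if it has at least `min_group_size` points and at least one
#' point at or above `group_intensity_threshold` (the "group intensity
#' threshold" is applied to the trace's maximum point). Each data point
#' belongs to at most one trace.
#'
#' @param run an [MsRun-class] (typically after [detectMasses()]).
#' @param params a [featureParams()].
#' @return list of [Eic-class], ordered by decreasing maximum intensity.
#' @export
buildEics <- function(run, params = featureParams()) {
    stopifnot(is(run, "MsRun"))
    if (!length(run@scans)) stop("run has no scans")
    rts <- rtime(run)
    n_per <- vapply(run@scans, function(s) length(s@mz), integer(1))
    mz <- unlist(lapply(run@scans, function(s) s@mz), use.names = FALSE)
    ity <- unlist(lapply(run@scans, function(s) s@intensity),
                  use.names = FALSE)
    scan <- rep.int(seq_along(run@scans), n_per)
    if (!length(mz)) return(list())
    o <- order(mz)
    mz <- mz[o]; ity <- ity[o]; scan <- scan[o]
    assigned <- logical(length(mz))
    seeds <- order(ity, decreasing = TRUE)
    out <- list()
    for (sd in seeds) {
        if (assigned[sd]) next
        tol0 <- .mz_tol(mz[sd], params)
        lo <- findInterval(mz[sd] - 1.5 * tol0, mz) + 1L
        hi <- findInterval(mz[sd] + 1.5 * tol0, mz)
        cand <- lo:hi
        cand <- cand[!assigned[cand]]
        center <- mz[sd]
        wsum <- ity[sd]
        picked <- integer(0)
        for (s in sort(unique(scan[cand]))) {
            in_scan <- cand[scan[cand] == s]
            d <- abs(mz[in_scan] - center)
            j <- in_scan[which.min(d)]
            if (abs(mz[j] - center) > .mz_tol(center, params)) next
            picked <- c(picked, j)
            center <- (center * wsum + mz[j] * ity[j]) / (wsum + ity[j])
            wsum <- wsum + ity[j]
        }
        assigned[picked] <- TRUE
        if (length(picked) < params$min_group_size) next
        if (max(ity[picked]) < params$group_intensity_threshold) next
        ord <- picked[order(scan[picked])]
        pts <- data.frame(scan = scan[ord], rt = rts[scan[ord]],
                          mz = mz[ord], intensity = ity[ord])
        out[[length(out) + 1L]] <- new("Eic",
            mzCenter = sum(pts$mz * pts$intensity) / sum(pts$intensity),
            runId = run@runId, polarity = run@polarity, points = pts)
    }
    out
}

#' Savitzky-Golay smoothing of an ion trace
#'
#' Replaces the trace intensities by a least-squares polynomial convolution
#' (via [signal::sgolayfilt()]); negative smoothed values are clamped to
#' zero and m/z values are untouched. Traces shorter than the window are
#' returned unchanged.
#'
#' @param eic an [Eic-class].
#' @param window filter window length (odd, > `poly_order`).
#' @param poly_order polynomial order.
#' @return the smoothed [Eic-class].
#' @export
smoothEic <- function(eic, window = 7, poly_order = 2) {
    stopifnot(is(eic, "Eic"))
    if (window %% 2 != 1 || window <= poly_order)
        stop("window must be odd and greater than poly_order")
    pts <- eic@points
    if (nrow(pts) < window) return(eic)
    sm <- signal::sgolayfilt(pts$intensity, p = poly_order, n = window)
    ## keep the half-window edge points unsmoothed: the least-squares
    ## endpoint filters overshoot on steeply truncated traces and would
    ## seed spurious local minima at the peak borders
    k <- (window - 1) %/% 2
    edge <- c(seq_len(k), nrow(pts) - seq_len(k) + 1L)
    sm[edge] <- pts$intensity[edge]
    pts$intensity <- pmax(sm, 0)
    initialize(eic, points = pts)
}

#' Resolve chromatographic features at local intensity minima
#'
#' Splits a trace at its local intensity minima (a plateau minimum splits at
#' its first index) and emits each candidate segment as a feature iff (a)
#' its apex intensity exceeds the `chrom_threshold` intensity quantile of
#' the whole trace, (b) the apex is at least `min_top_edge_ratio` times the
#' larger of the two edge intensities (the minimum intensity on each side of
#' the apex within the segment), and (c) the segment spans at least
#' `min_points` points. Area is trapezoidal over RT; the apex is the RT of
#' the maximum intensity.
#'
#' @param eic an [Eic-class] (typically after [smoothEic()]).
#' @param params a [featureParams()].
#' @return data.frame of features: `run_id`, `mz`, `rt_apex`, `height`,
#'   `area`, `scan_first`, `scan_last`, `n_points`, `polarity`.
#' @export
resolveFeatures <- function(eic, params = featureParams()) {
    stopifnot(is(eic, "Eic"))
    pts <- eic@points
    y <- pts$intensity
    n <- length(y)
    if (n < params$min_points) return(.empty_features())
    ## an EIC may hold several isomeric traces separated by long stretches
    ## with no signal (e.g. leucine/isoleucine at one exact mass): resolve
    ## each contiguous scan block on its own, never integrating across a
    ## gap of more than 3 missing scans
    block <- cumsum(c(1L, diff(pts$scan) > 4L))
    out <- list()
    for (bl in unique(block)) {
        sel <- which(block == bl)
        if (length(sel) < params$min_points) next
        yb <- y[sel]
        nb <- length(yb)
        ## local minima; ties split to the left (first index of a plateau)
        i <- seq_len(nb)
        is_min <- i > 1L & i < nb &
            yb < c(Inf, yb[-nb]) & yb <= c(yb[-1], Inf)
        bounds <- c(0L, which(is_min), nb)
        qthr <- as.numeric(quantile(yb, params$chrom_threshold))
        for (k in seq_len(length(bounds) - 1L)) {
            a <- sel[1] - 1L + bounds[k] + 1L
            b <- sel[1] - 1L + bounds[k + 1L]
            if (b - a + 1L < params$min_points) next
            seg <- a:b
            apex <- seg[which.max(y[seg])]
            if (!(y[apex] > qthr)) next
            edge_l <- min(y[a:apex])
            edge_r <- min(y[apex:b])
            edge <- max(edge_l, edge_r)
            if (edge > 0 && y[apex] / edge < params$min_top_edge_ratio)
                next
            if (edge == 0 && y[apex] == 0) next
            area <- .trapz(pts$rt[seg], y[seg])
            if (area <= 0) next
            out[[length(out) + 1L]] <- data.frame(
                run_id = eic@runId,
                mz = sum(pts$mz[seg] * y[seg]) / sum(y[seg]),
                rt_apex = pts$rt[apex], height = y[apex], area = area,
                scan_first = pts$scan[a], scan_last = pts$scan[b],
                n_points = length(seg), polarity = eic@polarity,
                stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else .empty_features()
}

.empty_features <- function()
    data.frame(run_id = character(), mz = numeric(), rt_apex = numeric(),
               height = numeric(), area = numeric(),
               scan_first = integer(), scan_last = integer(),
               n_points = integer(), polarity = character(),
               stringsAsFactors = FALSE)

#' Run the full per-sample untargeted stack
#'
#' [detectMasses()] on every scan, [buildEics()], [smoothEic()] and
#' [resolveFeatures()] in sequence, i.e. one run in, one feature list out.
#'
#' @param run an [MsRun-class].
#' @param params a [featureParams()].
#' @return data.frame of features as from [resolveFeatures()].
#' @examples
#' lib <- buildLibrary(0, seed = 1)
#' run <- simulateRun(lib, spec = noiselessRunSpec(), seed = 1)
#' nrow(extractFeatures(run))
#' @export
extractFeatures <- function(run, params = featureParams()) {
    stopifnot(is(run, "MsRun"))
    scans <- lapply(run@scans, detectMasses,
                    noise_level = params$noise_level)
    clean <- initialize(run, scans = scans)
    eics <- buildEics(clean, params)
    eics <- lapply(eics, smoothEic, window = params$sg_window,
                   poly_order = params$sg_order)
    feats <- lapply(eics, resolveFeatures, params = params)
    feats <- feats[vapply(feats, nrow, integer(1)) > 0]
    if (!length(feats)) return(.empty_features())
    do.call(rbind, feats)
}
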