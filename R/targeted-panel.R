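#' Load the MRM transition panel
#'
#' With no argument, returns the built-in 19-analyte amino acid transition
#' panel (nominal Q1/Q3 in m/z, collision energy in V, positive mode; the
#' panel has no glycine entry and carries cystine rather than cysteine).
#' With a path, reads a CSV with columns `analyte`, `q1`, `q3`, `ce`,
#' `polarity`. Each analyte with a known formula is validated against its
#' formula-derived nominal Q1 (monoisotopic [M+H]+); a deviation above
#' 0.25 m/z raises a warning, not an error, because printed transition
#' tables mix rounding conventions.
#'
#' @param source path to a transition CSV, or `NULL` for the built-in
#'   panel.
#' @return data.frame with columns `analyte`, `q1`, `q3`, `ce`,
#'   `polarity`.
#' @examples
#' tr <- loadTransitions()
#' subset(tr, analyte == "glutamate")
#' @export
loadTransitions <- function(source = NULL) {
    tr <- if (is.null(source)) .TRANSITIONS
          else read.csv(source, stringsAsFactors = FALSE)
    need <- c("analyte", "q1", "q3", "ce", "polarity")
    if (!all(need %in% names(tr)))
        stop("transition table needs columns: ",
             paste(need, collapse = ", "))
    if (any(tr$q3 >= tr$q1 + 0.1))
        stop("Q3 must be below Q1 for a fragment transition")
    ## leucine/isoleucine legitimately share one (Q1, Q3): isobaric amino
    ## acids are separated by retention time, so uniqueness is enforced on
    ## the (analyte, Q1, Q3) triple
    if (anyDuplicated(tr[c("analyte", "q1", "q3")]))
        stop("duplicate transition rows")
    known <- intersect(tr$analyte, names(.TRANSITION_FORMULAS))
    if (length(known)) {
        theo <- ionMz(formulaMass(.TRANSITION_FORMULAS[known]), "[M+H]+")
        dev <- abs(tr$q1[match(known, tr$analyte)] - theo)
        if (any(dev > 0.25))
            warning("Q1 deviates > 0.25 from formula-derived nominal ",
                    "mass for: ",
                    paste(known[dev > 0.25], collapse = ", "))
    }
    tr
}

#' Integrate an MRM chromatogram window
#'
#' Trapezoidal area over an RT window after local baseline subtraction: a
#' straight line through the window's endpoint intensities is subtracted
#' and negative values clamped to zero, so the area is invariant under any
#' constant baseline offset.
#'
#' @param trace data.frame with columns `rt` (minutes, ordered) and
#'   `intensity`.
#' @param rt_window numeric length-2, `c(from, to)` in minutes.
#' @return list with `area` (counts x min), `height` and `rt_apex` (both
#'   after baseline subtraction; `NA` apex for an empty window).
#' @export
integrateTrace <- function(trace, rt_window) {
    stopifnot(length(rt_window) == 2, rt_window[1] <= rt_window[2])
    sel <- trace$rt >= rt_window[1] & trace$rt <= rt_window[2]
    x <- trace$rt[sel]; y <- trace$intensity[sel]
    if (length(x) < 2L)
        return(list(area = 0, height = if (length(y)) max(y, 0) else 0,
                    rt_apex = NA_real_))
    base <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
    yc <- pmax(y - base, 0)
    apex <- which.max(yc)
    list(area = .trapz(x, yc), height = yc[apex], rt_apex = x[apex])
}

#' Compare a targeted amino acid panel between groups
#'
#' Integrates every analyte's MRM trace per run (window: the analyte's
#' reference RT +/- `rt_halfwidth`, or the full trace when no reference is
#' given), averages areas per group, and computes the vector/enzyme ratio
#' with the same pseudocount rule as the untargeted ranking
#' ([defaultPseudocount()] over all integrated areas). Analytes with ratio
#' at or above `fold_threshold` are flagged as depleted. The report is
#' ordered by ratio descending.
#'
#' @param traces long data.frame of MRM points: `analyte`, `run_id`,
#'   `group` (`"vector"`/`"enzyme"`), `rt`, `intensity` (as produced by
#'   [simulateExperiment()]).
#' @param transitions transition table from [loadTransitions()]; only
#'   analytes present in it are reported.
#' @param reference_rt optional named vector of reference RTs (minutes) per
#'   analyte.
#' @param rt_halfwidth integration half-window, minutes.
#' @param fold_threshold depletion flag threshold (> 1), shared with
#'   [callCandidates()].
#' @param pseudocount override for the shared pseudocount rule.
#' @return data.frame with columns `analyte`, `mean_vector`,
#'   `mean_enzyme`, `ratio`, `depleted`, ordered by ratio descending.
#' @export
panelCompare <- function(traces, transitions = loadTransitions(),
                         reference_rt = NULL, rt_halfwidth = 0.5,
                         fold_threshold = 2, pseudocount = NULL) {
    need <- c("analyte", "run_id", "group", "rt", "intensity")
    stopifnot(all(need %in% names(traces)))
    analytes <- intersect(transitions$analyte, unique(traces$analyte))
    if (!length(analytes))
        stop("no panel transition has a trace; check analyte names")
    areas <- list()
    for (a in analytes) {
        ta <- traces[traces$analyte == a, , drop = FALSE]
        for (g in c("vector", "enzyme")) {
            tg <- ta[ta$group == g, , drop = FALSE]
            if (!nrow(tg))
                stop("analyte \"", a, "\" has no trace in the ", g,
                     " group")
            for (r in unique(tg$run_id)) {
                tr <- tg[tg$run_id == r, , drop = FALSE]
                tr <- tr[order(tr$rt), , drop = FALSE]
                win <- if (!is.null(reference_rt) && a %in%
                               names(reference_rt))
                    reference_rt[[a]] + c(-1, 1) * rt_halfwidth
                else range(tr$rt)
                areas[[length(areas) + 1L]] <- data.frame(
                    analyte = a, group = g, run_id = r,
                    area = integrateTrace(tr, win)$area,
                    stringsAsFactors = FALSE)
            }
        }
    }
    areas <- do.call(rbind, areas)
    if (is.null(pseudocount))
        pseudocount <- defaultPseudocount(areas$area)
    out <- do.call(rbind, lapply(analytes, function(a) {
        aa <- areas[areas$analyte == a, ]
        mv <- mean(aa$area[aa$group == "vector"])
        me <- mean(aa$area[aa$group == "enzyme"])
        data.frame(analyte = a, mean_vector = mv, mean_enzyme = me,
                   ratio = (mv + pseudocount) / (me + pseudocount),
                   stringsAsFactors = FALSE)
    }))
    out$depleted <- out$ratio >= fold_threshold
    out <- out[order(-out$ratio), , drop = FALSE]
    rownames(out) <- NULL
    out
}
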