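#' Default pseudocount for ratio computation
#'
#' Half the smallest nonzero intensity in the table. Products that are
#' absent from the vector-control group (a zero group mean) would otherwise
#' make the vector/enzyme ratio degenerate; the pseudocount keeps every
#' ratio finite and positive while leaving well-measured ratios essentially
#' untouched.
#'
#' @param intensity numeric intensity matrix (or vector).
#' @return a single pseudocount value (0 when there is no nonzero cell).
#' @export
defaultPseudocount <- function(intensity) {
    nz <- intensity[intensity > 0]
    if (!length(nz)) return(0)
    min(nz) / 2
}

#' Rank features by the vector/enzyme signal ratio
#'
#' Per aligned feature, the group means of the (gap-filled) intensities are
#' computed and the ratio `(mean_vector + pseudocount) /
#' (mean_enzyme + pseudocount)` is ranked from low to high: rank 1 is the
#' lowest ratio (strongest accumulation, candidate product) and rank n the
#' highest (strongest depletion, candidate substrate). Ties are broken by
#' ascending m/z.
#'
#' @param table a [FeatureTable-class] with both groups present.
#' @param pseudocount counts added to both group means; `NULL` uses
#'   [defaultPseudocount()].
#' @param summary `"mean"` (default) or `"median"` group summary.
#' @return data.frame sorted by ascending ratio with columns `row_id`,
#'   `mz`, `rt`, `mean_vector`, `mean_enzyme`, `ratio`, `rank`, `polarity`.
#' @export
rankRatios <- function(table, pseudocount = NULL, summary = c("mean",
                                                              "median")) {
    stopifnot(is(table, "FeatureTable"))
    summary <- match.arg(summary)
    g <- runGroups(table)
    if (!any(g == "vector") || !any(g == "enzyme"))
        stop("table needs at least one vector run and one enzyme run")
    ints <- intensityMatrix(table)
    fun <- if (summary == "mean") rowMeans else
        function(m) apply(m, 1, median)
    mv <- fun(ints[, g == "vector", drop = FALSE])
    me <- fun(ints[, g == "enzyme", drop = FALSE])
    if (is.null(pseudocount)) pseudocount <- defaultPseudocount(ints)
    ratio <- (mv + pseudocount) / (me + pseudocount)
    out <- data.frame(row_id = rownames(table), mz = featureMz(table),
                      rt = featureRt(table), mean_vector = mv,
                      mean_enzyme = me, ratio = ratio,
                      polarity = S4Vectors::metadata(table)$polarity,
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$ratio, out$mz), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Call depleted (substrate) and accumulated (product) candidates
#'
#' A feature is called `depleted` when its vector/enzyme ratio is at least
#' `fold_threshold` (the metabolite was consumed by the enzyme — a
#' candidate substrate) and `accumulated` when the ratio is at most
#' `1 / fold_threshold` (a candidate product); both boundaries are
#' inclusive. Output is ordered by effect size (fold) descending within
#' each direction, depleted first.
#'
#' @param ranked ratio records from [rankRatios()].
#' @param fold_threshold calling threshold (> 1).
#' @return data.frame with the ranked columns plus `direction` and `fold`
#'   (`ratio` for depleted rows, `1/ratio` for accumulated rows).
#' @export
callCandidates <- function(ranked, fold_threshold = 2) {
    if (!nrow(ranked)) stop("ranked list is empty")
    if (fold_threshold <= 1) stop("fold_threshold must be > 1")
    dep <- ranked[ranked$ratio >= fold_threshold, , drop = FALSE]
    acc <- ranked[ranked$ratio <= 1 / fold_threshold, , drop = FALSE]
    if (nrow(dep)) {
        dep$direction <- "depleted"
        dep$fold <- dep$ratio
        dep <- dep[order(-dep$fold), , drop = FALSE]
    }
    if (nrow(acc)) {
        acc$direction <- "accumulated"
        acc$fold <- 1 / acc$ratio
        acc <- acc[order(-acc$fold), , drop = FALSE]
    }
    out <- rbind(
        if (nrow(dep)) dep else cbind(ranked[0, ], direction = character(),
                                      fold = numeric()),
        if (nrow(acc)) acc else cbind(ranked[0, ], direction = character(),
                                      fold = numeric()))
    rownames(out) <- NULL
    out
}

#' Optional permutation p-value per ranked feature
#'
#' A descriptive add-on, not part of the core ranking procedure: for each
#' feature, group labels are permuted `n_perm` times and the p-value is the
#' fraction of permutations whose |log ratio| is at least the observed one
#' (with the +1 continuity correction). Useful as a sanity check at larger
#' replicate numbers; with 3-vs-3 designs its resolution is limited.
#'
#' @param table a [FeatureTable-class].
#' @param n_perm number of label permutations.
#' @param pseudocount as in [rankRatios()].
#' @param seed integer seed.
#' @return the [rankRatios()] data.frame with an extra `p_perm` column.
#' @export
permutationP <- function(table, n_perm = 200, pseudocount = NULL,
                         seed = 1L) {
    ranked <- rankRatios(table, pseudocount)
    ints <- intensityMatrix(table)
    g <- runGroups(table)
    if (is.null(pseudocount)) pseudocount <- defaultPseudocount(ints)
    idx <- match(ranked$row_id, rownames(table))
    obs <- abs(log(ranked$ratio))
    hits <- integer(nrow(ranked))
    .with_seed(seed, {
        for (b in seq_len(n_perm)) {
            gp <- sample(g)
            mv <- rowMeans(ints[idx, gp == "vector", drop = FALSE])
            me <- rowMeans(ints[idx, gp == "enzyme", drop = FALSE])
            r <- abs(log((mv + pseudocount) / (me + pseudocount)))
            hits <- hits + (r >= obs)
        }
    })
    ranked$p_perm <- (hits + 1) / (n_perm + 1)
    ranked
}
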