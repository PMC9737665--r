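#' Pair depleted substrates with accumulated products by the CO2 loss
#'
#' For every depleted/accumulated feature combination of equal polarity, a
#' pair is emitted when the accumulated m/z matches the depleted m/z minus
#' the CO2 mass (43.98983 Da) within `ppm_tol`. Because the adduct shift
#' cancels in the same-adduct difference, the test is polarity-safe. The
#' default tolerance (10 ppm) is looser than the annotation tolerance
#' because it compounds two measured m/z values.
#'
#' @param depleted,accumulated data.frames with at least columns `mz` and
#'   `polarity` (e.g. rows of [callCandidates()] output).
#' @param ppm_tol pairing tolerance, ppm.
#' @return data.frame sorted by |ppm error| with columns
#'   `substrate_mz`, `substrate_rt`, `product_mz`, `product_rt`,
#'   `delta_da`, `ppm_error`, `polarity` (RT columns are `NA` when the
#'   inputs carry no `rt`).
#' @examples
#' dep <- data.frame(mz = 148.0600, polarity = "positive")
#' acc <- data.frame(mz = 104.0703, polarity = "positive")
#' pairDecarboxylation(dep, acc)
#' @export
pairDecarboxylation <- function(depleted, accumulated, ppm_tol = 10) {
    empty <- data.frame(substrate_mz = numeric(), substrate_rt = numeric(),
                        product_mz = numeric(), product_rt = numeric(),
                        delta_da = numeric(), ppm_error = numeric(),
                        polarity = character(), stringsAsFactors = FALSE)
    if (!nrow(depleted) || !nrow(accumulated)) return(empty)
    rt_of <- function(df, i)
        if ("rt" %in% names(df)) df$rt[i] else NA_real_
    out <- list()
    for (i in seq_len(nrow(depleted))) {
        expect <- decarboxylationMz(depleted$mz[i])
        for (j in seq_len(nrow(accumulated))) {
            if (depleted$polarity[i] != accumulated$polarity[j]) next
            err <- ppmError(accumulated$mz[j], expect)
            if (abs(err) > ppm_tol) next
            out[[length(out) + 1L]] <- data.frame(
                substrate_mz = depleted$mz[i],
                substrate_rt = rt_of(depleted, i),
                product_mz = accumulated$mz[j],
                product_rt = rt_of(accumulated, j),
                delta_da = depleted$mz[i] - accumulated$mz[j],
                ppm_error = err,
                polarity = depleted$polarity[i],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) return(empty)
    out <- do.call(rbind, out)
    out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Annotate a feature against a metabolite library
#'
#' Returns every (library metabolite, adduct) combination whose theoretical
#' ion m/z matches the observed m/z within `ppm_tol` and, when both the
#' feature and the library carry retention times, whose RT matches within
#' `rt_tol`; results are sorted by |ppm error|.
#'
#' @param mz observed m/z.
#' @param polarity `"positive"` or `"negative"`; only adducts of that
#'   polarity are considered.
#' @param library data.frame with columns `name`, `formula` and optionally
#'   `rt` (minutes).
#' @param rt observed RT in minutes, or `NA` to skip the RT test.
#' @param adducts adducts to consider.
#' @param ppm_tol annotation mass tolerance, ppm.
#' @param rt_tol annotation RT tolerance, minutes.
#' @return data.frame with columns `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `rt_error`; zero rows when nothing
#'   matches.
#' @examples
#' annotateFeature(148.0600, "positive", aminoAcidTable())
#' @export
annotateFeature <- function(mz, polarity, library, rt = NA,
                            adducts = c("[M+H]+", "[M-H]-"), ppm_tol = 5,
                            rt_tol = 0.5) {
    adducts <- vapply(adducts, .norm_adduct, character(1))
    adducts <- adducts[.ADDUCTS$polarity[match(adducts,
                                               .ADDUCTS$adduct)] ==
                           polarity]
    out <- list()
    mass <- formulaMass(library$formula)
    for (a in adducts) {
        theo <- ionMz(mass, a)
        err <- ppmError(mz, theo)
        rt_err <- if (!is.na(rt) && "rt" %in% names(library))
            rt - library$rt else rep(NA_real_, nrow(library))
        ok <- abs(err) <= ppm_tol &
            (is.na(rt_err) | abs(rt_err) <= rt_tol)
        if (any(ok))
            out[[length(out) + 1L]] <- data.frame(
                name = library$name[ok], formula = library$formula[ok],
                adduct = a, theoretical_mz = theo[ok],
                ppm_error = err[ok], rt_error = rt_err[ok],
                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(name = character(), formula = character(),
                          adduct = character(), theoretical_mz = numeric(),
                          ppm_error = numeric(), rt_error = numeric(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, out)
    out[order(abs(out$ppm_error)), , drop = FALSE]
}

## Greedy fragment matching: candidate pairs within the tolerance, visited
## by descending intensity product (tie: smaller m/z difference), each
## fragment used at most once.
.match_fragments <- function(a, b, frag_tol) {
    na <- length(a@mz); nb <- length(b@mz)
    if (!na || !nb) return(cbind(i = integer(), j = integer()))
    d <- abs(outer(a@mz, b@mz, "-"))
    cand <- which(d <= frag_tol, arr.ind = TRUE)
    if (!nrow(cand)) return(cbind(i = integer(), j = integer()))
    prod <- a@intensity[cand[, 1]] * b@intensity[cand[, 2]]
    o <- order(-prod, d[cand])
    cand <- cand[o, , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        keep[k] <- TRUE
    }
    cbind(i = cand[keep, 1], j = cand[keep, 2])
}

#' Cosine similarity of two MS2 spectra
#'
#' Fragments are matched greedily within `frag_tol` (best available
#' partner first, each fragment used once); the score is the normalized
#' dot product of the matched intensities, 1 for identical spectra and 0
#' when no fragments match. Optionally intensities are square-root
#' transformed first.
#'
#' @param a,b [Ms2Spectrum-class] objects of the same polarity.
#' @param frag_tol fragment m/z matching tolerance, Da.
#' @param sqrt_transform apply `sqrt` to intensities before scoring.
#' @return similarity in `[0, 1]`.
#' @export
cosineScore <- function(a, b, frag_tol = 0.02, sqrt_transform = FALSE) {
    stopifnot(is(a, "Ms2Spectrum"), is(b, "Ms2Spectrum"))
    if (a@polarity != b@polarity)
        stop("spectra must share polarity")
    ia <- a@intensity; ib <- b@intensity
    if (sqrt_transform) { ia <- sqrt(ia); ib <- sqrt(ib) }
    m <- .match_fragments(a, b, frag_tol)
    if (!nrow(m)) return(0)
    na <- sqrt(sum(ia^2)); nb <- sqrt(sum(ib^2))
    if (na == 0 || nb == 0) return(0)
    min(1, sum(ia[m[, "i"]] * ib[m[, "j"]]) / (na * nb))
}

#' Identify an MS2 spectrum against a spectral library
#'
#' Library entries whose precursor ion (for the query polarity) matches the
#' query precursor within `ppm_tol` are scored with [cosineScore()]; the
#' best match with score at least `min_score` is returned, ties broken by
#' smaller precursor ppm error.
#'
#' @param query an [Ms2Spectrum-class].
#' @param library data.frame with columns `name`, `formula` and list-column
#'   `ms2` (fragment `mz`/`relint` matrices), as from [buildLibrary()].
#' @param min_score minimum acceptable cosine score.
#' @param ppm_tol precursor mass tolerance, ppm.
#' @param frag_tol fragment tolerance, Da.
#' @return one-row data.frame (`name`, `formula`, `score`,
#'   `precursor_ppm_error`) or a zero-row data.frame when nothing passes.
#' @export
identifyMs2 <- function(query, library, min_score = 0.7, ppm_tol = 5,
                        frag_tol = 0.02) {
    stopifnot(is(query, "Ms2Spectrum"))
    adduct <- adductForPolarity(query@polarity)
    theo <- ionMz(formulaMass(library$formula), adduct)
    err <- ppmError(query@precursorMz, theo)
    cand <- which(abs(err) <= ppm_tol)
    best <- data.frame(name = character(), formula = character(),
                       score = numeric(), precursor_ppm_error = numeric(),
                       stringsAsFactors = FALSE)
    for (i in cand) {
        frag <- library$ms2[[i]]
        if (is.null(frag) || !nrow(frag)) next
        ref <- Ms2Spectrum(theo[i], frag[, 1], frag[, 2], query@polarity)
        sc <- cosineScore(query, ref, frag_tol)
        if (sc < min_score) next
        better <- !nrow(best) || sc > best$score[1] ||
            (sc == best$score[1] && abs(err[i]) <
                 abs(best$precursor_ppm_error[1]))
        if (better)
            best <- data.frame(name = library$name[i],
                               formula = library$formula[i], score = sc,
                               precursor_ppm_error = err[i],
                               stringsAsFactors = FALSE)
    }
    best
}
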