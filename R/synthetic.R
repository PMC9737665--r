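## Seeded simulator for vector-control vs. enzyme LC-MS experiments. All
## randomness goes through .with_seed so identical inputs give bit-identical
## fixtures and the caller's RNG stream is left untouched.

.with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Simulation run specification
#'
#' Acquisition and noise parameters for simulated runs. Defaults describe a
#' short HILIC-style gradient sampled at 1 Hz with QTOF-like mass accuracy:
#' 10-minute runs, 0.05-min Gaussian peak sigma, 5 ppm per-point m/z jitter,
#' 15% lognormal replicate variation on peak heights, and sparse baseline
#' noise whose mean intensity (30 counts) sits below the 100-count detection
#' floor so noise rejection is exercised without swamping signal.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param duration run length, minutes.
#' @param scan_interval time between scans, seconds.
#' @param peak_sigma chromatographic peak sigma, minutes.
#' @param mz_jitter_ppm per-point Gaussian m/z jitter sigma, ppm (0 = exact).
#' @param replicate_sigma lognormal sigma applied to each metabolite's peak
#'   height once per run (0 = none).
#' @param baseline_peaks_per_scan expected number of baseline noise centroids
#'   per scan (Poisson; 0 = none).
#' @param baseline_intensity mean intensity of baseline noise centroids
#'   (exponential).
#' @param mz_range m/z range for baseline noise centroids.
#' @return a list of class `"RunSpec"`.
#' @export
runSpec <- function(polarity = "positive", duration = 10,
                    scan_interval = 1, peak_sigma = 0.05,
                    mz_jitter_ppm = 5, replicate_sigma = 0.15,
                    baseline_peaks_per_scan = 20, baseline_intensity = 30,
                    mz_range = c(60, 600)) {
    stopifnot(scan_interval > 0, duration > 0, peak_sigma > 0)
    structure(list(polarity = polarity, duration = duration,
                   scan_interval = scan_interval, peak_sigma = peak_sigma,
                   mz_jitter_ppm = mz_jitter_ppm,
                   replicate_sigma = replicate_sigma,
                   baseline_peaks_per_scan = baseline_peaks_per_scan,
                   baseline_intensity = baseline_intensity,
                   mz_range = mz_range),
              class = "RunSpec")
}

#' Noise-free run specification
#'
#' [runSpec()] with all noise terms (m/z jitter, replicate variation,
#' baseline centroids) switched off, used for calibration against analytic
#' peak areas.
#'
#' @param ... passed to [runSpec()].
#' @export
noiselessRunSpec <- function(...)
    runSpec(mz_jitter_ppm = 0, replicate_sigma = 0,
            baseline_peaks_per_scan = 0, ...)

.empty_ms2 <- function()
    matrix(numeric(), 0, 2, dimnames = list(NULL, c("mz", "relint")))

.random_ms2 <- function(neutral_mass, n = 6L) {
    precursor <- neutral_mass + .PROTON
    frag <- sort(runif(n, 50, max(51, precursor - 1)))
    relint <- runif(n)^2
    cbind(mz = frag, relint = relint / max(relint))
}

#' Build a seeded metabolite library
#'
#' Returns the 20 proteinogenic amino acids plus `n_background` synthetic
#' background metabolites with random (but chemically plausible CHNOS)
#' formulas, retention times, base intensities and MS2 fragment lists,
#' emulating a complex tissue-extract metabolite pool. Background ion m/z
#' values are kept at least `avoid_ppm` away (both adducts) from every known
#' decarboxylase substrate/product ion so that simulated enzyme effects are
#' never shadowed by construction.
#'
#' @param n_background number of background metabolites (>= 0).
#' @param seed integer seed; fixes the library exactly.
#' @param rt_range retention-time range (minutes) metabolites are placed in.
#' @param avoid_ppm exclusion window (ppm) around known substrate/product
#'   ions for background metabolites.
#' @return data.frame with columns `name`, `formula`, `rt`,
#'   `base_intensity` and list-column `ms2` (two-column `mz`/`relint`
#'   matrices).
#' @examples
#' lib <- buildLibrary(0, seed = 1)
#' nrow(lib)  # 20 amino acids
#' @export
buildLibrary <- function(n_background, seed = 1L,
                         rt_range = c(0.5, 9.5), avoid_ppm = 25) {
    stopifnot(n_background >= 0)
    aa <- aminoAcidTable()
    pairs <- knownDecarboxylationPairs()
    guard <- unique(c(pairs$substrate_formula, pairs$product_formula))
    guard_mz <- c(ionMz(formulaMass(guard), "[M+H]+"),
                  ionMz(formulaMass(guard), "[M-H]-"))
    .with_seed(seed, {
        lib <- data.frame(name = aa$name, formula = aa$formula,
                          rt = runif(nrow(aa), rt_range[1], rt_range[2]),
                          base_intensity = rlnorm(nrow(aa), log(2e5), 0.7),
                          stringsAsFactors = FALSE)
        if (n_background > 0) {
            bg <- vector("list", n_background)
            i <- 0L
            while (i < n_background) {
                nC <- sample(3:14, 1)
                nH <- sample(seq(nC, 2 * nC + 2), 1)
                nN <- sample(0:3, 1)
                nO <- sample(0:6, 1)
                nS <- sample(0:1, 1, prob = c(0.9, 0.1))
                f <- paste0("C", nC, "H", nH,
                            if (nN) paste0("N", if (nN > 1) nN else "")
                            else "",
                            if (nO) paste0("O", if (nO > 1) nO else "")
                            else "",
                            if (nS) "S" else "")
                m <- formulaMass(f)
                mzs <- c(m + .PROTON, m - .PROTON)
                if (any(vapply(mzs, function(x)
                        any(abs(ppmError(x, guard_mz)) < avoid_ppm),
                        logical(1))))
                    next
                i <- i + 1L
                bg[[i]] <- data.frame(
                    name = sprintf("bg_%03d", i), formula = f,
                    rt = runif(1, rt_range[1], rt_range[2]),
                    base_intensity = rlnorm(1, log(2e5), 0.7),
                    stringsAsFactors = FALSE)
            }
            lib <- rbind(lib, do.call(rbind, bg))
        }
        lib$ms2 <- lapply(formulaMass(lib$formula), .random_ms2)
        lib
    })
}

#' Simulate one centroided LC-MS run
#'
#' Each metabolite with a positive concentration contributes a Gaussian
#' elution profile (apex at its library RT, height = concentration x
#' base_intensity x a per-run lognormal replicate factor) sampled on the
#' scan grid, with per-point m/z jitter; Poisson-count baseline noise
#' centroids are added per scan. Analytic peak area is
#' `height * peak_sigma * sqrt(2*pi)` (counts x min).
#'
#' @param library metabolite library from [buildLibrary()].
#' @param concentrations named (by metabolite) or unnamed scale-factor
#'   vector, recycled; 0 removes a metabolite from the run.
#' @param spec a [runSpec()].
#' @param run_id run identifier.
#' @param seed integer seed.
#' @return an [MsRun-class].
#' @export
simulateRun <- function(library, concentrations = 1, spec = runSpec(),
                        run_id = "run", seed = 1L) {
    if (!nrow(library)) stop("library is empty")
    conc <- rep_len(concentrations, nrow(library))
    if (!is.null(names(concentrations))) {
        conc <- rep_len(1, nrow(library))
        idx <- match(names(concentrations), library$name)
        if (anyNA(idx))
            stop("unknown metabolite: ",
                 names(concentrations)[is.na(idx)][1])
        conc[idx] <- concentrations
    }
    adduct <- adductForPolarity(spec$polarity)
    ion <- ionMz(formulaMass(library$formula), adduct)
    rt_grid <- seq(0, spec$duration, by = spec$scan_interval / 60)
    n_scan <- length(rt_grid)
    .with_seed(seed, {
        repfac <- if (spec$replicate_sigma > 0)
            rlnorm(nrow(library), 0, spec$replicate_sigma)
        else rep(1, nrow(library))
        pts <- vector("list", nrow(library))
        for (i in seq_len(nrow(library))) {
            if (conc[i] <= 0) next
            h <- conc[i] * library$base_intensity[i] * repfac[i]
            span <- which(abs(rt_grid - library$rt[i]) <=
                              4 * spec$peak_sigma)
            if (!length(span)) next
            y <- h * exp(-(rt_grid[span] - library$rt[i])^2 /
                             (2 * spec$peak_sigma^2))
            keep <- y >= 1          # emission floor, well below detection
            if (!any(keep)) next
            span <- span[keep]; y <- y[keep]
            m <- rep(ion[i], length(span))
            if (spec$mz_jitter_ppm > 0)
                m <- m * (1 + rnorm(length(span)) *
                              spec$mz_jitter_ppm * 1e-6)
            pts[[i]] <- data.frame(scan = span, mz = m, intensity = y)
        }
        if (spec$baseline_peaks_per_scan > 0) {
            n_noise <- stats::rpois(n_scan, spec$baseline_peaks_per_scan)
            tot <- sum(n_noise)
            pts[[length(pts) + 1L]] <- data.frame(
                scan = rep(seq_len(n_scan), n_noise),
                mz = runif(tot, spec$mz_range[1], spec$mz_range[2]),
                intensity = rexp(tot, 1 / spec$baseline_intensity))
        }
        all_pts <- do.call(rbind, pts)
        scans <- vector("list", n_scan)
        if (!is.null(all_pts)) {
            by_scan <- split(all_pts[c("mz", "intensity")],
                             factor(all_pts$scan, levels = seq_len(n_scan)))
        } else by_scan <- rep(list(NULL), n_scan)
        for (s in seq_len(n_scan)) {
            b <- by_scan[[s]]
            if (is.null(b) || !nrow(b))
                scans[[s]] <- CentroidSpectrum(rt_grid[s], numeric(),
                                               numeric(), spec$polarity)
            else
                scans[[s]] <- CentroidSpectrum(rt_grid[s], b$mz,
                                               b$intensity, spec$polarity)
        }
        MsRun(scans, runId = run_id, polarity = spec$polarity,
              metadata = list(seed = seed))
    })
}

#' Enzyme effect description
#'
#' One decarboxylation effect: in the enzyme group the substrate is reduced
#' `depletion_factor`-fold and the product appears (it is absent from the
#' vector group) with peak height `accumulation_intensity`.
#'
#' @param substrate library name of the depleted metabolite.
#' @param depletion_factor fold reduction in the enzyme group (> 1, or
#'   exactly 1 for a no-effect control).
#' @param product,product_formula name and neutral formula of the product;
#'   `NA` for a depletion-only effect.
#' @param accumulation_intensity product peak height in the enzyme group.
#' @param product_rt product retention time (minutes); `NA` places it 1 min
#'   before the substrate (floored at 0.5 min).
#' @return data.frame with one row per effect.
#' @export
enzymeEffect <- function(substrate, depletion_factor, product = NA,
                         product_formula = NA,
                         accumulation_intensity = 1e5, product_rt = NA) {
    stopifnot(depletion_factor >= 1)
    data.frame(substrate = substrate,
               depletion_factor = depletion_factor,
               product = product, product_formula = product_formula,
               accumulation_intensity = accumulation_intensity,
               product_rt = product_rt, stringsAsFactors = FALSE)
}

#' Preset enzyme effects
#'
#' `gad65Effect()`: glutamate decarboxylase — 10-fold glutamate depletion
#' with GABA accumulation. `aadcEffect()`: aromatic amino acid decarboxylase
#' — phenylalanine and tryptophan depleted more strongly (8-fold) than
#' tyrosine (3-fold), each with its amine product accumulating.
#'
#' @param depletion_factor substrate fold-depletion for GAD65.
#' @param accumulation_intensity product peak height.
#' @return an effect data.frame as from [enzymeEffect()].
#' @export
gad65Effect <- function(depletion_factor = 10,
                        accumulation_intensity = 1e5)
    enzymeEffect("glutamate", depletion_factor, "GABA", "C4H9NO2",
                 accumulation_intensity)

#' @rdname gad65Effect
#' @export
aadcEffect <- function(accumulation_intensity = 1e5)
    rbind(enzymeEffect("phenylalanine", 8, "phenethylamine", "C8H11N",
                       accumulation_intensity),
          enzymeEffect("tryptophan", 8, "tryptamine", "C10H12N2",
                       accumulation_intensity),
          enzymeEffect("tyrosine", 3, "tyramine", "C8H11NO",
                       accumulation_intensity))

.augment_library <- function(library, effect) {
    if (is.null(effect) || !nrow(effect)) return(library)
    miss <- setdiff(effect$substrate, library$name)
    if (length(miss))
        stop("effect substrate not in library: ", miss[1])
    dm <- formulaMass(library$formula[match(effect$substrate,
                                            library$name)])
    prod <- effect[!is.na(effect$product), , drop = FALSE]
    if (!nrow(prod)) return(library)
    pm <- formulaMass(prod$product_formula)
    sm <- formulaMass(library$formula[match(prod$substrate, library$name)])
    if (any(abs(sm - pm - co2Mass()) > 1e-3))
        stop("effect is not a decarboxylation: substrate/product mass ",
             "difference is not one CO2")
    sub_rt <- library$rt[match(prod$substrate, library$name)]
    prt <- ifelse(is.na(prod$product_rt), pmax(0.5, sub_rt - 1),
                  prod$product_rt)
    add <- data.frame(name = prod$product, formula = prod$product_formula,
                      rt = prt, base_intensity = prod$accumulation_intensity,
                      stringsAsFactors = FALSE)
    add$ms2 <- lapply(seq_len(nrow(add)), function(i)
        .with_seed(sum(utf8ToInt(add$name[i])), .random_ms2(pm[i])))
    rbind(library, add[!add$name %in% library$name, , drop = FALSE])
}

.group_concentrations <- function(library, effect, group) {
    conc <- setNames(rep(1, nrow(library)), library$name)
    prods <- effect$product[!is.na(effect$product)]
    if (group == "vector") {
        conc[prods] <- 0
    } else {
        conc[effect$substrate] <- 1 / effect$depletion_factor
        conc[prods] <- 1
    }
    conc
}

#' Simulate a two-arm vector vs. enzyme experiment
#'
#' Generates `n_replicates` vector-control and `n_replicates` enzyme-group
#' runs from one library and one enzyme effect, plus MS2 spectra for the
#' effect's substrates and products and MRM chromatograms for the built-in
#' amino acid transition panel. Vector runs use unit concentrations (and no
#' product); enzyme runs deplete each substrate by its fold factor and add
#' its product.
#'
#' @param library metabolite library from [buildLibrary()].
#' @param effect effect data.frame from [enzymeEffect()] or a preset;
#'   `NULL` for a null (vector-vs-vector-like) experiment.
#' @param n_replicates runs per group (>= 1).
#' @param spec a [runSpec()].
#' @param seed integer seed.
#' @return list of class `"DecarbExperiment"` with elements `runs` (named
#'   list of [MsRun-class]), `groups` (named `"vector"`/`"enzyme"` vector),
#'   `ms2` (named list of [Ms2Spectrum-class]), `mrm` (long data.frame of
#'   MRM trace points: `analyte`, `run_id`, `group`, `rt`, `intensity`),
#'   `library` (augmented with products), `effect`, `spec`, `seed`.
#' @export
simulateExperiment <- function(library, effect = gad65Effect(),
                               n_replicates = 3, spec = runSpec(),
                               seed = 1L) {
    stopifnot(n_replicates >= 1)
    if (is.null(effect))
        effect <- enzymeEffect(library$name[1], 1)   # no-op effect
    lib <- .augment_library(library, effect)
    ids <- c(sprintf("vector_%d", seq_len(n_replicates)),
             sprintf("enzyme_%d", seq_len(n_replicates)))
    groups <- setNames(rep(c("vector", "enzyme"), each = n_replicates), ids)
    runs <- vector("list", length(ids))
    names(runs) <- ids
    for (i in seq_along(ids)) {
        conc <- .group_concentrations(lib, effect, groups[[i]])
        runs[[i]] <- simulateRun(lib, conc, spec, run_id = ids[i],
                                 seed = seed * 1000L + i)
    }
    ## MS2 spectra for the effect's substrate(s) and product(s)
    targets <- unique(c(effect$substrate,
                        effect$product[!is.na(effect$product)]))
    adduct <- adductForPolarity(spec$polarity)
    ms2 <- lapply(targets, function(nm) {
        j <- match(nm, lib$name)
        frag <- lib$ms2[[j]]
        Ms2Spectrum(ionMz(formulaMass(lib$formula[j]), adduct),
                    frag[, "mz"], 1000 * frag[, "relint"], spec$polarity)
    })
    names(ms2) <- targets
    mrm <- .simulate_mrm(lib, effect, groups, spec, seed)
    structure(list(runs = runs, groups = groups, ms2 = ms2, mrm = mrm,
                   library = lib, effect = effect, spec = spec,
                   seed = seed),
              class = "DecarbExperiment")
}

## MRM traces for the built-in transition panel analytes present in the
## library: one Gaussian trace per analyte per run on a +/- 1 min window.
.simulate_mrm <- function(lib, effect, groups, spec, seed) {
    analytes <- intersect(.TRANSITIONS$analyte, lib$name)
    if (!length(analytes)) return(data.frame())
    out <- vector("list", length(groups) * length(analytes))
    k <- 0L
    for (i in seq_along(groups)) {
        conc <- .group_concentrations(lib, effect, groups[[i]])
        for (a in analytes) {
            j <- match(a, lib$name)
            lo <- max(0, min(lib$rt[j] - 1, spec$duration))
            hi <- min(spec$duration, max(lib$rt[j] + 1, 0))
            if (hi <= lo) next
            rt <- seq(lo, hi, by = spec$scan_interval / 60)
            h <- .with_seed(seed * 1000L + i + 7L * j,
                if (spec$replicate_sigma > 0)
                    rlnorm(1, 0, spec$replicate_sigma) else 1)
            y <- conc[[a]] * lib$base_intensity[j] * h *
                exp(-(rt - lib$rt[j])^2 / (2 * spec$peak_sigma^2))
            k <- k + 1L
            out[[k]] <- data.frame(analyte = a,
                                   run_id = names(groups)[i],
                                   group = groups[[i]], rt = rt,
                                   intensity = y,
                                   stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out[seq_len(k)])
}
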