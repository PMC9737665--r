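#' Assemble a pipeline configuration
#'
#' One fully-resolved, serializable configuration drives an end-to-end
#' analysis: either a simulation preset (`"gad65-liver"` — glutamate
#' decarboxylase acting on a complex tissue-extract-like background;
#' `"aadc"` — aromatic amino acid decarboxylase; `"null"` — vector vs.
#' vector, no enzyme effect) or user-supplied runs.
#'
#' @param preset `"gad65-liver"`, `"aadc"`, `"null"`, or `NULL` when
#'   `runs` are supplied.
#' @param runs named list (by polarity) of named lists of [MsRun-class]
#'   objects, used when `preset` is `NULL`.
#' @param groups named `"vector"`/`"enzyme"` vector for user-supplied runs.
#' @param library annotation library (data.frame with `name`, `formula`,
#'   optional `rt`, optional `ms2`); defaults to the simulation library in
#'   preset mode and to [aminoAcidTable()] otherwise.
#' @param polarities polarities to process, subset of
#'   `c("positive", "negative")`.
#' @param n_background background metabolites for simulation presets.
#' @param n_replicates runs per group for simulation presets.
#' @param params a [featureParams()].
#' @param spec a [runSpec()] used as template for simulation (its polarity
#'   is overridden per processed polarity).
#' @param fold_threshold candidate-calling threshold (> 1).
#' @param pseudocount ratio pseudocount (`NULL` = [defaultPseudocount()]).
#' @param pairing_ppm CO2-loss pairing tolerance, ppm.
#' @param annotation_ppm annotation mass tolerance, ppm.
#' @param annotation_rt_tol annotation RT tolerance, minutes.
#' @param min_ms2_score minimum MS2 cosine score for identification.
#' @param seed integer master seed; every stage derives from it.
#' @return a list of class `"DecarbConfig"`.
#' @export
decarbConfig <- function(preset = "gad65-liver", runs = NULL,
                         groups = NULL, library = NULL,
                         polarities = c("positive", "negative"),
                         n_background = 300, n_replicates = 3,
                         params = featureParams(), spec = runSpec(),
                         fold_threshold = 2, pseudocount = NULL,
                         pairing_ppm = 10, annotation_ppm = 5,
                         annotation_rt_tol = 0.5, min_ms2_score = 0.7,
                         seed = 1L) {
    stopifnot(all(polarities %in% c("positive", "negative")),
              fold_threshold > 1)
    if (is.null(preset) && (is.null(runs) || is.null(groups)))
        stop("either a preset or runs + groups must be given")
    if (!is.null(preset) &&
        !preset %in% c("gad65-liver", "aadc", "null"))
        stop("unknown preset \"", preset, "\"")
    structure(as.list(environment()), class = "DecarbConfig")
}

.preset_effect <- function(preset) {
    switch(preset,
           "gad65-liver" = gad65Effect(),
           "aadc" = aadcEffect(),
           "null" = NULL)
}

.sim_inputs <- function(config, pol, pol_idx) {
    lib <- buildLibrary(config$n_background, seed = config$seed,
                        rt_range = c(0.5, config$spec$duration - 0.5))
    spec <- config$spec
    spec$polarity <- pol
    simulateExperiment(lib, .preset_effect(config$preset),
                       n_replicates = config$n_replicates, spec = spec,
                       seed = config$seed * 10L + pol_idx)
}

.annotate_names <- function(mz, rt, pol, config, lib) {
    ann <- annotateFeature(mz, pol, lib, rt = rt,
                           ppm_tol = config$annotation_ppm,
                           rt_tol = config$annotation_rt_tol)
    if (nrow(ann)) ann$name[1] else NA_character_
}

#' Run the untargeted substrate-identification workflow
#'
#' Per polarity: per-run feature extraction, join alignment, gap filling,
#' duplicate filtering, vector/enzyme ratio ranking, candidate calling,
#' CO2-loss substrate/product pairing, library annotation of the paired
#' ions and (when MS2 spectra are available) cosine identification of the
#' product. Deterministic given the configuration and its seed.
#'
#' @param config a [decarbConfig()].
#' @return a [DecarbReport-class].
#' @seealso [writeReport()]
#' @export
runUntargeted <- function(config) {
    stopifnot(inherits(config, "DecarbConfig"))
    tables <- list(); ranked <- list(); calls <- list()
    pairs_all <- list(); log <- list()
    for (pi in seq_along(config$polarities)) {
        pol <- config$polarities[pi]
        if (!is.null(config$preset)) {
            exp <- .sim_inputs(config, pol, pi)
            runs <- exp$runs; groups <- exp$groups
            lib <- if (is.null(config$library)) exp$library
                   else config$library
            ms2 <- exp$ms2
        } else {
            runs <- config$runs[[pol]]
            if (is.null(runs))
                stop("no runs supplied for ", pol, " mode")
            groups <- config$groups
            lib <- if (is.null(config$library)) aminoAcidTable()
                   else config$library
            ms2 <- list()
        }
        feats <- lapply(names(runs), function(id) {
            f <- tryCatch(extractFeatures(runs[[id]], config$params),
                          error = function(e)
                              stop("feature extraction failed for run ",
                                   id, ": ", conditionMessage(e)))
            f
        })
        names(feats) <- names(runs)
        tab <- joinAlign(feats, groups, config$params)
        n_aligned <- nrow(tab)
        tab <- gapFill(tab, runs, config$params)
        n_filled <- sum(statusMatrix(tab) == "gap_filled")
        tab <- filterDuplicates(tab, config$params)
        rk <- rankRatios(tab, config$pseudocount)
        cl <- callCandidates(rk, config$fold_threshold)
        dep <- cl[cl$direction == "depleted", , drop = FALSE]
        acc <- cl[cl$direction == "accumulated", , drop = FALSE]
        pr <- pairDecarboxylation(dep, acc, config$pairing_ppm)
        if (nrow(pr)) {
            pr$substrate_name <- vapply(seq_len(nrow(pr)), function(i)
                .annotate_names(pr$substrate_mz[i], pr$substrate_rt[i],
                                pol, config, lib), character(1))
            pr$product_name <- vapply(seq_len(nrow(pr)), function(i)
                .annotate_names(pr$product_mz[i], pr$product_rt[i],
                                pol, config, lib), character(1))
            pr$ms2_name <- NA_character_
            pr$ms2_score <- NA_real_
            if (length(ms2) && "ms2" %in% names(lib)) {
                for (i in seq_len(nrow(pr))) {
                    hit <- NULL
                    for (q in ms2) {
                        if (abs(ppmError(q@precursorMz,
                                         pr$product_mz[i])) >
                                config$pairing_ppm) next
                        id <- identifyMs2(q, lib, config$min_ms2_score,
                                          config$annotation_ppm)
                        if (nrow(id)) { hit <- id; break }
                    }
                    if (!is.null(hit)) {
                        pr$ms2_name[i] <- hit$name[1]
                        pr$ms2_score[i] <- hit$score[1]
                    }
                }
            }
        }
        tables[[pol]] <- tab
        ranked[[pol]] <- rk
        calls[[pol]] <- cl
        pairs_all[[pol]] <- pr
        log[[length(log) + 1L]] <- data.frame(
            polarity = pol, runs = length(runs),
            features = sum(vapply(feats, nrow, integer(1))),
            rows_aligned = n_aligned, gaps_filled = n_filled,
            rows_final = nrow(tab), calls = nrow(cl), pairs = nrow(pr),
            stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pairs_all)
    rownames(pairs) <- NULL
    new("DecarbReport", tables = tables, ranked = ranked, calls = calls,
        pairs = pairs, panel = data.frame(),
        config = unclass(config), log = do.call(rbind, log))
}

#' Run the targeted amino acid panel workflow
#'
#' Quantifies the MRM transition panel in vector vs. enzyme samples and
#' reports per-analyte depletion. In preset mode the traces come from
#' [simulateExperiment()]; otherwise supply a long trace data.frame via
#' `traces`.
#'
#' @param config a [decarbConfig()].
#' @param traces optional MRM trace data.frame (columns `analyte`,
#'   `run_id`, `group`, `rt`, `intensity`) overriding simulation.
#' @return a [DecarbReport-class] whose `panel` slot holds the
#'   [panelCompare()] result.
#' @export
runTargeted <- function(config, traces = NULL) {
    stopifnot(inherits(config, "DecarbConfig"))
    if (is.null(traces)) {
        if (is.null(config$preset))
            stop("runTargeted needs either a preset or traces")
        spec <- config$spec
        spec$polarity <- "positive"
        lib <- buildLibrary(0, seed = config$seed,
                            rt_range = c(0.5, spec$duration - 0.5))
        exp <- simulateExperiment(lib, .preset_effect(config$preset),
                                  n_replicates = config$n_replicates,
                                  spec = spec, seed = config$seed * 10L + 1L)
        traces <- exp$mrm
        ref <- setNames(exp$library$rt, exp$library$name)
    } else ref <- NULL
    transitions <- loadTransitions()
    present <- intersect(transitions$analyte, unique(traces$analyte))
    if (!length(present))
        stop("no panel transition matches the traces; missing: ",
             paste(head(transitions$analyte, 5), collapse = ", "), ", ...")
    panel <- panelCompare(traces, transitions, reference_rt = ref,
                          fold_threshold = config$fold_threshold)
    new("DecarbReport", tables = list(), ranked = list(), calls = list(),
        pairs = data.frame(), panel = panel, config = unclass(config),
        log = data.frame(polarity = "positive",
                         runs = length(unique(traces$run_id)),
                         features = nrow(panel), rows_aligned = NA,
                         gaps_filled = NA, rows_final = NA,
                         calls = sum(panel$depleted), pairs = NA,
                         stringsAsFactors = FALSE))
}

#' Write a report to disk
#'
#' Writes the ranked table and candidate calls per polarity, the
#' substrate/product pair table, the targeted panel (when present), a
#' plain-text summary and the echoed configuration into a directory.
#'
#' @param report a [DecarbReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
    stopifnot(is(report, "DecarbReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (pol in names(report@ranked)) {
        write.csv(report@ranked[[pol]],
                  file.path(dir, paste0("ranked_", pol, ".csv")),
                  row.names = FALSE)
        write.csv(report@calls[[pol]],
                  file.path(dir, paste0("calls_", pol, ".csv")),
                  row.names = FALSE)
        writeFeatureTable(report@tables[[pol]],
                          file.path(dir, paste0("table_", pol, ".csv")))
    }
    write.csv(report@pairs, file.path(dir, "pairs.csv"),
              row.names = FALSE)
    if (nrow(report@panel))
        write.csv(report@panel, file.path(dir, "panel.csv"),
                  row.names = FALSE)
    txt <- c("decarbID report", "===============", "",
             utils::capture.output(show(report)), "",
             "Stage log", "---------",
             utils::capture.output(print(report@log)))
    if (nrow(report@pairs))
        txt <- c(txt, "", "Substrate/product pairs",
                 "-----------------------",
                 utils::capture.output(print(report@pairs)))
    writeLines(txt, file.path(dir, "summary.txt"))
    dput(report@config[setdiff(names(report@config),
                               c("runs", "library"))],
         file.path(dir, "config.R"))
    invisible(dir)
}
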