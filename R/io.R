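## Internal plain-text run format: line-oriented, one file per run.
##   #msrun <id> polarity=<positive|negative>
##   #scan rt=<minutes>
##   <mz>\t<intensity>
## Chosen so fixtures stay small, diffable and text-only.

#' Write an LC-MS run to the plain-text fixture format
#'
#' @param run an [MsRun-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readMsRun()]
#' @export
writeMsRun <- function(run, path) {
    stopifnot(is(run, "MsRun"))
    con <- file(path, "w")
    on.exit(close(con))
    cat(sprintf("#msrun %s polarity=%s\n", run@runId, run@polarity),
        file = con)
    for (s in run@scans) {
        cat(sprintf("#scan rt=%.6f\n", s@rtime), file = con)
        if (length(s@mz))
            writeLines(sprintf("%.6f\t%.4f", s@mz, s@intensity), con)
    }
    invisible(path)
}

.read_msrun_text <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#msrun ", lines, value = TRUE)
    if (!length(hdr)) stop("not a run fixture file: ", path)
    id <- sub("^#msrun +(\\S+).*$", "\\1", hdr[1])
    pol <- sub("^.*polarity=(\\S+).*$", "\\1", hdr[1])
    scan_at <- grep("^#scan ", lines)
    bounds <- c(scan_at, length(lines) + 1L)
    scans <- vector("list", length(scan_at))
    for (i in seq_along(scan_at)) {
        rt <- as.numeric(sub("^#scan rt=", "", lines[scan_at[i]]))
        body <- lines[seq(scan_at[i] + 1L, bounds[i + 1L] - 1L)]
        body <- body[nzchar(body) & !startsWith(body, "#")]
        if (length(body)) {
            m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
            scans[[i]] <- CentroidSpectrum(rt, as.numeric(m[, 1]),
                                           as.numeric(m[, 2]), pol)
        } else {
            scans[[i]] <- CentroidSpectrum(rt, numeric(), numeric(), pol)
        }
    }
    MsRun(scans, runId = id, polarity = pol)
}

.read_msrun_mzml <- function(path) {
    if (!requireNamespace("mzR", quietly = TRUE))
        stop("reading mzML requires the mzR package")
    h <- NULL
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    h <- mzR::header(fh)
    ms1 <- which(h$msLevel == 1L)
    pol <- if (all(h$polarity[ms1] == 0L)) "negative" else "positive"
    scans <- lapply(ms1, function(i) {
        p <- mzR::peaks(fh, i)
        CentroidSpectrum(h$retentionTime[i] / 60, p[, 1], p[, 2], pol)
    })
    o <- order(vapply(scans, rtime, numeric(1)))
    MsRun(scans[o], runId = sub("\\.mzML$", "", basename(path),
                                ignore.case = TRUE), polarity = pol)
}

#' Read an LC-MS run
#'
#' Reads either the package's plain-text fixture format or (when the file
#' ends in `.mzML` and \pkg{mzR} is installed) centroided mzML.
#'
#' @param path path to a run file.
#' @return an [MsRun-class].
#' @export
readMsRun <- function(path) {
    if (grepl("\\.mzml$", path, ignore.case = TRUE))
        .read_msrun_mzml(path)
    else
        .read_msrun_text(path)
}

#' Write / read MS2 spectra as MGF-style blocks
#'
#' Standard `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE` and
#' `TITLE` headers; one file may hold many spectra.
#'
#' @param spectra list of [Ms2Spectrum-class] (named: names become titles).
#' @param path file path.
#' @return `writeMs2Spectra`: `path` invisibly; `readMs2Spectra`: a named
#'   list of [Ms2Spectrum-class].
#' @export
writeMs2Spectra <- function(spectra, path) {
    con <- file(path, "w")
    on.exit(close(con))
    nm <- names(spectra)
    if (is.null(nm)) nm <- sprintf("spectrum_%d", seq_along(spectra))
    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        writeLines(c("BEGIN IONS",
                     sprintf("TITLE=%s", nm[i]),
                     sprintf("PEPMASS=%.6f", s@precursorMz),
                     sprintf("CHARGE=1%s",
                             if (s@polarity == "positive") "+" else "-"),
                     sprintf("%.6f %.4f", s@mz, s@intensity),
                     "END IONS"), con)
    }
    invisible(path)
}

#' @rdname writeMs2Spectra
#' @export
readMs2Spectra <- function(path) {
    lines <- readLines(path)
    begin <- grep("^BEGIN IONS", lines)
    end <- grep("^END IONS", lines)
    stopifnot(length(begin) == length(end))
    out <- vector("list", length(begin))
    titles <- character(length(begin))
    for (i in seq_along(begin)) {
        blk <- lines[seq(begin[i] + 1L, end[i] - 1L)]
        titles[i] <- sub("^TITLE=", "", grep("^TITLE=", blk, value = TRUE)[1])
        pm <- as.numeric(sub("^PEPMASS=", "",
                             grep("^PEPMASS=", blk, value = TRUE)[1]))
        ch <- grep("^CHARGE=", blk, value = TRUE)[1]
        pol <- if (grepl("-", ch, fixed = TRUE)) "negative" else "positive"
        frag <- blk[!grepl("=", blk, fixed = TRUE) & nzchar(blk)]
        m <- do.call(rbind, strsplit(frag, " ", fixed = TRUE))
        out[[i]] <- Ms2Spectrum(pm, as.numeric(m[, 1]), as.numeric(m[, 2]),
                                pol)
    }
    names(out) <- titles
    out
}

#' Write / read a metabolite library file
#'
#' CSV with columns `name`, `formula`, `rt_min`, `base_intensity` and an
#' optional `ms2` column holding the fragment list encoded as
#' `"mz:relint;mz:relint;..."`.
#'
#' @param library a metabolite library data.frame (see [buildLibrary()]).
#' @param path file path.
#' @return `writeLibrary`: `path` invisibly; `readLibrary`: the library
#'   data.frame with the `ms2` list-column decoded.
#' @export
writeLibrary <- function(library, path) {
    x <- library
    x$ms2 <- vapply(library$ms2, function(f) {
        if (is.null(f) || !nrow(f)) return("")
        paste(sprintf("%.6f:%.4f", f[, 1], f[, 2]), collapse = ";")
    }, character(1))
    write.csv(x, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLibrary
#' @export
readLibrary <- function(path) {
    x <- read.csv(path, stringsAsFactors = FALSE)
    ms2 <- lapply(x$ms2, function(s) {
        if (is.na(s) || !nzchar(s))
            return(matrix(numeric(), 0, 2,
                          dimnames = list(NULL, c("mz", "relint"))))
        p <- do.call(rbind, strsplit(strsplit(s, ";", fixed = TRUE)[[1]],
                                     ":", fixed = TRUE))
        matrix(as.numeric(p), ncol = 2,
               dimnames = list(NULL, c("mz", "relint")))
    })
    x$ms2 <- NULL
    x$ms2 <- ms2
    x
}

#' Serialize a feature table to CSV
#'
#' One row per aligned feature: `row_id`, `mz`, `rt`, then one intensity and
#' one status column per run.
#'
#' @param table a [FeatureTable-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
    ints <- intensityMatrix(table)
    st <- statusMatrix(table)
    colnames(ints) <- paste0("intensity_", colnames(ints))
    colnames(st) <- paste0("status_", colnames(st))
    df <- data.frame(row_id = rownames(table), mz = featureMz(table),
                     rt = featureRt(table), ints, st,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
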