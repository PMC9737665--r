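## Monoisotopic element masses (IUPAC, 5 decimals is ample for small
## metabolites at the ppm tolerances used here).
.ELEMENT_MASS <- c(C = 12.000000, H = 1.007825, N = 14.003074,
                   O = 15.994915, S = 31.972071, P = 30.973762)

## Proton mass shift for singly charged adducts; the electron mass
## (~0.5 mDa) is ignored, well below every tolerance in the workflow.
.PROTON <- 1.007276

#' Mass of the CO2 neutral loss
#'
#' Monoisotopic mass of one carbon plus two oxygens, the mass a metabolite
#' loses on enzymatic decarboxylation.
#'
#' @return 43.98983 (Da).
#' @examples
#' co2Mass()
#' @export
co2Mass <- function() unname(.ELEMENT_MASS["C"] + 2 * .ELEMENT_MASS["O"])

.parse_formula <- function(formula) {
    if (length(formula) != 1L || is.na(formula) || !nzchar(formula))
        stop("formula must be a non-empty string")
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
    if (sum(nchar(parts)) != nchar(formula))
        stop("unparseable formula: \"", formula, "\"")
    sym <- sub("[0-9]*$", "", parts)
    bad <- setdiff(sym, names(.ELEMENT_MASS))
    if (length(bad))
        stop("unsupported element \"", bad[1], "\" in formula \"",
             formula, "\"")
    n <- sub("^[A-Za-z]+", "", parts)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    counts <- tapply(n, sym, sum)
    if (all(counts == 0L)) stop("formula \"", formula, "\" is empty")
    counts
}

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-notation formula over C, H, N, O, S (and P) and sums the
#' IUPAC monoisotopic element masses.
#'
#' @param formula character vector of Hill-notation formulas, e.g.
#'   `"C5H9NO4"` (glutamate).
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' formulaMass("CO2")      # 43.98983
#' formulaMass("C5H9NO4")  # glutamate, 147.05316
#' @export
formulaMass <- function(formula) {
    vapply(formula, function(f) {
        counts <- .parse_formula(f)
        sum(counts * .ELEMENT_MASS[names(counts)])
    }, numeric(1), USE.NAMES = length(formula) > 1L)
}

.ADDUCTS <- data.frame(
    adduct = c("[M+H]+", "[M-H]-"),
    polarity = c("positive", "negative"),
    shift = c(.PROTON, -.PROTON),
    stringsAsFactors = FALSE)

.norm_adduct <- function(adduct) {
    ## tolerate the typographic minus occasionally found in method tables
    a <- gsub("−", "-", adduct)
    if (!a %in% .ADDUCTS$adduct)
        stop("unsupported adduct \"", adduct,
             "\" (supported: [M+H]+, [M-H]-)")
    a
}

#' Default adduct for a polarity
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return `"[M+H]+"` or `"[M-H]-"`.
#' @export
adductForPolarity <- function(polarity) {
    i <- match(polarity, .ADDUCTS$polarity)
    if (is.na(i)) stop("unknown polarity \"", polarity, "\"")
    .ADDUCTS$adduct[i]
}

#' Ion m/z of a neutral mass under a singly charged adduct
#'
#' Only the singly charged protonated/deprotonated forms are supported
#' (`[M+H]+`, `[M-H]-`), the ion species small polar metabolites give on
#' HILIC electrospray.
#'
#' @param neutralMass neutral monoisotopic mass in Da (> 0).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return m/z of the adduct ion.
#' @examples
#' ionMz(formulaMass("C5H9NO4"), "[M+H]+")  # 148.06043
#' @export
ionMz <- function(neutralMass, adduct = "[M+H]+") {
    if (any(neutralMass <= 0)) stop("neutralMass must be > 0")
    a <- .norm_adduct(adduct)
    neutralMass + .ADDUCTS$shift[match(a, .ADDUCTS$adduct)]
}

#' Inverse of [ionMz()]: neutral mass from an ion m/z
#'
#' @param mz observed ion m/z.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return neutral monoisotopic mass in Da.
#' @export
neutralMass <- function(mz, adduct = "[M+H]+") {
    a <- .norm_adduct(adduct)
    mz - .ADDUCTS$shift[match(a, .ADDUCTS$adduct)]
}

#' Signed mass error in parts per million
#'
#' @param observed observed m/z.
#' @param expected expected (theoretical) m/z, > 0.
#' @return `1e6 * (observed - expected) / expected`.
#' @examples
#' ppmError(146.0461, 146.04588)  # about +1.5 ppm
#' @export
ppmError <- function(observed, expected) {
    if (any(expected <= 0)) stop("expected m/z must be > 0")
    1e6 * (observed - expected) / expected
}

#' Expected product ion m/z after decarboxylation
#'
#' Subtracts the CO2 neutral-loss mass from a substrate ion m/z. Because the
#' adduct shift cancels in the difference, the same subtraction is valid in
#' positive and negative mode as long as substrate and product carry the
#' same adduct.
#'
#' @param substrateIonMz substrate ion m/z (must exceed the CO2 mass).
#' @return expected product ion m/z.
#' @examples
#' decarboxylationMz(148.0600)  # 104.07017, near the GABA [M+H]+ ion
#' @export
decarboxylationMz <- function(substrateIonMz) {
    out <- substrateIonMz - co2Mass()
    if (any(out <= 0))
        stop("substrate ion m/z must exceed the CO2 mass (",
             round(co2Mass(), 5), " Da)")
    out
}
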