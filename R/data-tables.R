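#' The 20 proteinogenic amino acids
#'
#' Names and neutral elemental formulas of the 20 proteinogenic amino acids,
#' the canonical substrate mixture for decarboxylase activity assays.
#'
#' @return data.frame with columns `name`, `formula`.
#' @examples
#' aa <- aminoAcidTable()
#' subset(aa, name == "glutamate")
#' @export
aminoAcidTable <- function() {
    data.frame(
        name = c("glycine", "alanine", "serine", "proline", "valine",
                 "threonine", "cysteine", "leucine", "isoleucine",
                 "asparagine", "aspartate", "glutamine", "lysine",
                 "glutamate", "methionine", "histidine", "phenylalanine",
                 "arginine", "tyrosine", "tryptophan"),
        formula = c("C2H5NO2", "C3H7NO2", "C3H7NO3", "C5H9NO2", "C5H11NO2",
                    "C4H9NO3", "C3H7NO2S", "C6H13NO2", "C6H13NO2",
                    "C4H8N2O3", "C4H7NO4", "C5H10N2O3", "C6H14N2O2",
                    "C5H9NO4", "C5H11NO2S", "C6H9N3O2", "C9H11NO2",
                    "C6H14N4O2", "C9H11NO3", "C11H12N2O2"),
        stringsAsFactors = FALSE)
}

#' Known substrate/product pairs of the group II amino acid decarboxylases
#'
#' The six decarboxylation reactions catalysed by the human group II
#' enzymes: glutamate decarboxylase (GAD) makes GABA, histidine
#' decarboxylase (HDC) makes histamine, cysteine sulfinic acid decarboxylase
#' (CSAD) makes hypotaurine, and aromatic amino acid decarboxylase (AADC)
#' makes phenethylamine, tyramine and tryptamine. Every pair differs by one
#' CO2 (43.98983 Da), the neutral loss the pairing step searches for.
#'
#' @return data.frame with columns `enzyme`, `substrate`,
#'   `substrate_formula`, `product`, `product_formula`.
#' @examples
#' p <- knownDecarboxylationPairs()
#' formulaMass(p$substrate_formula) - formulaMass(p$product_formula)
#' @export
knownDecarboxylationPairs <- function() {
    data.frame(
        enzyme = c("GAD", "HDC", "CSAD", "AADC", "AADC", "AADC"),
        substrate = c("glutamate", "histidine", "cysteine sulfinic acid",
                      "phenylalanine", "tyrosine", "tryptophan"),
        substrate_formula = c("C5H9NO4", "C6H9N3O2", "C3H7NO4S",
                              "C9H11NO2", "C9H11NO3", "C11H12N2O2"),
        product = c("GABA", "histamine", "hypotaurine", "phenethylamine",
                    "tyramine", "tryptamine"),
        product_formula = c("C4H9NO2", "C5H9N3", "C2H7NO2S", "C8H11N",
                            "C8H11NO", "C10H12N2"),
        stringsAsFactors = FALSE)
}

## The built-in triple-quadrupole transition panel: 19 amino acid analytes
## (no glycine entry; cystine rather than cysteine), positive mode.
## Q1/Q3 are nominal instrument-method values and are kept verbatim,
## including their mixed rounding conventions (e.g. tryptophan Q1 = 205).
.TRANSITIONS <- data.frame(
    analyte = c("alanine", "arginine", "asparagine", "aspartate", "cystine",
                "glutamate", "glutamine", "histidine", "isoleucine",
                "leucine", "lysine", "methionine", "phenylalanine",
                "proline", "serine", "threonine", "tryptophan", "tyrosine",
                "valine"),
    q1 = c(90.1, 175.02, 133.1, 134, 241.002, 148.1, 147.1, 156.1, 132.1,
           132.1, 147, 150.1, 166.1, 116.1, 106, 120, 205, 182.1, 118.1),
    q3 = c(44.2, 60, 74, 74, 74, 84.1, 84.1, 110.1, 86, 86, 67, 133, 103,
           70.1, 60, 74, 146, 77, 55.2),
    ce = c(13, 16, 19, 17, 32, 17, 17, 14, 13, 13, 32, 12, 30, 13, 15, 13,
           18, 39, 13),
    polarity = "positive",
    stringsAsFactors = FALSE)

.TRANSITION_FORMULAS <- c(
    alanine = "C3H7NO2", arginine = "C6H14N4O2", asparagine = "C4H8N2O3",
    aspartate = "C4H7NO4", cystine = "C6H12N2O4S2", glutamate = "C5H9NO4",
    glutamine = "C5H10N2O3", histidine = "C6H9N3O2",
    isoleucine = "C6H13NO2", leucine = "C6H13NO2", lysine = "C6H14N2O2",
    methionine = "C5H11NO2S", phenylalanine = "C9H11NO2",
    proline = "C5H9NO2", serine = "C3H7NO3", threonine = "C4H9NO3",
    tryptophan = "C11H12N2O2", tyrosine = "C9H11NO3", valine = "C5H11NO2")
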