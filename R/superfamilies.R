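#' Canonical TE superfamily labels
#'
#' The twelve superfamily labels used as the stratification unit throughout
#' the package: five Class I (retrotransposon) and seven Class II
#' (DNA transposon) superfamilies.
#'
#' @return Character vector of the 12 canonical superfamily labels.
#' @export
#' @examples
#' te_superfamilies()
te_superfamilies <- function() {
  c("SINE", "LINE", "LTR/Unclassed", "LTR/Gypsy", "LTR/Copia",
    "CACTA", "hAT", "Helitron", "PIF/Harbinger", "Tc1/Mariner",
    "Mutator", "DNA/Unclassed")
}

#' TE class (I or II) of a superfamily
#'
#' Class I superfamilies transpose via an RNA intermediate (SINE, LINE and the
#' LTR families); all others are Class II DNA transposons.
#'
#' @param superfamily Character vector of canonical superfamily labels.
#' @return Character vector of "I"/"II".
#' @export
te_class_of <- function(superfamily) {
  .check_superfamily(superfamily)
  ifelse(superfamily %in% c("SINE", "LINE", "LTR/Unclassed",
                            "LTR/Gypsy", "LTR/Copia"), "I", "II")
}

#' Superfamilies with a planted tetraploid H3K27me3 boost
#'
#' The five superfamilies whose adjacent non-TE chromatin gains H3K27me3 in
#' the tetraploid condition of the default simulation: LINE, CACTA,
#' PIF/Harbinger, Tc1/Mariner and the unclassed DNA transposons.
#'
#' @return Character vector of 5 superfamily labels.
#' @export
boosted_superfamilies <- function() {
  c("LINE", "CACTA", "PIF/Harbinger", "Tc1/Mariner", "DNA/Unclassed")
}

.check_superfamily <- function(superfamily) {
  bad <- setdiff(superfamily, te_superfamilies())
  if (length(bad))
    .err(sprintf("unknown superfamily label(s): %s",
                 paste(unique(bad), collapse = ", ")),
         "ploidyTE_value_error")
  invisible(superfamily)
}
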