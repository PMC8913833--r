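#' The default 11-metabolite panel
#'
#' The metabolites quantifiable in murine hippocampal MRS that pass the usual
#' CRLB reliability screen: alanine, creatine, phosphocreatine, GABA,
#' glutamate, glutamine, phosphorylcholine, glutathione, myo-inositol,
#' N-acetylaspartate and taurine. The order is fixed and shared by every
#' matrix the package produces.
#'
#' @return character vector of metabolite names.
#' @export
default_panel <- function() {
  c("Ala", "Cr", "PCr", "GABA", "Glu", "Gln", "PCh", "GSH", "Ins", "NAA", "Tau")
}

#' Validate a metabolite panel
#'
#' @param names character vector of unique metabolite identifiers.
#' @return the validated panel (invisibly usable downstream as matrix dimnames).
#' @export
metabolite_panel <- function(names = default_panel()) {
  if (!is.character(names) || length(names) == 0L) {
    stop_invalid("panel must be a non-empty character vector")
  }
  if (anyDuplicated(names)) stop_invalid("panel names must be unique")
  names
}
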