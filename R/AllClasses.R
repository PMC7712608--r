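#' @import methods
NULL

#' Backbone structure of a single protein chain
#'
#' Holds the six backbone atoms N, H, CA, HA, C, O per residue (rows of a
#' \code{6n x 3} coordinate matrix, Angstrom) together with the one-letter
#' sequence. Atoms that are not (yet) placed -- the amide hydrogen of
#' proline, or trailing atoms of a partially elongated fragment -- are
#' \code{NA}. Residue numbering is 1-based.
#'
#' @slot sequence character vector of one-letter residue codes.
#' @slot coords numeric matrix with \code{6 * length(sequence)} rows and 3
#'   columns; row order is N, H, CA, HA, C, O within each residue.
#' @exportClass BackboneStructure
setClass("BackboneStructure",
  representation(sequence = "character", coords = "matrix"))

setValidity("BackboneStructure", function(object) {
  n <- length(object@sequence)
  if (n < 1L) return("empty sequence")
  if (!all(object@sequence %in% .AA1))
    return(paste0("unknown residue letter(s): ",
                  paste(setdiff(object@sequence, .AA1), collapse = ", ")))
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric matrix with 3 columns")
  if (nrow(object@coords) != 6L * n)
    return("coords must have 6 rows per residue (N, H, CA, HA, C, O)")
  if (any(is.infinite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' Saupe order tensor
#'
#' A 3x3 symmetric traceless alignment tensor stored by its five independent
#' components (Sxx, Syy, Sxy, Sxz, Syz); Szz = -Sxx - Syy by construction,
#' so the trace is exactly zero.
#'
#' @slot s numeric vector of length 5, named Sxx, Syy, Sxy, Sxz, Syz.
#' @exportClass SaupeTensor
setClass("SaupeTensor", representation(s = "numeric"))

setValidity("SaupeTensor", function(object) {
  if (length(object@s) != 5L) return("need exactly 5 components")
  if (any(!is.finite(object@s))) return("non-finite tensor components")
  TRUE
})

#' A set of residual dipolar coupling restraints
#'
#' Thin container around a data frame with one row per coupling: the two
#' atoms (residue number + backbone atom name, optionally residue name), the
#' alignment-medium index, the coupling value and its uncertainty (Hz).
#'
#' @slot records data.frame with columns residue_1, atom_1, residue_2,
#'   atom_2, medium, value, uncertainty (and optionally resname_1/resname_2).
#' @exportClass RdcSet
setClass("RdcSet", representation(records = "data.frame"))

.RDC_COLS <- c("residue_1", "atom_1", "residue_2", "atom_2",
               "medium", "value", "uncertainty")

setValidity("RdcSet", function(object) {
  r <- object@records
  miss <- setdiff(.RDC_COLS, names(r))
  if (length(miss)) return(paste("missing column(s):",
                                 paste(miss, collapse = ", ")))
  if (nrow(r)) {
    if (!all(is.finite(r$value))) return("non-finite RDC value(s)")
    if (any(r$uncertainty < 0, na.rm = TRUE))
      return("negative uncertainty")
    if (any(r$medium < 1L)) return("medium indices must be >= 1")
    bad <- !(r$atom_1 %in% .ATOMS) | !(r$atom_2 %in% .ATOMS)
    if (any(bad)) return("unsupported backbone atom name in records")
  }
  TRUE
})
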