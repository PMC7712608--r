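#' Number of residues in a structure
#' @param x a \linkS4class{BackboneStructure}.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' One-letter residue sequence
#' @param x a \linkS4class{BackboneStructure}.
#' @return character vector of one-letter codes.
#' @export
setGeneric("residueSequence",
           function(x) standardGeneric("residueSequence"))

#' Backbone atom coordinates
#' @param x a \linkS4class{BackboneStructure}.
#' @return numeric \code{6n x 3} matrix (rows N, H, CA, HA, C, O per
#'   residue), \code{NA} rows for unplaced atoms.
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Saupe tensor as a 3x3 matrix
#' @param x a \linkS4class{SaupeTensor}.
#' @return symmetric traceless 3x3 matrix.
#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))

#' RDC records as a data frame
#' @param x an \linkS4class{RdcSet}.
#' @return data.frame, one row per coupling.
#' @export
setGeneric("rdcRecords", function(x) standardGeneric("rdcRecords"))

#' Number of alignment media represented in an RDC set
#' @param x an \linkS4class{RdcSet}.
#' @return integer.
#' @export
setGeneric("nMedia", function(x) standardGeneric("nMedia"))
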