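#' @rdname nResidues
setMethod("nResidues", "BackboneStructure",
          function(x) length(x@sequence))

#' @rdname residueSequence
setMethod("residueSequence", "BackboneStructure",
          function(x) x@sequence)

#' @rdname atomCoords
setMethod("atomCoords", "BackboneStructure", function(x) x@coords)

#' @rdname saupeMatrix
setMethod("saupeMatrix", "SaupeTensor", function(x) {
  s <- x@s
  m <- matrix(c(s[1L], s[3L], s[4L],
                s[3L], s[2L], s[5L],
                s[4L], s[5L], -s[1L] - s[2L]), 3L, 3L)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m
})

#' @rdname rdcRecords
setMethod("rdcRecords", "RdcSet", function(x) x@records)

#' @rdname nMedia
setMethod("nMedia", "RdcSet", function(x) {
  if (!nrow(x@records)) 0L else max(x@records$medium)
})

setMethod("show", "BackboneStructure", function(object) {
  n <- nResidues(object)
  placed <- sum(stats::complete.cases(object@coords))
  cat(sprintf("BackboneStructure: %d residue%s, %d/%d atoms placed\n",
              n, if (n == 1L) "" else "s", placed, 6L * n))
  s <- paste(object@sequence, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence: ", s, "\n", sep = "")
})

setMethod("show", "SaupeTensor", function(object) {
  cat("SaupeTensor (symmetric traceless):\n")
  print(signif(saupeMatrix(object), 4))
})

setMethod("show", "RdcSet", function(object) {
  r <- object@records
  cat(sprintf("RdcSet: %d coupling%s in %d alignment medium/media\n",
              nrow(r), if (nrow(r) == 1L) "" else "s", nMedia(object)))
  if (nrow(r)) {
    types <- table(paste0(r$atom_1, "-", r$atom_2))
    cat("  vector types:",
        paste(sprintf("%s (%d)", names(types), types), collapse = ", "),
        "\n")
  }
})

#' Construct a Saupe tensor
#'
#' @param sxx,syy,sxy,sxz,syz the five independent components
#'   (dimensionless order parameters); Szz is \code{-sxx - syy}.
#' @return a \linkS4class{SaupeTensor}.
#' @examples
#' saupeTensor(-3e-4, -5e-4, 0, 0, 0)
#' @export
saupeTensor <- function(sxx = 0, syy = 0, sxy = 0, sxz = 0, syz = 0) {
  new("SaupeTensor", s = c(Sxx = sxx, Syy = syy, Sxy = sxy,
                           Sxz = sxz, Syz = syz))
}

#' Construct a Saupe tensor from any symmetric traceless matrix
#' @param m 3x3 symmetric matrix with (near-)zero trace.
#' @return a \linkS4class{SaupeTensor}.
#' @export
saupeFromMatrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 3L))
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m))))
    stop("matrix is not symmetric")
  if (abs(sum(diag(m))) > 1e-9 * max(1, max(abs(m))))
    stop("matrix is not traceless")
  saupeTensor(m[1, 1], m[2, 2], m[1, 2], m[1, 3], m[2, 3])
}

#' Construct an RDC set from a data frame of couplings
#'
#' @param records data.frame with columns residue_1, atom_1, residue_2,
#'   atom_2, medium, value, uncertainty.
#' @return an \linkS4class{RdcSet}.
#' @export
rdcSet <- function(records) {
  records$residue_1 <- as.integer(records$residue_1)
  records$residue_2 <- as.integer(records$residue_2)
  records$medium <- as.integer(records$medium)
  records$atom_1 <- as.character(records$atom_1)
  records$atom_2 <- as.character(records$atom_2)
  rownames(records) <- NULL
  new("RdcSet", records = records)
}
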