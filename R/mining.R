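# Data-driven dihedral restraints from a local fragment corpus: a
# rolling sequence window fragments every corpus chain into k-mers, the
# (phi, psi) series of each k-mer is stored under its sequence, and a
# query sequence is predicted per position from the pooled observations
# of all matching windows covering it.

#' Mine (phi, psi) fragments from a structure corpus
#'
#' Every length-k subsequence of every corpus chain contributes its
#' torsion series to the library, keyed by the k-mer sequence. Chains
#' shorter than the window are skipped with a message.
#'
#' @param corpus list of \linkS4class{BackboneStructure} objects, or a
#'   directory path containing PDB files.
#' @param window rolling window size k (>= 3); 6 is the standard
#'   operating point.
#' @return list of class \code{FragmentLibrary}: \code{window} and
#'   \code{kmers}, a named list mapping k-mer sequences to lists of
#'   \code{k x 2} torsion matrices.
#' @export
mineFragments <- function(corpus, window = 6L) {
  if (window < 3L) stop("window must be >= 3")
  if (is.character(corpus) && length(corpus) == 1L && dir.exists(corpus)) {
    paths <- list.files(corpus, pattern = "\\.pdb$", full.names = TRUE,
                        ignore.case = TRUE)
    if (!length(paths)) stop("no PDB files in ", corpus)
    corpus <- lapply(sort(paths), readPdb)
  }
  kmers <- new.env(parent = emptyenv())
  nSkipped <- 0L
  for (s in corpus) {
    stopifnot(is(s, "BackboneStructure"))
    n <- nResidues(s)
    if (n < window) {
      nSkipped <- nSkipped + 1L
      message("skipping a chain shorter than the window (", n, " < ",
              window, ")")
      next
    }
    tor <- extractTorsions(s)
    seq1 <- residueSequence(s)
    for (start in seq_len(n - window + 1L)) {
      idx <- start:(start + window - 1L)
      km <- paste(seq1[idx], collapse = "")
      series <- tor[idx, , drop = FALSE]
      kmers[[km]] <- c(if (!is.null(kmers[[km]])) kmers[[km]],
                       list(series))
    }
  }
  structure(list(window = as.integer(window),
                 kmers = as.list(kmers), nSkippedChains = nSkipped),
            class = "FragmentLibrary")
}

#' @export
print.FragmentLibrary <- function(x, ...) {
  nObs <- sum(vapply(x$kmers, length, integer(1L)))
  cat(sprintf("FragmentLibrary: window %d, %d distinct k-mers, %d series\n",
              x$window, length(x$kmers), nObs))
  invisible(x)
}

#' Library size (total stored k-mer series)
#' @param library a \code{FragmentLibrary}.
#' @return integer: sum over corpus chains of (length - k + 1).
#' @export
librarySize <- function(library) {
  sum(vapply(library$kmers, length, integer(1L)))
}

#' Predict per-residue dihedrals for a query sequence
#'
#' For each residue, the (phi, psi) observations of every matching k-mer
#' window covering that position are pooled (all offsets contribute
#' equally) and the prediction is the mode of the pooled distribution on
#' a 2-D histogram with \code{binWidth}-degree bins (tie-break: lowest
#' (phi, psi) bin lexicographically; bin centers are reported). Residues
#' with no matching window are absent from the output.
#'
#' @param sequence one-letter query sequence.
#' @param library a \code{FragmentLibrary} from \code{\link{mineFragments}}.
#' @param binWidth histogram bin width in degrees (default 10).
#' @param half_width,step expansion parameters stored on the emitted
#'   restraints (defaults 25 and 5 degrees).
#' @return data.frame with columns residue, phi, psi, half_width, step,
#'   n_obs.
#' @export
predictDihedrals <- function(sequence, library, binWidth = 10,
                             half_width = 25, step = 5) {
  stopifnot(inherits(library, "FragmentLibrary"))
  if (!length(library$kmers)) stop("empty fragment library")
  sequence <- .parseSeq(sequence)
  n <- length(sequence)
  k <- library$window
  obs <- vector("list", n)
  if (n >= k) {
    for (start in seq_len(n - k + 1L)) {
      km <- paste(sequence[start:(start + k - 1L)], collapse = "")
      hits <- library$kmers[[km]]
      if (is.null(hits)) next
      for (series in hits)
        for (o in seq_len(k)) {
          pos <- start + o - 1L
          obs[[pos]] <- rbind(obs[[pos]], series[o, , drop = FALSE])
        }
    }
  }
  nb <- round(360 / binWidth)
  # the 1e-9 guard keeps angles sitting exactly on a bin boundary from
  # flipping bins through floating-point noise
  binOf <- function(a) pmin(pmax(ceiling((a + 180) / binWidth - 1e-9),
                                 1L), nb)
  rows <- list()
  for (i in seq_len(n)) {
    o <- obs[[i]]
    if (is.null(o)) next
    o <- o[stats::complete.cases(o), , drop = FALSE]
    if (!nrow(o)) next
    bp <- binOf(o[, 1L]); bq <- binOf(o[, 2L])
    tab <- table(factor(bp, levels = 1:nb), factor(bq, levels = 1:nb))
    best <- which(tab == max(tab), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      residue = i,
      phi = -180 + (best[1L] - 0.5) * binWidth,
      psi = -180 + (best[2L] - 0.5) * binWidth,
      half_width = half_width, step = step, n_obs = nrow(o))
  }
  if (!length(rows))
    return(data.frame(residue = integer(0L), phi = numeric(0L),
                      psi = numeric(0L), half_width = numeric(0L),
                      step = numeric(0L), n_obs = integer(0L)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand dihedral restraints into Stage-I candidate lists
#'
#' Each restraint becomes a per-residue candidate list by varying the
#' prediction +/- half_width in steps of \code{step} degrees (121 pairs
#' at the 25/5 defaults), optionally written as Stage-I candidate files.
#'
#' @param restraints data.frame as from \code{\link{predictDihedrals}}.
#' @param outDir if non-NULL, write one file per restrained residue.
#' @return named list (by residue) of data.frames with columns phi, psi.
#' @export
emitStage1Lists <- function(restraints, outDir = NULL) {
  out <- list()
  for (i in seq_len(nrow(restraints))) {
    r <- restraints[i, , drop = FALSE]
    out[[as.character(r$residue)]] <- expandRestraint(r)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      utils::write.table(
        cbind(residue = r$residue, out[[as.character(r$residue)]]),
        file.path(outDir, sprintf("restraint_candidates_%03d.txt",
                                  r$residue)),
        row.names = FALSE, quote = FALSE)
    }
  }
  out
}
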