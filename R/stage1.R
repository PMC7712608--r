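# Stage-I: per-junction candidate (phi, psi) lists.
#
# A junction i is the pair of adjoining peptide planes meeting at CA(i);
# its geometry is set by residue i's (phi, psi). Candidates are enumerated
# on a regular grid (or expanded from a predicted dihedral restraint),
# filtered by Ramachandran class, and ranked by local RDC fitness: only
# couplings whose two atoms lie in the two rigid planes of the junction
# (plus HA(i)) are scored, because only those have junction-determined
# relative geometry.

#' Enumerate the discretized torsion grid
#'
#' Full \code{(360/step)^2} grid over \code{(-180, 180]^2}, ordered
#' lexicographically by (phi, psi).
#'
#' @param step grid step in degrees; must divide 360.
#' @return data.frame with columns phi, psi.
#' @export
enumerateGrid <- function(step) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("grid step must be a positive divisor of 360")
  v <- seq(-180 + step, 180, by = step)
  data.frame(phi = rep(v, each = length(v)), psi = rep(v, length(v)))
}

#' Ramachandran allowed-region tables
#'
#' Generously inclusive allowed regions for the four residue classes,
#' shipped as explicit polygon tables (swappable data, in degrees). Each
#' class maps to a list of polygons (data.frames with columns phi, psi);
#' a pair is allowed if it falls inside (or on the boundary of) any
#' polygon of its class. The boundaries are deliberately loose: targets
#' can sample atypical Ramachandran space, and over-strict filtering would
#' eliminate the true conformation before the RDC data can vote.
#'
#' @return named list (general, GLY, PRO, prePRO) of polygon lists.
#' @export
ramaRegions <- function() {
  rect <- function(phi1, phi2, psi1, psi2)
    data.frame(phi = c(phi1, phi2, phi2, phi1),
               psi = c(psi1, psi1, psi2, psi2))
  list(
    general = list(rect(-180, -20, -180, 180)),
    GLY = list(rect(-180, -20, -180, 180),
               rect(20, 180, -180, 180),
               rect(-20, 20, 90, 180),
               rect(-20, 20, -180, -90)),
    PRO = list(rect(-110, -40, -180, 180)),
    prePRO = list(rect(-180, -40, -180, 180)))
}

#' Residue Ramachandran class
#'
#' @param sequence one-letter sequence (string or vector).
#' @param i residue index.
#' @return one of \code{"general"}, \code{"GLY"}, \code{"PRO"},
#'   \code{"prePRO"}.
#' @export
residueClass <- function(sequence, i) {
  sequence <- .parseSeq(sequence)
  if (i < 1L || i > length(sequence)) stop("residue index out of range")
  if (sequence[i] == "P") return("PRO")
  if (sequence[i] == "G") return("GLY")
  if (i < length(sequence) && sequence[i + 1L] == "P") return("prePRO")
  "general"
}

#' Filter torsion pairs by Ramachandran class
#'
#' Keeps pairs inside (boundary inclusive) any allowed polygon of the
#' class. Idempotent; an empty result is allowed (and flagged upstream).
#'
#' @param pairs data.frame with columns phi, psi.
#' @param residueClass one of general, GLY, PRO, prePRO.
#' @param regions region table, default \code{\link{ramaRegions}}.
#' @return the allowed subset of \code{pairs}.
#' @export
ramaFilter <- function(pairs, residueClass = "general",
                       regions = ramaRegions()) {
  if (!residueClass %in% names(regions))
    stop("unknown residue class '", residueClass, "'")
  keep <- rep(FALSE, nrow(pairs))
  for (poly in regions[[residueClass]]) {
    inp <- pracma::inpolygon(pairs$phi, pairs$psi, poly$phi, poly$psi,
                             boundary = TRUE)
    keep <- keep | inp
  }
  pairs[keep, , drop = FALSE]
}

#' Restrict candidate pairs by a predicted dihedral restraint
#'
#' Retains pairs within the restraint's half-width of the prediction in
#' both phi and psi, with circular (wrap-around) distances. \code{NULL}
#' restraint returns the pairs unchanged.
#'
#' @param pairs data.frame with columns phi, psi.
#' @param restraint one-row data.frame (or list) with phi, psi,
#'   half_width; or NULL.
#' @return the retained subset.
#' @export
restrictByRestraint <- function(pairs, restraint) {
  if (is.null(restraint)) return(pairs)
  hw <- if (!is.null(restraint$half_width)) restraint$half_width else 25
  keep <- abs(.angdiff(pairs$phi, restraint$phi)) <= hw + 1e-9 &
    abs(.angdiff(pairs$psi, restraint$psi)) <= hw + 1e-9
  pairs[keep, , drop = FALSE]
}

#' Expand a dihedral restraint into a candidate list
#'
#' The prediction varied by +/- half_width in steps of \code{step}
#' degrees on both axes (the restraint-driven replacement for the full
#' grid): \code{(2 * half_width / step + 1)^2} pairs, wrapped into
#' \code{(-180, 180]}.
#'
#' @param restraint one-row data.frame (or list) with phi, psi and
#'   optionally half_width (default 25) and step (default 5).
#' @return data.frame with columns phi, psi.
#' @export
expandRestraint <- function(restraint) {
  hw <- if (!is.null(restraint$half_width)) restraint$half_width else 25
  st <- if (!is.null(restraint$step)) restraint$step else 5
  if (st <= 0 || st > hw) stop("need 0 < step <= half_width")
  dp <- seq(-hw, hw, by = st)
  phi <- .wrap180(restraint$phi + dp)
  psi <- .wrap180(restraint$psi + dp)
  data.frame(phi = rep(phi, each = length(psi)), psi = rep(psi,
                                                           length(phi)))
}

# linear indices of the junction-local atom set (see header comment)
.localAtomIdx <- function(j, n) {
  idx <- c()
  if (j >= 2L) idx <- c(idx, .aidx(j - 1L, c("CA", "C", "O")))
  idx <- c(idx, .aidx(j, .ATOMS))
  if (j < n) idx <- c(idx, .aidx(j + 1L, c("N", "H", "CA")))
  idx
}

#' Rank candidate pairs at a junction by local RDC fitness
#'
#' Builds the two-peptide-plane fragment implied by each candidate pair
#' and scores it against the couplings local to the junction (both atoms
#' within the junction's two rigid planes). Candidates are returned sorted
#' by ascending score with deterministic lexicographic (phi, psi)
#' tie-breaking; when no local data exist, all scores are zero, the input
#' order is preserved and the result is flagged with attribute
#' \code{"noLocalData"}.
#'
#' @param junction residue index (1..n; terminal junctions orient the
#'   chain-end proxy atoms).
#' @param pairs data.frame with columns phi, psi.
#' @param data an \linkS4class{RdcSet}.
#' @param sequence one-letter sequence.
#' @return data.frame (residue, phi, psi, score) sorted by score, class
#'   \code{CandidateList}.
#' @export
rankCandidates <- function(junction, pairs, data, sequence) {
  sequence <- .parseSeq(sequence)
  n <- length(sequence)
  if (junction < 1L || junction > n) stop("junction index out of range")
  if (!nrow(pairs)) stop("empty candidate list at junction ", junction)
  prep <- .prepData(data, sequence)
  local <- .localAtomIdx(junction, n)
  keep <- prep$l1 %in% local & prep$l2 %in% local
  for (f in c("l1", "l2", "dmax", "med", "val", "step"))
    prep[[f]] <- prep[[f]][keep]
  # canonical frame: placeholder chain through junction - 1
  ph <- rep(c(-60, -45), max(junction - 1L, 0L))
  frag <- .partialChain(sequence, ph, prep = NULL)
  # absorb junction-independent local records (both atoms already placed)
  placedNow <- stats::complete.cases(frag$xyz)
  fixed <- which(placedNow[prep$l1] & placedNow[prep$l2])
  stepRecs <- which(prep$step == junction)
  frag$stats <- .emptyStats(prep$nm)
  sc <- .scoreCandidatesExact(frag, prep, junction, pairs$phi, pairs$psi,
                              stepRecs, fixed)
  res <- data.frame(residue = junction, phi = pairs$phi, psi = pairs$psi,
                    score = if (sc$cnt > 0L)
                      sqrt(sc$scoreSq / sc$cnt) else rep(0, nrow(pairs)))
  noData <- sc$cnt == 0L
  if (!noData)
    res <- res[order(res$score, res$phi, res$psi), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "noLocalData") <- noData
  class(res) <- c("CandidateList", "data.frame")
  res
}

#' Stage-I: candidate lists for every junction
#'
#' For each junction: enumerate the torsion grid (or expand the residue's
#' dihedral restraint at 5-degree steps when one is supplied), filter by
#' the residue's Ramachandran class, and rank by local RDC fitness. An
#' empty post-filter list falls back to the unfiltered list with a
#' warning.
#'
#' @param sequence one-letter sequence.
#' @param data an \linkS4class{RdcSet}.
#' @param gridStep grid step in degrees (default 10).
#' @param restraints optional restraint data.frame (see
#'   \code{\link{readRestraints}}).
#' @param useRama apply the Ramachandran filter (default TRUE).
#' @param regions Ramachandran region table.
#' @param outDir if non-NULL, write one candidate file per junction
#'   (columns residue, phi, psi, score) into this directory.
#' @return list of \code{CandidateList} objects, one per junction 1..n.
#' @export
stage1Candidates <- function(sequence, data, gridStep = 10,
                             restraints = NULL, useRama = TRUE,
                             regions = ramaRegions(), outDir = NULL) {
  sequence <- .parseSeq(sequence)
  n <- length(sequence)
  grid <- enumerateGrid(gridStep)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    rj <- NULL
    if (!is.null(restraints) && j %in% restraints$residue)
      rj <- restraints[match(j, restraints$residue), , drop = FALSE]
    pairs <- if (!is.null(rj)) expandRestraint(rj) else grid
    if (useRama) {
      filtered <- ramaFilter(pairs, residueClass(sequence, j), regions)
      if (!nrow(filtered)) {
        warning("junction ", j, ": Ramachandran filter removed all ",
                "candidates; keeping the unfiltered list")
      } else {
        pairs <- filtered
      }
    }
    out[[j]] <- rankCandidates(j, pairs, data, sequence)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      utils::write.table(out[[j]],
                         file.path(outDir,
                                   sprintf("candidates_%03d.txt", j)),
                         row.names = FALSE, quote = FALSE)
    }
  }
  out
}
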