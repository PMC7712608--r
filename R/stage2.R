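# Stage-II: beam-search elongation over peptide planes with static
# (legacy) or dynamic (adaptive percentage-of-best) decimation.

#' Dynamic decimation of a scored fragment pool
#'
#' Retains fragments whose score is below
#' \code{max(s0 * (1 + tolerance/100), epsAbs)} where \code{s0} is the
#' best (smallest) score in the pool. The multiplicative band adapts to
#' the data quality at each step; the absolute floor \code{epsAbs}
#' governs the under-determined early steps where \code{s0} is zero (or
#' numerically indistinguishable from it), where a percentage band would
#' collapse to exact ties. Never empty: the best fragment is always kept.
#' With \code{additive = TRUE} the threshold is
#' \code{s0 + tolerance/100} Hz instead (alternative reading; see
#' vignette).
#'
#' @param pool data.frame with a \code{score} column (sorted ascending),
#'   or a list of fragments each carrying \code{$score}.
#' @param tolerance percentage tolerance (> 0).
#' @param epsAbs absolute floor in Hz for near-zero best scores.
#' @param additive use the additive reading of the threshold.
#' @return the retained subset of \code{pool} (same type).
#' @export
decimateDynamic <- function(pool, tolerance, epsAbs = 0.01,
                            additive = FALSE) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  scores <- if (is.data.frame(pool)) pool$score else
    vapply(pool, function(f) f$score, numeric(1L))
  if (!length(scores)) return(pool)
  if (is.unsorted(scores)) stop("pool must be sorted by ascending score")
  s0 <- scores[1L]
  thr <- if (additive) s0 + tolerance / 100 else
    max(s0 * (1 + tolerance / 100), epsAbs)
  keep <- scores < thr
  keep[1L] <- TRUE
  if (is.data.frame(pool)) pool[keep, , drop = FALSE] else pool[keep]
}

#' Static (legacy) decimation of a scored fragment pool
#'
#' Representative selection: fragments are bucketed by rounding their
#' terminal (phi, psi) to \code{bucketWidth} degrees and only the
#' best-scoring member of each bucket survives (\code{bucketWidth = 0}
#' disables bucketing); an absolute score threshold is then applied.
#' Kept for comparison experiments with the historical behaviour; the
#' best fragment always survives.
#'
#' @param pool data.frame with columns score, phi, psi (sorted ascending
#'   by score), or a list of fragments with \code{$score} and
#'   \code{$torsions}.
#' @param threshold absolute score threshold in Hz (default Inf).
#' @param bucketWidth bucket width in degrees (default 10).
#' @return the retained subset of \code{pool} (same type).
#' @export
decimateStatic <- function(pool, threshold = Inf, bucketWidth = 10) {
  isDF <- is.data.frame(pool)
  scores <- if (isDF) pool$score else
    vapply(pool, function(f) f$score, numeric(1L))
  if (!length(scores)) return(pool)
  if (is.unsorted(scores)) stop("pool must be sorted by ascending score")
  if (isDF) {
    phi <- pool$phi; psi <- pool$psi
  } else {
    term <- t(vapply(pool, function(f) {
      tor <- f$torsions
      as.numeric(tor[nrow(tor), ])
    }, numeric(2L)))
    phi <- term[, 1L]; psi <- term[, 2L]
  }
  keep <- rep(TRUE, length(scores))
  if (bucketWidth > 0) {
    bucket <- paste(round(phi / bucketWidth), round(psi / bucketWidth))
    keep <- !duplicated(bucket)
  }
  keep <- keep & scores <= threshold
  keep[1L] <- TRUE
  if (isDF) pool[keep, , drop = FALSE] else pool[keep]
}

.applyPolicy <- function(pool, policy) {
  # pool: data.frame(parent, phi, psi, score) sorted ascending
  kept <- switch(policy$mode,
    dynamic = decimateDynamic(pool, policy$tolerance,
                              epsAbs = policy$epsAbs,
                              additive = isTRUE(policy$additive)),
    static = decimateStatic(pool, threshold = policy$staticThreshold,
                            bucketWidth = policy$bucketWidth),
    stop("unknown decimation mode '", policy$mode, "'"))
  if (!nrow(kept)) {
    warning("decimation emptied the pool; falling back to the top-",
            policy$depth, " fragments")
    kept <- pool
  }
  utils::head(kept, policy$depth)
}

#' A decimation policy
#'
#' @param mode \code{"dynamic"} or \code{"static"}.
#' @param depth beam width n: fragments carried to the next step.
#' @param tolerance dynamic-mode percentage tolerance.
#' @param staticThreshold static-mode absolute score threshold (Hz).
#' @param bucketWidth static-mode representative bucket width (degrees).
#' @param epsAbs dynamic-mode absolute floor (Hz) for zero best scores.
#' @param additive dynamic-mode additive threshold reading.
#' @return a list of class \code{DecimationPolicy}.
#' @export
decimationPolicy <- function(mode = c("dynamic", "static"), depth = 1000L,
                             tolerance = 20, staticThreshold = Inf,
                             bucketWidth = 10, epsAbs = 0.01,
                             additive = FALSE) {
  mode <- match.arg(mode)
  if (depth < 1L) stop("depth must be >= 1")
  if (mode == "dynamic" && tolerance <= 0)
    stop("dynamic mode needs tolerance > 0")
  structure(list(mode = mode, depth = as.integer(depth),
                 tolerance = tolerance, staticThreshold = staticThreshold,
                 bucketWidth = bucketWidth, epsAbs = epsAbs,
                 additive = additive),
            class = "DecimationPolicy")
}

# one elongation step over an internal beam; returns list(beam, pool)
.stepBeam <- function(beam, prep, t, cand, policy) {
  ri <- which(prep$step == t)
  K <- nrow(cand)
  pools <- vector("list", length(beam))
  for (p in seq_along(beam)) {
    sc <- .scoreCandidates(beam[[p]], prep, t, cand$phi, cand$psi, ri)
    cnt <- sc$cnt
    pools[[p]] <- data.frame(
      parent = p, phi = cand$phi, psi = cand$psi,
      score = if (cnt > 0L) sqrt(sc$scoreSq / cnt) else rep(0, K))
  }
  pool <- do.call(rbind, pools)
  pkey <- vapply(beam, function(f) f$key, character(1L))
  pool <- pool[order(pool$score, pkey[pool$parent], pool$phi, pool$psi), ,
               drop = FALSE]
  rawSize <- nrow(pool)
  kept <- .applyPolicy(pool, policy)
  newBeam <- lapply(seq_len(nrow(kept)), function(i)
    .materializeChild(beam[[kept$parent[i]]], prep, t,
                      kept$phi[i], kept$psi[i], ri))
  # materialized scores can differ from pool scores in the last bit
  # (different summation order); re-sort so the ranked list is monotone
  ord <- order(vapply(newBeam, function(f) f$score, numeric(1L)),
               vapply(newBeam, function(f) f$key, character(1L)))
  list(beam = newBeam[ord], rawSize = rawSize, keptSize = nrow(kept))
}

.publicFragment <- function(frag, sequence) {
  list(torsions = matrix(frag$tors, ncol = 2L, byrow = TRUE,
                         dimnames = list(NULL, c("phi", "psi"))),
       structure = .fragStructure(frag, sequence),
       score = frag$score)
}

#' One beam-search elongation step
#'
#' Scores the cross product of the incoming beam and the junction's
#' candidate list (pooled RDC fitness of each extended fragment over all
#' couplings resolvable within it), sorts ascending with deterministic
#' lexicographic tie-breaks, applies the decimation policy and returns at
#' most \code{policy$depth} fragments.
#'
#' @param beam list of fragments: each a list with \code{$torsions} (t x 2
#'   matrix of the junctions chosen so far). An empty-torsion fragment
#'   (\code{nrow = 0}) is the search seed.
#' @param candidates \code{CandidateList} (or data.frame with phi, psi)
#'   for junction t + 1.
#' @param data an \linkS4class{RdcSet}.
#' @param sequence full one-letter target sequence.
#' @param policy a \code{\link{decimationPolicy}}.
#' @return list of fragments (torsions, structure, score), best first.
#' @export
elongateStep <- function(beam, candidates, data, sequence, policy) {
  if (!length(beam)) stop("beam must be non-empty")
  if (!nrow(candidates)) stop("candidate list must be non-empty")
  sequence <- .parseSeq(sequence)
  prep <- .prepData(data, sequence)
  tlens <- vapply(beam, function(f) nrow(f$torsions), integer(1L))
  if (length(unique(tlens)) != 1L)
    stop("all beam fragments must have the same number of junctions")
  t <- tlens[1L] + 1L
  if (t > length(sequence)) stop("fragment already complete")
  ibeam <- lapply(beam, function(f)
    .partialChain(sequence, as.numeric(t(f$torsions)), prep = prep))
  res <- .stepBeam(ibeam, prep, t, candidates, policy)
  lapply(res$beam, .publicFragment, sequence = sequence)
}

#' Stage-II: fold a full chain by beam-search elongation
#'
#' Starting from the first peptide plane, iterates
#' \code{\link{elongateStep}} over junctions 1..n, carrying at most
#' \code{depth} fragments, and returns the best final structure together
#' with the per-step trace. Deterministic for identical inputs.
#'
#' @param sequence one-letter target sequence.
#' @param data an \linkS4class{RdcSet}.
#' @param candidates Stage-I output (list of \code{CandidateList}, one per
#'   junction); computed via \code{\link{stage1Candidates}} when NULL.
#' @param policy a \code{\link{decimationPolicy}}.
#' @param gridStep,restraints,useRama passed to
#'   \code{\link{stage1Candidates}} when \code{candidates} is NULL.
#' @param audit recompute the winner's score from scratch after every step
#'   (cache-coherence audit, reported in \code{$audit}).
#' @param verbose log per-step pool sizes and best scores.
#' @return list of class \code{Stage2Result}: \code{structure} (the final
#'   \linkS4class{BackboneStructure}), \code{torsions}, \code{score} (Hz),
#'   \code{trace} (per-step ranked lists for \code{\link{writeOutTrace}}),
#'   \code{poolLog} (per-step pool sizes), \code{audit}, \code{beam}
#'   (final public fragments).
#' @export
runStage2 <- function(sequence, data, candidates = NULL,
                      policy = decimationPolicy(), gridStep = 10,
                      restraints = NULL, useRama = TRUE, audit = TRUE,
                      verbose = FALSE) {
  sequence <- .parseSeq(sequence)
  n <- length(sequence)
  if (is.null(candidates))
    candidates <- stage1Candidates(sequence, data, gridStep = gridStep,
                                   restraints = restraints,
                                   useRama = useRama)
  if (length(candidates) != n)
    stop("need one candidate list per junction (", n, ")")
  for (j in seq_len(n))
    if (is.null(candidates[[j]]) || !nrow(candidates[[j]]))
      stop("empty candidate list at residue ", j)
  prep <- .prepData(data, sequence)
  beam <- list(.baseFragment(sequence, prep))
  trace <- vector("list", n)
  poolLog <- data.frame(step = integer(0L), poolRaw = integer(0L),
                        poolKept = integer(0L), best = numeric(0L))
  auditLog <- data.frame(step = integer(0L), incremental = numeric(0L),
                         scratch = numeric(0L))
  for (t in seq_len(n)) {
    res <- .stepBeam(beam, prep, t, candidates[[t]], policy)
    beam <- res$beam
    scores <- vapply(beam, function(f) f$score, numeric(1L))
    trace[[t]] <- data.frame(
      rank = seq_along(beam), score = scores,
      angles = vapply(beam, function(f)
        .angleString(matrix(f$tors, ncol = 2L, byrow = TRUE)),
        character(1L)),
      stringsAsFactors = FALSE)
    poolLog <- rbind(poolLog, data.frame(step = t, poolRaw = res$rawSize,
                                         poolKept = res$keptSize,
                                         best = scores[1L]))
    if (audit) {
      scratch <- rdcFitness(.fragStructure(beam[[1L]], sequence),
                            data)$value
      auditLog <- rbind(auditLog,
                        data.frame(step = t, incremental = scores[1L],
                                   scratch = scratch))
    }
    if (verbose)
      message(sprintf(
        "step %3d/%d: pool %6d -> %4d, best fitness %.6g Hz",
        t, n, res$rawSize, res$keptSize, scores[1L]))
  }
  winner <- beam[[1L]]
  out <- list(structure = .fragStructure(winner, sequence),
              torsions = matrix(winner$tors, ncol = 2L, byrow = TRUE,
                                dimnames = list(NULL, c("phi", "psi"))),
              score = winner$score, trace = trace, poolLog = poolLog,
              audit = auditLog, nSkipped = prep$nSkipped,
              beam = lapply(beam, .publicFragment, sequence = sequence))
  class(out) <- "Stage2Result"
  out
}

#' @export
print.Stage2Result <- function(x, ...) {
  cat(sprintf(
    "Stage-II result: %d residues, final RDC fitness %.4g Hz (beam %d)\n",
    nResidues(x$structure), x$score, length(x$beam)))
  invisible(x)
}
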