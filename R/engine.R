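# Internal elongation engine shared by Stage-I candidate ranking and the
# Stage-II beam search.
#
# A fragment that has processed junctions 1..t consists of residues 1..t
# complete plus the amide unit (N, H, CA) of residue t+1. Junction t+1
# places, for all candidate (phi, psi) pairs at once: C'(t+1), HA(t+1),
# O(t+1) and -- when residue t+2 exists -- N, H, CA of residue t+2. Because
# elongation is append-only, the design-matrix rows of already-resolved
# couplings never change, so each fragment carries the packed
# normal-equation pieces (A'A, A'd, |d|^2) per alignment medium and a
# candidate pool is scored by a small dense solve per candidate
# (scorePoolCpp).

#' @useDynLib rdcfold, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# packing order of the 5x5 symmetric normal matrix into 15 columns
.PACK_I <- unlist(lapply(1:5, function(i) rep(i, 6L - i)))
.PACK_J <- unlist(lapply(1:5, function(i) i:5))

# step at which an atom's position becomes determined (junction index);
# res is the residue number, a the atom name index into .ATOMS
.atomStep <- function(res, a) {
  atom <- .ATOMS[a]
  ifelse(res == 1L,
         ifelse(atom %in% c("H", "O"), 1L, 0L),
         ifelse(atom %in% c("N", "H", "CA"), res - 1L, res))
}

# Resolve + index an RdcSet for the engine.
.prepData <- function(data, sequence) {
  rec <- if (is(data, "RdcSet")) data@records else data
  res <- .resolveRecords(rec, sequence)
  media <- sort(unique(res$records$medium))
  a1 <- (res$l1 - 1L) %% 6L + 1L
  a2 <- (res$l2 - 1L) %% 6L + 1L
  r1 <- (res$l1 - 1L) %/% 6L + 1L
  r2 <- (res$l2 - 1L) %/% 6L + 1L
  list(n = length(sequence), sequence = sequence,
       l1 = res$l1, l2 = res$l2, dmax = res$dmax,
       med = match(res$records$medium, media), nm = length(media),
       val = res$records$value,
       step = pmax(.atomStep(r1, a1), .atomStep(r2, a2)),
       nSkipped = res$nSkipped)
}

.emptyStats <- function(nm) {
  list(M = matrix(0, max(nm, 1L), 15L), b = matrix(0, max(nm, 1L), 5L),
       dd = numeric(max(nm, 1L)), cnt = 0L)
}

# absorb resolved records (indices ri of prep) whose endpoints are all
# placed in xyz into per-medium packed stats
.absorbRecords <- function(stats, prep, ri, xyz) {
  if (!length(ri)) return(stats)
  V <- xyz[prep$l2[ri], , drop = FALSE] - xyz[prep$l1[ri], , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  A <- .designRows(V, prep$dmax[ri])
  for (m in unique(prep$med[ri])) {
    i <- ri[prep$med[ri] == m]
    Am <- A[match(i, ri), , drop = FALSE]
    stats$M[m, ] <- stats$M[m, ] +
      colSums(Am[, .PACK_I, drop = FALSE] * Am[, .PACK_J, drop = FALSE])
    stats$b[m, ] <- stats$b[m, ] + colSums(Am * prep$val[i])
    stats$dd[m] <- stats$dd[m] + sum(prep$val[i]^2)
  }
  stats$cnt <- stats$cnt + length(ri)
  stats
}

.statsScore <- function(stats, rcond = 1e-10) {
  if (stats$cnt == 0L) return(0)
  ss <- sum(scorePoolCpp(stats$M, stats$b, stats$dd, rcond))
  sqrt(max(ss, 0) / stats$cnt)
}

# the base fragment: canonical frame N1, CA1, C'1 (+ HA1), no junction yet
.baseFragment <- function(sequence, prep) {
  n <- length(sequence)
  g <- .GEO
  xyz <- matrix(NA_real_, 6L * n, 3L)
  xyz[.aidx(1L, "N"), ] <- c(0, 0, 0)
  xyz[.aidx(1L, "CA"), ] <- c(g$b_NCA, 0, 0)
  a <- g$a_NCAC * .DEG
  xyz[.aidx(1L, "C"), ] <- c(g$b_NCA - g$b_CAC * cos(a), g$b_CAC * sin(a), 0)
  xyz[.aidx(1L, "HA"), ] <- .placeHA(xyz[.aidx(1L, "N"), ],
                                     xyz[.aidx(1L, "CA"), ],
                                     xyz[.aidx(1L, "C"), ])
  stats <- .emptyStats(prep$nm)
  stats <- .absorbRecords(stats, prep, which(prep$step == 0L), xyz)
  list(tors = numeric(0L), key = "", xyz = xyz, stats = stats,
       score = .statsScore(stats))
}

# Atoms placed by junction t, as a plan: list of (name = linear atom index)
# entries with the NeRF recipe. phi/psi may be vectors (K candidates);
# returns list(idx = integer vector, pos = list of K x 3 matrices).
.placeJunction <- function(xyz, sequence, t, phi, psi) {
  g <- .GEO
  n <- length(sequence)
  K <- length(phi)
  at <- function(i, atom) xyz[.aidx(i, atom), ]
  out <- list(); idx <- integer(0L)
  add <- function(i, atom, pos) {
    out[[length(out) + 1L]] <<- pos
    idx[length(idx) + 1L] <<- .aidx(i, atom)
  }
  if (t == 1L) {
    if (sequence[1L] != "P")
      add(1L, "H", .nerfV(at(1L, "C"), at(1L, "CA"), at(1L, "N"),
                          g$b_NH, g$a_CANH, .wrap180(phi + 180)))
    add(1L, "O", .nerfV(at(1L, "N"), at(1L, "CA"), at(1L, "C"),
                        g$b_CO, g$a_CACO, .wrap180(psi + 180)))
    if (n >= 2L) {
      N2 <- .nerfV(at(1L, "N"), at(1L, "CA"), at(1L, "C"),
                   g$b_CN, g$a_CACN, psi)
      add(2L, "N", N2)
      add(2L, "CA", .nerfV(at(1L, "CA"), at(1L, "C"), N2,
                           g$b_NCA, g$a_CNCA, rep(g$omega, K)))
      if (sequence[2L] != "P")
        add(2L, "H", .nerfV(at(1L, "CA"), at(1L, "C"), N2,
                            g$b_NH, g$a_CNH, rep(0, K)))
    }
  } else {
    Ct <- .nerfV(at(t - 1L, "C"), at(t, "N"), at(t, "CA"),
                 g$b_CAC, g$a_NCAC, phi)
    add(t, "C", Ct)
    Nt <- matrix(at(t, "N"), K, 3L, byrow = TRUE)
    CAt <- matrix(at(t, "CA"), K, 3L, byrow = TRUE)
    add(t, "HA", .placeHAV(Nt, CAt, Ct))
    add(t, "O", .nerfV(at(t, "N"), at(t, "CA"), Ct,
                       g$b_CO, g$a_CACO, .wrap180(psi + 180)))
    if (t < n) {
      N2 <- .nerfV(at(t, "N"), at(t, "CA"), Ct, g$b_CN, g$a_CACN, psi)
      add(t + 1L, "N", N2)
      add(t + 1L, "CA", .nerfV(at(t, "CA"), Ct, N2,
                               g$b_NCA, g$a_CNCA, rep(g$omega, K)))
      if (sequence[t + 1L] != "P")
        add(t + 1L, "H", .nerfV(at(t, "CA"), Ct, N2,
                                g$b_NH, g$a_CNH, rep(0, K)))
    }
  }
  names(out) <- as.character(idx)
  list(idx = idx, pos = out)
}

# Score all K candidate (phi, psi) pairs at junction t against a parent
# fragment. `ri` are the prep record indices to absorb at this step (their
# endpoints must be placed atoms or atoms produced by .placeJunction).
# Returns list(scoreSq = K vector of pooled sums of squares, cnt, placed).
.scoreCandidates <- function(frag, prep, t, phi, psi, ri,
                             rcond = 1e-10) {
  K <- length(phi)
  placed <- .placeJunction(frag$xyz, prep$sequence, t, phi, psi)
  getPos <- function(l) {
    j <- match(as.character(l), names(placed$pos))
    if (!is.na(j)) placed$pos[[j]]
    else matrix(frag$xyz[l, ], K, 3L, byrow = TRUE)
  }
  nm <- max(prep$nm, 1L)
  Mk <- lapply(seq_len(nm), function(m)
    matrix(frag$stats$M[m, ], K, 15L, byrow = TRUE))
  Bk <- lapply(seq_len(nm), function(m)
    matrix(frag$stats$b[m, ], K, 5L, byrow = TRUE))
  for (i in ri) {
    V <- getPos(prep$l2[i]) - getPos(prep$l1[i])
    V <- V / sqrt(rowSums(V^2))
    A <- .designRows(V, prep$dmax[i])      # K x 5
    m <- prep$med[i]
    Mk[[m]] <- Mk[[m]] + A[, .PACK_I, drop = FALSE] * A[, .PACK_J, drop = FALSE]
    Bk[[m]] <- Bk[[m]] + A * prep$val[i]
  }
  dd <- frag$stats$dd
  ddAdd <- numeric(nm)
  for (i in ri) ddAdd[prep$med[i]] <- ddAdd[prep$med[i]] + prep$val[i]^2
  ssq <- numeric(K)
  for (m in seq_len(nm))
    ssq <- ssq + scorePoolCpp(Mk[[m]], Bk[[m]],
                              rep(dd[m] + ddAdd[m], K), rcond)
  list(scoreSq = pmax(ssq, 0), cnt = frag$stats$cnt + length(ri),
       placed = placed)
}

# Exact-residual variant used by Stage-I ranking: solves the same
# least-squares problems but evaluates |A s - d|^2 directly from the
# rows, avoiding the catastrophic cancellation of the normal-equation
# identity near zero residual (self-consistent candidates then score at
# machine precision rather than ~1e-7).
.scoreCandidatesExact <- function(frag, prep, t, phi, psi, ri, fixedRi,
                                  rcond = 1e-10) {
  K <- length(phi)
  placed <- .placeJunction(frag$xyz, prep$sequence, t, phi, psi)
  getPos <- function(l) {
    j <- match(as.character(l), names(placed$pos))
    if (!is.na(j)) placed$pos[[j]]
    else matrix(frag$xyz[l, ], K, 3L, byrow = TRUE)
  }
  nm <- max(prep$nm, 1L)
  Afix <- dfix <- mfix <- NULL
  if (length(fixedRi)) {
    V <- frag$xyz[prep$l2[fixedRi], , drop = FALSE] -
      frag$xyz[prep$l1[fixedRi], , drop = FALSE]
    V <- V / sqrt(rowSums(V^2))
    Afix <- .designRows(V, prep$dmax[fixedRi])
    dfix <- prep$val[fixedRi]
    mfix <- prep$med[fixedRi]
  }
  Mk <- lapply(seq_len(nm), function(m) {
    M0 <- numeric(15L)
    if (length(fixedRi) && any(mfix == m)) {
      Am <- Afix[mfix == m, , drop = FALSE]
      M0 <- colSums(Am[, .PACK_I, drop = FALSE] *
                      Am[, .PACK_J, drop = FALSE])
    }
    matrix(M0, K, 15L, byrow = TRUE)
  })
  Bk <- lapply(seq_len(nm), function(m) {
    b0 <- numeric(5L)
    if (length(fixedRi) && any(mfix == m))
      b0 <- colSums(Afix[mfix == m, , drop = FALSE] * dfix[mfix == m])
    matrix(b0, K, 5L, byrow = TRUE)
  })
  stepRows <- vector("list", length(ri))
  for (j in seq_along(ri)) {
    i <- ri[j]
    V <- getPos(prep$l2[i]) - getPos(prep$l1[i])
    V <- V / sqrt(rowSums(V^2))
    A <- .designRows(V, prep$dmax[i])
    m <- prep$med[i]
    Mk[[m]] <- Mk[[m]] + A[, .PACK_I, drop = FALSE] * A[, .PACK_J,
                                                        drop = FALSE]
    Bk[[m]] <- Bk[[m]] + A * prep$val[i]
    stepRows[[j]] <- A
  }
  ssq <- numeric(K)
  for (m in seq_len(nm)) {
    S <- solvePoolCpp(Mk[[m]], Bk[[m]], rcond)
    if (length(fixedRi) && any(mfix == m)) {
      R <- Afix[mfix == m, , drop = FALSE] %*% t(S) - dfix[mfix == m]
      ssq <- ssq + colSums(R^2)
    }
    for (j in seq_along(ri)) {
      i <- ri[j]
      if (prep$med[i] == m)
        ssq <- ssq + (rowSums(stepRows[[j]] * S) - prep$val[i])^2
    }
  }
  list(scoreSq = ssq, cnt = length(fixedRi) + length(ri))
}

# Materialize one surviving child: fill coordinates and update stats.
.materializeChild <- function(frag, prep, t, phi, psi, ri) {
  placed <- .placeJunction(frag$xyz, prep$sequence, t, phi, psi)
  xyz <- frag$xyz
  for (j in seq_along(placed$idx))
    xyz[placed$idx[j], ] <- placed$pos[[j]][1L, ]
  stats <- .absorbRecords(frag$stats, prep, ri, xyz)
  key <- paste0(frag$key, sprintf("%07.2f%07.2f", phi + 360, psi + 360))
  list(tors = c(frag$tors, phi, psi), key = key, xyz = xyz,
       stats = stats, score = .statsScore(stats))
}

# build a partial chain through junctions 1..t with fixed torsions
# (used for canonical Stage-I ranking frames); tors is a 2t vector
.partialChain <- function(sequence, tors, prep = NULL) {
  sequence <- .parseSeq(sequence)
  if (is.null(prep))
    prep <- .prepData(rdcSet(data.frame(residue_1 = integer(0L),
                                        atom_1 = character(0L),
                                        residue_2 = integer(0L),
                                        atom_2 = character(0L),
                                        medium = integer(0L),
                                        value = numeric(0L),
                                        uncertainty = numeric(0L))),
                      sequence)
  frag <- .baseFragment(sequence, prep)
  t <- 0L
  while (2L * t < length(tors)) {
    t <- t + 1L
    frag <- .materializeChild(frag, prep, t, tors[2L * t - 1L],
                              tors[2L * t], which(prep$step == t))
  }
  frag
}

.fragStructure <- function(frag, sequence) {
  new("BackboneStructure", sequence = sequence, coords = frag$xyz)
}
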