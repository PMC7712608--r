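# Peptide-plane geometry: torsion-space chain building, torsion extraction,
# internuclear vectors, backbone RMSD and PDB I/O.
#
# Convention for the undefined terminal torsions: phi(1) has no preceding
# C' and psi(n) no following N, so the builder realizes them as proxy
# orientations -- phi(1) orients the N-terminal amide hydrogen
# (dihedral(C'1, CA1, N1, H1) = phi1 + 180) and psi(n) orients the
# C-terminal carbonyl oxygen (dihedral(N, CA, C', O) = psi + 180, the same
# formula used at every residue). extractTorsions() inverts both, so
# build/extract round-trips cover all residues.

.checkTorsions <- function(torsions, n) {
  if (is.data.frame(torsions)) torsions <- as.matrix(torsions)
  if (is.list(torsions)) torsions <- do.call(rbind, torsions)
  if (is.null(dim(torsions))) torsions <- matrix(torsions, ncol = 2L,
                                                 byrow = TRUE)
  if (nrow(torsions) != n || ncol(torsions) != 2L)
    stop("torsions must provide one (phi, psi) pair per residue (",
         n, " needed, got ", nrow(torsions), ")")
  t <- torsions
  t[1L, 1L] <- if (is.na(t[1L, 1L])) 180 else t[1L, 1L]
  t[n,  2L] <- if (is.na(t[n, 2L])) 180 else t[n, 2L]
  if (anyNA(t)) stop("interior torsion angles must not be NA")
  if (any(t <= -180 - 1e-9 | t > 180 + 1e-9))
    stop("torsion angles must lie in (-180, 180]")
  .wrap180(t)
}

.parseSeq <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  sequence <- toupper(sequence)
  if (!all(sequence %in% .AA1))
    stop("unknown residue letter(s): ",
         paste(unique(setdiff(sequence, .AA1)), collapse = ", "))
  sequence
}

#' Build a backbone chain from torsion angles
#'
#' Elongates ideal trans peptide planes (fixed Engh--Huber-style bonded
#' geometry, omega = 180) according to per-residue (phi, psi) pairs.
#' \code{phi[1]} and \code{psi[n]} are undefined dihedrals; \code{NA} there
#' is accepted and realized as a fixed placeholder orientation (see package
#' vignette). Proline gets no amide hydrogen; glycine a single HA.
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param torsions \code{n x 2} matrix / data.frame (columns phi, psi, in
#'   degrees within \code{(-180, 180]}), or a list of length-2 vectors.
#' @return a \linkS4class{BackboneStructure}.
#' @examples
#' s <- buildChain("AAAA", matrix(c(-60, -45), 4, 2, byrow = TRUE))
#' extractTorsions(s)
#' @export
buildChain <- function(sequence, torsions) {
  sequence <- .parseSeq(sequence)
  n <- length(sequence)
  tor <- .checkTorsions(torsions, n)
  g <- .GEO
  xyz <- matrix(NA_real_, 6L * n, 3L)
  put <- function(i, atom, p) xyz[.aidx(i, atom), ] <<- p
  get1 <- function(i, atom) xyz[.aidx(i, atom), ]

  # canonical frame for residue 1
  put(1L, "N", c(0, 0, 0))
  put(1L, "CA", c(g$b_NCA, 0, 0))
  a <- g$a_NCAC * .DEG
  put(1L, "C", c(g$b_NCA - g$b_CAC * cos(a), g$b_CAC * sin(a), 0))
  if (sequence[1L] != "P")
    put(1L, "H", .nerf(get1(1L, "C"), get1(1L, "CA"), get1(1L, "N"),
                       g$b_NH, g$a_CANH, .wrap180(tor[1L, 1L] + 180)))
  put(1L, "HA", .placeHA(get1(1L, "N"), get1(1L, "CA"), get1(1L, "C")))
  put(1L, "O", .nerf(get1(1L, "N"), get1(1L, "CA"), get1(1L, "C"),
                     g$b_CO, g$a_CACO, .wrap180(tor[1L, 2L] + 180)))

  for (i in seq_len(n)[-1L]) {
    Np <- .nerf(get1(i - 1L, "N"), get1(i - 1L, "CA"), get1(i - 1L, "C"),
                g$b_CN, g$a_CACN, tor[i - 1L, 2L])
    put(i, "N", Np)
    put(i, "CA", .nerf(get1(i - 1L, "CA"), get1(i - 1L, "C"), Np,
                       g$b_NCA, g$a_CNCA, g$omega))
    if (sequence[i] != "P")
      put(i, "H", .nerf(get1(i - 1L, "CA"), get1(i - 1L, "C"), Np,
                        g$b_NH, g$a_CNH, 0))
    put(i, "C", .nerf(get1(i - 1L, "C"), Np, get1(i, "CA"),
                      g$b_CAC, g$a_NCAC, tor[i, 1L]))
    put(i, "HA", .placeHA(Np, get1(i, "CA"), get1(i, "C")))
    put(i, "O", .nerf(Np, get1(i, "CA"), get1(i, "C"),
                      g$b_CO, g$a_CACO, .wrap180(tor[i, 2L] + 180)))
  }
  new("BackboneStructure", sequence = sequence, coords = xyz)
}

#' Append one residue (one peptide plane) to a fragment
#'
#' The existing coordinates are untouched (elongation is append-only): the
#' psi of the current last residue is recovered from its carbonyl-oxygen
#' orientation, the new amide plane is attached at that dihedral, and the
#' supplied (phi, psi) pair completes the new residue.
#'
#' @param fragment a \linkS4class{BackboneStructure}.
#' @param nextResidue one-letter code of the residue to append.
#' @param tp numeric length-2 (phi, psi) in degrees for the new residue.
#' @return a \linkS4class{BackboneStructure} with one more residue.
#' @export
extendFragment <- function(fragment, nextResidue, tp) {
  stopifnot(is(fragment, "BackboneStructure"))
  nextResidue <- .parseSeq(nextResidue)
  if (length(nextResidue) != 1L) stop("one residue at a time")
  if (length(tp) != 2L || anyNA(tp))
    stop("tp must be a (phi, psi) pair")
  if (any(tp <= -180 - 1e-9 | tp > 180 + 1e-9))
    stop("torsion angles must lie in (-180, 180]")
  g <- .GEO
  n <- nResidues(fragment)
  xyz <- rbind(fragment@coords, matrix(NA_real_, 6L, 3L))
  get1 <- function(i, atom) xyz[.aidx(i, atom), ]
  if (anyNA(get1(n, "O")))
    stop("fragment's last residue has no carbonyl oxygen; cannot elongate")
  psiPrev <- .wrap180(.dihedral(get1(n, "N"), get1(n, "CA"),
                                get1(n, "C"), get1(n, "O")) - 180)
  i <- n + 1L
  Np <- .nerf(get1(n, "N"), get1(n, "CA"), get1(n, "C"),
              g$b_CN, g$a_CACN, psiPrev)
  xyz[.aidx(i, "N"), ] <- Np
  xyz[.aidx(i, "CA"), ] <- .nerf(get1(n, "CA"), get1(n, "C"), Np,
                                 g$b_NCA, g$a_CNCA, g$omega)
  if (nextResidue != "P")
    xyz[.aidx(i, "H"), ] <- .nerf(get1(n, "CA"), get1(n, "C"), Np,
                                  g$b_NH, g$a_CNH, 0)
  xyz[.aidx(i, "C"), ] <- .nerf(get1(n, "C"), Np, get1(i, "CA"),
                                g$b_CAC, g$a_NCAC, tp[1L])
  xyz[.aidx(i, "HA"), ] <- .placeHA(Np, get1(i, "CA"), get1(i, "C"))
  xyz[.aidx(i, "O"), ] <- .nerf(Np, get1(i, "CA"), get1(i, "C"),
                                g$b_CO, g$a_CACO, .wrap180(tp[2L] + 180))
  new("BackboneStructure", sequence = c(fragment@sequence, nextResidue),
      coords = xyz)
}

#' Extract per-residue (phi, psi) torsions
#'
#' phi(i) = dihedral(C'(i-1), N(i), CA(i), C'(i)); psi(i) = dihedral(N(i),
#' CA(i), C'(i), N(i+1)). The terminal proxies phi(1) and psi(n) are read
#' back from the H1 and O(n) orientations (NA when those atoms are absent).
#'
#' @param s a \linkS4class{BackboneStructure} with at least 2 residues.
#' @return \code{n x 2} matrix with columns \code{phi}, \code{psi} (degrees).
#' @export
extractTorsions <- function(s) {
  stopifnot(is(s, "BackboneStructure"))
  n <- nResidues(s)
  if (n < 2L) stop("need at least 2 residues")
  xyz <- s@coords
  get1 <- function(i, atom) {
    p <- xyz[.aidx(i, atom), ]
    if (anyNA(p)) stop("missing backbone atom ", atom, " at residue ", i)
    p
  }
  has <- function(i, atom) !anyNA(xyz[.aidx(i, atom), ])
  tor <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(n)) {
    if (i == 1L) {
      if (has(1L, "H") && has(1L, "C"))
        tor[1L, 1L] <- .wrap180(.dihedral(get1(1L, "C"), get1(1L, "CA"),
                                          get1(1L, "N"), get1(1L, "H")) - 180)
    } else {
      tor[i, 1L] <- .dihedral(get1(i - 1L, "C"), get1(i, "N"),
                              get1(i, "CA"), get1(i, "C"))
    }
    if (i < n) {
      tor[i, 2L] <- .dihedral(get1(i, "N"), get1(i, "CA"),
                              get1(i, "C"), get1(i + 1L, "N"))
    } else if (has(n, "O") && has(n, "C")) {
      tor[n, 2L] <- .wrap180(.dihedral(get1(n, "N"), get1(n, "CA"),
                                       get1(n, "C"), get1(n, "O")) - 180)
    }
  }
  tor
}

#' Unit internuclear vector between two backbone atoms
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param residue_i,residue_j 1-based residue indices.
#' @param atom_i,atom_j backbone atom names (N, H, CA, HA, C, O).
#' @return unit 3-vector from atom i to atom j.
#' @export
internuclearVector <- function(s, residue_i, atom_i, residue_j, atom_j) {
  stopifnot(is(s, "BackboneStructure"))
  n <- nResidues(s)
  if (residue_i < 1L || residue_i > n || residue_j < 1L || residue_j > n)
    stop("residue index out of range")
  p1 <- s@coords[.aidx(residue_i, atom_i), ]
  p2 <- s@coords[.aidx(residue_j, atom_j), ]
  if (anyNA(p1) || anyNA(p2))
    stop("atom not placed: ", atom_i, "(", residue_i, ") or ",
         atom_j, "(", residue_j, ")")
  .unitv(p2 - p1)
}

.kabsch <- function(P, Q) {
  # returns rotation matrix (proper, det = +1) aligning centered P onto Q
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Backbone RMSD after optimal rigid superposition
#'
#' Kabsch closed-form superposition (proper rotations only) over the
#' backbone atoms N, CA, C' of all residues, in Angstrom.
#'
#' @param a,b \linkS4class{BackboneStructure} objects with equal residue
#'   counts.
#' @return non-negative RMSD in Angstrom.
#' @export
bbRmsd <- function(a, b) {
  stopifnot(is(a, "BackboneStructure"), is(b, "BackboneStructure"))
  if (nResidues(a) != nResidues(b))
    stop("structures have different residue counts (",
         nResidues(a), " vs ", nResidues(b), ")")
  idx <- .aidx(rep(seq_len(nResidues(a)), each = 3L),
               rep(c("N", "CA", "C"), nResidues(a)))
  P <- a@coords[idx, , drop = FALSE]
  Q <- b@coords[idx, , drop = FALSE]
  ok <- stats::complete.cases(P) & stats::complete.cases(Q)
  if (sum(ok) < 3L) stop("fewer than 3 shared placed backbone atoms")
  P <- P[ok, , drop = FALSE]; Q <- Q[ok, , drop = FALSE]
  P <- sweep(P, 2L, colMeans(P)); Q <- sweep(Q, 2L, colMeans(Q))
  R <- .kabsch(P, Q)
  sqrt(sum((P %*% R - Q)^2) / nrow(P))
}

#' Write a backbone structure to a PDB file
#'
#' Single chain, single model; ATOM records with element columns. Unplaced
#' atoms (e.g. proline amide H) are omitted.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePdb <- function(s, path) {
  stopifnot(is(s, "BackboneStructure"))
  n <- nResidues(s)
  res <- rep(seq_len(n), each = 6L)
  ele <- rep(.ATOMS, n)
  keep <- stats::complete.cases(s@coords)
  xyz <- as.vector(t(s@coords[keep, , drop = FALSE]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = res[keep],
                   resid = .aa1to3(s@sequence)[res[keep]],
                   eleno = seq_len(sum(keep)),
                   elety = ele[keep],
                   chain = rep("A", sum(keep)),
                   o = rep(1, sum(keep)), b = rep(0, sum(keep)),
                   elesy = substr(ele[keep], 1L, 1L))
  invisible(path)
}

#' Read a backbone structure from a PDB file
#'
#' Reads ATOM records of the first chain / first model; amide and alpha
#' hydrogens are rebuilt from ideal geometry when absent from the file.
#'
#' @param path PDB file path.
#' @param chain chain identifier; default: first chain present.
#' @return a \linkS4class{BackboneStructure}.
#' @export
readPdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  resnos <- unique(at$resno)
  n <- length(resnos)
  if (n < 1L) stop("no residues found for chain ", chain)
  seq1 <- character(n)
  xyz <- matrix(NA_real_, 6L * n, 3L)
  alias <- list(N = "N", H = c("H", "HN", "H1"), CA = "CA",
                HA = c("HA", "HA2", "1HA"), C = "C", O = c("O", "O1", "OT1"))
  for (k in seq_len(n)) {
    rows <- at[at$resno == resnos[k], , drop = FALSE]
    seq1[k] <- .aa3to1(rows$resid[1L])
    for (atom in .ATOMS) {
      m <- rows[rows$elety %in% alias[[atom]], , drop = FALSE]
      if (nrow(m))
        xyz[.aidx(k, atom), ] <- as.numeric(m[1L, c("x", "y", "z")])
    }
    if (anyNA(xyz[.aidx(k, "N"), ]) || anyNA(xyz[.aidx(k, "CA"), ]) ||
        anyNA(xyz[.aidx(k, "C"), ]))
      stop("residue ", resnos[k], ": backbone N/CA/C incomplete")
  }
  if (any(seq1 == "X"))
    stop("non-standard residue(s): ",
         paste(unique(at$resid[.aa3to1(at$resid) == "X"]), collapse = ", "))
  g <- .GEO
  get1 <- function(i, atom) xyz[.aidx(i, atom), ]
  for (k in seq_len(n)) {
    if (anyNA(get1(k, "HA")))
      xyz[.aidx(k, "HA"), ] <- .placeHA(get1(k, "N"), get1(k, "CA"),
                                        get1(k, "C"))
    if (anyNA(get1(k, "H")) && seq1[k] != "P") {
      if (k == 1L)
        xyz[.aidx(1L, "H"), ] <- .nerf(get1(1L, "C"), get1(1L, "CA"),
                                       get1(1L, "N"), g$b_NH, g$a_CANH, 0)
      else
        xyz[.aidx(k, "H"), ] <- .nerf(get1(k - 1L, "CA"), get1(k - 1L, "C"),
                                      get1(k, "N"), g$b_NH, g$a_CNH, 0)
    }
  }
  new("BackboneStructure", sequence = seq1, coords = xyz)
}

#' Apply a rigid-body motion to a structure
#'
#' Utility mainly used in invariance checks: rotates (proper rotation) and
#' translates all placed atoms.
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation vector.
#' @return the transformed \linkS4class{BackboneStructure}.
#' @export
transformStructure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is(s, "BackboneStructure"))
  if (abs(det(R) - 1) > 1e-8) stop("R must be a proper rotation")
  xyz <- s@coords %*% t(R)
  xyz <- sweep(xyz, 2L, -t)
  new("BackboneStructure", sequence = s@sequence, coords = xyz)
}
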