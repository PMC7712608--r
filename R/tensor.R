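# Dipolar-coupling math: maximal couplings, back-calculation through a
# Saupe order tensor, least-squares tensor estimation and the pooled
# RMS fitness score.
#
# Couplings are kept in raw Hz. Each record's maximal coupling dmax (set by
# the gyromagnetic ratios and the fixed internuclear distance of its vector
# type) is folded into the design-matrix row, so mixed vector types share a
# single dimensionless order tensor per alignment medium:
#   D = dmax * v' S v,   rows  dmax * [vx^2-vz^2, vy^2-vz^2,
#                                      2 vx vy, 2 vx vz, 2 vy vz].

.vtypeTable <- function() {
  g <- .GEO
  r_CH <- sqrt(g$b_CN^2 + g$b_NH^2 -
               2 * g$b_CN * g$b_NH * cos(g$a_CNH * .DEG))
  data.frame(
    type   = c("N-H", "CA-HA", "CA-C", "C-O", "N-CA", "C-N", "C-H"),
    atom_1 = c("N", "CA", "CA", "C", "N", "C", "C"),
    atom_2 = c("H", "HA", "C", "O", "CA", "N", "H"),
    offset = c(0L, 0L, 0L, 0L, 0L, 1L, 1L),
    r      = c(g$b_NH, g$b_CAHA, g$b_CAC, g$b_CO, g$b_NCA, g$b_CN, r_CH),
    stringsAsFactors = FALSE)
}

#' Supported backbone RDC vector types
#'
#' The registry of backbone atom pairs with fixed internuclear distance.
#' Cross-residue pairs carry \code{offset = residue_2 - residue_1 = 1}
#' (C'(i)-N(i+1) and C'(i)-H(i+1)). Pairs are recognised in either atom
#' order. The maximal coupling is computed from the gyromagnetic ratios of
#' the atoms' elements (1H, 13C, 15N, 17O) and the tabulated distance.
#'
#' @return data.frame with columns type, atom_1, atom_2, offset, r
#'   (Angstrom), gamma_1, gamma_2 (rad s^-1 T^-1) and dmax (Hz).
#' @examples
#' vectorTypes()
#' @export
vectorTypes <- function() {
  tab <- .vtypeTable()
  tab$gamma_1 <- .PHYS$gamma[substr(tab$atom_1, 1L, 1L)]
  tab$gamma_2 <- .PHYS$gamma[substr(tab$atom_2, 1L, 1L)]
  tab$dmax <- mapply(function(g1, g2, r) dmax(list(gamma_1 = g1,
                                                   gamma_2 = g2, r = r)),
                     tab$gamma_1, tab$gamma_2, tab$r)
  rownames(tab) <- tab$type
  tab
}

#' Maximal dipolar coupling for a vector type
#'
#' \code{dmax = -mu0 * gamma_1 * gamma_2 * h / (2 pi r)^3} in Hz, with h the
#' Planck constant and r the fixed internuclear distance. A signed scalar:
#' the N-H coupling constant is positive (gamma(15N) < 0).
#'
#' @param spec a vector-type name from \code{\link{vectorTypes}} (e.g.
#'   \code{"N-H"}), or a list with elements \code{gamma_1}, \code{gamma_2}
#'   (rad s^-1 T^-1) and \code{r} (Angstrom).
#' @return maximal coupling in Hz.
#' @examples
#' dmax("N-H")
#' @export
dmax <- function(spec) {
  if (is.character(spec)) {
    tab <- vectorTypes()
    if (!spec %in% tab$type)
      stop("unknown vector type '", spec, "' (supported: ",
           paste(tab$type, collapse = ", "), ")")
    return(tab[spec, "dmax"])
  }
  stopifnot(is.list(spec), all(c("gamma_1", "gamma_2", "r") %in% names(spec)))
  if (spec$r <= 0) stop("internuclear distance r must be > 0")
  r_m <- spec$r * 1e-10
  -.PHYS$mu0 * spec$gamma_1 * spec$gamma_2 * .PHYS$h / (2 * pi * r_m)^3
}

.designRows <- function(V, dmaxs) {
  # V: K x 3 unit vectors; dmaxs: scalar or length K. Returns K x 5.
  if (is.null(dim(V))) V <- matrix(V, 1L, 3L)
  cbind(V[, 1L]^2 - V[, 3L]^2,
        V[, 2L]^2 - V[, 3L]^2,
        2 * V[, 1L] * V[, 2L],
        2 * V[, 1L] * V[, 3L],
        2 * V[, 2L] * V[, 3L]) * dmaxs
}

#' Back-calculate an RDC from a unit vector and an order tensor
#'
#' \code{D = dmax * v' S v} (Hz). Invariant under \code{v -> -v}.
#'
#' @param v unit 3-vector (checked to within 1e-6).
#' @param S a \linkS4class{SaupeTensor}.
#' @param spec vector-type name, spec list (see \code{\link{dmax}}), or a
#'   numeric maximal coupling in Hz.
#' @return coupling in Hz.
#' @export
backCalc <- function(v, S, spec) {
  stopifnot(is(S, "SaupeTensor"), length(v) == 3L)
  if (abs(sqrt(sum(v * v)) - 1) > 1e-6)
    stop("v must be a unit vector")
  dm <- if (is.numeric(spec)) spec else dmax(spec)
  drop(.designRows(v, dm) %*% S@s)
}

#' Least-squares Saupe tensor from vectors and couplings
#'
#' Solves the linear system in the five independent tensor components by
#' singular-value pseudo-inverse (relative cutoff 1e-10): the unique
#' least-squares solution when five or more independent rows are present,
#' and the minimum-norm solution for under-determined early fragments.
#'
#' @param vectors \code{K x 3} matrix of unit vectors (rows).
#' @param rdcs length-K couplings in Hz.
#' @param specs vector-type names, a numeric vector of maximal couplings
#'   (recycled if scalar), or a list of spec lists.
#' @return a \linkS4class{SaupeTensor}.
#' @export
fitTensor <- function(vectors, rdcs, specs) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 3L,
                                               byrow = TRUE)
  K <- nrow(vectors)
  if (K < 1L || length(rdcs) != K) stop("need >= 1 RDC, one per vector")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("vectors must be unit norm")
  dm <- if (is.numeric(specs)) rep_len(specs, K)
        else vapply(as.list(specs), dmax, numeric(1L))
  A <- .designRows(vectors, dm)
  s <- .pinvSolve(A, rdcs)
  saupeTensor(s[1L], s[2L], s[3L], s[4L], s[5L])
}

.pinvSolve <- function(A, d, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * max(sv$d, 0)
  if (!any(keep)) return(numeric(ncol(A)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], d)) / sv$d[keep]))
}

# Resolve raw records against a sequence: linear atom indices, dmax, type.
# Unresolvable rows (unknown pair, residue out of range, proline amide H)
# are dropped and counted.
.resolveRecords <- function(rec, sequence) {
  n <- length(sequence)
  tab <- vectorTypes()
  key <- paste(tab$atom_1, tab$atom_2, tab$offset)
  keyR <- paste(tab$atom_2, tab$atom_1, -tab$offset)
  off <- rec$residue_2 - rec$residue_1
  k <- match(paste(rec$atom_1, rec$atom_2, off), key)
  kR <- match(paste(rec$atom_1, rec$atom_2, off), keyR)
  type <- ifelse(!is.na(k), tab$type[k], tab$type[kR])
  ok <- !is.na(type)
  inRange <- rec$residue_1 >= 1L & rec$residue_1 <= n &
             rec$residue_2 >= 1L & rec$residue_2 <= n
  pro <- rep(FALSE, nrow(rec))
  if (nrow(rec)) {
    r1in <- pmin(pmax(rec$residue_1, 1L), n)
    r2in <- pmin(pmax(rec$residue_2, 1L), n)
    pro <- (rec$atom_1 == "H" & sequence[r1in] == "P" & inRange) |
           (rec$atom_2 == "H" & sequence[r2in] == "P" & inRange)
  }
  use <- ok & inRange & !pro
  out <- rec[use, , drop = FALSE]
  list(records = out,
       l1 = .aidx(out$residue_1, out$atom_1),
       l2 = .aidx(out$residue_2, out$atom_2),
       dmax = tab[type[use], "dmax"],
       type = type[use],
       nSkipped = sum(!use),
       nUnknownPair = sum(!ok),
       nOutOfRange = sum(ok & !inRange),
       nProlineH = sum(ok & inRange & pro))
}

#' RDC fitness of a structure (pooled RMS deviation)
#'
#' For each alignment medium the best-fit order tensor is estimated from
#' the structure's internuclear vectors and that medium's couplings; the
#' squared deviations between measured and back-calculated couplings are
#' then pooled over all media and couplings and returned as a
#' root-mean-square in Hz (the number of pooled terms -- M x N for balanced
#' media -- is the denominator). Records referencing residues outside the
#' structure, or atoms not (yet) placed, are skipped and counted, which is
#' the normal situation while a fragment is being elongated.
#'
#' @param structure a \linkS4class{BackboneStructure}.
#' @param data an \linkS4class{RdcSet} (or bare data.frame of records).
#' @param weighted if TRUE, residuals are weighted by 1/uncertainty^2 in
#'   the tensor fit (couplings with zero/NA uncertainty get unit weight);
#'   the reported score stays unweighted. Default FALSE.
#' @return a list of class \code{FitnessScore}: \code{value} (Hz),
#'   \code{nRdcs} (couplings used), \code{nMedia}, \code{nSkipped}, and
#'   per-medium tensors in \code{tensors}.
#' @export
rdcFitness <- function(structure, data, weighted = FALSE) {
  stopifnot(is(structure, "BackboneStructure"))
  rec <- if (is(data, "RdcSet")) data@records else data
  res <- .resolveRecords(rec, structure@sequence)
  xyz <- structure@coords
  placed <- stats::complete.cases(xyz)
  ok <- placed[res$l1] & placed[res$l2]
  nSkip <- res$nSkipped + sum(!ok)
  l1 <- res$l1[ok]; l2 <- res$l2[ok]
  dm <- res$dmax[ok]
  rr <- res$records[ok, , drop = FALSE]
  if (!nrow(rr))
    return(structure(list(value = 0, nRdcs = 0L, nMedia = 0L,
                          nSkipped = nSkip, tensors = list()),
                     class = "FitnessScore"))
  V <- xyz[l2, , drop = FALSE] - xyz[l1, , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  A <- .designRows(V, dm)
  media <- sort(unique(rr$medium))
  ss <- 0; tensors <- list()
  for (m in media) {
    i <- rr$medium == m
    Am <- A[i, , drop = FALSE]
    d <- rr$value[i]
    if (weighted) {
      w <- 1 / rr$uncertainty[i]^2
      w[!is.finite(w)] <- 1
      s <- .pinvSolve(Am * sqrt(w), d * sqrt(w))
    } else {
      s <- .pinvSolve(Am, d)
    }
    tensors[[as.character(m)]] <- saupeTensor(s[1L], s[2L], s[3L],
                                              s[4L], s[5L])
    ss <- ss + sum((drop(Am %*% s) - d)^2)
  }
  structure(list(value = sqrt(ss / nrow(rr)), nRdcs = nrow(rr),
                 nMedia = length(media), nSkipped = nSkip,
                 tensors = tensors),
            class = "FitnessScore")
}

#' @export
print.FitnessScore <- function(x, ...) {
  cat(sprintf(
    "RDC fitness: %.4g Hz over %d coupling(s) in %d medium/media (%d skipped)\n",
    x$value, x$nRdcs, x$nMedia, x$nSkipped))
  invisible(x)
}
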