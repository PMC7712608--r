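# Internal vector geometry and physical constants. Angles in degrees
# everywhere at the API surface; radians only inside these helpers.

.DEG <- pi / 180

.ATOMS <- c("N", "H", "CA", "HA", "C", "O")

# Fixed bonded geometry (Engh--Huber-style ideal values, Angstrom / degrees).
.GEO <- list(
  b_NCA  = 1.458, b_CAC = 1.525, b_CN = 1.329,
  b_NH   = 1.020, b_CAHA = 1.090, b_CO = 1.231,
  a_NCAC = 111.2,  # N-CA-C
  a_CACN = 116.2,  # CA-C-N(+1)
  a_CNCA = 121.7,  # C(-1)-N-CA
  a_CACO = 120.8,  # CA-C-O
  a_CNH  = 119.0,  # C(-1)-N-H
  a_CANH = 119.3,  # CA-N-H (planar closure, used for the N-terminal amide)
  a_NCAHA = 109.5, # target N-CA-HA
  omega  = 180     # trans peptide bond
)

# Physical constants for Eq.-style dmax: -mu0*g1*g2*h / (2*pi*r)^3.
# Gyromagnetic ratios in rad s^-1 T^-1; h is the Planck constant (J s);
# mu0 in T^2 m^3 J^-1. r is supplied in Angstrom and converted to m.
.PHYS <- list(
  mu0 = 1.25663706212e-6,
  h   = 6.62607015e-34,
  gamma = c(H = 2.6752218744e8, C = 6.728284e7, N = -2.7126e7,
            O = -3.62808e7)  # O as 17O
)

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
.AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

.aa1to3 <- function(x) {
  i <- match(x, .AA1)
  if (anyNA(i)) stop("unknown residue letter(s): ",
                     paste(unique(x[is.na(i)]), collapse = ", "))
  .AA3[i]
}

.aa3to1 <- function(x) {
  i <- match(toupper(x), .AA3)
  ifelse(is.na(i), "X", .AA1[i])
}

.wrap180 <- function(x) {
  # map to (-180, 180]
  y <- x - 360 * floor((x + 180) / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

.angdiff <- function(a, b) .wrap180(a - b)

.vnorm <- function(v) sqrt(sum(v * v))

.unitv <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.angle3 <- function(p1, p2, p3) {
  u <- .unitv(p1 - p2); v <- .unitv(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / .DEG
}

# Signed dihedral p1-p2-p3-p4 in (-180, 180], IUPAC convention.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("dihedral undefined: collinear atoms")
  m1 <- .cross3(n1, .unitv(b2))
  .wrap180(atan2(sum(m1 * n2), sum(n1 * n2)) / .DEG)
}

# Natural-extension (NeRF) placement: atom D bonded to C, with bond length r,
# angle(B, C, D) = theta and dihedral(A, B, C, D) = chi.
.nerf <- function(A, B, C, r, theta, chi) {
  bc <- .unitv(C - B)
  n  <- .unitv(.cross3(B - A, bc))
  m  <- .cross3(n, bc)
  th <- theta * .DEG; ch <- chi * .DEG
  d  <- r * c(-cos(th), sin(th) * cos(ch), -sin(th) * sin(ch))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Vectorized NeRF over K dihedrals (and optionally K reference frames).
# A, B, C: 3-vectors or K x 3 matrices; chi: length-K vector. Returns K x 3.
.nerfV <- function(A, B, C, r, theta, chi) {
  K <- length(chi)
  toM <- function(p) if (is.matrix(p)) p else matrix(p, K, 3L, byrow = TRUE)
  A <- toM(A); B <- toM(B); C <- toM(C)
  bc <- C - B
  bc <- bc / sqrt(rowSums(bc * bc))
  ab <- B - A
  n <- cbind(ab[, 2L] * bc[, 3L] - ab[, 3L] * bc[, 2L],
             ab[, 3L] * bc[, 1L] - ab[, 1L] * bc[, 3L],
             ab[, 1L] * bc[, 2L] - ab[, 2L] * bc[, 1L])
  n <- n / sqrt(rowSums(n * n))
  m <- cbind(n[, 2L] * bc[, 3L] - n[, 3L] * bc[, 2L],
             n[, 3L] * bc[, 1L] - n[, 1L] * bc[, 3L],
             n[, 1L] * bc[, 2L] - n[, 2L] * bc[, 1L])
  th <- theta * .DEG; ch <- chi * .DEG
  C + r * (-cos(th)) * bc + (r * sin(th) * cos(ch)) * m -
    (r * sin(th) * sin(ch)) * n
}

# HA direction off CA: in the plane bisecting N-CA-C, out-of-plane component
# chosen on the side matching L-amino-acid backbone hydrogens. u1 = CA->N,
# u2 = CA->C unit vectors (rows for the vectorized form).
.placeHA <- function(Npos, CApos, Cpos) {
  u1 <- .unitv(Npos - CApos); u2 <- .unitv(Cpos - CApos)
  b <- -(u1 + u2); b <- .unitv(b)
  p <- .unitv(.cross3(u2, u1))
  d <- .unitv(.HA_ALPHA * b + .HA_BETA * p)
  CApos + .GEO$b_CAHA * d
}

# coefficients so that angle(N, CA, HA) = angle(C, CA, HA) = a_NCAHA given
# a_NCAC; see vignette. Computed once at load time.
.haCoef <- function() {
  c12 <- cos(.GEO$a_NCAC * .DEG)
  mdotu <- -(1 + c12) / sqrt(2 + 2 * c12)
  alpha <- cos(.GEO$a_NCAHA * .DEG) / mdotu
  beta <- sqrt(max(0, 1 - alpha^2))
  c(alpha, beta)
}
.HA_ALPHA <- .haCoef()[1L]
.HA_BETA  <- .haCoef()[2L]

.placeHAV <- function(Npos, CApos, Cpos) {
  u1 <- Npos - CApos; u1 <- u1 / sqrt(rowSums(u1 * u1))
  u2 <- Cpos - CApos; u2 <- u2 / sqrt(rowSums(u2 * u2))
  b <- -(u1 + u2); b <- b / sqrt(rowSums(b * b))
  p <- cbind(u2[, 2L] * u1[, 3L] - u2[, 3L] * u1[, 2L],
             u2[, 3L] * u1[, 1L] - u2[, 1L] * u1[, 3L],
             u2[, 1L] * u1[, 2L] - u2[, 2L] * u1[, 1L])
  p <- p / sqrt(rowSums(p * p))
  d <- .HA_ALPHA * b + .HA_BETA * p
  d <- d / sqrt(rowSums(d * d))
  CApos + .GEO$b_CAHA * d
}

# linear atom index into the 6n x 3 coordinate matrix
.aidx <- function(res, atom) {
  a <- match(atom, .ATOMS)
  if (anyNA(a)) stop("unknown backbone atom name(s): ",
                     paste(unique(atom[is.na(a)]), collapse = ", "),
                     " (supported: ", paste(.ATOMS, collapse = ", "), ")")
  (res - 1L) * 6L + a
}
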