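# Independent oracles used across the suite.

# Rodrigues-rotation chain builder: an alternative to the package's
# internal frame-based placement. Atom D is placed by taking the extension
# of B->C, bending it by (180 - theta) about the normal of the A-B-C
# plane, then twisting by chi about the B->C axis.
.rotAxis <- function(axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

oraclePlace <- function(A, B, C, r, theta, chi) {
  bc <- (C - B) / sqrt(sum((C - B)^2))
  nrm <- c(
    (B - A)[2] * bc[3] - (B - A)[3] * bc[2],
    (B - A)[3] * bc[1] - (B - A)[1] * bc[3],
    (B - A)[1] * bc[2] - (B - A)[2] * bc[1])
  d0 <- .rotAxis(nrm, 180 - theta) %*% bc
  d1 <- .rotAxis(bc, -chi) %*% d0
  C + r * drop(d1)
}

# backbone N, CA, C chain from (phi, psi), trans peptide, same ideal
# geometry table as the package but a different placement algorithm
oracleChain <- function(n, phi, psi) {
  g <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329,
            a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7)
  xyz <- matrix(NA_real_, 3 * n, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$b_NCA, 0, 0)
  a <- g$a_NCAC * pi / 180
  xyz[3, ] <- xyz[2, ] + g$b_CAC * c(-cos(a), sin(a), 0)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  for (i in 2:n) {
    N <- oraclePlace(xyz[3 * i - 8 + 3, ], xyz[3 * i - 7 + 3, ],
                     xyz[3 * i - 6 + 3, ],
                     g$b_CN, g$a_CACN, psi[i - 1])
    CA <- oraclePlace(xyz[3 * i - 7 + 3, ], xyz[3 * i - 6 + 3, ], N,
                      g$b_NCA, g$a_CNCA, 180)
    C <- oraclePlace(xyz[3 * i - 6 + 3, ], N, CA,
                     g$b_CAC, g$a_NCAC, phi[i])
    xyz[3 * i - 2, ] <- N; xyz[3 * i - 1, ] <- CA; xyz[3 * i, ] <- C
  }
  xyz
}

# brute-force minimum RMSD over a dense rotation grid (tiny point sets)
bruteRmsd <- function(P, Q, stepDeg = 3) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  ang <- seq(0, 360 - stepDeg, by = stepDeg) * pi / 180
  half <- seq(0, 180, by = stepDeg) * pi / 180
  best <- Inf
  for (a in ang) for (b in half) for (c in ang) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    R <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(sum((P %*% R - Q)^2) / nrow(P))
    if (v < best) best <- v
  }
  best
}

randomRotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-8) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

randomTracelessTensor <- function() {
  saupeTensor(runif(1, -5e-4, 5e-4), runif(1, -5e-4, 5e-4),
              runif(1, -3e-4, 3e-4), runif(1, -3e-4, 3e-4),
              runif(1, -3e-4, 3e-4))
}

helixN <- function(n, phi = -60, psi = -45, seq1 = strrep("A", n)) {
  buildChain(seq1, matrix(c(phi, psi), n, 2, byrow = TRUE))
}
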