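test_that("dmax follows the dipolar scaling laws and frozen constants", {
  expect_equal(dmax(list(gamma_1 = 0, gamma_2 = 2.675e8, r = 1.02)), 0)
  base <- dmax(list(gamma_1 = 1e8, gamma_2 = 1e8, r = 1.0))
  expect_equal(dmax(list(gamma_1 = 1e8, gamma_2 = 1e8, r = 2.0)),
               base / 8, tolerance = 1e-12)
  expect_error(dmax(list(gamma_1 = 1, gamma_2 = 1, r = 0)), "r must be")
  # frozen values from an independent hand evaluation of
  # -mu0*g1*g2*h/(2*pi*r)^3 with g(1H) = 2.6752218744e8,
  # g(15N) = -2.7126e7, g(13C) = 6.728284e7 rad/s/T
  expect_equal(dmax("N-H"), 22954.685, tolerance = 1e-6)
  expect_equal(dmax("CA-HA"), -46656.367, tolerance = 1e-6)
  expect_equal(dmax("N-H") / dmax("CA-HA"), -0.4919947, tolerance = 1e-6)
  expect_error(dmax("CB-HB"), "unknown vector type")
})

test_that("backCalc is the scaled quadratic form, even in v", {
  S <- saupeTensor(2e-4, -1e-4, 5e-5, -3e-5, 8e-5)
  # axis evaluation picks out diagonal elements
  m <- saupeMatrix(S)
  for (ax in 1:3) {
    v <- c(0, 0, 0); v[ax] <- 1
    expect_equal(backCalc(v, S, 1000), 1000 * m[ax, ax],
                 tolerance = 1e-12)
  }
  # tracelessness: axis back-calculations sum to zero
  expect_equal(backCalc(c(1, 0, 0), S, "N-H") +
                 backCalc(c(0, 1, 0), S, "N-H") +
                 backCalc(c(0, 0, 1), S, "N-H"), 0, tolerance = 1e-9)
  set.seed(3)
  for (k in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    S <- randomTracelessTensor()
    direct <- dmax("N-H") * drop(t(v) %*% saupeMatrix(S) %*% v)
    expect_equal(backCalc(v, S, "N-H"), direct, tolerance = 1e-10)
    expect_equal(backCalc(-v, S, "N-H"), backCalc(v, S, "N-H"),
                 tolerance = 1e-12)
  }
  expect_error(backCalc(c(1, 1, 0), S, "N-H"), "unit")
})

test_that("fitTensor recovers generating tensors and degenerate cases", {
  set.seed(5)
  for (k in 1:5) {
    S <- randomTracelessTensor()
    V <- matrix(rnorm(60), 20, 3)
    V <- V / sqrt(rowSums(V^2))
    d <- apply(V, 1, backCalc, S = S, spec = "N-H")
    Sf <- fitTensor(V, d, "N-H")
    expect_equal(saupeMatrix(Sf), saupeMatrix(S), tolerance = 1e-9)
    expect_equal(sum(diag(saupeMatrix(Sf))), 0)
    # scale equivariance
    S2 <- fitTensor(V, 3 * d, "N-H")
    expect_equal(saupeMatrix(S2), 3 * saupeMatrix(S), tolerance = 1e-9)
  }
  # all-zero couplings with independent vectors give the null tensor
  V <- matrix(rnorm(30), 10, 3); V <- V / sqrt(rowSums(V^2))
  expect_equal(max(abs(saupeMatrix(fitTensor(V, rep(0, 10), "N-H")))), 0)
  # exactly five independent rows: equals the dense direct solve
  set.seed(9)
  repeat {
    V5 <- matrix(rnorm(15), 5, 3); V5 <- V5 / sqrt(rowSums(V5^2))
    A <- rdcfold:::.designRows(V5, dmax("N-H"))
    if (abs(det(A)) > 1e-4) break
  }
  d5 <- rnorm(5)
  expect_equal(fitTensor(V5, d5, "N-H")@s,
               setNames(solve(A, d5), c("Sxx", "Syy", "Sxy", "Sxz", "Syz")),
               tolerance = 1e-9)
  expect_error(fitTensor(matrix(numeric(0), 0, 3), numeric(0), "N-H"),
               ">= 1 RDC")
})

test_that("fitness is zero on self-consistent data and pools per the RMS formula", {
  s <- helixN(10, seq1 = "AEKLHDRVNQ")
  data <- simulateRdcs(s)
  f <- rdcFitness(s, data)
  expect_lt(f$value, 1e-9)
  expect_identical(f$nMedia, 2L)
  # pooled arithmetic: perturb the couplings of one medium by a vector in
  # the orthogonal complement of the design column space, so the fit is
  # unchanged and the residuals equal the perturbation exactly
  rec <- rdcRecords(data)
  m1 <- which(rec$medium == 1L)
  res <- rdcfold:::.resolveRecords(rec[m1, ], residueSequence(s))
  xyz <- atomCoords(s)
  V <- xyz[res$l2, ] - xyz[res$l1, ]
  V <- V / sqrt(rowSums(V^2))
  A <- rdcfold:::.designRows(V, res$dmax)
  set.seed(21)
  z <- rnorm(length(m1))
  e <- z - A %*% qr.solve(A, z)          # projection onto null(A')
  rec$value[m1] <- rec$value[m1] + e
  expected <- sqrt(sum(e^2) / nrow(rec))  # other medium stays exact
  expect_equal(rdcFitness(s, rdcSet(rec))$value, expected,
               tolerance = 1e-9)
})

test_that("fitness is invariant under rigid motion of the structure", {
  set.seed(33)
  s <- helixN(10, seq1 = "AEKLHDRVNQ")
  data <- addRdcNoise(simulateRdcs(s), 2, seed = 77)
  f0 <- rdcFitness(s, data)$value
  for (k in 1:5) {
    s2 <- transformStructure(s, randomRotation(), rnorm(3, sd = 20))
    expect_equal(rdcFitness(s2, data)$value, f0, tolerance = 1e-9)
  }
})

test_that("uniform +/-E noise keeps the fitted fitness at or below the raw RMS", {
  s <- makeFixture("helix_turn_helix20")$structure
  data <- simulateRdcs(s)
  E <- 2
  for (seed in 1:20) {
    noisy <- addRdcNoise(data, E, seed = seed)
    f <- rdcFitness(s, noisy)$value
    # raw deltas RMS ~ E/sqrt(3); the least-squares refit cannot exceed it
    raw <- sqrt(mean((rdcRecords(noisy)$value - rdcRecords(data)$value)^2))
    expect_lte(f, raw + 1e-9)
    expect_lte(f, E / sqrt(3) * 1.15)
  }
})

test_that("records beyond the current fragment are skipped, not fatal", {
  fx <- makeFixture("helix15")
  frag <- buildChain(substr(fx$sequence, 1, 8), fx$torsions[1:8, ])
  f <- rdcFitness(frag, fx$data$E0)
  expect_gt(f$nSkipped, 0L)
  expect_lt(f$value, 1e-9)   # the resolvable subset is still self-consistent
})

test_that("uncertainty-weighted fitting is available but off by default", {
  s <- helixN(8, seq1 = "AEKLHDRV")
  rec <- rdcRecords(simulateRdcs(s))
  rec$uncertainty <- rep(c(0.5, 2), length.out = nrow(rec))
  expect_equal(rdcFitness(s, rdcSet(rec))$value,
               rdcFitness(s, rdcSet(rec), weighted = TRUE)$value,
               tolerance = 1e-9)  # exact data: both zero residual
  rec$value[1] <- rec$value[1] + 5
  fw <- rdcFitness(s, rdcSet(rec), weighted = TRUE)
  expect_s3_class(fw, "FitnessScore")
  expect_gt(fw$value, 0)
})
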