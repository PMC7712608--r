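test_that("build/extract torsion round-trips hold on varied conformations", {
  cases <- list(
    helix = matrix(c(-60, -45), 8, 2, byrow = TRUE),
    sheet = matrix(c(-120, 120), 8, 2, byrow = TRUE),
    mixed = cbind(phi = c(-60, -70, -120, -135, -60, -80, -60, -100),
                  psi = c(-45, -30, 120, 135, -40, 0, -45, 170)))
  for (nm in names(cases)) {
    tor <- cases[[nm]]
    s <- buildChain("AEKLHDRV", tor)
    expect_equal(unname(extractTorsions(s)), unname(tor),
                 tolerance = 1e-9, info = nm)
  }
  # wrap boundary: psi = 180 round-trips as +180, not -180
  s <- buildChain("AAAA", cbind(c(-60, -90, -90, -60), c(180, 180, 180, 180)))
  expect_equal(unname(extractTorsions(s)[, 2]), rep(180, 4))
})

test_that("bonded geometry matches the fixed table without drift over 100 residues", {
  n <- 100
  s <- helixN(n)
  x <- atomCoords(s)
  d <- function(i, a, j, b)
    sqrt(sum((x[(i - 1) * 6 + match(a, c("N", "H", "CA", "HA", "C", "O")), ] -
              x[(j - 1) * 6 + match(b, c("N", "H", "CA", "HA", "C", "O")), ])^2))
  for (i in seq_len(n)) {
    expect_equal(d(i, "N", i, "CA"), 1.458, tolerance = 1e-6)
    expect_equal(d(i, "CA", i, "C"), 1.525, tolerance = 1e-6)
    expect_equal(d(i, "N", i, "H"), 1.020, tolerance = 1e-6)
    expect_equal(d(i, "CA", i, "HA"), 1.090, tolerance = 1e-6)
    expect_equal(d(i, "C", i, "O"), 1.231, tolerance = 1e-6)
    if (i < n) expect_equal(d(i, "C", i + 1, "N"), 1.329, tolerance = 1e-6)
  }
})

test_that("built chains agree with an independent rotation-matrix builder", {
  for (tp in list(c(-60, -45), c(-120, 120), c(-75, 140))) {
    n <- 12
    s <- helixN(n, tp[1], tp[2])
    idx <- rep(seq_len(n) - 1, each = 3) * 6 + rep(c(1, 3, 5), n)
    P <- atomCoords(s)[idx, ]
    Q <- oracleChain(n, tp[1], tp[2])
    expect_lt(bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE),
              1e-6)
  }
})

test_that("an ideal alpha helix forms i -> i+4 hydrogen-bond geometry", {
  s <- helixN(12)
  x <- atomCoords(s)
  for (i in 1:8) {
    dON <- sqrt(sum((x[(i - 1) * 6 + 6, ] - x[(i + 3) * 6 + 1, ])^2))
    expect_gt(dON, 2.7); expect_lt(dON, 3.3)
  }
})

test_that("trans-peptide CA-CA distance is fixed at ~3.8 A", {
  s <- buildChain(strrep("A", 6), matrix(c(-120, 120), 6, 2, byrow = TRUE))
  x <- atomCoords(s)
  for (i in 1:5) {
    dCA <- sqrt(sum((x[(i - 1) * 6 + 3, ] - x[i * 6 + 3, ])^2))
    expect_equal(dCA, 3.8, tolerance = 0.1 / 3.8)
  }
})

test_that("extendFragment is append-only and equivalent to building at once", {
  tor <- cbind(c(-60, -75, -120, -60, -90), c(-45, -30, 130, -40, 160))
  full <- buildChain("AEKLH", tor)
  s <- buildChain("A", tor[1, , drop = FALSE])
  for (i in 2:5) {
    prev <- s
    s <- extendFragment(s, substr("AEKLH", i, i), tor[i, ])
    # prefix untouched
    expect_identical(atomCoords(s)[seq_len(6 * (i - 1)), ],
                     atomCoords(prev))
  }
  expect_equal(atomCoords(s), atomCoords(full), tolerance = 1e-9)
  # appended pair recovered exactly
  expect_equal(unname(extractTorsions(s)[5, ]), unname(tor[5, ]),
               tolerance = 1e-9)
  # different pair changes only the last residue's atoms
  a <- extendFragment(full, "A", c(-60, -45))
  b <- extendFragment(full, "A", c(-120, 120))
  expect_identical(atomCoords(a)[seq_len(30), ], atomCoords(b)[seq_len(30), ])
  expect_gt(max(abs(atomCoords(a)[31:36, ] - atomCoords(b)[31:36, ])), 0.1)
})

test_that("torsions are invariant under rigid motion; degenerate atoms error", {
  set.seed(42)
  s <- helixN(8)
  for (k in 1:5) {
    s2 <- transformStructure(s, randomRotation(), rnorm(3, sd = 10))
    expect_equal(extractTorsions(s2), extractTorsions(s),
                 tolerance = 1e-9)
  }
  # collinear backbone atoms make the dihedral undefined
  bad <- s
  xyz <- atomCoords(bad)
  xyz[2 * 6 + 1, ] <- xyz[6 + 3, ] + c(1, 0, 0)  # N3 collinear hack
  xyz[6 + 5, ] <- xyz[6 + 3, ] + c(0.5, 0, 0)    # C2 on the same line
  xyz[2 * 6 + 3, ] <- xyz[6 + 3, ] + c(1.5, 0, 0)
  bad <- new("BackboneStructure", sequence = residueSequence(s),
             coords = xyz)
  expect_error(extractTorsions(bad), "collinear")
})

test_that("input validation: residue letters and torsion ranges", {
  expect_error(buildChain("AZB", matrix(0, 3, 2)), "unknown residue")
  expect_error(buildChain("AAA", matrix(c(-60, 200), 3, 2, byrow = TRUE)),
               "-180, 180")
  expect_error(buildChain("AAA", matrix(0, 2, 2)), "per residue")
  # placeholders for the undefined terminal torsions are accepted
  tor <- matrix(c(-60, -45), 3, 2, byrow = TRUE)
  tor[1, 1] <- NA; tor[3, 2] <- NA
  expect_s4_class(buildChain("AAA", tor), "BackboneStructure")
})

test_that("internuclearVector returns unit vectors for supported atoms", {
  s <- helixN(5)
  v <- internuclearVector(s, 2, "N", 2, "H")
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  # N->H direction equals the geometric bond direction
  x <- atomCoords(s)
  u <- x[6 + 2, ] - x[6 + 1, ]; u <- u / sqrt(sum(u^2))
  expect_equal(v, u, tolerance = 1e-12)
  # the new vector type N-CA is available
  v2 <- internuclearVector(s, 3, "N", 3, "CA")
  expect_equal(sqrt(sum(v2^2)), 1, tolerance = 1e-12)
  expect_error(internuclearVector(s, 2, "CB", 2, "H"), "N, H, CA")
})

test_that("bbRmsd: identity, symmetry, rigid invariance, brute-force oracle", {
  set.seed(11)
  a <- helixN(10)
  b <- helixN(10, -120, 120)
  expect_equal(bbRmsd(a, a), 0, tolerance = 1e-12)
  expect_equal(bbRmsd(a, b), bbRmsd(b, a), tolerance = 1e-9)
  expect_gt(bbRmsd(a, b), 0)
  for (k in 1:5)
    expect_lt(bbRmsd(a, transformStructure(a, randomRotation(),
                                           rnorm(3, sd = 5))), 1e-9)
  expect_error(bbRmsd(a, helixN(9)), "residue counts")
  # 3-point toys against the exhaustive rotation-grid oracle
  toPseudo <- function(P) {
    xyz <- matrix(NA_real_, 6, 3)
    xyz[c(1, 3, 5), ] <- P
    new("BackboneStructure", sequence = "A", coords = xyz)
  }
  for (k in 1:3) {
    P <- matrix(rnorm(9), 3, 3); Q <- matrix(rnorm(9), 3, 3)
    expect_equal(bbRmsd(toPseudo(P), toPseudo(Q)), bruteRmsd(P, Q),
                 tolerance = 2e-3)
  }
})

test_that("PDB I/O round-trips and rebuilds missing hydrogens", {
  s <- buildChain("AEKGPHDV",
                  cbind(c(-60, -75, -120, 100, -70, -60, -135, -80),
                        c(-45, -30, 130, 20, 150, -40, 140, 120)))
  f <- tempfile(fileext = ".pdb")
  writePdb(s, f)
  s2 <- readPdb(f)
  expect_identical(residueSequence(s2), residueSequence(s))
  expect_lt(bbRmsd(s, s2), 2e-3)   # PDB stores 3 decimals
  # proline has no amide H on disk or after reading
  expect_true(anyNA(atomCoords(s2)[(5 - 1) * 6 + 2, ]))
  # strip hydrogens: reader rebuilds them from ideal geometry
  lines <- readLines(f)
  keep <- !(startsWith(lines, "ATOM") &
              trimws(substr(lines, 13, 16)) %in% c("H", "HA"))
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines[keep], f2)
  s3 <- readPdb(f2)
  expect_false(anyNA(atomCoords(s3)[6 + 2, ]))   # H2 rebuilt
  expect_false(anyNA(atomCoords(s3)[6 + 4, ]))   # HA2 rebuilt
  expect_lt(bbRmsd(s, s3), 2e-3)
})
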