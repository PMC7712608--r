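sortedRecords <- function(x) {
  r <- rdcRecords(x)[, c("residue_1", "atom_1", "residue_2", "atom_2",
                         "medium", "value", "uncertainty")]
  r <- r[do.call(order, r), ]
  rownames(r) <- NULL
  r
}

test_that("NEF files round-trip through write and read", {
  fx <- makeFixture("helix15")
  data <- fx$data$E1
  f <- tempfile(fileext = ".nef")
  writeNef(data, f, sequence = fx$sequence)
  back <- readNef(f, sequence = fx$sequence)
  expect_equal(sortedRecords(back), sortedRecords(data), tolerance = 1e-6)
  # a second write/read cycle is stable
  f2 <- tempfile(fileext = ".nef")
  writeNef(back, f2)
  expect_equal(sortedRecords(readNef(f2)), sortedRecords(back),
               tolerance = 1e-6)
})

test_that("NEF reader maps fields, accepts new vector types, rejects unknown pairs", {
  txt <- c(
    "data_test",
    "save_nef_rdc_restraint_list_1",
    "   _nef_rdc_restraint_list.sf_category   nef_rdc_restraint_list",
    "   loop_",
    "      _nef_rdc_restraint.chain_code_1",
    "      _nef_rdc_restraint.sequence_code_1",
    "      _nef_rdc_restraint.residue_name_1",
    "      _nef_rdc_restraint.atom_name_1",
    "      _nef_rdc_restraint.chain_code_2",
    "      _nef_rdc_restraint.sequence_code_2",
    "      _nef_rdc_restraint.residue_name_2",
    "      _nef_rdc_restraint.atom_name_2",
    "      _nef_rdc_restraint.target_value",
    "      _nef_rdc_restraint.target_value_uncertainty",
    "      A 5 ALA N  A 5 ALA H  3.25 0.2",
    "      A 6 ALA HA A 6 ALA CA 7.5  0.1",
    "      A 7 ALA N  A 7 ALA O  1.0  0.1",
    "   stop_",
    "save_")
  f <- tempfile(fileext = ".nef")
  writeLines(txt, f)
  expect_warning(data <- readNef(f), "rejected 1")
  rec <- rdcRecords(data)
  expect_identical(nrow(rec), 2L)
  expect_equal(rec$residue_1[1], 5L)
  expect_identical(rec$atom_1[1], "N")
  expect_identical(rec$atom_2[1], "H")
  expect_equal(rec$value[1], 3.25)
  expect_equal(rec$uncertainty[1], 0.2)
  # the previously unusable HA-CA pair is accepted
  expect_identical(rec$atom_1[2], "HA")
  expect_identical(attr(data, "nSkipped"), 1L)
})

test_that("legacy reader counts records and honors the 999 sentinel", {
  f <- tempfile()
  full <- paste(rep("1.5", 6), collapse = " ")
  errs <- paste(rep("0.2", 6), collapse = " ")
  writeLines(rep(paste(full, errs), 10), f)
  d <- readLegacyRdc(f)
  expect_identical(nrow(rdcRecords(d)), 60L)   # 6 per residue row
  # one all-sentinel row drops exactly its 6 records
  lines <- readLines(f)
  lines[4] <- paste(paste(rep("999", 6), collapse = " "), errs)
  writeLines(lines, f)
  d2 <- readLegacyRdc(f)
  expect_identical(nrow(rdcRecords(d2)), 54L)
  expect_false(any(rdcRecords(d2)$residue_1 == 4L))
  # wrong column count errors with the line number
  writeLines(c(paste(full, errs), "1 2 3"), f)
  expect_error(readLegacyRdc(f), "line 2")
  # proline amide-H rows are rejected loudly, with a counter
  writeLines(rep(paste(full, errs), 4), f)
  expect_warning(dp <- readLegacyRdc(f, sequence = "APAA"), "proline")
  expect_identical(attr(dp, "nSkipped"), 2L)   # N-H(2) and C'(1)-H(2)
  expect_false(any(rdcRecords(dp)$residue_2 == 2 &
                     rdcRecords(dp)$atom_2 == "H"))
})

test_that("legacy -> NEF conversion preserves the record multiset", {
  fx <- makeFixture("hairpin12")
  leg1 <- tempfile(); leg2 <- tempfile(); nef <- tempfile(fileext = ".nef")
  writeLegacyRdc(fx$data$E1, leg1, medium = 1, nResidues = 12)
  writeLegacyRdc(fx$data$E1, leg2, medium = 2, nResidues = 12)
  convertLegacyToNef(c(leg1, leg2), nef, sequence = fx$sequence)
  viaNef <- sortedRecords(readNef(nef, sequence = fx$sequence))
  direct <- rbind(rdcRecords(readLegacyRdc(leg1, 1, fx$sequence)),
                  rdcRecords(readLegacyRdc(leg2, 2, fx$sequence)))
  expect_equal(viaNef, sortedRecords(rdcSet(direct)), tolerance = 1e-4)
  # the legacy writer/reader pair loses nothing but trailing cross-residue
  # records (they reference one residue past the chain)
  orig <- rdcRecords(fx$data$E1)
  keep <- orig$residue_2 <= 12L
  expect_equal(viaNef, sortedRecords(rdcSet(orig[keep, ])),
               tolerance = 1e-4)
})

test_that("INI configs parse with comments, defaults and validation", {
  dir <- tempfile(); dir.create(dir)
  writeLines("AEKLH", file.path(dir, "seq.txt"))
  writeLines("", file.path(dir, "rdcs.nef"))
  cfg <- c("# run configuration",
           "[files]",
           "sequence = seq.txt   ; inline comment",
           "rdc = rdcs.nef",
           "",
           "[stage2]",
           "depth = 50",
           "decimation = dynamic",
           "tolerance = 20",
           "; comment-only line",
           "seed = 7")
  f <- file.path(dir, "run.ini")
  writeLines(cfg, f)
  rc <- readRunConfig(f)
  expect_identical(rc$depth, 50L)
  expect_identical(rc$decimation, "dynamic")
  expect_equal(rc$tolerance, 20)
  expect_identical(rc$seed, 7L)
  expect_equal(rc$gridStep, 10)           # default
  expect_match(rc$sequenceFile, "seq.txt")
  # missing mandatory key names the key
  writeLines(c("[files]", "rdc = rdcs.nef"), f)
  expect_error(readRunConfig(f), "files.sequence")
  writeLines(c("[files]", "sequence = seq.txt"), f)
  expect_error(readRunConfig(f), "files.rdc")
  # unknown keys warn but do not fail
  writeLines(c(cfg, "[stage2]", "frobnicate = 1"), f)
  expect_warning(readRunConfig(f), "frobnicate")
})

test_that("stage-II trace files round-trip and replay into torsions", {
  trace <- list(
    data.frame(rank = 1:2, score = c(0.1, 0.2),
               angles = c("-60:-45", "-120:120"),
               stringsAsFactors = FALSE),
    data.frame(rank = 1L, score = 0.15,
               angles = "-60:-45;-60:-45", stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".out")
  writeOutTrace(trace, f)
  back <- readOutTrace(f)
  expect_identical(length(back), 2L)
  expect_equal(back[[1]]$score, trace[[1]]$score)
  expect_identical(back[[2]]$angles, trace[[2]]$angles)
  tor <- parseAngleString(back[[2]]$angles[1])
  expect_equal(unname(tor), matrix(c(-60, -45, -60, -45), 2, 2,
                                   byrow = TRUE))
  # scores are non-decreasing within each step of a real run
  fx <- makeFixture("hairpin12")
  res <- runStage2(fx$sequence, fx$data$E0,
                   policy = decimationPolicy("dynamic", depth = 50,
                                             tolerance = 20),
                   gridStep = 45)
  for (st in res$trace) expect_false(is.unsorted(st$score))
})

test_that("restraint tables round-trip", {
  r <- data.frame(residue = c(2L, 5L), phi = c(-65, -120),
                  psi = c(-45, 130), half_width = 25, step = 5,
                  n_obs = c(10L, 3L))
  f <- tempfile(fileext = ".tsv")
  writeRestraints(r, f)
  back <- readRestraints(f)
  expect_equal(back[, c("residue", "phi", "psi")],
               r[, c("residue", "phi", "psi")])
  writeLines("residue\tphi\n1\t2", f)
  expect_error(readRestraints(f), "psi")
})
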