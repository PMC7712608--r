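emptyRdcSet <- function()
  rdcSet(data.frame(residue_1 = integer(0), atom_1 = character(0),
                    residue_2 = integer(0), atom_2 = character(0),
                    medium = integer(0), value = numeric(0),
                    uncertainty = numeric(0)))

test_that("dynamic decimation applies the percentage band with a zero guard", {
  pool <- data.frame(score = c(1.0, 1.1, 1.5))
  expect_equal(decimateDynamic(pool, 20)$score, c(1.0, 1.1))
  # all-equal scores are all retained
  expect_identical(nrow(decimateDynamic(data.frame(score = rep(2, 5)), 20)),
                   5L)
  # zero best score: absolute floor takes over
  pool0 <- data.frame(score = c(0, 1e-4, 5))
  expect_equal(decimateDynamic(pool0, 20, epsAbs = 0.01)$score, c(0, 1e-4))
  # never empty
  expect_identical(nrow(decimateDynamic(data.frame(score = c(3, 9)), 1e-9)),
                   1L)
  # additive reading is selectable
  expect_equal(decimateDynamic(data.frame(score = c(1.0, 1.15, 1.5)), 20,
                               additive = TRUE)$score, c(1.0, 1.15))
  # list-of-fragments form
  frags <- list(list(score = 1.0), list(score = 1.3))
  expect_length(decimateDynamic(frags, 20), 1L)
  expect_error(decimateDynamic(data.frame(score = c(2, 1)), 20), "sorted")
})

test_that("static decimation keeps bucket representatives then thresholds", {
  pool <- data.frame(score = c(0.5, 0.6, 2.5),
                     phi = c(-61, -59, -120), psi = c(-44, -43, 130))
  # the two near-identical terminal pairs share a 10-degree bucket
  kept <- decimateStatic(pool, threshold = Inf, bucketWidth = 10)
  expect_equal(kept$score, c(0.5, 2.5))
  # bucket width 0 disables bucketing: pure threshold
  kept0 <- decimateStatic(pool, threshold = 1.0, bucketWidth = 0)
  expect_equal(kept0$score, c(0.5, 0.6))
  # loose parameters: both modes keep everything identically
  big <- data.frame(score = sort(runif(20, 1, 2)),
                    phi = seq(-150, 40, by = 10), psi = seq(-150, 40, 10))
  expect_identical(decimateStatic(big, Inf, 0), big)
  expect_identical(decimateDynamic(big, 1e6), big)
  # best always survives the threshold
  expect_identical(nrow(decimateStatic(data.frame(score = 5, phi = 0,
                                                  psi = 0), 1, 0)), 1L)
})

test_that("elongateStep enumerates, sorts and bounds the pool", {
  fx <- makeFixture("hairpin12")
  cand <- rankCandidates(1, enumerateGrid(45), fx$data$E0, fx$sequence)
  seed <- list(list(torsions = matrix(numeric(0), 0, 2)))
  pol <- decimationPolicy("dynamic", depth = 1000, tolerance = 1e6,
                          epsAbs = Inf)
  out <- elongateStep(seed, cand, fx$data$E0, fx$sequence, pol)
  expect_length(out, nrow(cand))      # depth >= k, no-pruning regime
  scores <- vapply(out, function(f) f$score, numeric(1))
  expect_false(is.unsorted(scores))
  # output is bounded by the search depth
  pol5 <- decimationPolicy("dynamic", depth = 5, tolerance = 1e6,
                           epsAbs = Inf)
  expect_length(elongateStep(seed, cand, fx$data$E0, fx$sequence, pol5), 5L)
  expect_error(elongateStep(list(), cand, fx$data$E0, fx$sequence, pol),
               "non-empty")
})

test_that("the true extension scores minimally at every noise-free step", {
  fx <- makeFixture("hairpin12")
  g <- enumerateGrid(15)
  pol <- decimationPolicy("dynamic", depth = 1, tolerance = 20)
  beam <- list(list(torsions = matrix(numeric(0), 0, 2)))
  for (t in 1:12) {
    cand <- rbind(g, fx$torsions[t, ])   # ensure truth present
    cand <- cand[!duplicated(cand), ]
    ranked <- rankCandidates(t, cand, fx$data$E0, fx$sequence)
    # extend the true prefix with every candidate: truth attains min
    out <- elongateStep(beam, ranked, fx$data$E0, fx$sequence,
                        decimationPolicy("dynamic", depth = nrow(ranked),
                                         tolerance = 1e6, epsAbs = Inf))
    scores <- vapply(out, function(f) f$score, numeric(1))
    tors <- t(vapply(out, function(f) as.numeric(f$torsions[t, ]),
                     numeric(2)))
    iTruth <- which(tors[, 1] == fx$torsions[t, 1] &
                      tors[, 2] == fx$torsions[t, 2])
    expect_lte(scores[iTruth], min(scores) + 1e-9)
    # walk along the true path
    beam <- list(list(torsions = fx$torsions[seq_len(t), , drop = FALSE]))
  }
})

test_that("runStage2 recovers a noise-free hairpin and audits its cache", {
  fx <- makeFixture("hairpin12")
  pol <- decimationPolicy("dynamic", depth = 300, tolerance = 20)
  res <- runStage2(fx$sequence, fx$data$E0, policy = pol, gridStep = 15)
  expect_lt(res$score, 0.1)
  expect_lt(bbRmsd(res$structure, fx$structure), 0.5)
  # reported incremental scores equal the from-scratch recomputation
  expect_lt(max(abs(res$audit$incremental - res$audit$scratch)), 1e-6)
  # pool sizes never exceed depth after decimation
  expect_true(all(res$poolLog$poolKept <= 300))
})

test_that("runStage2 is deterministic and its trace replays", {
  fx <- makeFixture("hairpin12")
  pol <- decimationPolicy("dynamic", depth = 100, tolerance = 20)
  r1 <- runStage2(fx$sequence, fx$data$E1, policy = pol, gridStep = 45)
  r2 <- runStage2(fx$sequence, fx$data$E1, policy = pol, gridStep = 45)
  expect_identical(r1$torsions, r2$torsions)
  f1 <- tempfile(); f2 <- tempfile()
  writeOutTrace(r1$trace, f1); writeOutTrace(r2$trace, f2)
  expect_identical(readLines(f1), readLines(f2))  # bit-identical trace
  # replaying the final line reproduces the final structure
  tor <- parseAngleString(readOutTrace(f1)[[12]]$angles[1])
  expect_lt(bbRmsd(buildChain(fx$sequence, tor), r1$structure), 1e-9)
})

test_that("empty candidate lists fail loudly, naming the residue", {
  fx <- makeFixture("hairpin12")
  lists <- stage1Candidates(fx$sequence, fx$data$E0, gridStep = 45)
  lists[[7]] <- lists[[7]][0, ]
  expect_error(runStage2(fx$sequence, fx$data$E0, candidates = lists),
               "residue 7")
})

test_that("dynamic pools shrink sparse-data searches relative to loose static", {
  # sparse early data: one N-H coupling per residue, single medium
  fx <- makeFixture("helix_turn_helix20")
  sparse <- rdcSet(subset(rdcRecords(fx$data$E1),
                          medium == 1 & atom_1 == "N" & atom_2 == "H"))
  cand <- stage1Candidates(fx$sequence, sparse, gridStep = 15)
  # partially determined regime: the true prefix through junction 8, so
  # child scores are non-zero and spread (during the fully
  # under-determined opening both policies keep everything, by design)
  beam <- list(list(torsions = fx$torsions[1:8, , drop = FALSE]))
  grow <- function(pol) length(elongateStep(beam, cand[[9]], sparse,
                                            fx$sequence, pol))
  nDyn <- grow(decimationPolicy("dynamic", depth = 10000, tolerance = 20))
  nStat <- grow(decimationPolicy("static", depth = 10000,
                                 staticThreshold = 5, bucketWidth = 0))
  expect_lt(nDyn, nStat)
  # and the dynamic pool is itself bounded by the tolerance = infinity pool
  nDynInf <- grow(decimationPolicy("dynamic", depth = 10000,
                                   tolerance = 1e9))
  expect_lte(nDyn, nDynInf)
})
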