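encFixture <- function(D = 2000, seed = 1, timeMode = "independent")
  newEncoder(areas = c("VISp", "CA1"), regions = c("Striate cortex",
             "Hippocampus"), D = D, seed = seed, timeMode = timeMode)

test_that("receptive-field encoding is a bounded kernel feature map", {
  enc <- encFixture()
  # zero response vector -> zero HV (sin(0) = 0), the documented degenerate case
  expect_identical(encodeReceptiveField(numeric(81), enc), numeric(2000))

  Fi <- withr::with_seed(1, runif(81, 0, 5))
  h <- encodeReceptiveField(Fi, enc)
  expect_true(all(abs(h) <= 1))
  expect_equal(cosineSim(h, encodeReceptiveField(Fi, enc)), 1)

  # similarity decays monotonically as one response coordinate drifts
  # (averaged over 20 basis seeds)
  eps <- c(0.2, 0.5, 1, 2)
  sims <- sapply(1:20, function(s) {
    e <- encFixture(seed = s)
    h0 <- encodeReceptiveField(Fi, e)
    vapply(eps, function(d) {
      Fj <- Fi; Fj[1] <- Fj[1] + d
      cosineSim(h0, encodeReceptiveField(Fj, e))
    }, numeric(1))
  })
  expect_true(all(diff(rowMeans(sims)) < 0))
  expect_error(encodeReceptiveField(numeric(10), enc), "81")
})

test_that("spatial HVs at each level follow the substitution rules", {
  ds <- toyGaborDataset(4, reps = 1, fillFun = function(i, k) {
    v <- integer(250); v[i] <- 1L; v
  })
  enc <- encFixture()
  bt <- binTemporal(ds, 250)
  # two units in the same area with identical RFs share an HV; different
  # areas differ
  rf <- matrix(1, nrow = 4, ncol = 81)
  S <- buildSpatialHVs(bt, enc, rfMatrix = rf)
  # units 1,3 are VISp; 2,4 CA1 (alternating areas in the fixture)
  expect_identical(S[1, ], S[3, ])
  expect_false(identical(S[1, ], S[2, ]))
  expect_error(buildSpatialHVs(bt, enc), "receptive-field")

  areaBt <- aggregateSpatial(bt, "area")
  Sa <- buildSpatialHVs(areaBt, enc)
  expect_identical(nrow(Sa), 2L)
  expect_identical(unname(Sa), unname(enc@areaHVs[unitInfo(areaBt)$area, ]))

  popBt <- aggregateSpatial(bt, "population",
                            eiLabels = c("E", "E", "I", "I"))
  Sp <- buildSpatialHVs(popBt, enc)
  expect_equal(unname(Sp[1, ]),
               enc@eiHVs[unitInfo(popBt)$ei[1], ] *
               enc@areaHVs[unitInfo(popBt)$area[1], ])

  regBt <- aggregateSpatial(bt, "region")
  expect_identical(nrow(buildSpatialHVs(regBt, enc)), 2L)
  expect_null(buildSpatialHVs(aggregateSpatial(bt, "whole_brain"), enc))
})

test_that("time HVs interpolate linearly between binary endpoints", {
  enc <- encFixture(D = 500)
  ends <- makeBinaryHV(500, seed = streamSeed(1L, "time-trial-tA"), n = 2)
  Tm <- makeTimeHVs(4, enc, "tA")
  expect_equal(Tm[1, ], ends[1, ])                       # t = 0 endpoint
  expect_equal(Tm[3, ], 0.5 * ends[1, ] + 0.5 * ends[2, ])
  Tm2 <- makeTimeHVs(2, enc, "tA")
  expect_equal(Tm2[2, ], 0.5 * ends[1, ] + 0.5 * ends[2, ])

  # similarity decays with temporal distance (fixed seed, M = 250)
  encB <- encFixture(D = 10000)
  Tb <- makeTimeHVs(250, encB, "tB")
  s0 <- vapply(c(1, 50, 125, 200, 250), function(t)
    cosineSim(Tb[1, ], Tb[t, ]), numeric(1))
  expect_true(all(diff(s0) < 0))
  expect_error(makeTimeHVs(0, enc), ">= 1")
})

test_that("trial encoding matches the hand-expanded single-unit formulas", {
  units <- data.frame(unit_id = "u1", area = "VISp")
  for (count in c(0L, 3L)) {
    counts <- array(count, c(1, 250, 1))
    trials <- data.frame(trial_id = "tr9", task = "gabor", class_label = 0L)
    ds <- newSpikeDataset(units, trials, counts)
    bt <- aggregateSpatial(binTemporal(ds, 250), "area")  # S = area HV
    enc <- encFixture(D = 300)
    V <- encodeTrials(bt, enc)
    S <- enc@areaHVs["VISp", ]
    Tm <- makeTimeHVs(1, enc, "tr9")
    expected <- if (count == 0) (S * -enc@Hplus) * Tm[1, ]
                else (250 * count) * (S * enc@Hplus) * Tm[1, ]
    expect_equal(drop(V), expected)
  }
})

test_that("trial encoding is linear in counts away from the zero boundary", {
  ds <- withr::with_seed(3, toyGaborDataset(4, reps = 1,
    fillFun = function(i, k) rpois(250, 0.3) + 1L))  # strictly positive
  enc <- encFixture(D = 500)
  bt <- binTemporal(ds, 125)
  bt2 <- bt; bt2@counts <- bt@counts * 2
  rf <- matrix(withr::with_seed(5, runif(4 * 81)), nrow = 4)
  V1 <- encodeTrials(bt, enc, rfMatrix = rf)
  V2 <- encodeTrials(bt2, enc, rfMatrix = rf)
  expect_equal(V2, 2 * V1)
})

test_that("polarization is antisymmetric for unit counts", {
  units <- data.frame(unit_id = c("u1", "u2", "u3"), area = "VISp")
  trials <- data.frame(trial_id = "tZ", task = "gabor", class_label = 0L)
  mk <- function(pattern) {
    counts <- array(0L, c(3, 250, 1)); counts[, 1, 1] <- pattern
    newSpikeDataset(units, trials, counts)
  }
  enc <- encFixture(D = 400)
  rf <- matrix(withr::with_seed(6, runif(3 * 81)), nrow = 3)
  enc1 <- encodeTrials(binTemporal(mk(c(1L, 0L, 1L)), 250), enc, rfMatrix = rf)
  enc2 <- encodeTrials(binTemporal(mk(c(0L, 1L, 0L)), 250), enc, rfMatrix = rf)
  expect_equal(enc1 + enc2, enc1 * 0)
})

test_that("shared time HVs make identical count tensors identical; independent do not", {
  units <- data.frame(unit_id = sprintf("u%d", 1:5), area = "VISp")
  trials <- data.frame(trial_id = c("tr1", "tr2"), task = "gabor",
                       class_label = c(0L, 0L))
  counts <- array(0L, c(5, 250, 2))
  base <- withr::with_seed(8, matrix(rpois(5 * 250, 0.1), 5))
  counts[, , 1] <- base; counts[, , 2] <- base
  ds <- newSpikeDataset(units, trials, counts)
  rf <- matrix(withr::with_seed(9, runif(5 * 81)), nrow = 5)

  encS <- encFixture(D = 10000, timeMode = "shared")
  Vs <- encodeTrials(binTemporal(ds, 125), encS, rfMatrix = rf)
  expect_equal(cosineSim(Vs[1, ], Vs[2, ]), 1)

  # independent endpoints leave only the shared-mean component of the
  # binary time HVs: similarity drops well below 1 (about 0.6 here)
  sims <- vapply(1:25, function(s) {
    encI <- encFixture(D = 10000, seed = s)
    Vi <- encodeTrials(binTemporal(ds, 125), encI, rfMatrix = rf)
    cosineSim(Vi[1, ], Vi[2, ])
  }, numeric(1))
  expect_true(all(abs(sims) < 0.8))

  # with distinct same-class tensors, shared mode yields systematically
  # higher pairwise similarity than independent mode
  counts[, , 2] <- withr::with_seed(10, matrix(rpois(5 * 250, 0.1), 5))
  ds2 <- newSpikeDataset(units, trials, counts)
  Vs2 <- encodeTrials(binTemporal(ds2, 125), encS, rfMatrix = rf)
  encI <- encFixture(D = 10000)
  Vi2 <- encodeTrials(binTemporal(ds2, 125), encI, rfMatrix = rf)
  expect_gt(abs(cosineSim(Vs2[1, ], Vs2[2, ])),
            abs(cosineSim(Vi2[1, ], Vi2[2, ])))
})
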