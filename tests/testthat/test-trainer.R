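test_that("grid adjacency has 3/5/8 neighbors for corner/edge/interior cells", {
  adj <- gridAdjacency()
  deg <- lengths(adj)
  g <- gaborGrid()
  corner <- g$x %in% c(0, 8) & g$y %in% c(0, 8)
  edge <- xor(g$x %in% c(0, 8), g$y %in% c(0, 8))
  expect_true(all(deg[corner] == 3))
  expect_true(all(deg[edge] == 5))
  expect_true(all(deg[!corner & !edge] == 8))
  # symmetry
  for (i in seq_along(adj)) for (j in adj[[i]])
    expect_true(i %in% adj[[j]])
})

test_that("prediction takes the argmax similarity with low-index tie-breaking", {
  D <- 200
  model <- newClassModel("natural_scenes", D = D, m = 6)
  v <- makeBipolarHV(D, seed = 1)
  expect_identical(predictClasses(model, v), 0L)   # all-zero model -> class 0

  C <- makeBipolarHV(D, seed = 2, n = 6)
  C[4, ] <- v
  model@classHVs <- C
  expect_identical(predictClasses(model, v), 3L)

  model@classHVs[6, ] <- -v                        # delta = -1: never chosen
  expect_false(predictClasses(model, v) == 5L)
})

test_that("scenes updates follow the similarity-proportional rules", {
  D <- 300
  v <- makeBipolarHV(D, seed = 3)
  # fresh model predicts 0 by the tie rule; label 0 -> correct case with
  # delta_l = 0, so C_0 += eta * v
  m0 <- trainScenes(matrix(v, 1), 0L, newClassModel("natural_scenes", D = D, m = 4),
                    epochs = 1)
  expect_equal(m0@classHVs[1, ], 0.01 * v)
  expect_equal(m0@classHVs[2:4, ], matrix(0, 3, D))

  # a sample already at delta_l = 1 produces a bit-exact zero update
  m1 <- newClassModel("natural_scenes", D = D, m = 4)
  m1@classHVs[2, ] <- 2 * v
  m1@classHVs[3, ] <- makeBipolarHV(D, seed = 4)
  before <- m1@classHVs
  m2 <- trainScenes(matrix(v, 1), 1L, m1, epochs = 1)
  expect_identical(m2@classHVs, before)

  # error case: increment to C_l mirrors the decrement to C_l'
  m3 <- newClassModel("natural_scenes", D = D, m = 4)
  m3@classHVs[4, ] <- v                    # label 0 will be mispredicted as 3
  m4 <- trainScenes(matrix(v, 1), 0L, m3, epochs = 1)
  inc <- m4@classHVs[1, ] - m3@classHVs[1, ]
  dec <- m3@classHVs[4, ] - m4@classHVs[4, ]
  expect_equal(inc, dec)
  expect_equal(inc, 0.01 * (1 - 0) * v)    # eta * (delta_l' - delta_l) * v
})

test_that("gabor updates touch center plus neighbors, push-pull on errors", {
  D <- 300
  v <- makeBipolarHV(D, seed = 5)
  w <- makeBipolarHV(D, seed = 6)
  adj <- gridAdjacency()

  # correct prediction at interior class 40 (delta < 1): 9 rows change
  m <- newClassModel("gabor", D = D)
  m@classHVs[41, ] <- v + w                 # similar but not colinear
  m2 <- trainGabor(matrix(v, 1), 40L, m, epochs = 1)
  changed <- which(rowSums(m2@classHVs != m@classHVs) > 0)
  expect_setequal(changed, c(41L, adj[[41]]))
  expect_length(changed, 9)

  # correct prediction at corner class 0: 4 rows change
  mC <- newClassModel("gabor", D = D)
  mC@classHVs[1, ] <- v + w
  mC2 <- trainGabor(matrix(v, 1), 0L, mC, epochs = 1)
  changedC <- which(rowSums(mC2@classHVs != mC@classHVs) > 0)
  expect_setequal(changedC, c(1L, adj[[1]]))
  expect_length(changedC, 4)

  # misclassification between non-adjacent interior classes 20 -> 60:
  # 18 rows change, 9 pulled toward v, 9 pushed away
  mE <- newClassModel("gabor", D = D)
  mE@classHVs[61, ] <- v + 0.1 * w
  mE2 <- trainGabor(matrix(v, 1), 20L, mE, epochs = 1)
  delta <- mE2@classHVs - mE@classHVs
  changedE <- which(rowSums(delta != 0) > 0)
  expect_length(changedE, 18)
  toward <- which(as.vector(delta %*% v) > 0)
  away <- which(as.vector(delta %*% v) < 0)
  expect_setequal(toward, c(21L, adj[[21]]))
  expect_setequal(away, c(61L, adj[[61]]))
})

test_that("a perfectly fit training set is a bit-exact fixed point", {
  D <- 400
  hv <- makeBipolarHV(D, seed = 7, n = 3)
  m <- newClassModel("natural_scenes", D = D, m = 3)
  m@classHVs <- hv * 5
  m2 <- trainScenes(hv, 0:2, m, epochs = 3)
  expect_identical(m2@classHVs, m@classHVs)
})

test_that("adaptive training separates noisy orthogonal classes", {
  # two classes, 20 clean samples each: held-out accuracy >= 0.95
  d <- easyTrialHVs(2, 20, perClassTest = 10, D = 10000, noiseSd = 1,
                    seed = 11)
  m <- trainScenes(d$V, d$labels, newClassModel("natural_scenes",
                                                D = 10000, m = 2), seed = 1)
  expect_gte(mean(predictClasses(m, d$Vtest) == d$labelsTest), 0.95)
})

test_that("held-out accuracy beats 10x chance on the easy regime, both tasks", {
  dS <- easyTrialHVs(118, 4, perClassTest = 2, D = 2000, noiseSd = 2,
                     seed = 21)
  mS <- trainScenes(dS$V, dS$labels, seed = 2)
  expect_gt(mean(predictClasses(mS, dS$Vtest) == dS$labelsTest), 10 / 118)

  dG <- easyTrialHVs(81, 4, perClassTest = 2, D = 2000, noiseSd = 2,
                     seed = 23)
  mG <- trainGabor(dG$V, dG$labels, seed = 3)
  expect_gt(mean(predictClasses(mG, dG$Vtest) == dG$labelsTest), 10 / 81)
})

test_that("training is deterministic given seed and data", {
  tr <- easyTrialHVs(5, 6, D = 500, noiseSd = 1, seed = 31)
  m1 <- trainScenes(tr$V, tr$labels, newClassModel("natural_scenes",
                                                   D = 500, m = 5), seed = 9)
  m2 <- trainScenes(tr$V, tr$labels, newClassModel("natural_scenes",
                                                   D = 500, m = 5), seed = 9)
  expect_identical(m1@classHVs, m2@classHVs)
  gv <- easyTrialHVs(81, 1, D = 400, seed = 32)$V
  g1 <- trainGabor(gv, 0:80, seed = 4)
  g2 <- trainGabor(gv, 0:80, seed = 4)
  expect_identical(g1@classHVs, g2@classHVs)

  expect_error(trainScenes(matrix(1, 1, 10), 5L,
                           newClassModel("natural_scenes", D = 10, m = 3)),
               "labels")
})
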