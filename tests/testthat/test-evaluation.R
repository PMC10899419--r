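# independent brute-force F1 oracle via full contingency table
f1Oracle <- function(truth, pred, m) {
  tab <- table(factor(truth, 0:(m - 1)), factor(pred, 0:(m - 1)))
  f1 <- numeric(m)
  for (c in seq_len(m)) {
    tp <- tab[c, c]; fp <- sum(tab[-c, c]); fn <- sum(tab[c, -c])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  f1
}

test_that("per-class and macro F1 match a brute-force contingency oracle", {
  expect_equal(f1Scores(0:4, 0:4, 5)$perClass$f1, rep(1, 5))
  # all predictions class 0 on balanced 2-class data
  r <- f1Scores(c(0, 0, 1, 1), c(0, 0, 0, 0), 2)
  expect_equal(r$perClass$f1, c(2 / 3, 0))
  # random instances, m <= 10, against the oracle
  for (s in 1:100) {
    set.seed(s)
    m <- sample(2:10, 1)
    truth <- sample(0:(m - 1), 40, TRUE)
    pred <- sample(0:(m - 1), 40, TRUE)
    r <- f1Scores(truth, pred, m)
    expect_equal(r$perClass$f1, f1Oracle(truth, pred, m))
    expect_equal(r$macroF1, mean(f1Oracle(truth, pred, m)))
  }
  expect_error(f1Scores(0:1, c(0, 5), 2), "\\[0, m\\)")
})

test_that("chance-level F1 for 118 balanced classes is 1/118", {
  expect_equal(round(chanceF1(118), 3), 0.008)
})

test_that("Euclidean grid errors follow the 9x9 geometry", {
  expect_equal(euclidErrors(c(5L, 0L), c(5L, 39L)), c(0, 5))  # 39 -> (3,4)
  expect_equal(max(euclidErrors(0L, 80L)), sqrt(128))
})

test_that("enumerated chance Euclidean error matches Monte Carlo", {
  ce <- chanceEuclid()
  expect_lt(abs(ce - 4.7), 0.1)            # the nominal chance level
  set.seed(2)
  mc <- mean(euclidErrors(sample(0:80, 1e5, TRUE), sample(0:80, 1e5, TRUE)))
  expect_lt(abs(ce - mc), 0.05)
})

test_that("augmentation expands 5-fold and preserves count multisets", {
  set.seed(3)
  x <- array(rpois(4 * 6 * 8, 2), c(4, 6, 8))   # N=4, T=6, K=8
  a <- augmentTrials(x, copies = 4, seed = 5)
  expect_identical(dim(a), c(4L, 6L, 40L))
  expect_identical(a[, , 1:8], x + 0)           # original retained
  for (cp in 1:4) for (i in 1:4) for (t in 1:6)
    expect_identical(sort(a[i, t, cp * 8 + 1:8]), sort(x[i, t, ] + 0))
  # shuffling is uniform across neurons: each copy's time-t slab is a
  # whole-column permutation of the original (unique entries make the
  # column matching unambiguous)
  u <- array(seq_len(4 * 6 * 8), c(4, 6, 8))
  au <- augmentTrials(u, copies = 4, seed = 4)
  for (t in 1:6) for (cp in 1:4) {
    src <- vapply(1:8, function(k) {
      which(vapply(1:8, function(j)
        all(au[, t, cp * 8 + k] == u[, t, j]), logical(1)))
    }, integer(1))
    expect_identical(sort(src), 1:8)
  }

  # N=1, T=1: every augmented trial is one of the originals
  y <- array(1:5, c(1, 1, 5))
  ay <- augmentTrials(y, seed = 1)
  expect_true(all(ay %in% 1:5))

  expect_warning(augmentTrials(array(1, c(2, 2, 1))), "no-op")
})

test_that("augmentation is deterministic given its seed", {
  x <- array(rpois(2 * 3 * 5, 1), c(2, 3, 5))
  expect_identical(augmentTrials(x, seed = 7), augmentTrials(x, seed = 7))
})

test_that("optimal-resolution selection keeps statistically tied resolutions", {
  # strict domination -> singleton
  e <- list(a = rep(1, 40), b = rep(2, 40), c = rep(3, 40))
  e$a <- e$a + runif(40, 0, 0.01)   # break exact ties in the test statistic
  expect_identical(selectOptimalResolution(e), "a")
  # identical vectors are jointly optimal
  z <- runif(30)
  expect_setequal(selectOptimalResolution(list(p = z, q = z)), c("p", "q"))
  # shifted distributions, shift >> noise: only lowest median survives
  set.seed(9)
  base <- rnorm(100, sd = 0.1)
  shifted <- list(r1 = base + 0, r2 = base + 1, r3 = base + 2)
  expect_identical(selectOptimalResolution(shifted), "r1")
  expect_error(selectOptimalResolution(list(a = 1:3, b = 1:4)), "paired")
})

test_that("the paired signed-rank decision agrees with exact enumeration at n = 10", {
  # brute force: enumerate all 2^n sign assignments of |d| ranks
  exactSignedRankP <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    Tobs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Tall <- signs %*% r
    mu <- n * (n + 1) / 4
    mean(abs(Tall - mu) >= abs(Tobs - mu))
  }
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    d <- x - y
    pEnum <- exactSignedRankP(d)
    pW <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(pW, pEnum, tolerance = 1e-10)
  }
})

test_that("group histogram counts each subject's whole optimal set", {
  res <- c("1", "125", "250")
  h <- groupLevelHistogram(list(c("125"), c("125"), c("125")), res)
  expect_identical(unname(h), c(0L, 3L, 0L))
  h2 <- groupLevelHistogram(list(c("125", "250"), "1"), res)
  expect_identical(unname(h2), c(1L, 1L, 1L))
  expect_identical(unname(groupLevelHistogram(list(), res)), c(0L, 0L, 0L))
})

test_that("randomization test for Pearson correlation behaves at the extremes", {
  x <- 1:20
  r <- pearsonRandomizationTest(x, x, nPerm = 999, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 1000)
  expect_equal(pearsonRandomizationTest(x, -x, nPerm = 99, seed = 1)$r, -1)
  expect_error(pearsonRandomizationTest(x, rep(1, 20)), "zero-variance")
  expect_error(pearsonRandomizationTest(1:2, 2:1), "at least 3")
})

test_that("randomization p-values are calibrated under independence", {
  rejections <- 0
  for (s in 1:100) {
    set.seed(100 + s)
    x <- rnorm(50); y <- rnorm(50)
    p <- pearsonRandomizationTest(x, y, nPerm = 200, seed = s)$p
    if (p <= 0.05) rejections <- rejections + 1
  }
  # super-uniform under the null: rejection rate ~5%, well within
  # binomial error of 100 replicates
  expect_lte(rejections, 12)
})

test_that("stratified folds balance classes and are deterministic", {
  labels <- rep(0:3, each = 10)
  f <- makeFolds(labels, k = 5, seed = 2)
  for (cl in 0:3)
    expect_identical(as.integer(table(f[labels == cl])), rep(2L, 5))
  expect_identical(makeFolds(labels, k = 5, seed = 2), f)
})
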