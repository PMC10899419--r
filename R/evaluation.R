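## Accuracy metrics, chance levels, augmentation, optimal-resolution
## selection and the randomization test.

#' Per-class one-vs-rest F1 scores and macro mean
#'
#' `F1 = 2 * precision * recall / (precision + recall)` per class, with the
#' convention that a class absent from both truth and prediction (all four
#' one-vs-rest cells empty of positives) scores 0, not NA. The macro mean
#' averages over all `m` classes.
#'
#' @param trueLabels,predLabels Integer 0-based labels.
#' @param m Number of classes.
#' @return List with `perClass` (data.frame: class, precision, recall, f1)
#'   and `macroF1`.
#' @export
f1Scores <- function(trueLabels, predLabels, m) {
  stopifnot(length(trueLabels) == length(predLabels))
  if (any(c(trueLabels, predLabels) < 0 | c(trueLabels, predLabels) >= m))
    stop("labels must lie in [0, m)")
  tp <- fp <- fn <- numeric(m)
  for (c in seq_len(m) - 1L) {
    tp[c + 1] <- sum(trueLabels == c & predLabels == c)
    fp[c + 1] <- sum(trueLabels != c & predLabels == c)
    fn[c + 1] <- sum(trueLabels == c & predLabels != c)
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(perClass = data.frame(class = seq_len(m) - 1L, precision = prec,
                             recall = rec, f1 = f1),
       macroF1 = mean(f1))
}

#' Chance-level macro F1 for uniform random prediction
#'
#' With balanced truth and uniform random predictions over `m` classes,
#' per-class precision and recall both converge to `1/m`, hence macro F1
#' converges to `1/m` (0.008 for the 118-class natural-scenes task).
#'
#' @param m Number of classes.
#' @return `1/m`.
#' @export
chanceF1 <- function(m) 1 / m

#' Per-trial Euclidean grid errors for Gabor predictions
#'
#' Distance on the 9x9 location grid between true and predicted classes:
#' `sqrt((x_t - x_p)^2 + (y_t - y_p)^2)` with coordinates in \{0..8\}
#' (range 0 to `sqrt(128)`).
#'
#' @param trueLabels,predLabels Integer 0-based Gabor labels (0..80).
#' @param grid Label-to-coordinate map, default [gaborGrid()].
#' @return Numeric vector of per-trial distances.
#' @export
euclidErrors <- function(trueLabels, predLabels, grid = gaborGrid()) {
  stopifnot(length(trueLabels) == length(predLabels))
  gt <- grid[trueLabels + 1L, ]; gp <- grid[predLabels + 1L, ]
  sqrt((gt$x - gp$x)^2 + (gt$y - gp$y)^2)
}

#' Chance-level mean Euclidean grid error by exact enumeration
#'
#' Mean distance between independently uniform true and predicted cells,
#' enumerated exactly over all 81 x 81 pairs (approximately 4.75).
#'
#' @param grid Label-to-coordinate map, default [gaborGrid()].
#' @return Scalar mean distance.
#' @export
chanceEuclid <- function(grid = gaborGrid()) {
  d <- outer(seq_len(nrow(grid)), seq_len(nrow(grid)), function(i, j)
    sqrt((grid$x[i] - grid$x[j])^2 + (grid$y[i] - grid$y[j])^2))
  mean(d)
}

#' Trial-shuffling data augmentation within one class
#'
#' For each augmented copy, the trial indices are permuted independently at
#' every time bin but uniformly across neurons:
#' `N_hat[, t, k] = N[, t, j_k^t]`, each `(j_1^t..j_K^t)` a fresh
#' permutation of `1..K`. This preserves every per-(neuron, time) count
#' multiset while creating new trial combinations. With the original
#' retained and `copies = 4`, the sample count grows 5-fold. Intended to be
#' applied separately to training and test partitions of each class.
#'
#' @param x Numeric array `N x T x K` of one class's binned counts.
#' @param copies Number of shuffled copies (default 4).
#' @param seed Integer seed.
#' @return Array `N x T x (copies + 1) * K`; the first `K` slices are the
#'   original trials. Attribute `"source"` gives each output trial's source
#'   copy (0 = original).
#' @export
augmentTrials <- function(x, copies = 4L, seed = 1L) {
  stopifnot(length(dim(x)) == 3L)
  N <- dim(x)[1]; Tn <- dim(x)[2]; K <- dim(x)[3]
  if (K < 2L) {
    warning("fewer than 2 trials; augmentation is a no-op")
    return(x)
  }
  out <- array(0, dim = c(N, Tn, (copies + 1L) * K))
  out[, , seq_len(K)] <- x
  withSeed(streamSeed(seed, "augment"), {
    for (cp in seq_len(copies)) {
      sl <- cp * K + seq_len(K)
      for (t in seq_len(Tn)) {
        perm <- sample.int(K)
        out[, t, sl] <- x[, t, perm]
      }
    }
  })
  attr(out, "source") <- rep(0:copies, each = K)
  out
}

#' Select the optimal resolutions from paired per-trial errors
#'
#' The resolution with the lowest median error is optimal; every other
#' resolution whose paired Wilcoxon signed-rank test against it is not
#' significant (`p >= alpha`) is counted as jointly optimal, so the result
#' is a set. Error vectors must be paired (same trials, same order).
#'
#' @param errors Named list of equal-length per-trial error vectors, one per
#'   resolution.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of optimal resolution names.
#' @export
selectOptimalResolution <- function(errors, alpha = 0.05) {
  stopifnot(is.list(errors), length(errors) >= 1L, !is.null(names(errors)))
  lens <- lengths(errors)
  if (length(unique(lens)) != 1L)
    stop("error vectors must be paired (equal lengths)")
  med <- vapply(errors, median, numeric(1))
  best <- names(errors)[which.min(med)]
  keep <- vapply(names(errors), function(r) {
    if (r == best) return(TRUE)
    d <- errors[[r]] - errors[[best]]
    if (all(d == 0)) return(TRUE)   # identical vectors: jointly optimal
    p <- suppressWarnings(
      stats::wilcox.test(errors[[r]], errors[[best]], paired = TRUE)$p.value)
    !is.na(p) && p >= alpha
  }, logical(1))
  names(errors)[keep]
}

#' Group-level histogram of optimal resolutions
#'
#' Each subject contributes one count to every resolution in its optimal
#' set (jointly optimal resolutions are all counted).
#'
#' @param optimalSets List of character vectors (one per subject).
#' @param resolutions All resolution names (the histogram's support).
#' @return Named integer vector of counts.
#' @export
groupLevelHistogram <- function(optimalSets, resolutions) {
  counts <- setNames(integer(length(resolutions)), resolutions)
  for (s in optimalSets) {
    s <- intersect(s, resolutions)
    counts[s] <- counts[s] + 1L
  }
  counts
}

#' Pearson correlation with a permutation randomization test
#'
#' Two-sided p-value from `nPerm` random permutations of `y`:
#' `p = (1 + #{perm : |r_perm| >= |r|}) / (1 + nPerm)`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param nPerm Number of permutations (default 10^4).
#' @param seed Integer seed.
#' @return List with `r` and `p`.
#' @export
pearsonRandomizationTest <- function(x, y, nPerm = 10000L, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  r <- cor(x, y)
  hits <- withSeed(streamSeed(seed, "perm-test"), {
    sum(vapply(seq_len(nPerm), function(i)
      abs(cor(x, sample(y))) >= abs(r), logical(1)))
  })
  list(r = r, p = (1 + hits) / (1 + nPerm))
}

#' Stratified k-fold assignment
#'
#' @param labels Class labels (stratification variable).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `1..k`, balanced within each class.
#' @export
makeFolds <- function(labels, k = 5L, seed = 1L) {
  folds <- integer(length(labels))
  withSeed(streamSeed(seed, "folds"), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}
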