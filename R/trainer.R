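## Adaptive class-hypervector training and prediction.

#' Create an untrained ClassModel
#'
#' Class HVs start at zero; an all-zero model predicts class 0 everywhere
#' (all similarities 0, ties resolved to the lowest class index).
#'
#' @param task `"gabor"` (81 classes) or `"natural_scenes"` (118 classes).
#' @param D Hyperdimension; must match the encoder used for trial HVs.
#' @param m Number of classes (defaults to the task's class count).
#' @return A [ClassModel-class].
#' @export
newClassModel <- function(task = c("natural_scenes", "gabor"), D = 10000L,
                          m = NULL) {
  task <- match.arg(task)
  if (is.null(m)) m <- taskClassCount(task)
  hp <- if (task == "gabor")
    list(etaCenter = 0.01, etaNeighbor = 0.001, epochs = 2L)
  else list(eta = 0.01, epochs = 3L)
  new("ClassModel", classHVs = matrix(0, nrow = m, ncol = checkDim(D)),
      task = task, hyperparams = hp)
}

#' 8-connectivity adjacency of the 9x9 Gabor location grid
#'
#' Classes are grid cells (`x = label mod 9`, `y = label div 9`); each class
#' is adjacent to its up-to-8 touching cells (corners have 3 neighbors,
#' edges 5, interior cells 8).
#'
#' @param nx,ny Grid extent (default 9 x 9).
#' @return List of integer vectors: 1-based class indices of each class's
#'   neighbors.
#' @export
gridAdjacency <- function(nx = 9L, ny = 9L) {
  lab <- 0:(nx * ny - 1L)
  xs <- lab %% nx; ys <- lab %/% nx
  lapply(seq_along(lab), function(i) {
    dx <- abs(xs - xs[i]); dy <- abs(ys - ys[i])
    which(dx <= 1L & dy <= 1L & (dx + dy) > 0L)
  })
}

#' Predict classes by maximal cosine similarity
#'
#' @param model A [ClassModel-class].
#' @param V Trial HV matrix (`n x D`) or a single length-D vector.
#' @return Integer vector of 0-based class labels; ties (including the
#'   all-zero model) resolve to the lowest class index.
#' @export
predictClasses <- function(model, V) {
  if (!is.matrix(V)) V <- matrix(V, nrow = 1)
  C <- model@classHVs
  rn <- sqrt(rowSums(C * C))
  apply(V, 1, function(v) which.max(rowCosine(C, v, rn)) - 1L)
}

## shared inner loop; `updateFun(C, env, l, lp, dl, dlp, v)` applies updates
## and returns the affected row indices.
adaptiveTrain <- function(V, labels, model, epochs, seed, updateFun) {
  m <- nrow(model@classHVs)
  if (any(labels < 0 | labels >= m))
    stop("labels must lie in [0, ", m, ")")
  C <- model@classHVs
  rn <- sqrt(rowSums(C * C))
  vnorm <- sqrt(rowSums(V * V))
  n <- nrow(V)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(streamSeed(seed, paste0("epoch-", ep)), sample.int(n))
    for (k in ord) {
      v <- V[k, ]
      if (vnorm[k] == 0) sims <- numeric(m)
      else {
        sims <- as.vector(C %*% v) / vnorm[k]
        nz <- rn > 0
        sims[nz] <- sims[nz] / rn[nz]
        sims[!nz] <- 0
      }
      lp <- which.max(sims)                 # predicted (1-based)
      l <- labels[k] + 1L                   # true (1-based)
      touched <- updateFun(environment(), l, lp, sims[l], sims[lp], v)
      if (length(touched)) {
        touched <- unique(touched)
        rn[touched] <- sqrt(rowSums(C[touched, , drop = FALSE]^2))
      }
    }
  }
  model@classHVs <- C
  model
}

#' Adaptive training for the natural-scenes task
#'
#' Similarity-proportional perceptron-style updates on class HVs. For a
#' correctly predicted sample: `C_l += eta * (1 - d_l) * V`. For a
#' misprediction `l -> l'`: `C_l += eta * (d_l' - d_l) * V` and
#' `C_l' -= eta * (d_l' - d_l) * V`, where `d` denotes cosine similarity of
#' the sample to the named class HV. Defaults: `eta = 0.01`, 3 epochs;
#' samples are presented in a freshly seeded shuffled order each epoch.
#'
#' @param V `n x D` matrix of trial HVs.
#' @param labels Integer 0-based class labels.
#' @param model A [ClassModel-class] (task `"natural_scenes"`).
#' @param eta,epochs Learning rate and epoch count (default from the model).
#' @param seed Seed for the per-epoch shuffles.
#' @return The updated [ClassModel-class].
#' @export
trainScenes <- function(V, labels, model = NULL, eta = NULL, epochs = NULL,
                        seed = 1L) {
  if (is.null(model)) model <- newClassModel("natural_scenes", D = ncol(V))
  if (is.null(eta)) eta <- model@hyperparams$eta
  if (is.null(epochs)) epochs <- model@hyperparams$epochs
  adaptiveTrain(V, labels, model, epochs, seed,
    function(env, l, lp, dl, dlp, v) {
      if (lp == l) {
        env$C[l, ] <- env$C[l, ] + eta * (1 - dl) * v
        l
      } else {
        d <- dlp - dl
        env$C[l, ] <- env$C[l, ] + eta * d * v
        env$C[lp, ] <- env$C[lp, ] - eta * d * v
        c(l, lp)
      }
    })
}

#' Adaptive training for the Gabor location task
#'
#' Like [trainScenes()] but exploiting grid proximity: on a correct
#' prediction the center class is updated with `etaCenter` and its (up to 8)
#' grid neighbors with `etaNeighbor`; on a misprediction the true class and
#' its neighbors are pulled toward the sample (`+`) while the predicted
#' class and its neighbors are pushed away (`-`), with the same
#' center/neighbor rates. Updates are applied additively in that order when
#' neighborhoods overlap. Defaults: `etaCenter = 0.01`,
#' `etaNeighbor = 0.001`, 2 epochs.
#'
#' @inheritParams trainScenes
#' @param adjacency Neighbor lists from [gridAdjacency()].
#' @param etaCenter,etaNeighbor Learning rates.
#' @return The updated [ClassModel-class].
#' @export
trainGabor <- function(V, labels, model = NULL, adjacency = gridAdjacency(),
                       etaCenter = NULL, etaNeighbor = NULL, epochs = NULL,
                       seed = 1L) {
  if (is.null(model)) model <- newClassModel("gabor", D = ncol(V))
  if (is.null(etaCenter)) etaCenter <- model@hyperparams$etaCenter
  if (is.null(etaNeighbor)) etaNeighbor <- model@hyperparams$etaNeighbor
  if (is.null(epochs)) epochs <- model@hyperparams$epochs
  adaptiveTrain(V, labels, model, epochs, seed,
    function(env, l, lp, dl, dlp, v) {
      nb <- adjacency[[l]]
      if (lp == l) {
        s <- etaCenter * (1 - dl)
        env$C[l, ] <- env$C[l, ] + s * v
        sn <- etaNeighbor * (1 - dl)
        env$C[nb, ] <- env$C[nb, ] + rep(sn, length(nb)) %o% v
        c(l, nb)
      } else {
        d <- dlp - dl
        nbp <- adjacency[[lp]]
        env$C[l, ] <- env$C[l, ] + etaCenter * d * v
        env$C[nb, ] <- env$C[nb, ] + rep(etaNeighbor * d, length(nb)) %o% v
        env$C[lp, ] <- env$C[lp, ] - etaCenter * d * v
        env$C[nbp, ] <- env$C[nbp, ] - rep(etaNeighbor * d, length(nbp)) %o% v
        c(l, nb, lp, nbp)
      }
    })
}
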