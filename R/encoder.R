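## NeuroPixelHD encoding: receptive-field, area, polarization and time HVs
## fused into one hypervector per trial.

#' Create an HDEncoder
#'
#' Draws every random basis of the encoding from named substreams of one
#' master seed: the 81 x D standard-normal projection matrix `B` and phase
#' vector `b` (receptive-field encoding), one uniform \[0,1) HV per brain
#' area and per region, a bipolar polarization HV `H+` (with `H- = -H+`),
#' and two bipolar E/I population HVs shared across areas.
#'
#' @param areas Character vector of area names present in the data.
#' @param regions Character vector of region names.
#' @param D Hyperdimension (default 10^4).
#' @param seed Integer master seed.
#' @param timeMode `"independent"` (default): fresh time-HV endpoints per
#'   trial, preventing implicit averaging across trials during training;
#'   `"shared"`: one set of time HVs reused by every trial.
#' @param normalizeByUnits Divide each time bin's spatial bundle by the
#'   number of spatial units (default `FALSE`, following the encoding
#'   formula literally).
#' @return An [HDEncoder-class] object.
#' @export
newEncoder <- function(areas, regions = character(), D = 10000L, seed = 1L,
                       timeMode = c("independent", "shared"),
                       normalizeByUnits = FALSE) {
  timeMode <- match.arg(timeMode)
  D <- checkDim(D)
  areas <- unique(as.character(areas))
  regions <- unique(as.character(regions))
  B <- withSeed(streamSeed(seed, "rf-projection"),
                matrix(rnorm(81L * D), nrow = 81L, ncol = D))
  b <- withSeed(streamSeed(seed, "rf-phase"), runif(D, 0, 2 * pi))
  areaHVs <- matrix(numeric(0), nrow = 0, ncol = D)
  if (length(areas)) {
    areaHVs <- do.call(rbind, lapply(areas, function(a)
      makeUnitHV(D, seed = streamSeed(seed, paste0("area-", a)))))
    rownames(areaHVs) <- areas
  }
  regionHVs <- matrix(numeric(0), nrow = 0, ncol = D)
  if (length(regions)) {
    regionHVs <- do.call(rbind, lapply(regions, function(r)
      makeUnitHV(D, seed = streamSeed(seed, paste0("region-", r)))))
    rownames(regionHVs) <- regions
  }
  Hplus <- makeBipolarHV(D, seed = streamSeed(seed, "polarization"))
  eiHVs <- rbind(E = makeBipolarHV(D, seed = streamSeed(seed, "ei-E")),
                 I = makeBipolarHV(D, seed = streamSeed(seed, "ei-I")))
  new("HDEncoder", D = D, seed = as.integer(seed), B = B, b = b,
      areaHVs = areaHVs, regionHVs = regionHVs, Hplus = Hplus,
      eiHVs = eiHVs, timeMode = timeMode,
      normalizeByUnits = isTRUE(normalizeByUnits))
}

#' Encode a receptive-field response vector into a hypervector
#'
#' Random-Fourier-feature style encoding inspired by the RBF kernel trick:
#' `cos(B^T F + b)` bound (element-wise product) with `sin(B^T F)`, giving
#' entries in \[-1, 1\] whose pairwise cosine similarity decays with the
#' distance between response vectors. The all-zero response vector encodes
#' to the zero HV (sin(0) = 0) — a documented degenerate case: such units
#' contribute only through the polarization structure.
#'
#' @param Fi Length-81 receptive-field response vector (or an `n x 81`
#'   matrix of them).
#' @param enc An [HDEncoder-class] (its `B`, `b` slots are used).
#' @return Length-D numeric HV (or `n x D` matrix).
#' @export
encodeReceptiveField <- function(Fi, enc) {
  if (is.matrix(Fi)) {
    if (ncol(Fi) != 81L) stop("receptive-field matrix must have 81 columns")
    proj <- Fi %*% enc@B                       # n x D
    cos(sweep(proj, 2, enc@b, "+")) * sin(proj)
  } else {
    if (length(Fi) != 81L) stop("receptive-field vector must have length 81")
    proj <- drop(crossprod(enc@B, Fi))         # length D
    cos(proj + enc@b) * sin(proj)
  }
}

#' Spatial hypervectors for a binned tensor at its aggregation level
#'
#' Neuron level: each unit's encoded receptive field bound with its area HV.
#' Population level: the shared E or I bipolar HV bound with the area HV.
#' Area level: the area HV itself. Region level: one fresh independent HV
#' per region. Whole-brain level: no spatial HV is used (the trial encoding
#' reduces to counts times time HVs) — returns `NULL`.
#'
#' @param bt A [BinnedTensor-class].
#' @param enc An [HDEncoder-class].
#' @param rfMatrix `n_units x 81` receptive-field matrix (required at neuron
#'   level; rows in `bt@unitInfo` order).
#' @return `n_spatial_units x D` numeric matrix, or `NULL` at whole-brain
#'   level.
#' @export
buildSpatialHVs <- function(bt, enc, rfMatrix = NULL) {
  ui <- bt@unitInfo
  lookup <- function(M, keys, what) {
    miss <- setdiff(unique(keys), rownames(M))
    if (length(miss))
      stop("encoder has no ", what, " HV for: ", paste(miss, collapse = ", "))
    M[keys, , drop = FALSE]
  }
  switch(bt@spatialLevel,
    neuron = {
      if (is.null(rfMatrix))
        stop("neuron-level encoding needs a receptive-field matrix ",
             "(see receptiveFieldMatrix)")
      if (nrow(rfMatrix) != nrow(ui))
        stop("rfMatrix rows must match the tensor's spatial units")
      encodeReceptiveField(rfMatrix, enc) *
        lookup(enc@areaHVs, ui$area, "area")
    },
    population = lookup(enc@eiHVs, ui$ei, "E/I") *
                 lookup(enc@areaHVs, ui$area, "area"),
    area = lookup(enc@areaHVs, ui$area, "area"),
    region = lookup(enc@regionHVs, ui$region, "region"),
    whole_brain = NULL)
}

#' Time hypervectors for M bins by linear interpolation
#'
#' Random binary \{0,1\} endpoint HVs `T(0)` and `T(M-1)` are drawn and
#' intermediate bins are convex combinations
#' `T(t) = (1 - t/M) T(0) + (t/M) T(M-1)`, `t = 0..M-1`, so similarity
#' between time HVs decays with temporal distance. Endpoints are drawn per
#' trial (`timeMode = "independent"`) or once (`"shared"`).
#'
#' @param M Number of time bins (>= 1).
#' @param enc An [HDEncoder-class].
#' @param trialId Trial identifier, used to derive the per-trial substream
#'   in independent mode (ignored in shared mode).
#' @return `M x D` numeric matrix, rows `T(0) .. T(M-1)`.
#' @export
makeTimeHVs <- function(M, enc, trialId = NULL) {
  M <- as.integer(M)
  if (M < 1L) stop("number of time bins M must be >= 1")
  stream <- if (enc@timeMode == "shared") "time-shared"
            else paste0("time-trial-", trialId)
  ends <- makeBinaryHV(enc@D, seed = streamSeed(enc@seed, stream), n = 2L)
  w <- (seq_len(M) - 1L) / M
  (1 - w) %o% ends[1L, ] + w %o% ends[2L, ]
}

#' Encode trials into hypervectors
#'
#' For each trial, each time bin's spatial bundle is formed by scaling the
#' spatial HVs of spiking units by their spike counts and binding with `H+`,
#' adding the spatial HVs of silent units bound with `H-`; the bundle is
#' bound with that bin's time HV and bundled over time:
#' `V = sum_t [ sum_{i: n_i(t)>0} n_i(t) S_i (x) H+  +  sum_{i: n_i(t)=0} S_i (x) H- ] (x) T(t)`.
#' At whole-brain level this reduces to `V = sum_t n(t) T(t)`.
#'
#' @param bt A [BinnedTensor-class].
#' @param enc An [HDEncoder-class].
#' @param trialIds Identifiers of the trials (dimnames of `bt@counts` by
#'   default); used to seed per-trial time HVs in independent mode.
#' @param rfMatrix Passed to [buildSpatialHVs()] (neuron level only).
#' @param spatialHVs Precomputed spatial HVs, to avoid rebuilding across
#'   calls.
#' @return `n_trials x D` numeric matrix of trial hypervectors.
#' @export
encodeTrials <- function(bt, enc, trialIds = NULL, rfMatrix = NULL,
                         spatialHVs = NULL) {
  d <- dim(bt@counts)
  n <- d[1]; M <- d[2]; K <- d[3]
  if (is.null(trialIds)) {
    trialIds <- dimnames(bt@counts)[[3]]
    if (is.null(trialIds)) trialIds <- as.character(seq_len(K))
  }
  if (length(trialIds) != K) stop("trialIds length must match trials")
  wholeBrain <- bt@spatialLevel == "whole_brain"
  if (!wholeBrain && is.null(spatialHVs))
    spatialHVs <- buildSpatialHVs(bt, enc, rfMatrix)
  Hp <- enc@Hplus; Hm <- -Hp
  V <- matrix(0, nrow = K, ncol = enc@D)
  sharedT <- if (enc@timeMode == "shared") makeTimeHVs(M, enc) else NULL
  for (k in seq_len(K)) {
    Tm <- if (is.null(sharedT)) makeTimeHVs(M, enc, trialIds[k]) else sharedT
    cnt <- matrix(bt@counts[, , k], nrow = n)      # n x M
    if (wholeBrain) {
      V[k, ] <- colSums(drop(cnt) * Tm)            # n == 1 here
      next
    }
    # spatial bundles per bin: D x M matrices via one BLAS call each
    Aplus <- crossprod(spatialHVs, cnt)            # D x M, zero counts drop out
    Aminus <- crossprod(spatialHVs, (cnt == 0) * 1)
    A <- Aplus * Hp + Aminus * Hm                  # polarization binding
    if (enc@normalizeByUnits) A <- A / n
    V[k, ] <- rowSums(A * t(Tm))                   # bind time HVs, bundle over t
  }
  rownames(V) <- trialIds
  V
}
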