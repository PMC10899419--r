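## S4 container classes.

#' SpikeDataset: units, trials, and 1 ms-binned spike counts
#'
#' The base container for a decoding session: a units table (unit id, brain
#' area, brain region), a trials table (trial id, task, class label), and an
#' integer count array of dimension `n_units x 250 x n_trials` holding spike
#' counts in half-open 1 ms bins `[k, k+1)` relative to trial onset. Trials
#' last 250 ms. Tasks are `"gabor"` (81 classes, the 9x9 location grid) and
#' `"natural_scenes"` (118 classes).
#'
#' @slot units data.frame with columns `unit_id`, `area`, `region`.
#' @slot trials data.frame with columns `trial_id`, `task`, `class_label`.
#' @slot counts integer array `n_units x 250 x n_trials`; dimnames carry
#'   unit ids and trial ids.
#' @seealso [readSpikeDataset()], [synthesizeDataset()], [binTemporal()]
#' @export
setClass("SpikeDataset",
  representation(units = "data.frame", trials = "data.frame",
                 counts = "array"))

setValidity("SpikeDataset", function(object) {
  msg <- character()
  u <- object@units; tr <- object@trials; x <- object@counts
  if (!all(c("unit_id", "area", "region") %in% names(u)))
    msg <- c(msg, "units table needs columns unit_id, area, region")
  if (!all(c("trial_id", "task", "class_label") %in% names(tr)))
    msg <- c(msg, "trials table needs columns trial_id, task, class_label")
  if (anyDuplicated(u$unit_id)) msg <- c(msg, "duplicated unit_id")
  if (anyDuplicated(tr$trial_id)) msg <- c(msg, "duplicated trial_id")
  if (length(dim(x)) != 3L)
    msg <- c(msg, "counts must be a 3-d array [units x 250 x trials]")
  else {
    if (dim(x)[2] != 250L) msg <- c(msg, "counts must have 250 time bins")
    if (dim(x)[1] != nrow(u)) msg <- c(msg, "counts rows != number of units")
    if (dim(x)[3] != nrow(tr)) msg <- c(msg, "counts slices != number of trials")
    if (any(x < 0)) msg <- c(msg, "negative spike counts")
    if (any(x != round(x))) msg <- c(msg, "non-integer spike counts")
  }
  bad <- !tr$task %in% c("gabor", "natural_scenes")
  if (any(bad)) msg <- c(msg, "task must be 'gabor' or 'natural_scenes'")
  rng <- ifelse(tr$task == "gabor", 80L, 117L)
  if (any(tr$class_label < 0 | tr$class_label > rng))
    msg <- c(msg, "class_label out of range for its task (0-80 gabor, 0-117 scenes)")
  if (length(msg)) msg else TRUE
})

#' BinnedTensor: spike counts at a chosen spatiotemporal resolution
#'
#' Counts aggregated to one of five spatial levels (`neuron`, `population`,
#' `area`, `region`, `whole_brain`) and a temporal bin size. In `exact` mode
#' the bin size divides 250 and `M = 250 / bin_size_ms`; `overlap` and `crop`
#' modes admit non-divisor bin sizes by over- or under-counting respectively.
#'
#' @slot counts numeric array `n_spatial_units x M x n_trials`.
#' @slot unitInfo data.frame describing each spatial unit: columns `label`,
#'   `area`, `region`, `ei` (NA where not applicable).
#' @slot binSize integer bin width in ms.
#' @slot binMode one of `"exact"`, `"overlap"`, `"crop"`.
#' @slot spatialLevel one of `"neuron"`, `"population"`, `"area"`,
#'   `"region"`, `"whole_brain"`.
#' @seealso [binTemporal()], [aggregateSpatial()]
#' @export
setClass("BinnedTensor",
  representation(counts = "array", unitInfo = "data.frame",
                 binSize = "integer", binMode = "character",
                 spatialLevel = "character"))

setValidity("BinnedTensor", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be 3-d [spatial x time x trials]")
  else if (dim(object@counts)[1] != nrow(object@unitInfo))
    msg <- c(msg, "unitInfo rows must match counts rows")
  if (any(object@counts < 0)) msg <- c(msg, "negative counts")
  if (!object@binMode %in% c("exact", "overlap", "crop"))
    msg <- c(msg, "binMode must be exact/overlap/crop")
  if (!object@spatialLevel %in% spatialLevels())
    msg <- c(msg, "unknown spatialLevel")
  if (object@binMode == "exact" &&
      dim(object@counts)[2] != 250L %/% object@binSize)
    msg <- c(msg, "exact mode requires M = 250 / binSize")
  if (length(msg)) msg else TRUE
})

#' Spatial aggregation levels, finest to coarsest
#' @return Character vector of the five levels.
#' @export
spatialLevels <- function()
  c("neuron", "population", "area", "region", "whole_brain")

#' HDEncoder: the random bases of the NeuroPixelHD encoding
#'
#' Holds everything needed to map a trial's binned spike counts to one trial
#' hypervector: the receptive-field projection basis (`B`: 81 x D standard
#' normal, `b`: length D uniform on \[0, 2pi)), per-area HVs (uniform \[0,1)),
#' per-region HVs, the polarization pair (`Hplus` bipolar, `Hminus = -Hplus`),
#' two bipolar E/I population HVs shared across areas, and the time-HV mode.
#' All slots are regenerated deterministically from `seed` via named
#' substreams.
#'
#' @slot D integer hyperdimension.
#' @slot seed integer master seed.
#' @slot B,b receptive-field projection basis.
#' @slot areaHVs,regionHVs named matrices, one row per area/region.
#' @slot Hplus bipolar polarization HV (presence of spikes).
#' @slot eiHVs 2 x D bipolar matrix, rows "E" and "I".
#' @slot timeMode `"independent"` (fresh time HVs per trial; the default) or
#'   `"shared"` (one set reused across trials).
#' @slot normalizeByUnits logical; divide the spatial bundle by the number of
#'   spatial units (off by default, following the encoding formula literally).
#' @seealso [newEncoder()], [encodeTrials()]
#' @export
setClass("HDEncoder",
  representation(D = "integer", seed = "integer",
                 B = "matrix", b = "numeric",
                 areaHVs = "matrix", regionHVs = "matrix",
                 Hplus = "numeric", eiHVs = "matrix",
                 timeMode = "character", normalizeByUnits = "logical"))

setValidity("HDEncoder", function(object) {
  msg <- character()
  D <- object@D
  if (nrow(object@B) != 81L || ncol(object@B) != D)
    msg <- c(msg, "B must be 81 x D")
  if (length(object@b) != D) msg <- c(msg, "b must have length D")
  if (length(object@Hplus) != D || !all(object@Hplus %in% c(-1, 1)))
    msg <- c(msg, "Hplus must be a bipolar HV of length D")
  if (!identical(rownames(object@eiHVs), c("E", "I")))
    msg <- c(msg, "eiHVs must have rows E and I")
  if (!object@timeMode %in% c("independent", "shared"))
    msg <- c(msg, "timeMode must be 'independent' or 'shared'")
  if (length(msg)) msg else TRUE
})

#' ClassModel: adaptively trained class hypervectors
#'
#' One prototype hypervector per class, trained with similarity-proportional
#' updates; prediction assigns a trial HV to the class of maximal cosine
#' similarity. Class HVs are initialized to zero.
#'
#' @slot classHVs m x D numeric matrix.
#' @slot task `"gabor"` or `"natural_scenes"`.
#' @slot hyperparams named list of learning rates and epoch counts.
#' @seealso [newClassModel()], [trainScenes()], [trainGabor()],
#'   [predictClasses()]
#' @export
setClass("ClassModel",
  representation(classHVs = "matrix", task = "character",
                 hyperparams = "list"))

setValidity("ClassModel", function(object) {
  msg <- character()
  if (!object@task %in% c("gabor", "natural_scenes"))
    msg <- c(msg, "task must be 'gabor' or 'natural_scenes'")
  if (object@task == "gabor" && nrow(object@classHVs) != 81L)
    msg <- c(msg, "gabor model must have 81 classes")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "SpikeDataset", function(object) {
  tt <- table(object@trials$task)
  cat("SpikeDataset:", nrow(object@units), "units,",
      nrow(object@trials), "trials (",
      paste(names(tt), tt, sep = "=", collapse = ", "), ")\n")
  cat("  areas:", paste(sort(unique(object@units$area)), collapse = ", "), "\n")
  cat("  total spikes:", sum(object@counts), "\n")
})

setMethod("show", "BinnedTensor", function(object) {
  d <- dim(object@counts)
  cat("BinnedTensor:", d[1], "spatial units [", object@spatialLevel, "] x",
      d[2], "bins of", object@binSize, "ms [", object@binMode, "] x",
      d[3], "trials\n")
})

setMethod("show", "HDEncoder", function(object) {
  cat("HDEncoder: D =", object@D, ", seed =", object@seed,
      ", timeMode =", object@timeMode, "\n")
  cat("  areas:", nrow(object@areaHVs), " regions:", nrow(object@regionHVs), "\n")
})

setMethod("show", "ClassModel", function(object) {
  cat("ClassModel [", object@task, "]:", nrow(object@classHVs), "classes, D =",
      ncol(object@classHVs), "\n")
  cat("  trained:", if (any(object@classHVs != 0)) "yes" else "no (all-zero)", "\n")
})

## ---- accessors -------------------------------------------------------------

#' Accessors for the S4 containers
#'
#' @param x A `SpikeDataset` or `BinnedTensor`.
#' @return `unitsTable`/`trialsTable`/`unitInfo`: a data.frame;
#'   `spikeCounts`: the count array; `nUnits`/`nTrials`: integers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
unitsTable <- function(x) x@units

#' @rdname accessors
#' @export
trialsTable <- function(x) x@trials

#' @rdname accessors
#' @export
spikeCounts <- function(x) x@counts

#' @rdname accessors
#' @export
nUnits <- function(x) nrow(x@units)

#' @rdname accessors
#' @export
nTrials <- function(x) {
  if (is(x, "SpikeDataset")) nrow(x@trials) else dim(x@counts)[3]
}

#' @rdname accessors
#' @export
unitInfo <- function(x) x@unitInfo

#' @rdname accessors
#' @export
classHVs <- function(x) x@classHVs
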