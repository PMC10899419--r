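## Temporal binning and the five-level spatial aggregation.

DIVISOR_BINS <- c(1L, 2L, 5L, 10L, 25L, 50L, 125L, 250L)

#' Bin 1 ms spike counts into coarser time bins
#'
#' Three modes. `exact` (the default; bin size must divide 250): consecutive
#' disjoint bins, total count conserved, `M = 250 / bin_size`. For
#' non-divisor bin sizes: `overlap` places `M = ceiling(250 / w)` bins of
#' width `w` with starts `floor(j * (250 - w) / (M - 1))`, so the last bin
#' ends at 250 ms and bins may overlap (over-counting); `crop` uses
#' `M = floor(250 / w)` disjoint bins and discards the trailing remainder
#' (under-counting).
#'
#' @param ds A [SpikeDataset-class] (or a `n_units x 250 x n_trials` array).
#' @param binSize Positive integer bin width in ms.
#' @param binMode `"exact"`, `"overlap"`, or `"crop"`.
#' @param unitInfo Optional spatial-unit descriptor table (defaults to the
#'   dataset's units at neuron level).
#' @return A [BinnedTensor-class] at neuron level.
#' @examples
#' ds <- synthesizeDataset(synthConfig(task = "gabor", n_areas = 2,
#'   units_per_area = 3, reps_per_class = 1, seed = 1))
#' binTemporal(ds, 125)
#' @export
binTemporal <- function(ds, binSize, binMode = c("exact", "overlap", "crop"),
                        unitInfo = NULL) {
  binMode <- match.arg(binMode)
  if (is(ds, "SpikeDataset")) {
    x <- ds@counts
    if (is.null(unitInfo))
      unitInfo <- data.frame(label = as.character(ds@units$unit_id),
                             area = ds@units$area, region = ds@units$region,
                             ei = NA_character_, stringsAsFactors = FALSE)
  } else x <- ds
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == 250L)
  if (is.null(unitInfo))
    unitInfo <- data.frame(label = as.character(seq_len(dim(x)[1])),
                           area = NA_character_, region = NA_character_,
                           ei = NA_character_, stringsAsFactors = FALSE)
  binSize <- as.integer(binSize)
  if (binSize < 1L || binSize > 250L) stop("binSize must be in 1..250 ms")

  if (binMode == "exact") {
    if (250L %% binSize != 0L)
      stop("binSize ", binSize, " does not divide 250 ms; ",
           "use binMode = 'overlap' or 'crop' for non-divisor bins")
    M <- 250L %/% binSize
    starts <- (seq_len(M) - 1L) * binSize
  } else if (binMode == "crop") {
    M <- 250L %/% binSize
    if (M < 1L) stop("binSize too large to fit one bin")
    starts <- (seq_len(M) - 1L) * binSize
  } else { # overlap
    M <- as.integer(ceiling(250 / binSize))
    starts <- if (M == 1L) 0L else
      as.integer(floor((seq_len(M) - 1L) * (250L - binSize) / (M - 1L)))
  }
  n <- dim(x)[1]; K <- dim(x)[3]
  out <- array(0, dim = c(n, M, K),
               dimnames = list(unitInfo$label, NULL, dimnames(x)[[3]]))
  # cumulative sum over time lets each window be a difference of two slices
  cs <- apply(x, c(1, 3), cumsum)            # 250 x n x K
  winSum <- function(s, w) {                 # sum over base bins (s, s+w]
    hi <- cs[s + w, , , drop = FALSE]
    lo <- if (s == 0L) 0 else cs[s, , , drop = FALSE]
    hi - lo
  }
  for (j in seq_len(M)) out[, j, ] <- winSum(starts[j], binSize)
  new("BinnedTensor", counts = out, unitInfo = unitInfo,
      binSize = binSize, binMode = binMode, spatialLevel = "neuron")
}

#' Spike-count Fano factors per unit
#'
#' Variance-to-mean ratio of a unit's spike counts in bins of `fanoBin` ms,
#' pooled over all time bins, Gabor locations and trials. Elevated Fano
#' factor is used as a functional proxy for (putatively) inhibitory identity.
#' Silent units (mean 0) get Fano 0, so they land in the excitatory pool.
#'
#' @param ds A [SpikeDataset-class]; only gabor trials are used.
#' @param fanoBin Bin size in ms; must divide 250.
#' @param varType `"population"` (divide by N, the default) or `"sample"`.
#' @return Named numeric vector, one Fano factor per unit.
#' @export
fanoFactor <- function(ds, fanoBin = 25L, varType = c("population", "sample")) {
  varType <- match.arg(varType)
  fanoBin <- as.integer(fanoBin)
  if (250L %% fanoBin != 0L) stop("fanoBin must divide 250 ms")
  keep <- ds@trials$task == "gabor"
  if (!any(keep)) stop("Fano clustering needs gabor trials")
  bt <- binTemporal(ds@counts[, , keep, drop = FALSE], fanoBin, "exact")
  x <- bt@counts                                 # n x M x K
  n <- dim(x)[1]
  f <- vapply(seq_len(n), function(i) {
    z <- as.numeric(x[i, , ])
    m <- mean(z)
    if (m == 0) return(0)
    v <- if (varType == "population") mean((z - m)^2) else var(z)
    v / m
  }, numeric(1))
  names(f) <- as.character(ds@units$unit_id)
  f
}

#' Cluster units into putative E/I populations by Fano factor
#'
#' Within each brain area independently, the `ceiling(0.2 * n)` units with
#' the highest Fano factor are labeled putatively inhibitory (`"I"`), the
#' rest excitatory (`"E"`) — the nominal 80/20 cortical split. Ties at the
#' boundary are broken by unit-id order; an area with a single unit gets one
#' I unit by the ceiling rule (a degenerate case, flagged with a message).
#'
#' @param units Units data.frame (`unit_id`, `area`).
#' @param fano Per-unit Fano factors in `units` row order.
#' @param fracInhibitory Fraction labeled I per area (default 0.2).
#' @return Character vector of labels `"E"`/`"I"` in `units` row order.
#' @export
clusterPopulations <- function(units, fano, fracInhibitory = 0.2) {
  stopifnot(nrow(units) == length(fano))
  lab <- rep("E", nrow(units))
  for (a in unique(units$area)) {
    idx <- which(units$area == a)
    nI <- as.integer(ceiling(fracInhibitory * length(idx)))
    if (length(idx) == 1L)
      message("area ", a, " has a single unit; labeled I by the ceiling rule")
    ord <- idx[order(-fano[idx], units$unit_id[idx])]
    lab[ord[seq_len(nI)]] <- "I"
  }
  lab
}

#' Aggregate a BinnedTensor to a coarser spatial level
#'
#' Spike counts are summed within each group of spatial units: E/I
#' populations within areas (`population`), areas (`area`), regions
#' (`region`), or everything (`whole_brain`). Total spikes are conserved.
#'
#' @param bt A [BinnedTensor-class] at a finer level.
#' @param level Target level (see [spatialLevels()]).
#' @param eiLabels Per-row `"E"`/`"I"` labels, required for
#'   `level = "population"` when `bt@unitInfo$ei` is not already set.
#' @return A [BinnedTensor-class] at the requested level.
#' @export
aggregateSpatial <- function(bt, level, eiLabels = NULL) {
  level <- match.arg(level, spatialLevels())
  lv <- match(level, spatialLevels())
  cur <- match(bt@spatialLevel, spatialLevels())
  if (lv < cur) stop("cannot refine from ", bt@spatialLevel, " to ", level)
  if (lv == cur) return(bt)
  ui <- bt@unitInfo
  if (!is.null(eiLabels)) ui$ei <- eiLabels
  key <- switch(level,
    population = {
      if (any(is.na(ui$ei)))
        stop("population level needs E/I labels (eiLabels or unitInfo$ei)")
      paste(ui$area, ui$ei, sep = "/")
    },
    area = ui$area,
    region = ui$region,
    whole_brain = rep("brain", nrow(ui)))
  if (level %in% c("population", "area") && any(is.na(ui$area)))
    stop("spatial units lack area annotation")
  if (level == "region" && any(is.na(ui$region)))
    stop("spatial units lack region annotation")
  g <- factor(key, levels = unique(key))
  d <- dim(bt@counts)
  flat <- matrix(bt@counts, nrow = d[1])           # rows = spatial units
  agg <- rowsum(flat, g, reorder = FALSE)
  first <- match(levels(g), key)
  info <- data.frame(label = levels(g),
                     area = if (level %in% c("population", "area"))
                       ui$area[first] else NA_character_,
                     region = if (level != "whole_brain")
                       ui$region[first] else NA_character_,
                     ei = if (level == "population") ui$ei[first]
                          else NA_character_,
                     stringsAsFactors = FALSE)
  new("BinnedTensor",
      counts = array(agg, dim = c(nlevels(g), d[2], d[3]),
                     dimnames = list(levels(g), NULL,
                                     dimnames(bt@counts)[[3]])),
      unitInfo = info, binSize = bt@binSize, binMode = bt@binMode,
      spatialLevel = level)
}
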