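## Data model and CSV I/O for units, trials and 1 ms spike counts.

#' Brain area to region assignment
#'
#' The standard assignment of recorded areas to nine brain regions used for
#' region-level spatial averaging (striate / extrastriate visual cortex,
#' hippocampal formation, thalamus, hypothalamus, midbrain).
#'
#' @return data.frame with columns `area`, `region`.
#' @export
areaRegionTable <- function() {
  map <- list(
    "Striate cortex"              = "VISp",
    "Dorsal extrastriate cortex"  = c("VISam", "VISal", "VISrl", "VISmma"),
    "Ventral extrastriate cortex" = c("VISpm", "VISl"),
    "Hippocampus"                 = c("CA1", "CA2", "CA3"),
    "Subiculum"                   = c("SUB", "ProS"),
    "Dentate Gyrus"               = "DG",
    "Thalamus"                    = c("TH", "LP", "LGv", "LGd", "PP", "PIL",
                                      "MGv", "PO", "Eth", "POL"),
    "Hypothalamus"                = "ZI",
    "Midbrain"                    = "APN")
  data.frame(area = unlist(map, use.names = FALSE),
             region = rep(names(map), lengths(map)),
             stringsAsFactors = FALSE)
}

TRIAL_MS <- 250L

taskClassCount <- function(task)
  switch(task, gabor = 81L, natural_scenes = 118L,
         stop("unknown task: ", task))

#' Gabor class label to 9x9 grid coordinates
#'
#' Labels 0..80 map row-major onto the grid:
#' `x = label mod 9`, `y = label div 9`. The convention is configurable
#' wherever distances are computed (see [euclidErrors()]).
#'
#' @param label Integer vector of class labels in 0..80.
#' @return data.frame with columns `x`, `y` in 0..8.
#' @export
gaborGrid <- function(label = 0:80) {
  stopifnot(all(label >= 0 & label <= 80))
  data.frame(x = label %% 9L, y = label %/% 9L)
}

#' Construct a SpikeDataset from in-memory tables
#'
#' @param units data.frame with `unit_id`, `area` (and optionally `region`;
#'   otherwise derived via `areaMap`).
#' @param trials data.frame with `trial_id`, `task`, `class_label`.
#' @param counts integer array `n_units x 250 x n_trials`, rows in
#'   `units$unit_id` order.
#' @param areaMap data.frame `area`/`region` used to fill in regions;
#'   defaults to [areaRegionTable()]. Areas absent from the map are an error
#'   (supply your own map rather than silently dropping units).
#' @return A [SpikeDataset-class] object.
#' @export
newSpikeDataset <- function(units, trials, counts,
                            areaMap = areaRegionTable()) {
  units <- as.data.frame(units)
  trials <- as.data.frame(trials)
  if (is.null(units$region)) {
    idx <- match(units$area, areaMap$area)
    if (anyNA(idx))
      stop("areas not in the area->region map: ",
           paste(unique(units$area[is.na(idx)]), collapse = ", "),
           " (supply areaMap to extend the mapping)")
    units$region <- areaMap$region[idx]
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(as.character(units$unit_id), NULL,
                           as.character(trials$trial_id))
  new("SpikeDataset", units = units, trials = trials, counts = counts)
}

#' Read a SpikeDataset from three CSV tables
#'
#' Expected files (UTF-8, comma-delimited, header row; columns matched by
#' name): a spike-events table (`unit_id, trial_id, time_ms`), a units table
#' (`unit_id, area`), and a trials table (`trial_id, task, class_label`).
#' Spike times are trial-relative milliseconds in the half-open interval
#' \[0, 250) and are floored into 1 ms bins. Events referencing unknown unit
#' or trial ids, or times outside \[0, 250), are reported as errors with row
#' numbers.
#'
#' @param eventsPath,unitsPath,trialsPath File paths.
#' @param areaMap Optional area->region map (see [newSpikeDataset()]).
#' @return A [SpikeDataset-class] object.
#' @export
readSpikeDataset <- function(eventsPath, unitsPath, trialsPath,
                             areaMap = areaRegionTable()) {
  needCols <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("file ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  units <- read.csv(unitsPath, stringsAsFactors = FALSE)
  needCols(units, c("unit_id", "area"), unitsPath)
  trials <- read.csv(trialsPath, stringsAsFactors = FALSE)
  needCols(trials, c("trial_id", "task", "class_label"), trialsPath)
  ev <- read.csv(eventsPath, stringsAsFactors = FALSE)
  needCols(ev, c("unit_id", "trial_id", "time_ms"), eventsPath)

  ui <- match(ev$unit_id, units$unit_id)
  if (anyNA(ui))
    stop("events rows with unknown unit_id: ",
         paste(head(which(is.na(ui)), 10), collapse = ", "))
  ti <- match(ev$trial_id, trials$trial_id)
  if (anyNA(ti))
    stop("events rows with unknown trial_id: ",
         paste(head(which(is.na(ti)), 10), collapse = ", "))
  bad <- which(ev$time_ms < 0 | ev$time_ms >= TRIAL_MS)
  if (length(bad))
    stop("spike times outside [0, 250) ms at events rows: ",
         paste(head(bad, 10), collapse = ", "))

  counts <- array(0L, dim = c(nrow(units), TRIAL_MS, nrow(trials)))
  bin <- floor(ev$time_ms) + 1L
  # accumulate duplicate (unit, bin, trial) events via the linear index
  lin <- (ti - 1L) * (nrow(units) * TRIAL_MS) + (bin - 1L) * nrow(units) + ui
  counts[] <- as.integer(tabulate(lin, nbins = length(counts)))
  newSpikeDataset(units, trials, counts, areaMap = areaMap)
}

#' Write a SpikeDataset to three CSV tables
#'
#' Inverse of [readSpikeDataset()]: `read(write(ds))` reproduces the count
#' array and tables bit-exactly (spikes are written at the centers of their
#' 1 ms bins).
#'
#' @param ds A [SpikeDataset-class].
#' @param dir Output directory (created if needed); writes `events.csv`,
#'   `units.csv`, `trials.csv`.
#' @return Invisibly, the three file paths.
#' @export
writeSpikeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "units.csv", "trials.csv"))
  units <- ds@units; trials <- ds@trials
  nz <- which(ds@counts > 0, arr.ind = TRUE)
  reps <- ds@counts[nz]
  ev <- data.frame(
    unit_id = rep(units$unit_id[nz[, 1]], reps),
    trial_id = rep(trials$trial_id[nz[, 3]], reps),
    time_ms = rep(nz[, 2] - 0.5, reps))
  write.csv(ev, paths[1], row.names = FALSE)
  write.csv(units[c("unit_id", "area")], paths[2], row.names = FALSE)
  write.csv(trials[c("trial_id", "task", "class_label")], paths[3],
            row.names = FALSE)
  invisible(paths)
}

#' Per-unit receptive-field response vectors from Gabor tuning trials
#'
#' For each unit, the mean total spike count over the full 250 ms trial,
#' per Gabor location (class 0..80), averaged over that location's
#' repetitions: an 81-vector functional fingerprint used by the
#' receptive-field encoding.
#'
#' @param ds A [SpikeDataset-class] containing gabor trials.
#' @param trialFilter Optional logical/integer index selecting which gabor
#'   trials to use (e.g. to hold tuning trials out of decoding).
#' @return `n_units x 81` numeric matrix, rows named by unit id.
#' @export
receptiveFieldMatrix <- function(ds, trialFilter = NULL) {
  tr <- ds@trials
  keep <- tr$task == "gabor"
  if (!is.null(trialFilter)) {
    sel <- logical(nrow(tr)); sel[trialFilter] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) stop("no gabor trials available for receptive-field tuning")
  lab <- tr$class_label[keep]
  missing <- setdiff(0:80, unique(lab))
  if (length(missing))
    stop("gabor classes with zero trials: ", paste(missing, collapse = ", "))
  totals <- apply(ds@counts[, , keep, drop = FALSE], c(1, 3), sum)
  Fm <- t(apply(totals, 1, function(z) tapply(z, factor(lab, levels = 0:80), mean)))
  Fm <- matrix(Fm, nrow = nUnits(ds),
               dimnames = list(as.character(ds@units$unit_id), 0:80))
  Fm
}
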