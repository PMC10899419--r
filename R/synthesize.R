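## Synthetic spike-data generator emulating the 250 ms visual stimulation
## protocol: Gabor 9x9 grid (81 classes x 45 reps) and natural scenes
## (118 classes x 50 reps), units assigned to real area/region names.

## areas ordered so small n_areas still spans several regions
SYNTH_AREAS <- c("VISp", "CA1", "TH", "APN", "VISal", "VISpm", "DG", "SUB",
                 "ZI", "VISam", "CA3", "LP", "VISrl", "VISl", "ProS", "LGd")

#' Configuration for the synthetic spike-data generator
#'
#' Defaults encode the emulated study conditions: 250 ms trials, 81 Gabor
#' locations x 45 repetitions or 118 natural scenes x 50 repetitions, an
#' 80/20 E/I split, ~10 Hz base firing, and within-area shared noise.
#'
#' @param task `"gabor"` or `"natural_scenes"`.
#' @param n_areas Number of brain areas (named from the standard area list).
#' @param units_per_area Units recorded per area.
#' @param frac_inhibitory Fraction of inhibitory units per area.
#' @param reps_per_class Repetitions per class (default 45 gabor / 50
#'   scenes).
#' @param base_rate_hz Baseline firing rate.
#' @param signal_gain Multiplicative strength of the class signal.
#' @param signal_timescale_ms Class templates are piecewise-constant over
#'   windows of this length (a divisor of 250); 250 means one constant
#'   level per trial.
#' @param noise_corr Within-area shared-noise strength in \[0, 1):
#'   coefficient-of-variation^2 of the shared log-normal rate factor equals
#'   `noise_corr / (1 - noise_corr)`.
#' @param inhib_dispersion Count variance-to-mean ratio for inhibitory
#'   units (> 1 gives negative-binomial counts; excitatory units are
#'   Poisson).
#' @param rf_smoothness Gaussian-kernel bandwidth (grid cells) of Gabor
#'   tuning across the 9x9 grid.
#' @param rf_block_reps For the scenes task, repetitions of an auxiliary
#'   Gabor receptive-field mapping block prepended to the session (mirrors
#'   real sessions, which start with a tuning stimulus); 0 disables it.
#' @param osc_freq_hz Optional frequency (Hz) of a sinusoidal rate
#'   modulation running continuously across trials (for oscillation
#'   analyses); `NULL` for none.
#' @param osc_depth Modulation depth of that sinusoid.
#' @param seed Integer master seed.
#' @return A list of class `"SynthConfig"`.
#' @export
synthConfig <- function(task = c("gabor", "natural_scenes"),
                        n_areas = 4L, units_per_area = 10L,
                        frac_inhibitory = 0.2, reps_per_class = NULL,
                        base_rate_hz = 10, signal_gain = 1,
                        signal_timescale_ms = 250L, noise_corr = 0.2,
                        inhib_dispersion = 3, rf_smoothness = 1.5,
                        rf_block_reps = 5L, osc_freq_hz = NULL,
                        osc_depth = 0.5, seed = 1L) {
  task <- match.arg(task)
  if (is.null(reps_per_class))
    reps_per_class <- if (task == "gabor") 45L else 50L
  if (n_areas > length(SYNTH_AREAS))
    stop("at most ", length(SYNTH_AREAS), " areas supported")
  if (250L %% as.integer(signal_timescale_ms) != 0L)
    stop("signal_timescale_ms must divide 250")
  if (noise_corr < 0 || noise_corr >= 1) stop("noise_corr must be in [0, 1)")
  if (inhib_dispersion < 1) stop("inhib_dispersion must be >= 1")
  structure(list(task = task, n_areas = as.integer(n_areas),
                 units_per_area = as.integer(units_per_area),
                 frac_inhibitory = frac_inhibitory,
                 reps_per_class = as.integer(reps_per_class),
                 base_rate_hz = base_rate_hz, signal_gain = signal_gain,
                 signal_timescale_ms = as.integer(signal_timescale_ms),
                 noise_corr = noise_corr,
                 inhib_dispersion = inhib_dispersion,
                 rf_smoothness = rf_smoothness,
                 rf_block_reps = as.integer(rf_block_reps),
                 osc_freq_hz = osc_freq_hz, osc_depth = osc_depth,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

## Gaussian smoothing kernel over the 9x9 grid (81 x 81, rows normalized)
gridKernel <- function(h) {
  g <- gaborGrid()
  d2 <- outer(g$x, g$x, "-")^2 + outer(g$y, g$y, "-")^2
  K <- exp(-d2 / (2 * h^2))
  K / rowSums(K)
}

## templates s[i, c, w]: standard-normal class signal, grid-smoothed for
## gabor, re-standardized across classes per (unit, window)
synthTemplates <- function(cfg, nClasses, gridSmooth, stream) {
  W <- 250L %/% cfg$signal_timescale_ms
  n <- cfg$n_areas * cfg$units_per_area
  withSeed(streamSeed(cfg$seed, stream), {
    s <- array(rnorm(n * nClasses * W), dim = c(n, nClasses, W))
    if (gridSmooth && nClasses == 81L && cfg$rf_smoothness > 0) {
      K <- gridKernel(cfg$rf_smoothness)
      for (w in seq_len(W)) s[, , w] <- s[, , w] %*% t(K)
    }
    for (w in seq_len(W)) {
      sw <- s[, , w, drop = FALSE]
      dim(sw) <- c(n, nClasses)
      mu <- rowMeans(sw); sdv <- apply(sw, 1, sd)
      sdv[sdv == 0] <- 1
      s[, , w] <- (sw - mu) / sdv
    }
    s
  })
}

#' Ground truth of a synthetic dataset
#'
#' The generating quantities behind [synthesizeDataset()] for the same
#' config: true E/I labels, the class rate templates, and the signal
#' timescale — for parameter-recovery tests.
#'
#' @param cfg A [synthConfig()].
#' @return List with `units` (data.frame), `eiLabels`, `templates` (array
#'   `units x classes x windows` for the main task), `rfTemplates` (gabor
#'   tuning used for the scenes task's mapping block, else `NULL`),
#'   `timescale_ms`.
#' @export
groundTruth <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  areas <- SYNTH_AREAS[seq_len(cfg$n_areas)]
  map <- areaRegionTable()
  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(cfg$n_areas * cfg$units_per_area)),
    area = rep(areas, each = cfg$units_per_area),
    stringsAsFactors = FALSE)
  units$region <- map$region[match(units$area, map$area)]
  nI <- as.integer(ceiling(cfg$frac_inhibitory * cfg$units_per_area))
  ei <- rep(rep(c("E", "I"), c(cfg$units_per_area - nI, nI)), cfg$n_areas)
  nClasses <- taskClassCount(cfg$task)
  templates <- synthTemplates(cfg, nClasses, cfg$task == "gabor", "templates")
  rfTemplates <- NULL
  if (cfg$task == "natural_scenes" && cfg$rf_block_reps > 0L) {
    full <- synthTemplates(
      modifyList(cfg, list(signal_timescale_ms = 250L)), 81L, TRUE,
      "rf-templates")
    rfTemplates <- matrix(full, nrow = dim(full)[1])   # units x 81
  }
  list(units = units, eiLabels = ei, templates = templates,
       rfTemplates = rfTemplates, timescale_ms = cfg$signal_timescale_ms)
}

#' Generate a synthetic SpikeDataset
#'
#' Per unit `i` and class `c`, the firing rate is piecewise-constant over
#' windows of the signal timescale:
#' `lambda_{i,c}(t) = base_rate * max(0, 1 + gain * s_{i,c}(floor(t/tau)))`,
#' with `s` standard-normal class templates (Gaussian-smoothed over the 9x9
#' grid for the Gabor task). Counts are drawn per 1 ms bin: Poisson for
#' excitatory units, negative-binomial with variance inflated by
#' `inhib_dispersion` for inhibitory units; a per-(area, trial, window)
#' multiplicative log-normal factor induces within-area shared noise.
#' Deterministic given `cfg$seed`. Class presentation order is a seeded
#' shuffle.
#'
#' @param cfg A [synthConfig()].
#' @return A [SpikeDataset-class]. For `task = "natural_scenes"` with
#'   `rf_block_reps > 0`, the session additionally contains a leading Gabor
#'   receptive-field mapping block.
#' @export
synthesizeDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  gt <- groundTruth(cfg)
  units <- gt$units
  n <- nrow(units)
  tau <- cfg$signal_timescale_ms
  W <- 250L %/% tau
  base <- cfg$base_rate_hz / 1000                      # per 1 ms bin

  blocks <- list(list(task = cfg$task, templates = gt$templates,
                      reps = cfg$reps_per_class,
                      nClasses = taskClassCount(cfg$task), tau = tau))
  if (!is.null(gt$rfTemplates))
    blocks <- c(list(list(task = "gabor",
                          templates = array(gt$rfTemplates,
                                            dim = c(n, 81L, 1L)),
                          reps = cfg$rf_block_reps, nClasses = 81L,
                          tau = 250L)),
                blocks)

  labels <- unlist(lapply(seq_along(blocks), function(bi) {
    b <- blocks[[bi]]
    withSeed(streamSeed(cfg$seed, paste0("order-", bi)),
             sample(rep(seq_len(b$nClasses) - 1L, b$reps)))
  }), use.names = FALSE)
  tasks <- rep(vapply(blocks, `[[`, "", "task"),
               vapply(blocks, function(b) b$nClasses * b$reps, 0))
  K <- length(labels)
  trials <- data.frame(trial_id = sprintf("t%05d", seq_len(K)),
                       task = tasks, class_label = labels,
                       stringsAsFactors = FALSE)

  sigmaG <- sqrt(log(1 + cfg$noise_corr / (1 - cfg$noise_corr)))
  areaIdx <- match(units$area, unique(units$area))
  nA <- length(unique(units$area))
  isI <- gt$eiLabels == "I"
  phi <- cfg$inhib_dispersion
  clipped <- FALSE

  counts <- array(0L, dim = c(n, 250L, K))
  offset <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    bK <- b$nClasses * b$reps
    bW <- 250L %/% b$tau
    kIdx <- offset + seq_len(bK)
    counts[, , kIdx] <- withSeed(streamSeed(cfg$seed, paste0("counts-", bi)), {
      out <- array(0L, dim = c(n, 250L, bK))
      for (j in seq_len(bK)) {
        k <- kIdx[j]
        cl <- labels[k] + 1L
        lam <- base * (1 + cfg$signal_gain * b$templates[, cl, , drop = TRUE])
        lam <- matrix(lam, nrow = n, ncol = bW)
        if (any(lam < 0)) { clipped <- TRUE; lam[lam < 0] <- 0 }
        if (sigmaG > 0) {
          g <- exp(sigmaG * rnorm(nA * bW) - sigmaG^2 / 2)
          lam <- lam * matrix(g, nrow = nA, ncol = bW)[areaIdx, , drop = FALSE]
        }
        lamFull <- lam[, rep(seq_len(bW), each = b$tau), drop = FALSE]
        if (!is.null(cfg$osc_freq_hz)) {
          tGlob <- (k - 1L) * 250L + seq_len(250L)
          mod <- 1 + cfg$osc_depth * sin(2 * pi * cfg$osc_freq_hz * tGlob / 1000)
          lamFull <- sweep(lamFull, 2, mod, "*")
        }
        draw <- integer(n * 250L)
        lamV <- as.vector(lamFull)
        eMask <- rep(!isI, 250L)
        draw[eMask] <- rpois(sum(eMask), lamV[eMask])
        if (any(!eMask)) {
          mu <- lamV[!eMask]
          if (phi > 1) {
            d <- integer(length(mu))
            pos <- mu > 0
            d[pos] <- rnbinom(sum(pos), mu = mu[pos],
                              size = mu[pos] / (phi - 1))
            draw[!eMask] <- d
          } else draw[!eMask] <- rpois(length(mu), mu)
        }
        out[, , j] <- draw
      }
      out
    })
    offset <- offset + bK
  }
  if (clipped)
    warning("some rates were negative after applying signal_gain and were ",
            "clipped to 0")
  newSpikeDataset(units, trials, counts)
}
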