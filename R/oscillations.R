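## Oscillation analysis: pooled region firing rates, Welch spectra, and a
## simplified aperiodic-removed slowest-peak parameterization.

#' Pooled firing-rate series for one region
#'
#' Mean of the 1 ms-binned spike counts across the region's units, with
#' Gabor trials concatenated in trial-id order into one contiguous stream
#' (the series is not broken or averaged across trials), sampled at 1 kHz.
#'
#' @param ds A [SpikeDataset-class].
#' @param region Region name.
#' @return Numeric vector of length `250 * n_gabor_trials`.
#' @export
regionRate <- function(ds, region) {
  uidx <- which(ds@units$region == region)
  if (!length(uidx)) stop("no units in region: ", region)
  tidx <- which(ds@trials$task == "gabor")
  if (!length(tidx)) stop("no gabor trials")
  tidx <- tidx[order(ds@trials$trial_id[tidx])]
  x <- ds@counts[uidx, , tidx, drop = FALSE]
  as.vector(colMeans(x))        # averages over units; time-within-trial fastest
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hann-tapered, mean-removed segments.
#' One-sided density scaling: the integral of the PSD over frequency
#' approximates the signal variance. Defaults (4 s windows, 50% overlap at
#' 1 kHz) give 0.25 Hz resolution, enough to localize theta-band peaks.
#'
#' @param x Numeric time series.
#' @param fs Sampling frequency in Hz (default 1000).
#' @param windowSec Segment length in seconds (default 4).
#' @param overlapFrac Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `power` (density, x-units^2/Hz).
#' @export
welchPsd <- function(x, fs = 1000, windowSec = 4, overlapFrac = 0.5) {
  nw <- as.integer(round(windowSec * fs))
  if (length(x) < nw)
    stop("series shorter than one Welch window (", nw, " samples)")
  step <- max(1L, as.integer(round(nw * (1 - overlapFrac))))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))   # Hann taper
  U <- sum(w^2)
  nf <- nw %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))^2
    acc <- acc + sp[2:(nf + 1L)]
  }
  pow <- acc / length(starts) / (fs * U) * 2   # one-sided density
  list(freq = (seq_len(nf)) * fs / nw, power = pow)
}

#' Slowest spectral peak above the aperiodic trend
#'
#' Simplified spectral parameterization: the aperiodic (1/f-like) component
#' is fit as a robust line in log10-power versus log10-frequency over
#' \[fmin, fmax\] Hz and subtracted; the residual is lightly smoothed and
#' local maxima exceeding `threshold` times the robust residual spread are
#' peak candidates. The lowest-frequency qualifying peak at or above `fmin`
#' is returned; `NULL` means no oscillation was detected (a value, not an
#' error). Peaks below `fmin` (default 3 Hz) are never reported: the
#' frequency resolution there is too poor to establish that an oscillation
#' exists.
#'
#' @param freq,power A PSD as returned by [welchPsd()].
#' @param fmin,fmax Fit/search band in Hz (defaults 3 and 50).
#' @param threshold Peak threshold in multiples of the robust residual
#'   spread (default 2).
#' @return `NULL`, or a list with `centralFrequency` (Hz),
#'   `powerAboveAperiodic` (linear power units) and `bandwidth` (Hz,
#'   half-height width of the detrended peak).
#' @export
slowestPeak <- function(freq, power, fmin = 3, fmax = 50, threshold = 2) {
  sel <- which(freq >= fmin & freq <= fmax & power > 0)
  if (length(sel) < 10L)
    stop("PSD must cover the ", fmin, "-", fmax, " Hz band")
  f <- freq[sel]; p <- log10(power[sel])
  fit <- MASS::rlm(p ~ log10(f), maxit = 50)
  resid <- p - as.vector(fitted(fit))
  sigma <- mad(resid)
  if (sigma == 0) return(NULL)
  # light smoothing (5-bin moving average) suppresses single-bin noise spikes
  k <- 5L
  sm <- as.vector(stats::filter(resid, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  n <- length(sm)
  isMax <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    sm[i] == max(sm[lo:hi]) && sm[i] >= threshold * sigma
  }, logical(1))
  cand <- which(isMax)
  if (!length(cand)) return(NULL)
  i <- cand[1L]                                  # slowest qualifying peak
  half <- sm[i] / 2
  lo <- i; while (lo > 1L && sm[lo - 1L] > half) lo <- lo - 1L
  hi <- i; while (hi < n && sm[hi + 1L] > half) hi <- hi + 1L
  list(centralFrequency = f[i],
       powerAboveAperiodic = power[sel][i] - 10^fitted(fit)[i],
       bandwidth = f[hi] - f[lo])
}

#' Slowest oscillation peak per region of a dataset
#'
#' Runs [regionRate()] -> [welchPsd()] -> [slowestPeak()] for each region
#' present in the dataset.
#'
#' @param ds A [SpikeDataset-class].
#' @param fmin,fmax,threshold Passed to [slowestPeak()].
#' @param windowSec Welch window length in seconds.
#' @return data.frame with columns `region`, `central_frequency` (NA where
#'   no oscillation was detected), `power_above_aperiodic`, `bandwidth`.
#' @export
regionPeaks <- function(ds, fmin = 3, fmax = 50, threshold = 2,
                        windowSec = 4) {
  regions <- unique(ds@units$region)
  rows <- lapply(regions, function(r) {
    rate <- regionRate(ds, r)
    psd <- welchPsd(rate, fs = 1000, windowSec = windowSec)
    pk <- slowestPeak(psd$freq, psd$power, fmin, fmax, threshold)
    data.frame(region = r,
               central_frequency = if (is.null(pk)) NA_real_
                                   else pk$centralFrequency,
               power_above_aperiodic = if (is.null(pk)) NA_real_
                                       else pk$powerAboveAperiodic,
               bandwidth = if (is.null(pk)) NA_real_ else pk$bandwidth)
  })
  do.call(rbind, rows)
}

#' Correlate oscillation central frequencies with optimal bin sizes
#'
#' Thin wrapper over [pearsonRandomizationTest()] for paired
#' (subject x region) observations.
#'
#' @param centralFreqs,optimalBinSizes Paired numeric vectors.
#' @param nPerm,seed Passed to the randomization test.
#' @return List with `r` and `p`.
#' @export
frequencyResolutionCorrelation <- function(centralFreqs, optimalBinSizes,
                                           nPerm = 10000L, seed = 1L) {
  ok <- !(is.na(centralFreqs) | is.na(optimalBinSizes))
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  pearsonRandomizationTest(centralFreqs[ok], optimalBinSizes[ok],
                           nPerm = nPerm, seed = seed)
}

#' Synthetic 1/f rate series with an optional injected oscillation
#'
#' Test signal for the oscillation pipeline: Gaussian noise spectrally
#' shaped to power ~ 1/f^slope via FFT filtering, plus an optional
#' sinusoid. Used to calibrate peak recovery and the no-peak (pure 1/f)
#' case.
#'
#' @param durationSec Length in seconds.
#' @param fs Sampling rate in Hz (default 1000).
#' @param slope Aperiodic exponent (power ~ 1/f^slope; default 1).
#' @param oscFreq Oscillation frequency in Hz, or `NULL` for none.
#' @param oscAmp Oscillation amplitude relative to the noise SD.
#' @param seed Integer seed.
#' @return Numeric series of length `durationSec * fs`.
#' @export
synthRateSeries <- function(durationSec, fs = 1000, slope = 1,
                            oscFreq = NULL, oscAmp = 1, seed = 1L) {
  n <- as.integer(durationSec * fs)
  x <- withSeed(streamSeed(seed, "rate-series"), {
    z <- rnorm(n)
    zf <- fft(z)
    f <- c(1e-6, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f + 1e-9)               # mirror for negative freqs
    shaped <- Re(fft(zf / f^(slope / 2), inverse = TRUE)) / n
    shaped / sd(shaped)
  })
  if (!is.null(oscFreq))
    x <- x + oscAmp * sin(2 * pi * oscFreq * seq_len(n) / fs)
  x
}
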