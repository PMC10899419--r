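# Programmatic fixtures shared across test files.

# Minimal hand-built dataset: nUnits units over two areas, trials covering
# all 81 gabor classes `reps` times, counts filled by `fillFun(unit, trial)`
# returning a length-250 integer vector.
toyGaborDataset <- function(nUnits = 2, reps = 1, fillFun = NULL) {
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(nUnits)),
                      area = rep(c("VISp", "CA1"), length.out = nUnits),
                      stringsAsFactors = FALSE)
  K <- 81L * reps
  trials <- data.frame(trial_id = sprintf("t%04d", seq_len(K)),
                       task = "gabor",
                       class_label = rep(0:80, reps),
                       stringsAsFactors = FALSE)
  counts <- array(0L, dim = c(nUnits, 250L, K))
  if (!is.null(fillFun))
    for (i in seq_len(nUnits)) for (k in seq_len(K))
      counts[i, , k] <- fillFun(i, k)
  newSpikeDataset(units, trials, counts)
}

# Easy-regime trial HVs: orthogonal bipolar class templates plus Gaussian
# noise, split into train and held-out partitions sharing the templates.
easyTrialHVs <- function(m, perClassTrain, perClassTest = 0, D = 2000,
                         noiseSd = 0.5, seed = 1) {
  templates <- makeBipolarHV(D, seed = streamSeed(seed, "templates"), n = m)
  draw <- function(perClass, stream) {
    labels <- rep(seq_len(m) - 1L, each = perClass)
    V <- withSeed(streamSeed(seed, stream), {
      templates[labels + 1L, , drop = FALSE] +
        matrix(rnorm(length(labels) * D, sd = noiseSd), ncol = D)
    })
    list(V = V, labels = labels)
  }
  out <- draw(perClassTrain, "noise-train")
  if (perClassTest > 0) {
    te <- draw(perClassTest, "noise-test")
    out$Vtest <- te$V; out$labelsTest <- te$labels
  }
  out
}
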