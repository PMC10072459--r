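# Shared fixtures, built in code at test time.

# A small low-noise synthetic dataset; memoised so expensive suites reuse it.
fixture_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_per_class = 25, seed = 0, noise_sd = 0.03) {
    key <- paste(n_per_class, seed, noise_sd, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_dataset(
        synthetic_beat_spec(seed = seed, noise_sd = noise_sd), n_per_class)
    cache[[key]]
  }
})

# A tiny annotated record: flat baseline with spikes at known R locations.
fixture_record <- function(n = 2000, ann_samples = c(100, 400, 700),
                           symbols = rep("N", length(ann_samples)),
                           fs = 360, id = "t01") {
  sig <- rep(0.05, n)
  sig[ann_samples] <- 1.5
  ecg_record(id, fs, sig,
             data.frame(sample = ann_samples, symbol = symbols))
}

# Nearest-centroid oracle classifier: the independent separability check.
centroid_classify <- function(train, test) {
  cent <- sapply(train$class_names, function(cl)
    colMeans(train$beats[train$labels == cl, , drop = FALSE]))
  d <- sapply(seq_len(ncol(cent)), function(ci)
    rowSums(sweep(test$beats, 2, cent[, ci], "-")^2))
  train$class_names[max.col(-d, ties.method = "first")]
}
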