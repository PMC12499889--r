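# Independent oracles and small fixture builders used across the suite.

# exhaustive pair-counting AUC: wins + half-credit ties over all pos/neg pairs
auc_pair_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force decision boundary: density intersection located on a fine grid
boundary_grid_oracle <- function(fit, resolution = 1e-5) {
  x <- seq(fit$mu1, fit$mu2, by = resolution)
  d <- fit$w1 * dnorm(x, fit$mu1, fit$sigma1) -
       fit$w2 * dnorm(x, fit$mu2, fit$sigma2)
  x[which.min(abs(d))]
}

random_bimodal_fit <- function() {
  mu1 <- runif(1, 0.05, 0.4)
  mu2 <- runif(1, mu1 + 0.2, 0.95)
  structure(list(w1 = runif(1, 0.2, 0.8), mu1 = mu1, mu2 = mu2,
                 sigma1 = runif(1, 0.03, 0.12), sigma2 = runif(1, 0.03, 0.12),
                 unimodal = FALSE), class = "bimodal_fit")
  # w2 filled by caller
}

# noise-free trace with rectangular pulses at known positions
make_pulse_trace <- function(n = 50000, rate = 1e5, baseline = -1000,
                             pulses = list(list(start = 20000, len = 100, depth = 200))) {
  x <- rep(baseline, n)
  truth <- data.frame(start = integer(0), end = integer(0), class = character(0))
  for (p in pulses) {
    idx <- p$start:(p$start + p$len - 1L)
    x[idx] <- x[idx] - p$depth
    truth <- rbind(truth, data.frame(start = p$start - 1L,
                                     end = p$start - 1L + p$len,
                                     class = "pulse"))
  }
  structure(list(samples = x, sampling_rate = rate, voltage = -100,
                 run_id = "pulse", analyte_label = "pulse",
                 truth_events = truth, baseline_offset_true = 0),
            class = "trace_recording")
}

# feature table assembled directly from a matrix, for classifier unit tests
toy_feature_table <- function(x, labels = NULL, voltage = -100) {
  x <- as.data.frame(x)
  structure(list(x = x,
                 labels = if (is.null(labels)) NULL else factor(labels),
                 voltage = rep(voltage, nrow(x)),
                 run_id = rep("toy", nrow(x)),
                 featureset = "toy", standardization = NULL),
            class = "feature_table")
}

# truth-level event counts for one pure analyte over runs (no detection)
truth_event_count <- function(config, analyte, voltage, seed) {
  n <- 0L
  for (r in seq_len(config$runs_per_condition)) {
    tr <- simulate_trace(config, voltage,
                         run_id = sprintf("%s_r%d", analyte, r),
                         seed = voltmatrix:::derive_seed(seed, voltage, r, analyte),
                         analyte = analyte)
    n <- n + nrow(tr$truth_events)
  }
  n
}
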