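#' Histogram of classifier scores
#'
#' Uniform-bin histogram on [0, 1]; counts always sum to the number of
#' scores.
#'
#' @param scores numeric scores in [0, 1].
#' @param n_bins number of bins (default 20).
#' @return list with \code{edges} (length \code{n_bins + 1}) and
#'   \code{counts}.
#' @export
score_histogram <- function(scores, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  list(edges = edges, counts = tabulate(bin, nbins = n_bins))
}

#' Fit a two-component Gaussian mixture to classifier scores
#'
#' Expectation-maximization on the raw scores, initialized at means
#' 0.25/0.75 with equal weights and SD 0.1. Components are relabeled so
#' \code{mu1 < mu2}; SDs are floored at \code{sigma_floor}. Convergence is
#' declared when the log-likelihood change falls below \code{tol} or after
#' \code{max_iter} iterations. A degenerate fit — either weight below 0.01,
#' or a component SD pinned at the floor (the EM collapsing onto a point
#' mass of identical scores, as happens when a classifier emits hard 0/1
#' probabilities) — is flagged via \code{unimodal}; boundary optimization
#' then falls back to the fixed 0.5 threshold.
#'
#' @param scores numeric scores in [0, 1].
#' @param min_n minimum number of scores (default 50).
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @param sigma_floor lower bound for component SDs.
#' @param init_means starting component means.
#' @return object of class \code{bimodal_fit}: \code{w1, w2, mu1, mu2,
#'   sigma1, sigma2, converged, log_likelihood, unimodal, n}.
#' @export
fit_two_gaussians <- function(scores, min_n = 50L, max_iter = 500L,
                              tol = 1e-8, sigma_floor = 1e-3,
                              init_means = c(0.25, 0.75)) {
  n <- length(scores)
  if (n < min_n)
    stop(sprintf("need at least %d scores for a bimodal fit (got %d)", min_n, n))
  w <- c(0.5, 0.5); mu <- sort(init_means); sig <- c(0.1, 0.1)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(scores, mu[1], sig[1])
    d2 <- w[2] * stats::dnorm(scores, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # a component has emptied out
    mu[1] <- sum(g1 * scores) / n1
    mu[2] <- sum((1 - g1) * scores) / n2
    sig[1] <- max(sqrt(sum(g1 * (scores - mu[1])^2) / n1), sigma_floor)
    sig[2] <- max(sqrt(sum((1 - g1) * (scores - mu[2])^2) / n2), sigma_floor)
    w <- c(n1, n2) / n
  }
  if (mu[1] > mu[2]) {  # relabel so mu1 < mu2
    mu <- rev(mu); sig <- rev(sig); w <- rev(w)
  }
  # a weight collapse or a sigma pinned at the floor (EM collapsing onto a
  # point mass of identical scores) both invalidate the Gaussian model
  degenerate <- min(w) < 0.01 || min(sig) <= sigma_floor
  structure(list(w1 = w[1], w2 = w[2], mu1 = mu[1], mu2 = mu[2],
                 sigma1 = sig[1], sigma2 = sig[2],
                 converged = converged, log_likelihood = ll_old,
                 unimodal = degenerate, n = n),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf("<bimodal_fit> w=(%.3f, %.3f), mu=(%.3f, %.3f), sigma=(%.3f, %.3f)%s\n",
              x$w1, x$w2, x$mu1, x$mu2, x$sigma1, x$sigma2,
              if (x$unimodal) " [unimodal]" else ""))
  invisible(x)
}

#' Optimized decision boundary between two Gaussian components
#'
#' Primary rule: the intersection of the two weighted component densities,
#' i.e. the x in (mu1, mu2) solving
#' \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)}
#' (a quadratic in x; the root inside the interval is taken). Alternative
#' rule: the minimum of the mixture density on (mu1, mu2) by bounded scalar
#' minimization. If no intersection root falls inside the interval (extreme
#' weight imbalance) the density-minimum rule is used with a warning. For an
#' unimodal fit the boundary falls back to 0.5. The result is clipped to
#' [0, 1].
#'
#' @param fit a \code{\link{fit_two_gaussians}} result.
#' @param rule \code{"intersection"} (default) or \code{"density_min"}.
#' @return boundary score value.
#' @export
find_boundary <- function(fit, rule = c("intersection", "density_min")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit, "bimodal_fit"))
  if (isTRUE(fit$unimodal)) return(0.5)
  m1 <- fit$mu1; m2 <- fit$mu2; s1 <- fit$sigma1; s2 <- fit$sigma2
  w1 <- fit$w1; w2 <- fit$w2
  density_min <- function() {
    stats::optimize(function(x)
      w1 * stats::dnorm(x, m1, s1) + w2 * stats::dnorm(x, m2, s2),
      interval = c(m1, m2))$minimum
  }
  x <- if (rule == "density_min") {
    density_min()
  } else {
    # w1 phi1 = w2 phi2 in log form: quadratic a x^2 + b x + c = 0
    a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) +
      log(w1 / w2) + log(s2 / s1)
    roots <- if (abs(a) < 1e-14) {
      if (abs(b) < 1e-14) numeric(0) else -cc / b
    } else {
      disc <- b^2 - 4 * a * cc
      if (disc < 0) numeric(0) else
        c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    }
    inside <- roots[roots > m1 & roots < m2]
    if (!length(inside)) {
      warning("no density intersection inside (mu1, mu2); using density minimum")
      density_min()
    } else inside[1]
  }
  min(max(x, 0), 1)
}

#' Corrected event-count ratio
#'
#' Fraction of events attributed to the positive (high-score) class after
#' boundary optimization: either the proportion of scores exceeding the
#' boundary (\code{"exceedance"}, default — operates on the actual events)
#' or the weight of the high-score mixture component (\code{"peak_area"}).
#'
#' @param scores classifier scores of the mixed sample.
#' @param fit a \code{\link{fit_two_gaussians}} result.
#' @param boundary decision boundary (from \code{\link{find_boundary}}).
#' @param rule \code{"exceedance"} or \code{"peak_area"}.
#' @return fraction in [0, 1].
#' @export
corrected_event_ratio <- function(scores, fit, boundary,
                                  rule = c("exceedance", "peak_area")) {
  rule <- match.arg(rule)
  if (rule == "exceedance") mean(scores > boundary) else fit$w2
}

#' Capture-frequency correction of an event ratio
#'
#' Converts an observed event-count fraction r of the positive class into a
#' molecular fraction by inverse-rate weighting:
#' \deqn{p = \frac{r/\lambda_A}{r/\lambda_A + (1-r)/\lambda_B}}
#' where \eqn{\lambda_A, \lambda_B} are per-class capture rates measured on
#' pure reference runs at the same voltage. p is monotone increasing in r,
#' equals r when the rates are equal, and preserves the endpoints 0 and 1.
#'
#' @param event_ratio observed positive-class event fraction r in [0, 1].
#' @param rate_pos positive-class capture rate, events/s (> 0).
#' @param rate_neg negative-class capture rate, events/s (> 0).
#' @return molecular fraction of the positive class.
#' @export
frequency_correction <- function(event_ratio, rate_pos, rate_neg) {
  if (any(rate_pos <= 0) || any(rate_neg <= 0))
    stop("capture rates must be positive")
  if (any(event_ratio < 0 | event_ratio > 1))
    stop("event_ratio must lie in [0, 1]")
  a <- event_ratio / rate_pos
  b <- (1 - event_ratio) / rate_neg
  a / (a + b)
}

#' Capture rate from an event table
#'
#' Event count divided by total recording time, with the Poisson standard
#' error \eqn{\sqrt{n}/T}. For zero events the rule-of-three upper bound
#' 3/T is reported.
#'
#' @param events event data.frame (or an event count).
#' @param total_duration_s total recording time, seconds (> 0).
#' @return list with \code{rate}, \code{se}, \code{n}, and
#'   \code{upper_bound} (only meaningful when n = 0).
#' @export
estimate_capture_rate <- function(events, total_duration_s) {
  if (total_duration_s <= 0) stop("total_duration_s must be > 0")
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  list(rate = n / total_duration_s,
       se = sqrt(n) / total_duration_s,
       n = as.integer(n),
       upper_bound = if (n == 0L) 3 / total_duration_s else NA_real_)
}

#' Mixture composition from classifier scores
#'
#' Full quantification chain on a mixed sample: raw positive fraction at the
#' fixed 0.5 threshold, two-component Gaussian fit of the score histogram,
#' optimized decision boundary, corrected event ratio, and the
#' capture-frequency-corrected molecular ratio using pure-reference rates.
#'
#' @param scores classifier scores of the mixed-sample events, in [0, 1].
#' @param rate_pos,rate_neg per-class capture rates from pure reference runs
#'   at the same voltage, events/s.
#' @param boundary_rule passed to \code{\link{find_boundary}}.
#' @param ratio_rule passed to \code{\link{corrected_event_ratio}}.
#' @param min_n minimum scores for the bimodal fit.
#' @return object of class \code{mixture_estimate} with fields
#'   \code{raw_ratio_at_half}, \code{fit}, \code{boundary},
#'   \code{corrected_event_ratio}, \code{capture_rate_pos},
#'   \code{capture_rate_neg}, \code{molecular_ratio} and the rule names.
#' @export
estimate_mixture <- function(scores, rate_pos, rate_neg,
                             boundary_rule = c("intersection", "density_min"),
                             ratio_rule = c("exceedance", "peak_area"),
                             min_n = 50L) {
  boundary_rule <- match.arg(boundary_rule)
  ratio_rule <- match.arg(ratio_rule)
  fit <- fit_two_gaussians(scores, min_n = min_n)
  boundary <- find_boundary(fit, rule = boundary_rule)
  r <- corrected_event_ratio(scores, fit, boundary, rule = ratio_rule)
  structure(list(
    raw_ratio_at_half = mean(scores > 0.5),
    fit = fit,
    boundary = boundary,
    corrected_event_ratio = r,
    capture_rate_pos = rate_pos,
    capture_rate_neg = rate_neg,
    molecular_ratio = frequency_correction(r, rate_pos, rate_neg),
    boundary_rule = boundary_rule,
    ratio_rule = ratio_rule,
    n = length(scores)
  ), class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<mixture_estimate> n=%d events\n",
    "  raw ratio @0.5:        %.3f\n",
    "  optimized boundary:    %.3f (%s)\n",
    "  corrected event ratio: %.3f (%s)\n",
    "  capture rates:         %.3g / %.3g events/s\n",
    "  molecular ratio:       %.3f\n"),
    x$n, x$raw_ratio_at_half, x$boundary, x$boundary_rule,
    x$corrected_event_ratio, x$ratio_rule,
    x$capture_rate_pos, x$capture_rate_neg, x$molecular_ratio))
  invisible(x)
}

#' End-to-end mixture quantification at one voltage
#'
#' Convenience driver for the full chain: simulate pure reference runs for
#' the first two analytes and a mixture sample at one voltage, train a
#' classifier on the pure references (feature set A by default), score the
#' mixture events, and estimate composition with boundary optimization and
#' capture-frequency correction. Capture rates come from the pure reference
#' runs, never from the mixture.
#'
#' @param config a \code{\link{simulation_config}} with at least two
#'   molecules and a \code{"mixture"} analyte entry.
#' @param voltage voltage at which to quantify, mV.
#' @param seed base seed.
#' @param spec feature-set spec (default set A).
#' @param algo classifier algorithm.
#' @param params detection parameters.
#' @param ... passed to \code{\link{estimate_mixture}}.
#' @return a \code{\link{estimate_mixture}} result; the classifier, event
#'   tables and reference rates are attached as attributes.
#' @export
run_mixture_analysis <- function(config, voltage, seed = config$seed,
                                 spec = default_feature_sets()$A,
                                 algo = "random_forest",
                                 params = detection_params(), ...) {
  classes <- names(config$molecules)[1:2]
  ev_pos <- simulate_events(config, classes[1], voltages = voltage,
                            seed = seed, params = params)
  ev_neg <- simulate_events(config, classes[2], voltages = voltage,
                            seed = seed + 1L, params = params)
  ev_mix <- simulate_events(config, "mixture", voltages = voltage,
                            seed = seed + 2L, params = params)
  total_t <- config$duration_s * config$runs_per_condition
  rate_pos <- estimate_capture_rate(ev_pos, total_t)$rate
  rate_neg <- estimate_capture_rate(ev_neg, total_t)$rate
  ref <- rbind(ev_pos, ev_neg)
  ft <- build_feature_table(ref, spec, labels = ref$analyte)
  model <- train_classifier(ft, algo = algo, positive = classes[1],
                            seed = seed + 3L)
  scores <- score_events(model, build_feature_table(ev_mix, spec))
  est <- estimate_mixture(scores, rate_pos, rate_neg, ...)
  attr(est, "model") <- model
  attr(est, "scores") <- scores
  attr(est, "n_ref") <- c(pos = nrow(ev_pos), neg = nrow(ev_neg))
  est
}
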