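test_that("score histograms bin correctly and conserve counts", {
  h <- score_histogram(rep(0.25, 100), 20)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(max(h$counts), 100L)
  expect_length(h$edges, 21)

  set.seed(3)
  s <- runif(500)
  expect_equal(sum(score_histogram(s, 13)$counts), 500L)
  expect_error(score_histogram(c(-0.1, 0.5)), "0, 1")

  # bimodal input shows two smoothed modes
  set.seed(4)
  sb <- pmin(pmax(c(rnorm(2000, 0.25, 0.06), rnorm(2000, 0.75, 0.06)), 0), 1)
  counts <- score_histogram(sb, 25)$counts
  sm <- stats::filter(counts, rep(1 / 3, 3))
  sm[is.na(sm)] <- 0
  peaks <- sum(diff(sign(diff(sm))) == -2 & sm[2:(length(sm) - 1)] > max(sm) / 4)
  expect_equal(peaks, 2L)
})

test_that("the two-Gaussian EM recovers generating parameters", {
  set.seed(7)
  s <- pmin(pmax(c(rnorm(1000, 0.2, 0.05), rnorm(1000, 0.8, 0.05)), 0), 1)
  f <- fit_two_gaussians(s)
  expect_false(f$unimodal)
  expect_true(f$converged)
  expect_equal(f$mu1, 0.2, tolerance = 0.02)
  expect_equal(f$mu2, 0.8, tolerance = 0.02)
  expect_equal(f$w1, 0.5, tolerance = 0.05)
  expect_equal(f$w2, 0.5, tolerance = 0.05)
  expect_equal(f$w1 + f$w2, 1, tolerance = 1e-9)

  # initialization order never changes the mu1 < mu2 labeling
  f2 <- fit_two_gaussians(s, init_means = c(0.75, 0.25))
  expect_lt(f2$mu1, f2$mu2)
  expect_equal(f2$mu1, f$mu1, tolerance = 1e-6)

  expect_error(fit_two_gaussians(runif(10)), "at least")
})

test_that("the EM agrees with an independent mixture fitter", {
  set.seed(31)
  s <- pmin(pmax(c(rnorm(800, 0.3, 0.06), rnorm(1200, 0.7, 0.06)), 0), 1)
  f <- fit_two_gaussians(s)
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  ref <- Mclust(s, G = 2, modelNames = "V", verbose = FALSE)
  mus <- unname(sort(ref$parameters$mean))
  expect_equal(f$mu1, mus[1], tolerance = 0.01)
  expect_equal(f$mu2, mus[2], tolerance = 0.01)
  expect_equal(f$w2, ref$parameters$pro[which.max(ref$parameters$mean)],
               tolerance = 0.03)
})

test_that("degenerate score distributions are flagged and fall back to 0.5", {
  set.seed(9)
  s1 <- pmin(pmax(rnorm(200, 0.9, 0.01), 0), 1)   # single narrow mode
  f1 <- fit_two_gaussians(s1)
  expect_true(f1$unimodal)
  expect_equal(find_boundary(f1), 0.5)

  # hard 0/1 classifier output: sigma pinned at the floor
  s2 <- c(rep(0, 120), rep(1, 200), runif(30))
  f2 <- fit_two_gaussians(s2)
  expect_true(f2$unimodal)
  expect_equal(find_boundary(f2), 0.5)
})

test_that("the intersection boundary matches algebraic and grid oracles", {
  # symmetric case: exact midpoint
  fs <- structure(list(w1 = 0.5, w2 = 0.5, mu1 = 0.2, mu2 = 0.8,
                       sigma1 = 0.1, sigma2 = 0.1, unimodal = FALSE),
                  class = "bimodal_fit")
  expect_equal(find_boundary(fs), 0.5, tolerance = 1e-12)

  # weighted equal-sigma case vs grid search and closed form
  fw <- structure(list(w1 = 0.8, w2 = 0.2, mu1 = 0.3, mu2 = 0.7,
                       sigma1 = 0.1, sigma2 = 0.1, unimodal = FALSE),
                  class = "bimodal_fit")
  b <- find_boundary(fw)
  expect_equal(b, boundary_grid_oracle(fw), tolerance = 1e-4)
  closed <- (0.3 + 0.7) / 2 + 0.1^2 * log(0.8 / 0.2) / (0.7 - 0.3)
  expect_equal(b, closed, tolerance = 1e-9)

  # property: 100 random valid fits against the 1e-5 grid oracle
  set.seed(15)
  for (i in 1:100) {
    f <- random_bimodal_fit()
    f$w2 <- 1 - f$w1
    bb <- suppressWarnings(find_boundary(f))
    expect_equal(bb, boundary_grid_oracle(f), tolerance = 1e-4)
  }
})

test_that("corrected event ratios agree with generation under both rules", {
  set.seed(19)
  s <- pmin(pmax(c(rnorm(600, 0.2, 0.07), rnorm(1400, 0.8, 0.07)), 0), 1)
  f <- fit_two_gaussians(s)
  b <- find_boundary(f)
  r_exc <- corrected_event_ratio(s, f, b, "exceedance")
  r_area <- corrected_event_ratio(s, f, b, "peak_area")
  expect_equal(r_exc, 0.7, tolerance = 0.03)
  expect_equal(r_area, 0.7, tolerance = 0.03)
  expect_lt(abs(r_exc - r_area), 0.02)

  # symmetric mixture: both rules near one half
  set.seed(20)
  ss <- pmin(pmax(c(rnorm(1000, 0.25, 0.06), rnorm(1000, 0.75, 0.06)), 0), 1)
  fsym <- fit_two_gaussians(ss)
  bsym <- find_boundary(fsym)
  expect_equal(corrected_event_ratio(ss, fsym, bsym, "exceedance"), 0.5,
               tolerance = 0.03)
  expect_equal(corrected_event_ratio(ss, fsym, bsym, "peak_area"), 0.5,
               tolerance = 0.03)
  expect_equal(corrected_event_ratio(rep(0.9, 10), fsym, 0.5, "exceedance"), 1.0)
})

test_that("boundary refitting undoes a monotone shift of the score axis", {
  set.seed(23)
  s <- pmin(pmax(c(rnorm(700, 0.25, 0.08), rnorm(1300, 0.75, 0.08)), 0), 1)
  squash <- function(x) (x + 0.5) / 1.5     # bimodality-preserving, toward 1
  s2 <- squash(s)
  f <- fit_two_gaussians(s); f2 <- fit_two_gaussians(s2)
  r1 <- corrected_event_ratio(s, f, find_boundary(f))
  r2 <- corrected_event_ratio(s2, f2, find_boundary(f2))
  raw1 <- mean(s > 0.5); raw2 <- mean(s2 > 0.5)
  expect_gt(abs(raw2 - raw1), 0.1)          # fixed threshold is fooled
  expect_lt(abs(r2 - r1), 0.03)             # refit boundary is not
})

test_that("frequency correction satisfies its algebraic identities", {
  expect_equal(frequency_correction(0.4, 2, 2), 0.4)
  expect_equal(frequency_correction(2 / 3, 2, 1), 0.5)
  expect_equal(frequency_correction(0, 2, 1), 0)
  expect_equal(frequency_correction(1, 2, 1), 1)
  # monotone increasing in r
  r <- seq(0, 1, by = 0.05)
  expect_true(all(diff(frequency_correction(r, 3.2, 1.1)) > 0))
  expect_error(frequency_correction(0.5, 0, 1), "positive")
  expect_error(frequency_correction(1.5, 1, 1), "0, 1")
})

test_that("capture-rate estimates carry Poisson errors and match the model", {
  est <- estimate_capture_rate(120, 60)
  expect_equal(est$rate, 2)
  expect_equal(est$se, sqrt(120) / 60, tolerance = 1e-12)
  est0 <- estimate_capture_rate(0, 60)
  expect_equal(est0$rate, 0)
  expect_equal(est0$upper_bound, 0.05)
  expect_error(estimate_capture_rate(10, 0), "duration")

  cfg <- make_scenario("two_marker", duration_s = 10, runs_per_condition = 1)
  ev <- simulate_events(cfg, "CA15-3", voltages = -300, seed = 4)
  lam <- capture_rate(cfg$molecules[["CA15-3"]], -300)
  r <- estimate_capture_rate(ev, attr(ev, "total_duration_s"))
  expect_lt(abs(r$rate - lam), 3 * sqrt(lam / 10))
})
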