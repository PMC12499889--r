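test_that("capture rate follows the barrier-limited model and its two anchors", {
  cea <- molecule_model("CEA", 0.046, 61.6, 0.15, 0.03, 0.5, 0.4)
  ca <- molecule_model("CA15-3", 0.020, 20, 0.28, 0.05, 2.0, 0.5)

  # analytic anchor values: ratio = 2.30 * exp(-41.6 / |V|)
  expect_equal(capture_rate(cea, -50) / capture_rate(ca, -50),
               2.30 * exp(-41.6 / 50), tolerance = 1e-12)
  expect_equal(capture_rate(cea, -50) / capture_rate(ca, -50), 1.00,
               tolerance = 0.01)
  expect_equal(capture_rate(cea, -300) / capture_rate(ca, -300), 2.00,
               tolerance = 0.01)

  # vanishing barrier: lambda = alpha * |V|
  m0 <- molecule_model("m", 0.01, 0, 0.2, 0.02, 1, 0.3)
  expect_identical(capture_rate(m0, -100), 1.0)

  # strictly increasing in |V|
  lam <- capture_rate(cea, -seq(10, 400, by = 10))
  expect_true(all(diff(lam) > 0))

  expect_error(capture_rate(cea, 0), "nonzero")
  expect_error(molecule_model("bad", -1, 0, 0.2, 0.02, 1, 0.3), "alpha")
  expect_error(molecule_model("bad", 0.1, 0, 1.2, 0.02, 1, 0.3), "blockage")
})

test_that("noise-free traces obey the depth law exactly", {
  m <- molecule_model("m", 0.4, 0, 0.2, 0.0, 1.0, 0, edge_tau_us = 0)
  cfg <- simulation_config(list(m), voltage_grid = c(-100, -200),
                           duration_s = 5, runs_per_condition = 1,
                           noise_rms = 0, drift_rate = 0, run_offset_sigma = 0)
  tr <- simulate_trace(cfg, -100, "r1", seed = 3, analyte = "m")
  expect_gt(nrow(tr$truth_events), 0)
  # depth = f * |G*V| with f fixed at 0.2, G = 10 nS, V = -100 mV -> 200 pA
  expect_equal(min(tr$samples), -1000 - 200, tolerance = 1e-12)
  expect_equal(length(tr$samples), round(cfg$duration_s * cfg$sampling_rate))
  # every truth span sits exactly at the blocked level
  for (i in seq_len(nrow(tr$truth_events))) {
    core <- (tr$truth_events$start[i] + 1):tr$truth_events$end[i]
    expect_equal(unique(tr$samples[core]), -1200, tolerance = 1e-12)
  }
  # truth annotations sorted, non-overlapping
  expect_true(all(diff(tr$truth_events$start) > 0))
  expect_true(all(utils::head(tr$truth_events$end, -1) <=
                  tr$truth_events$start[-1]))
})

test_that("identical seeds give bit-identical traces, different seeds differ", {
  cfg <- make_scenario("two_marker", duration_s = 2)
  a <- simulate_trace(cfg, -150, "r1", seed = 11, analyte = "CEA")
  b <- simulate_trace(cfg, -150, "r1", seed = 11, analyte = "CEA")
  c <- simulate_trace(cfg, -150, "r1", seed = 12, analyte = "CEA")
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$samples, c$samples))
})

test_that("event arrivals follow the Poisson law", {
  cfg <- make_scenario("two_marker", duration_s = 2, runs_per_condition = 1)
  lam <- capture_rate(cfg$molecules[["CA15-3"]], -300)
  n_rep <- 50
  counts <- vapply(seq_len(n_rep), function(s)
    nrow(simulate_trace(cfg, -300, "r1", seed = 1000 + s,
                        analyte = "CA15-3")$truth_events), numeric(1))
  mu <- lam * cfg$duration_s
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_rep))

  # single long run: realized count within 3*sqrt(lambda*T) of lambda*T
  cfg60 <- make_scenario("two_marker", runs_per_condition = 1)
  n60 <- nrow(simulate_trace(cfg60, -300, "r1", seed = 77,
                             analyte = "CA15-3")$truth_events)
  expect_lt(abs(n60 - lam * 60), 3 * sqrt(lam * 60))
})

test_that("scenario library is validated and structurally correct", {
  expect_error(make_scenario("nope"), "two_marker")

  bod <- make_scenario("baseline_overfit_demo")
  p <- bod$molecules$class_pos; q <- bod$molecules$class_neg
  expect_identical(p[setdiff(names(p), "name")], q[setdiff(names(q), "name")])
  expect_identical(bod$run_offset_by_class,
                   c(class_pos = 40, class_neg = -40))

  eq <- make_scenario("equimolar_mixture")
  expect_equal(unname(eq$mixture_fractions), c(0.5, 0.5))

  se <- make_scenario("serum_shift")
  expect_equal(unname(se$analytes$uncentrifuged["long_shallow"]), 0.4)
  expect_equal(unname(se$analytes$centrifuged["long_shallow"]), 0.1)

  ap <- make_scenario("aptamer_shift")
  expect_identical(ap$molecules[[1]]$capture_prefactor_alpha,
                   ap$molecules[[2]]$capture_prefactor_alpha)
  expect_identical(ap$molecules[[1]]$capture_barrier_vstar,
                   ap$molecules[[2]]$capture_barrier_vstar)
  expect_true(ap$molecules[[2]]$blockage_voltage_slope != 0)

  tm <- make_scenario("two_marker")
  expect_equal(capture_rate(tm$molecules[[1]], -300) /
               capture_rate(tm$molecules[[2]], -300), 2, tolerance = 0.01)
})

test_that("overload of the trace raises a saturation error", {
  m <- molecule_model("jam", 50, 0, 0.2, 0.02, 50, 0.1)
  cfg <- simulation_config(list(m), duration_s = 2, noise_rms = 0)
  expect_error(simulate_trace(cfg, -100, "r1", seed = 1, analyte = "jam"),
               "saturat")
})

test_that("simulate_events assembles labeled multi-run event tables", {
  cfg <- make_scenario("two_marker", duration_s = 2, runs_per_condition = 2)
  ev <- simulate_events(cfg, "CEA", voltages = c(-200, -300), seed = 5)
  expect_true(all(ev$analyte == "CEA"))
  expect_setequal(unique(ev$voltage), c(-200, -300))
  expect_equal(attr(ev, "total_duration_s"), 4)
  expect_equal(length(unique(ev$run_id)), 4)
  expect_error(simulate_trace(cfg, -100, "r", 1, analyte = "unknown"),
               "available")
})
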