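test_that("auc equals the exhaustive pair-counting oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c("p", "p", "n", "n"), "p"), 1.0)
  expect_equal(auc(rep(0.5, 6), rep(c("p", "n"), 3), "p"), 0.5)
  # 4 wins + 2 half-credit ties over 6 pairs = 5/6
  expect_equal(auc(c(0.8, 0.5, 0.5, 0.5, 0.2),
                   c("p", "p", "p", "n", "n"), "p"), 5 / 6)

  set.seed(42)
  for (i in 1:40) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    s <- round(runif(n1 + n0), sample(1:2, 1))   # rounding induces ties
    lab <- c(rep("p", n1), rep("n", n0))
    expect_equal(auc(s, lab, "p"), auc_pair_oracle(s, lab, "p"))
  }

  expect_error(auc(c(1, 2), c("p", "p"), "p"), "both classes")
})

test_that("auc agrees with an independent ROC implementation", {
  set.seed(7)
  s <- c(rnorm(60, 0.6, 0.2), rnorm(40, 0.4, 0.2))
  lab <- c(rep("p", 60), rep("n", 40))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, s, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(s, lab, "p"), ref, tolerance = 1e-12)
})

test_that("classifiers separate disjoint classes and are seed-deterministic", {
  set.seed(5)
  x <- rbind(cbind(rnorm(100, 0), rnorm(100, 0)),
             cbind(rnorm(100, 8), rnorm(100, 8)))
  colnames(x) <- c("f1", "f2")
  lab <- rep(c("a", "b"), each = 100)
  ft <- toy_feature_table(x, lab)
  for (algo in c("random_forest", "svm")) {
    mod <- train_classifier(ft, algo = algo, positive = "a", seed = 3)
    expect_equal(auc(score_events(mod, ft), ft$labels, "a"), 1.0)
    mod2 <- train_classifier(ft, algo = algo, positive = "a", seed = 3)
    expect_identical(score_events(mod, ft), score_events(mod2, ft))
  }
})

test_that("shuffled labels give chance-level evaluation AUC", {
  set.seed(11)
  x <- cbind(f1 = rnorm(400), f2 = rnorm(400), f3 = runif(400))
  lab <- sample(rep(c("a", "b"), each = 200))    # labels carry no signal
  ft <- toy_feature_table(x, lab)
  sp <- split_dataset(ft, train_frac = 0.5, seed = 2)
  mod <- train_classifier(sp$train, algo = "random_forest", positive = "a",
                          seed = 4)
  a <- auc(score_events(mod, sp$eval), sp$eval$labels, "a")
  expect_lt(abs(a - 0.5), 0.07)
})

test_that("training guards: single class and per-class floor", {
  x <- cbind(f1 = rnorm(50))
  expect_error(train_classifier(toy_feature_table(x, rep("a", 50)),
                                positive = "a"), "single class")
  expect_error(train_classifier(toy_feature_table(x, c(rep("a", 45), rep("b", 5))),
                                positive = "a"), "fewer than")
})

test_that("stratified splits are disjoint, exhaustive and class-complete", {
  set.seed(8)
  ft <- toy_feature_table(cbind(f = rnorm(100)),
                          sample(rep(c("a", "b"), c(70, 30))))
  sp <- split_dataset(ft, train_frac = 0.7, seed = 1)
  expect_length(intersect(sp$train_idx, sp$eval_idx), 0)
  expect_setequal(c(sp$train_idx, sp$eval_idx), 1:100)
  expect_setequal(levels(sp$train$labels), c("a", "b"))
  expect_setequal(levels(sp$eval$labels), c("a", "b"))
  expect_equal(sum(sp$train$labels == "a"), 49)   # 0.7 * 70, stratified
})

test_that("exchangeable voltages give off-diagonal cells matching the diagonal", {
  set.seed(13)
  n <- 600
  an <- rep(rep(c("a", "b"), each = n / 4), 2)
  ev <- data.frame(dwell_ms = rlnorm(n, 0, 0.4) * ifelse(an == "a", 1, 3),
                   frac_blockage = rnorm(n, ifelse(an == "a", 0.15, 0.25), 0.04),
                   area_pa_ms = abs(rnorm(n, 200, 40)),
                   i0_local_pa = rep(-1000, n),
                   skewness = rnorm(n), kurtosis = rnorm(n),
                   fwhm_ms = runif(n, 0.5, 1), intra_event_sd_pa = rnorm(n, 12, 1),
                   delta_i_pa = rnorm(n, 200, 30), delta_i_max_pa = rnorm(n, 230, 30),
                   baseline_rms_pa = 12, drift_slope_pa_s = 0.5,
                   run_id = "r1",
                   analyte = an,
                   voltage = rep(c(-100, -200), each = n / 2),
                   stringsAsFactors = FALSE)
  m <- build_voltage_matrix(ev, default_feature_sets()$A, positive = "a", seed = 3)
  expect_equal(dim(m$auc), c(2L, 2L))
  expect_lt(max(abs(m$auc[row(m$auc) != col(m$auc)] - diag(m$auc))), 0.1)

  # cells do not depend on the ordering of the voltage list
  m2 <- build_voltage_matrix(ev, default_feature_sets()$A, positive = "a",
                             voltages = c(-200, -100), seed = 3)
  expect_equal(m$auc["-100", "-200"], m2$auc["-100", "-200"])
  expect_equal(m$auc["-200", "-200"], m2$auc["-200", "-200"])
})

test_that("permutation importance is zero for constants and peaks on the signal", {
  set.seed(21)
  n <- 300
  x <- cbind(signal = rep(c(0, 2), each = n / 2) + rnorm(n, 0, 0.5),
             noise1 = rnorm(n), noise2 = rnorm(n), flat = rep(1, n))
  lab <- rep(c("a", "b"), each = n / 2)
  ft <- toy_feature_table(x, lab)
  mod <- train_classifier(ft, algo = "random_forest", positive = "b", seed = 2)
  imp <- permutation_importance(mod, ft, repeats = 5, seed = 6)
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  expect_equal(imp$feature[which.max(imp$importance)], "signal")
  expect_true(all(imp$importance >= 0))
})
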