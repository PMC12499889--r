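#' Molecule model for trace simulation
#'
#' Describes one analyte class: its voltage-dependent capture kinetics and the
#' distributions of its translocation event shapes (dwell time, fractional
#' blockage, edge time constant).
#'
#' The capture rate follows a barrier-limited electrophoretic model
#' \deqn{\lambda(V) = \alpha |V| \exp(-V^*/|V|)}
#' so that the rate grows nearly linearly in |V| once the barrier term
#' saturates. Dwell times are log-normal with a median that scales as
#' \code{(100/|V|)^gamma}; fractional blockage is Gaussian with an optional
#' linear voltage sensitivity (\code{blockage_voltage_slope}, expressed per
#' 250 mV) used to emulate voltage-sensitive analytes such as
#' aptamer-protein complexes.
#'
#' @param name analyte label.
#' @param capture_prefactor_alpha capture prefactor, events s^-1 mV^-1.
#' @param capture_barrier_vstar capture barrier voltage V*, mV (>= 0).
#' @param blockage_frac_mean mean fractional blockage dI/|I0| at |V| = 100 mV.
#' @param blockage_frac_sd sd of fractional blockage.
#' @param dwell_median_ref_ms median dwell time in ms at |V| = 100 mV.
#' @param dwell_log_sd sd of log dwell (natural log units).
#' @param dwell_voltage_exponent_gamma dwell scales as (100/|V|)^gamma.
#' @param blockage_voltage_slope change in mean fractional blockage per
#'   250 mV increase of |V|; 0 for a voltage-invariant analyte.
#' @param edge_tau_us exponential event edge time constant, microseconds.
#' @return an object of class \code{molecule_model}.
#' @examples
#' m <- molecule_model("CEA", 0.046, 61.6, 0.15, 0.03, 0.5, 0.4)
#' capture_rate(m, -300)
#' @export
molecule_model <- function(name, capture_prefactor_alpha, capture_barrier_vstar,
                           blockage_frac_mean, blockage_frac_sd,
                           dwell_median_ref_ms, dwell_log_sd,
                           dwell_voltage_exponent_gamma = 1,
                           blockage_voltage_slope = 0,
                           edge_tau_us = 20) {
  stopifnot(is.character(name), length(name) == 1L)
  if (capture_prefactor_alpha <= 0)
    stop("capture_prefactor_alpha must be > 0")
  if (capture_barrier_vstar < 0)
    stop("capture_barrier_vstar must be >= 0")
  if (dwell_median_ref_ms <= 0)
    stop("dwell_median_ref_ms must be > 0")
  if (blockage_frac_mean <= 0 || blockage_frac_mean >= 1)
    stop("blockage_frac_mean must lie in (0, 1)")
  if (blockage_frac_sd < 0 || dwell_log_sd < 0 || edge_tau_us < 0)
    stop("spread and edge parameters must be non-negative")
  structure(list(
    name = name,
    capture_prefactor_alpha = capture_prefactor_alpha,
    capture_barrier_vstar = capture_barrier_vstar,
    blockage_frac_mean = blockage_frac_mean,
    blockage_frac_sd = blockage_frac_sd,
    dwell_median_ref_ms = dwell_median_ref_ms,
    dwell_log_sd = dwell_log_sd,
    dwell_voltage_exponent_gamma = dwell_voltage_exponent_gamma,
    blockage_voltage_slope = blockage_voltage_slope,
    edge_tau_us = edge_tau_us
  ), class = "molecule_model")
}

#' @export
print.molecule_model <- function(x, ...) {
  cat(sprintf("<molecule_model> %s: alpha=%.3g, V*=%.3g mV, f=%.3g+/-%.3g, dwell=%.3g ms\n",
              x$name, x$capture_prefactor_alpha, x$capture_barrier_vstar,
              x$blockage_frac_mean, x$blockage_frac_sd, x$dwell_median_ref_ms))
  invisible(x)
}

#' Voltage-dependent capture rate
#'
#' Evaluates the barrier-limited capture model
#' \eqn{\lambda(V) = \alpha |V| \exp(-V^*/|V|)} (events per second); strictly
#' increasing in |V|.
#'
#' @param molecule a \code{\link{molecule_model}}.
#' @param voltage applied voltage, mV (nonzero; negative by convention).
#' @return capture rate in events per second.
#' @export
capture_rate <- function(molecule, voltage) {
  stopifnot(inherits(molecule, "molecule_model"))
  if (any(voltage == 0)) stop("voltage must be nonzero")
  av <- abs(voltage)
  molecule$capture_prefactor_alpha * av *
    exp(-molecule$capture_barrier_vstar / av)
}

# Mean fractional blockage at a voltage, including the linear sensitivity
# term (slope is per 250 mV, referenced to |V| = 100 mV).
blockage_mean_at <- function(molecule, voltage) {
  molecule$blockage_frac_mean +
    molecule$blockage_voltage_slope * (abs(voltage) - 100) / 250
}

dwell_median_at <- function(molecule, voltage) {
  molecule$dwell_median_ref_ms *
    (100 / abs(voltage))^molecule$dwell_voltage_exponent_gamma
}

#' Simulation configuration
#'
#' Bundles the acquisition settings (voltage grid, sampling rate, run
#' structure), baseline/noise model and the analyte composition used by
#' \code{\link{simulate_trace}}.
#'
#' \code{analytes} maps an analyte label to a named weight vector over
#' \code{molecules}; pure samples are degenerate weights. By default every
#' molecule gets a pure entry under its own name, and a \code{"mixture"}
#' entry holds \code{mixture_fractions}. The per-class event rate during
#' simulation is \code{weight * capture_rate(molecule, V)}.
#'
#' @param molecules list of \code{\link{molecule_model}} objects.
#' @param voltage_grid applied voltages in mV, all negative and distinct.
#' @param sampling_rate acquisition rate, Hz.
#' @param duration_s duration of one run, seconds.
#' @param runs_per_condition independent runs per (voltage, analyte).
#' @param pore_conductance open-pore conductance, nS (baseline = G*V pA).
#' @param noise_rms white Gaussian noise RMS, pA.
#' @param drift_rate slow linear baseline drift, pA/s.
#' @param run_offset_sigma sd of the random per-run baseline offset, pA.
#' @param run_offset_by_class optional named vector of fixed per-analyte
#'   baseline offsets (pA) overriding the random offsets.
#' @param mixture_fractions molar fractions over \code{molecules}, summing
#'   to 1; default equal.
#' @param analytes optional named list of weight vectors; see Details.
#' @param seed default base seed for simulation helpers.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(molecules,
                              voltage_grid = c(-50, -100, -150, -200, -250, -300),
                              sampling_rate = 1e5,
                              duration_s = 60,
                              runs_per_condition = 3,
                              pore_conductance = 10,
                              noise_rms = 12,
                              drift_rate = 0.5,
                              run_offset_sigma = 25,
                              run_offset_by_class = NULL,
                              mixture_fractions = NULL,
                              analytes = NULL,
                              seed = 1L) {
  stopifnot(length(molecules) >= 1L,
            all(vapply(molecules, inherits, logical(1), "molecule_model")))
  names(molecules) <- vapply(molecules, `[[`, character(1), "name")
  if (anyDuplicated(names(molecules))) stop("molecule names must be distinct")
  if (any(voltage_grid >= 0)) stop("all voltages must be negative")
  if (anyDuplicated(voltage_grid)) stop("voltages must be distinct")
  if (sampling_rate <= 0 || duration_s <= 0 || runs_per_condition < 1)
    stop("invalid acquisition settings")
  if (is.null(mixture_fractions))
    mixture_fractions <- rep(1 / length(molecules), length(molecules))
  if (length(mixture_fractions) != length(molecules))
    stop("mixture_fractions must have one entry per molecule")
  if (abs(sum(mixture_fractions) - 1) > 1e-12)
    stop("mixture_fractions must sum to 1")
  names(mixture_fractions) <- names(molecules)
  # blockage must stay a valid fraction at every grid voltage
  for (m in molecules) {
    f <- blockage_mean_at(m, voltage_grid)
    if (any(f <= 0 | f >= 1))
      stop(sprintf("molecule '%s': blockage fraction leaves (0,1) on the voltage grid",
                   m$name))
  }
  if (is.null(analytes)) {
    analytes <- lapply(names(molecules), function(nm) {
      w <- stats::setNames(rep(0, length(molecules)), names(molecules))
      w[nm] <- 1
      w
    })
    names(analytes) <- names(molecules)
    analytes$mixture <- mixture_fractions
  } else {
    ok <- vapply(analytes, function(w)
      all(names(w) %in% names(molecules)) && all(w >= 0) && sum(w) > 0,
      logical(1))
    if (!all(ok)) stop("analytes weights must be named over known molecules")
  }
  structure(list(
    molecules = molecules,
    voltage_grid = voltage_grid,
    sampling_rate = sampling_rate,
    duration_s = duration_s,
    runs_per_condition = runs_per_condition,
    pore_conductance = pore_conductance,
    noise_rms = noise_rms,
    drift_rate = drift_rate,
    run_offset_sigma = run_offset_sigma,
    run_offset_by_class = run_offset_by_class,
    mixture_fractions = mixture_fractions,
    analytes = analytes,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d molecule(s) [%s], voltages %s mV\n",
              length(x$molecules), paste(names(x$molecules), collapse = ", "),
              paste(x$voltage_grid, collapse = ", ")))
  cat(sprintf("  %g kHz, %g s x %d run(s), G=%g nS, noise %g pA RMS, drift %g pA/s, offsets sd %g pA\n",
              x$sampling_rate / 1000, x$duration_s, x$runs_per_condition,
              x$pore_conductance, x$noise_rms, x$drift_rate, x$run_offset_sigma))
  invisible(x)
}

# Deterministic per-trace seed derived from the base seed and the run
# coordinates; kept below 2^31.
derive_seed <- function(seed, voltage, run_id, analyte) {
  h <- as.double(seed) %% 2147483647
  for (tok in c(as.character(abs(voltage)), as.character(run_id), analyte)) {
    for (ch in utf8ToInt(tok)) h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate one nanopore current trace
#'
#' Generates a seeded synthetic ionic-current recording: open-pore baseline
#' \code{pore_conductance * voltage} pA plus a per-run offset, linear drift
#' and white Gaussian noise; translocation events arrive as a Poisson process
#' with per-class rate \code{weight * capture_rate(molecule, V)} and are
#' rendered as rectangular depressions of depth \code{f * |local baseline|}
#' with exponential edges. Overlapping arrivals are rejected and redrawn, so
#' all simulated events are isolated. Identical arguments give bit-identical
#' traces.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param voltage applied voltage in mV (member of the grid convention,
#'   negative).
#' @param run_id run label (used in metadata and seed derivation).
#' @param seed integer seed for this trace.
#' @param analyte name of an entry of \code{config$analytes} ("mixture" or a
#'   molecule name by default).
#' @return an object of class \code{trace_recording} with elements
#'   \code{samples} (pA), \code{sampling_rate}, \code{voltage},
#'   \code{run_id}, \code{analyte_label}, \code{truth_events} (data.frame of
#'   0-based half-open sample intervals and source class),
#'   \code{baseline_offset_true} (pA) and \code{seed}.
#' @export
simulate_trace <- function(config, voltage, run_id = "run1", seed = config$seed,
                           analyte = "mixture") {
  stopifnot(inherits(config, "simulation_config"))
  if (voltage == 0) stop("voltage must be nonzero")
  if (voltage >= 0) stop("voltage must be negative")
  if (!analyte %in% names(config$analytes))
    stop(sprintf("unknown analyte '%s'; available: %s", analyte,
                 paste(names(config$analytes), collapse = ", ")))
  weights <- config$analytes[[analyte]]
  weights <- weights[weights > 0]
  rate <- config$sampling_rate
  n <- round(config$duration_s * rate)
  dt <- 1 / rate
  with_seed(seed, {
    offset <- if (!is.null(config$run_offset_by_class) &&
                  analyte %in% names(config$run_offset_by_class)) {
      unname(config$run_offset_by_class[[analyte]])
    } else {
      stats::rnorm(1, 0, config$run_offset_sigma)
    }
    tvec_end <- (n - 1) * dt
    base0 <- config$pore_conductance * voltage + offset
    # event bookkeeping: draw class, dwell, depth fraction, then place starts
    # by rejection so events never overlap
    ev <- list()
    for (nm in names(weights)) {
      mol <- config$molecules[[nm]]
      lam <- weights[[nm]] * capture_rate(mol, voltage)
      k <- stats::rpois(1, lam * config$duration_s)
      if (k == 0) next
      dwell_ms <- stats::rlnorm(k, log(dwell_median_at(mol, voltage)),
                                mol$dwell_log_sd)
      f <- stats::rnorm(k, blockage_mean_at(mol, voltage), mol$blockage_frac_sd)
      bad <- which(f <= 0.005 | f >= 0.95)
      tries <- 0L
      while (length(bad) && tries < 100L) {
        f[bad] <- stats::rnorm(length(bad), blockage_mean_at(mol, voltage),
                               mol$blockage_frac_sd)
        bad <- which(f <= 0.005 | f >= 0.95)
        tries <- tries + 1L
      }
      if (length(bad)) stop("could not draw valid blockage fractions")
      ev[[nm]] <- data.frame(class = nm, dwell_ms = dwell_ms, f = f,
                             tau_us = mol$edge_tau_us,
                             stringsAsFactors = FALSE)
    }
    ev <- if (length(ev)) do.call(rbind, ev) else
      data.frame(class = character(), dwell_ms = numeric(), f = numeric(),
                 tau_us = numeric())
    ne <- nrow(ev)
    gap_s <- 5e-4  # enforced clearance between events, 0.5 ms
    if (ne > 0) {
      if (sum(ev$dwell_ms) / 1000 + ne * gap_s > 0.8 * config$duration_s)
        stop("event rate saturates the trace: dwell load exceeds 80% of the run")
      start_s <- rep(NA_real_, ne)
      pending <- seq_len(ne)
      acc_s <- numeric(0); acc_e <- numeric(0)   # sorted placed intervals
      tries <- 0L
      while (length(pending) && tries < 200L) {
        prop_s <- stats::runif(length(pending), 0,
                               pmax(config$duration_s - ev$dwell_ms[pending] / 1000, 0))
        prop_e <- prop_s + ev$dwell_ms[pending] / 1000
        # clash with already-placed intervals (which have priority)
        if (length(acc_s)) {
          k <- findInterval(prop_s, acc_s)
          clash <- (k >= 1L & prop_s < acc_e[pmax(k, 1L)] + gap_s) |
                   (k < length(acc_s) & acc_s[pmin(k + 1L, length(acc_s))] < prop_e + gap_s)
        } else clash <- rep(FALSE, length(prop_s))
        # mutual clashes among surviving proposals: sweep, keep first
        ord <- order(prop_s)
        last_end <- -Inf
        for (i in ord) {
          if (clash[i]) next
          if (prop_s[i] >= last_end + gap_s) last_end <- prop_e[i]
          else clash[i] <- TRUE
        }
        placed <- !clash
        start_s[pending[placed]] <- prop_s[placed]
        acc_s <- c(acc_s, prop_s[placed]); acc_e <- c(acc_e, prop_e[placed])
        o <- order(acc_s); acc_s <- acc_s[o]; acc_e <- acc_e[o]
        pending <- pending[!placed]
        tries <- tries + 1L
      }
      if (length(pending))
        stop("event placement saturated: could not place all events without overlap")
      ev$start_s <- start_s
      ev <- ev[order(ev$start_s), , drop = FALSE]
    }
    # assemble the trace
    tcur <- base0 + config$drift_rate * (seq_len(n) - 1) * dt
    truth <- data.frame(start = integer(0), end = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
    if (ne > 0) {
      s_idx <- pmin(pmax(floor(ev$start_s * rate) + 1L, 1L), n)
      n_dw <- pmax(1L, round(ev$dwell_ms / 1000 * rate))
      e_idx <- pmin(s_idx + n_dw - 1L, n)
      for (i in seq_len(ne)) {
        s <- s_idx[i]; e <- e_idx[i]
        depth <- ev$f[i] * abs(tcur[s])
        core <- s:e
        tau_s <- ev$tau_us[i] * 1e-6
        if (tau_s > 0) {
          rise <- 1 - exp(-(seq_along(core)) * dt / tau_s)
          tcur[core] <- tcur[core] - depth * rise
          ntail <- min(ceiling(6 * tau_s / dt), n - e)
          if (ntail > 0) {
            tail_idx <- (e + 1L):(e + ntail)
            tcur[tail_idx] <- tcur[tail_idx] -
              depth * rise[length(rise)] * exp(-(seq_len(ntail)) * dt / tau_s)
          }
        } else {
          tcur[core] <- tcur[core] - depth
        }
      }
      truth <- data.frame(start = s_idx - 1L, end = e_idx,
                          class = ev$class, stringsAsFactors = FALSE)
    }
    if (config$noise_rms > 0)
      tcur <- tcur + stats::rnorm(n, 0, config$noise_rms)
    structure(list(
      samples = tcur,
      sampling_rate = rate,
      voltage = voltage,
      run_id = as.character(run_id),
      analyte_label = analyte,
      truth_events = truth,
      baseline_offset_true = offset,
      seed = as.integer(seed),
      duration_s = config$duration_s,
      pore_conductance = config$pore_conductance
    ), class = "trace_recording")
  })
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("<trace_recording> %s @ %d mV (%s): %d samples @ %g kHz, %d truth event(s)\n",
              x$analyte_label, x$voltage, x$run_id, length(x$samples),
              x$sampling_rate / 1000, nrow(x$truth_events)))
  invisible(x)
}

#' Prebuilt simulation scenarios
#'
#' Returns a fully populated \code{\link{simulation_config}} for one of the
#' named study designs:
#' \describe{
#'   \item{two_marker}{two tumor-marker-like analytes whose capture rates are
#'     equal at -50 mV and differ two-fold at -300 mV, with well separated
#'     voltage-invariant blockage distributions.}
#'   \item{aptamer_shift}{a protein and its aptamer complex: same capture
#'     kinetics, but the complex's blockage distribution shifts with voltage
#'     (\code{blockage_voltage_slope != 0}), degrading cross-voltage
#'     generalization.}
#'   \item{baseline_overfit_demo}{two classes with identical event statistics
#'     but fixed per-class run baseline offsets of +40 / -40 pA; only
#'     baseline-dependent features can separate them.}
#'   \item{equimolar_mixture}{the two_marker pair with molar fractions
#'     (0.5, 0.5) for mixture quantification.}
#'   \item{serum_shift}{three event subpopulations; the "centrifuged" variant
#'     down-weights the long-dwell shallow-blockage subpopulation from 0.4 to
#'     0.1 and slightly shifts the retained populations' blockage.}
#' }
#'
#' @param name scenario name.
#' @param ... overrides passed to \code{\link{simulation_config}} (e.g.
#'   \code{duration_s}, \code{seed}).
#' @return a \code{\link{simulation_config}}.
#' @export
make_scenario <- function(name, ...) {
  known <- c("two_marker", "aptamer_shift", "baseline_overfit_demo",
             "equimolar_mixture", "serum_shift")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop(sprintf("unknown scenario '%s'; options: %s",
                 as.character(name)[1], paste(known, collapse = ", ")))
  cea <- molecule_model("CEA", 0.046, 61.6, 0.15, 0.03, 0.5, 0.4)
  ca153 <- molecule_model("CA15-3", 0.020, 20, 0.28, 0.05, 2.0, 0.5)
  dots <- list(...)
  build <- function(molecules, defaults = list()) {
    args <- c(list(molecules = molecules), utils::modifyList(defaults, dots))
    do.call(simulation_config, args)
  }
  switch(name,
    two_marker = build(list(cea, ca153)),
    equimolar_mixture = build(list(cea, ca153),
                              list(mixture_fractions = c(0.5, 0.5))),
    aptamer_shift = {
      # complex shares the protein's capture model; its blockage crosses the
      # protein's near -110 mV (voltage-sensitive conformation) and its dwell
      # scaling differs, so matched-voltage separation stays usable while the
      # class ranking inverts across the grid
      complex <- molecule_model("CEA-aptamer", 0.046, 61.6, 0.14, 0.03, 1.04, 0.4,
                                dwell_voltage_exponent_gamma = 0.2,
                                blockage_voltage_slope = 0.20)
      build(list(cea, complex))
    },
    baseline_overfit_demo = {
      mk <- function(nm) molecule_model(nm, 0.15, 0, 0.20, 0.04, 1.0, 0.4,
                                        dwell_voltage_exponent_gamma = 0)
      build(list(mk("class_pos"), mk("class_neg")),
            list(run_offset_sigma = 0,
                 run_offset_by_class = c(class_pos = 40, class_neg = -40),
                 duration_s = 10))
    },
    serum_shift = {
      p1 <- molecule_model("long_shallow", 0.05, 40, 0.10, 0.02, 3.0, 0.4)
      p2 <- molecule_model("mid", 0.05, 40, 0.20, 0.03, 0.8, 0.4)
      p3 <- molecule_model("fast_deep", 0.05, 40, 0.32, 0.04, 0.3, 0.4)
      # centrifugation removes most of the long-dwell shallow population and
      # mildly shifts the waveform statistics of what remains
      p2c <- molecule_model("mid_c", 0.05, 40, 0.24, 0.03, 0.6, 0.4)
      p3c <- molecule_model("fast_deep_c", 0.05, 40, 0.36, 0.04, 0.22, 0.4)
      build(list(p1, p2, p3, p2c, p3c),
            list(analytes = list(
              uncentrifuged = c(long_shallow = 0.4, mid = 0.3, fast_deep = 0.3),
              centrifuged = c(long_shallow = 0.1, mid_c = 0.45, fast_deep_c = 0.45))))
    })
}

#' Simulate and detect events over a whole acquisition design
#'
#' Convenience driver: simulates all runs of one analyte over the requested
#' voltages, detects events in each trace, and returns a single event table
#' with \code{analyte}, \code{voltage} and \code{run_id} columns. Traces are
#' discarded after detection, so memory stays flat. Per-trace seeds are
#' derived deterministically from \code{seed} and the run coordinates.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param analyte entry of \code{config$analytes} to simulate.
#' @param voltages voltages to cover (default the config grid).
#' @param seed base seed.
#' @param params a \code{\link{detection_params}}.
#' @return data.frame of event records (see \code{\link{detect_events}}) with
#'   an extra \code{analyte} column; attribute \code{total_duration_s} gives
#'   the summed recording time per voltage.
#' @export
simulate_events <- function(config, analyte, voltages = config$voltage_grid,
                            seed = config$seed, params = detection_params()) {
  out <- vector("list", length(voltages) * config$runs_per_condition)
  i <- 0L
  for (v in voltages) {
    for (r in seq_len(config$runs_per_condition)) {
      rid <- sprintf("%s_V%d_r%d", analyte, abs(v), r)
      tr <- simulate_trace(config, v, run_id = rid,
                           seed = derive_seed(seed, v, r, analyte),
                           analyte = analyte)
      evs <- detect_events(tr, params)
      if (nrow(evs)) evs$analyte <- analyte
      i <- i + 1L
      out[[i]] <- evs
    }
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  res <- if (length(out)) do.call(rbind, out) else
    cbind(empty_event_table(), analyte = character(0))
  attr(res, "total_duration_s") <- config$duration_s * config$runs_per_condition
  res
}
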