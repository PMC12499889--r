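#' @name voltmatrix-io
#' @title Plain-text readers and writers
#' @description All pipeline artifacts round-trip through tab-separated text
#'   and JSON sidecars: traces as two-column \code{time_s}/\code{current_pA}
#'   TSV with a \code{.meta.json} sidecar, event tables and feature tables as
#'   TSV, voltage matrices as TSV plus a JSON sidecar, mixture reports as
#'   JSON.
NULL

meta_path <- function(file) {
  base <- sub("\\.[^.]*$", "", file)
  paste0(base, ".meta.json")
}

#' Write a trace recording
#'
#' Writes \code{time_s<TAB>current_pA} plus a \code{<name>.meta.json}
#' sidecar holding voltage_mv, sampling_rate_hz, run_id, analyte_label, seed
#' and the truth-event annotations.
#'
#' @param trace a \code{trace_recording}.
#' @param file output path (e.g. \code{trace.tsv}).
#' @return \code{file}, invisibly.
#' @export
write_trace <- function(trace, file) {
  n <- length(trace$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sampling_rate,
                   current_pA = trace$samples)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(voltage_mv = trace$voltage,
               sampling_rate_hz = trace$sampling_rate,
               run_id = trace$run_id,
               analyte_label = trace$analyte_label,
               seed = trace$seed,
               baseline_offset_true = trace$baseline_offset_true,
               truth_events = trace$truth_events)
  jsonlite::write_json(meta, meta_path(file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a trace recording written by \code{\link{write_trace}}
#'
#' @param file path to the trace TSV; the \code{.meta.json} sidecar must sit
#'   beside it.
#' @return a \code{trace_recording}.
#' @export
read_trace <- function(file) {
  if (!file.exists(file)) stop(sprintf("trace file not found: %s", file))
  df <- utils::read.delim(file, sep = "\t")
  if (nrow(df) == 0L) stop(sprintf("trace file is empty: %s", file))
  mp <- meta_path(file)
  if (!file.exists(mp)) stop(sprintf("metadata sidecar not found: %s", mp))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  truth <- meta$truth_events
  if (is.null(truth) || length(truth) == 0L)
    truth <- data.frame(start = integer(0), end = integer(0),
                        class = character(0))
  structure(list(samples = df$current_pA,
                 sampling_rate = meta$sampling_rate_hz,
                 voltage = meta$voltage_mv,
                 run_id = meta$run_id,
                 analyte_label = meta$analyte_label,
                 truth_events = as.data.frame(truth),
                 baseline_offset_true = meta$baseline_offset_true,
                 seed = meta$seed), class = "trace_recording")
}

#' Write / read an event table
#'
#' TSV with one header row; columns are the event-record fields in their
#' canonical order, followed by any extra columns (e.g. \code{analyte}).
#'
#' @param events event data.frame.
#' @param file path.
#' @return \code{file} (write) or the data.frame (read).
#' @export
write_events <- function(events, file) {
  lead <- intersect(event_record_columns, names(events))
  rest <- setdiff(names(events), lead)
  utils::write.table(events[, c(lead, rest), drop = FALSE], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  if (!file.exists(file)) stop(sprintf("event file not found: %s", file))
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a feature table
#'
#' TSV whose first line is a \code{#featureset=<name>} comment; feature
#' columns come first, then \code{label} (if present), \code{voltage} and
#' \code{run_id}.
#'
#' @param table a \code{feature_table}.
#' @param file path.
#' @return \code{file} (write) or a \code{feature_table} (read).
#' @export
write_feature_table <- function(table, file) {
  stopifnot(inherits(table, "feature_table"))
  df <- table$x
  if (!is.null(table$labels)) df$label <- as.character(table$labels)
  df$voltage <- table$voltage
  df$run_id <- table$run_id
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#featureset=%s", table$featureset), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(file) {
  if (!file.exists(file)) stop(sprintf("feature file not found: %s", file))
  first <- readLines(file, n = 1L)
  if (!grepl("^#featureset=", first))
    stop("not a feature table: missing #featureset header")
  fname <- sub("^#featureset=", "", first)
  df <- utils::read.delim(file, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) factor(df$label) else NULL
  voltage <- df$voltage
  run_id <- df$run_id
  df$label <- NULL; df$voltage <- NULL; df$run_id <- NULL
  structure(list(x = df, labels = labels, voltage = voltage, run_id = run_id,
                 featureset = fname, standardization = NULL),
            class = "feature_table")
}

#' Write a voltage-matrix result
#'
#' AUC grid as TSV (train voltages as rows, test voltages as columns) plus a
#' \code{.meta.json} sidecar with algorithm, feature set, positive class,
#' seed and the evaluation-count grid.
#'
#' @param result a \code{voltage_matrix_result}.
#' @param file output TSV path.
#' @return \code{file}, invisibly.
#' @export
write_matrix_result <- function(result, file) {
  stopifnot(inherits(result, "voltage_matrix_result"))
  df <- data.frame(train_voltage = result$train_voltages,
                   result$auc, check.names = FALSE)
  names(df)[-1] <- as.character(result$test_voltages)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(algo = result$algo, feature_set = result$feature_set,
               positive = result$positive, seed = result$seed,
               train_voltages = result$train_voltages,
               test_voltages = result$test_voltages,
               n_events = result$n_events)
  jsonlite::write_json(meta, meta_path(file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a voltage-matrix result written by \code{\link{write_matrix_result}}
#'
#' @param file TSV path with its \code{.meta.json} sidecar.
#' @return a \code{voltage_matrix_result} (without the model objects).
#' @export
read_matrix_result <- function(file) {
  if (!file.exists(file)) stop(sprintf("matrix file not found: %s", file))
  df <- utils::read.delim(file, sep = "\t", check.names = FALSE)
  meta <- jsonlite::read_json(meta_path(file), simplifyVector = TRUE)
  aucm <- as.matrix(df[, -1, drop = FALSE])
  dimnames(aucm) <- list(train = meta$train_voltages, test = meta$test_voltages)
  nm <- meta$n_events
  if (!is.null(nm)) {
    nm <- as.matrix(nm)
    dimnames(nm) <- dimnames(aucm)
  }
  structure(list(auc = aucm, n_events = nm, models = NULL, eval_tables = NULL,
                 train_voltages = meta$train_voltages,
                 test_voltages = meta$test_voltages,
                 algo = meta$algo, feature_set = meta$feature_set,
                 positive = meta$positive, seed = meta$seed),
            class = "voltage_matrix_result")
}

#' Write a mixture report
#'
#' JSON with every mixture-estimate field, the bimodal fit parameters and
#' rule names, plus a histogram TSV (\code{bin_left, bin_right, count}) of
#' the scores when available.
#'
#' @param estimate a \code{mixture_estimate}.
#' @param file output JSON path.
#' @param n_bins histogram bins for the companion TSV.
#' @return \code{file}, invisibly.
#' @export
write_mixture_report <- function(estimate, file, n_bins = 20L) {
  stopifnot(inherits(estimate, "mixture_estimate"))
  fit <- estimate$fit
  payload <- list(
    raw_ratio_at_half = estimate$raw_ratio_at_half,
    boundary = estimate$boundary,
    corrected_event_ratio = estimate$corrected_event_ratio,
    capture_rate_pos = estimate$capture_rate_pos,
    capture_rate_neg = estimate$capture_rate_neg,
    molecular_ratio = estimate$molecular_ratio,
    boundary_rule = estimate$boundary_rule,
    ratio_rule = estimate$ratio_rule,
    n = estimate$n,
    fit = list(w1 = fit$w1, w2 = fit$w2, mu1 = fit$mu1, mu2 = fit$mu2,
               sigma1 = fit$sigma1, sigma2 = fit$sigma2,
               converged = fit$converged, unimodal = fit$unimodal,
               log_likelihood = fit$log_likelihood))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  scores <- attr(estimate, "scores")
  if (!is.null(scores)) {
    h <- score_histogram(scores, n_bins)
    hdf <- data.frame(bin_left = utils::head(h$edges, -1),
                      bin_right = h$edges[-1], count = h$counts)
    utils::write.table(hdf, sub("\\.json$", ".hist.tsv", file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname write_mixture_report
#' @export
read_mixture_report <- function(file) {
  if (!file.exists(file)) stop(sprintf("mixture report not found: %s", file))
  jsonlite::read_json(file, simplifyVector = TRUE)
}

# FNV-1a hash of a deparsed object; used for provenance logging only
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline configuration file
#'
#' YAML mirroring the configuration field names: a \code{simulation} section
#' (either \code{scenario: <name>} or explicit \code{simulation_config}
#' fields with a \code{molecules} list), an optional \code{detection}
#' section (\code{detection_params} fields), and optional \code{feature_set}
#' (\code{"A"}/\code{"B"}), \code{algo}, \code{train_frac}, \code{seed},
#' \code{boundary_rule}, \code{ratio_rule}, \code{output_dir} entries. A
#' commented template ships at
#' \code{system.file("extdata", "config_template.yaml", package = "voltmatrix")}.
#'
#' @param file YAML path.
#' @return list with \code{simulation} (a \code{simulation_config}),
#'   \code{detection} (a \code{detection_params}) and the scalar settings.
#' @export
read_pipeline_config <- function(file) {
  if (!file.exists(file)) stop(sprintf("config file not found: %s", file))
  y <- yaml::read_yaml(file)
  sim_y <- y$simulation
  if (is.null(sim_y)) stop("config must contain a 'simulation' section")
  sim <- if (!is.null(sim_y$scenario)) {
    extra <- sim_y[setdiff(names(sim_y), "scenario")]
    do.call(make_scenario, c(list(sim_y$scenario), extra))
  } else {
    mols <- lapply(sim_y$molecules, function(m) do.call(molecule_model, m))
    args <- sim_y[setdiff(names(sim_y), "molecules")]
    do.call(simulation_config, c(list(molecules = mols), args))
  }
  det <- do.call(detection_params, if (is.null(y$detection)) list() else y$detection)
  list(simulation = sim,
       detection = det,
       feature_set = if (is.null(y$feature_set)) "A" else y$feature_set,
       algo = if (is.null(y$algo)) "random_forest" else y$algo,
       train_frac = if (is.null(y$train_frac)) 0.7 else y$train_frac,
       seed = if (is.null(y$seed)) sim$seed else as.integer(y$seed),
       boundary_rule = if (is.null(y$boundary_rule)) "intersection" else y$boundary_rule,
       ratio_rule = if (is.null(y$ratio_rule)) "exceedance" else y$ratio_rule,
       output_dir = if (is.null(y$output_dir)) "." else y$output_dir)
}
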