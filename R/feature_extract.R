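#' Feature set specification
#'
#' A named list of event-derived feature names. Set A contains only
#' event-intrinsic quantities (ratios and shape statistics that do not
#' depend on the absolute current scale); set B adds the baseline-dependent
#' quantities that allow a classifier to fingerprint the acquisition
#' condition instead of the molecule.
#'
#' @param name label ("A", "B" or custom).
#' @param members character vector of feature names; valid names are the
#'   event-record columns plus the derived ratios \code{area_norm}
#'   (\code{area_pa_ms / |i0_local_pa|}), \code{fwhm_ratio}
#'   (\code{fwhm_ms / dwell_ms}) and \code{sd_ratio}
#'   (\code{intra_event_sd_pa / delta_i_pa}).
#' @return object of class \code{feature_set_spec}.
#' @export
feature_set_spec <- function(name, members) {
  stopifnot(is.character(name), is.character(members), length(members) > 0)
  if (anyDuplicated(members)) stop("feature names must be distinct")
  structure(list(name = name, members = members), class = "feature_set_spec")
}

baseline_dependent_features <- c("delta_i_pa", "delta_i_max_pa", "i0_local_pa",
                                 "baseline_rms_pa", "drift_slope_pa_s")

#' Default feature sets A and B
#'
#' Set A holds seven event-intrinsic features: dwell time, fractional
#' blockage, normalized area (equivalent charge deficit divided by the local
#' open-pore current magnitude), skewness, excess kurtosis, FWHM/dwell ratio
#' and the intra-event SD / mean depth ratio. Set B is A plus the five
#' baseline-dependent features (absolute mean and max blockade amplitude,
#' local open-pore current, baseline RMS, drift slope).
#'
#' @return list with elements \code{A} and \code{B}, each a
#'   \code{\link{feature_set_spec}}.
#' @export
default_feature_sets <- function() {
  a <- c("dwell_ms", "frac_blockage", "area_norm", "skewness", "kurtosis",
         "fwhm_ratio", "sd_ratio")
  list(A = feature_set_spec("A", a),
       B = feature_set_spec("B", c(a, baseline_dependent_features)))
}

derived_feature <- function(events, name) {
  switch(name,
    area_norm = events$area_pa_ms / abs(events$i0_local_pa),
    fwhm_ratio = events$fwhm_ms / events$dwell_ms,
    sd_ratio = events$intra_event_sd_pa / events$delta_i_pa,
    events[[name]])
}

#' Build a feature table from event records
#'
#' One row per event, columns in the order given by the feature-set spec.
#' Labels are optional (absent for mixture samples); the per-event voltage
#' and run id are carried alongside the feature matrix.
#'
#' @param events event data.frame from \code{\link{detect_events}} /
#'   \code{\link{simulate_events}}.
#' @param spec a \code{\link{feature_set_spec}}.
#' @param labels optional class label per event (character or factor).
#' @return object of class \code{feature_table}: list with \code{x}
#'   (data.frame of features), \code{labels} (factor or NULL),
#'   \code{voltage}, \code{run_id}, \code{featureset} and
#'   \code{standardization} (NULL until \code{\link{standardize_features}}).
#' @export
build_feature_table <- function(events, spec, labels = NULL) {
  stopifnot(inherits(spec, "feature_set_spec"))
  if (is.null(events) || nrow(events) == 0L)
    stop("cannot build a feature table from zero events")
  cols <- lapply(spec$members, function(nm) {
    v <- derived_feature(events, nm)
    if (is.null(v)) stop(sprintf("unknown feature '%s'", nm))
    v
  })
  x <- as.data.frame(stats::setNames(cols, spec$members))
  if (anyNA(x)) stop("feature table contains missing values")
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    labels <- factor(labels)
  }
  structure(list(x = x, labels = labels,
                 voltage = events$voltage, run_id = events$run_id,
                 featureset = spec$name, standardization = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> set %s: %d event(s) x %d feature(s)%s\n",
              x$featureset, nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) " (unlabeled)" else
                sprintf(", classes: %s", paste(levels(x$labels), collapse = "/"))))
  invisible(x)
}

#' Standardize a feature table against reference statistics
#'
#' Z-scores each column using the mean and SD learned from \code{reference}
#' (the training table); the reference defaults to the table itself.
#' Zero-variance reference columns pass through unscaled (SD treated as 1)
#' and are flagged.
#'
#' @param table a \code{\link{build_feature_table}} result.
#' @param reference feature table supplying the standardization statistics.
#' @return the standardized \code{feature_table}; its
#'   \code{standardization} element stores \code{mean}, \code{sd} and the
#'   \code{constant} flag vector.
#' @export
standardize_features <- function(table, reference = table) {
  stopifnot(inherits(table, "feature_table"), inherits(reference, "feature_table"))
  if (!identical(names(table$x), names(reference$x)))
    stop("feature schema mismatch between table and reference")
  st <- reference$standardization
  if (is.null(st)) {
    mu <- vapply(reference$x, mean, numeric(1))
    sdev <- vapply(reference$x, stats::sd, numeric(1))
    constant <- !is.finite(sdev) | sdev < 1e-12
    sdev[constant] <- 1
    st <- list(mean = mu, sd = sdev, constant = constant)
  }
  if (any(st$constant))
    warning(sprintf("constant feature column(s) passed through unscaled: %s",
                    paste(names(table$x)[st$constant], collapse = ", ")))
  x <- sweep(sweep(as.matrix(table$x), 2, st$mean, "-"), 2, st$sd, "/")
  # constant columns keep their raw values
  if (any(st$constant))
    x[, st$constant] <- as.matrix(table$x)[, st$constant]
  out <- table
  out$x <- as.data.frame(x)
  names(out$x) <- names(table$x)
  out$standardization <- st
  out
}
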