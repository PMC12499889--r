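#' Detection parameters
#'
#' Settings of the two-threshold (Schmitt-trigger) event detector and its
#' moving-median baseline tracker.
#'
#' @param baseline_window_ms moving-median baseline window, ms.
#' @param threshold_k event entry threshold, multiples of baseline RMS.
#' @param exit_k event exit threshold, multiples of baseline RMS (must be
#'   smaller than \code{threshold_k}).
#' @param min_dwell_samples minimum event length in samples; shorter
#'   candidates are discarded.
#' @param refractory_samples events closer than this many samples are merged.
#' @param baseline_stride_samples stride at which the moving median is
#'   evaluated before interpolation; \code{NULL} = window/10. The baseline
#'   varies only through slow drift, so a strided estimate is equivalent to
#'   the per-sample one at a fraction of the cost.
#' @return an object of class \code{detection_params}.
#' @export
detection_params <- function(baseline_window_ms = 50, threshold_k = 5,
                             exit_k = 2, min_dwell_samples = 5,
                             refractory_samples = 5,
                             baseline_stride_samples = NULL) {
  if (exit_k >= threshold_k) stop("exit_k must be < threshold_k")
  if (min_dwell_samples < 1) stop("min_dwell_samples must be >= 1")
  if (baseline_window_ms <= 0) stop("baseline_window_ms must be > 0")
  structure(list(baseline_window_ms = baseline_window_ms,
                 threshold_k = threshold_k, exit_k = exit_k,
                 min_dwell_samples = as.integer(min_dwell_samples),
                 refractory_samples = as.integer(refractory_samples),
                 baseline_stride_samples = baseline_stride_samples),
            class = "detection_params")
}

# moving median evaluated on a strided grid, linearly interpolated back to
# every sample; long blocks are subsampled (49 evenly spaced points) and all
# block medians are extracted with a single order() pass
strided_median <- function(x, window, stride) {
  n <- length(x)
  nb <- max(1L, floor(n / stride))
  idx_start <- (seq_len(nb) - 1L) * stride + 1L
  idx_end <- pmin(idx_start + stride - 1L, n)
  idx_end[nb] <- n
  ksub <- 49L
  if (stride <= ksub) {
    med <- vapply(seq_len(nb), function(j)
      stats::median.default(x[idx_start[j]:idx_end[j]]), numeric(1))
  } else {
    off <- unique(round(seq(0L, stride - 1L, length.out = ksub)))
    ksub <- length(off)
    idx <- rep(idx_start, each = ksub) + rep.int(off, nb)
    idx[idx > n] <- n
    v <- x[idx]
    o <- order(rep.int(seq_len(nb), rep.int(ksub, nb)), v)
    sorted <- matrix(v[o], ksub, nb)
    med <- if (ksub %% 2L == 1L) sorted[(ksub + 1L) / 2L, ] else
      (sorted[ksub / 2L, ] + sorted[ksub / 2L + 1L, ]) / 2
  }
  k <- max(1L, round(window / stride))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L && nb >= k) med <- stats::runmed(med, k, endrule = "median")
  if (nb == 1L) return(rep(med, n))
  # linear interpolation from the (equally spaced) block centers
  centers <- (idx_start + idx_end) / 2
  p <- (seq_len(n) - centers[1]) / stride
  j <- pmin(pmax(floor(p), 0), nb - 2L)
  w <- pmin(pmax(p - j, 0), 1)
  # written so that equal neighbours interpolate exactly
  med[j + 1L] + w * (med[j + 2L] - med[j + 1L])
}

#' Baseline estimation
#'
#' Two-pass moving-median open-pore baseline: a first-pass median flags
#' candidate event spans, which are replaced by the first-pass baseline
#' before the second pass, so long blockades do not drag the baseline down.
#' RMS noise is estimated robustly (MAD on the first pass, SD of
#' out-of-event residuals on the second); the drift slope comes from a least
#' squares fit of the baseline on time.
#'
#' @param trace a \code{trace_recording} (or any list with \code{samples}
#'   and \code{sampling_rate}).
#' @param params a \code{\link{detection_params}}.
#' @return list with \code{baseline} (pA, one value per sample), \code{rms}
#'   (pA) and \code{drift_slope} (pA/s).
#' @export
estimate_baseline <- function(trace, params = detection_params()) {
  x <- trace$samples
  rate <- trace$sampling_rate
  n <- length(x)
  window <- max(3L, round(params$baseline_window_ms / 1000 * rate))
  if (n <= window) stop("trace shorter than the baseline window")
  stride <- params$baseline_stride_samples
  if (is.null(stride)) stride <- max(1L, round(window / 10))
  b1 <- strided_median(x, window, stride)
  resid1 <- x - b1
  sub1 <- if (n > 4e5) resid1[seq(1L, n, by = 7L)] else resid1
  rms1 <- stats::mad(sub1)
  # blockades deviate below baseline; mask anything past the exit threshold
  mask <- resid1 < -params$exit_k * rms1
  x2 <- x
  x2[mask] <- b1[mask]
  b2 <- strided_median(x2, window, stride)
  resid2 <- x - b2
  out <- !mask
  rms <- if (any(out)) stats::sd(resid2[out]) else 0
  if (!is.finite(rms)) rms <- 0
  tt <- (seq_len(n) - 1) / rate
  sub <- seq(1L, n, by = max(1L, stride))
  fit <- stats::lm.fit(cbind(1, tt[sub]), b2[sub])
  list(baseline = b2, rms = rms, drift_slope = unname(fit$coefficients[2]))
}

event_record_columns <- c("start_index", "end_index", "dwell_ms", "delta_i_pa",
                          "delta_i_max_pa", "i0_local_pa", "frac_blockage",
                          "area_pa_ms", "skewness", "kurtosis", "fwhm_ms",
                          "intra_event_sd_pa", "baseline_rms_pa",
                          "drift_slope_pa_s", "voltage", "run_id")

empty_event_table <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(event_record_columns)),
    event_record_columns))
  df$start_index <- integer(0); df$end_index <- integer(0)
  df$run_id <- character(0)
  df
}

#' Detect translocation events
#'
#' Schmitt-trigger event calling over the moving-median baseline: an event
#' opens when the current deviates below baseline by more than
#' \code{threshold_k * rms} and extends while the deviation exceeds
#' \code{exit_k * rms}. Candidates shorter than \code{min_dwell_samples} are
#' dropped; candidates separated by fewer than \code{refractory_samples} are
#' merged. Indices in the output are 0-based half-open.
#'
#' \code{delta_i_pa} is the mean depth over the event core (between the exit
#' threshold crossings), \code{delta_i_max_pa} the extreme depth; shape
#' statistics (skewness, excess kurtosis, FWHM, intra-event SD) are computed
#' on the within-event samples.
#'
#' @param trace a \code{trace_recording}.
#' @param params a \code{\link{detection_params}}.
#' @return data.frame with columns \code{start_index, end_index, dwell_ms,
#'   delta_i_pa, delta_i_max_pa, i0_local_pa, frac_blockage, area_pa_ms,
#'   skewness, kurtosis, fwhm_ms, intra_event_sd_pa, baseline_rms_pa,
#'   drift_slope_pa_s, voltage, run_id}, sorted by \code{start_index}.
#' @export
detect_events <- function(trace, params = detection_params()) {
  bl <- estimate_baseline(trace, params)
  x <- trace$samples
  rate <- trace$sampling_rate
  dev <- bl$baseline - x               # positive during a blockade
  # absolute floor keeps a zero-noise trace from triggering on float dust
  floor_pa <- 1e-8 * max(1, abs(stats::median(x)))
  entry_thr <- max(params$threshold_k * bl$rms, floor_pa)
  exit_thr <- max(params$exit_k * bl$rms, floor_pa / 2)
  above <- dev > exit_thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  if (!length(cand)) {
    out <- empty_event_table()
    attr(out, "baseline_rms") <- bl$rms
    return(out)
  }
  s <- starts[cand]; e <- ends[cand]
  # keep only runs that reach the entry threshold somewhere
  hit <- c(0L, cumsum(dev > entry_thr))
  nhit <- hit[e + 1L] - hit[s]
  keep <- nhit > 0L
  s <- s[keep]; e <- e[keep]
  if (!length(s)) {
    out <- empty_event_table()
    attr(out, "baseline_rms") <- bl$rms
    return(out)
  }
  # merge events separated by less than the refractory gap
  if (length(s) > 1L) {
    gap <- s[-1L] - e[-length(e)] - 1L
    grp <- cumsum(c(0L, as.integer(gap >= params$refractory_samples)))
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
    s <- as.integer(s); e <- as.integer(e)
  }
  len <- e - s + 1L
  keep <- len >= params$min_dwell_samples
  s <- s[keep]; e <- e[keep]; len <- len[keep]
  if (!length(s)) {
    out <- empty_event_table()
    attr(out, "baseline_rms") <- bl$rms
    return(out)
  }
  k <- length(s)
  rec <- vector("list", k)
  for (i in seq_len(k)) {
    core <- s[i]:e[i]
    d <- dev[core]
    di <- mean(d)
    dmax <- max(d)
    i0 <- bl$baseline[core[(length(core) + 1L) %/% 2L]]  # smooth -> midpoint
    m2 <- mean((d - di)^2)
    if (m2 > 1e-12) {
      skw <- mean((d - di)^3) / m2^1.5
      krt <- mean((d - di)^4) / m2^2 - 3
    } else {
      skw <- 0; krt <- 0
    }
    rec[[i]] <- c(di, dmax, i0, di / abs(i0), sum(d) / rate * 1000,
                  skw, krt, sum(d > dmax / 2) / rate * 1000,
                  stats::sd(x[core]))
  }
  m <- do.call(rbind, rec)
  out <- data.frame(
    start_index = s - 1L,
    end_index = e,
    dwell_ms = len / rate * 1000,
    delta_i_pa = m[, 1],
    delta_i_max_pa = m[, 2],
    i0_local_pa = m[, 3],
    frac_blockage = m[, 4],
    area_pa_ms = m[, 5],
    skewness = m[, 6],
    kurtosis = m[, 7],
    fwhm_ms = m[, 8],
    intra_event_sd_pa = m[, 9],
    baseline_rms_pa = bl$rms,
    drift_slope_pa_s = bl$drift_slope,
    voltage = trace$voltage,
    run_id = trace$run_id,
    stringsAsFactors = FALSE
  )
  attr(out, "baseline_rms") <- bl$rms
  out
}

#' Match detected events to ground-truth annotations
#'
#' Greedy one-to-one interval matching at >= 50 percent reciprocal overlap
#' (overlap covers at least half of the detected and half of the truth
#' interval). Pairs are taken in decreasing overlap order.
#'
#' @param events data.frame from \code{\link{detect_events}} (0-based
#'   half-open \code{start_index}/\code{end_index}).
#' @param truth data.frame with \code{start}, \code{end} (same convention),
#'   e.g. \code{trace$truth_events}.
#' @param min_overlap reciprocal overlap fraction required (default 0.5).
#' @return list with \code{precision}, \code{recall}, \code{n_matched} and
#'   \code{undefined} (TRUE when there were no detections, in which case
#'   precision is reported as 0 with the flag set).
#' @export
match_to_truth <- function(events, truth, min_overlap = 0.5) {
  nd <- nrow(events); nt <- nrow(truth)
  if (nd == 0L) {
    return(list(precision = 0, recall = if (nt == 0L) 1 else 0,
                n_matched = 0L, undefined = TRUE))
  }
  if (nt == 0L)
    return(list(precision = 0, recall = 1, n_matched = 0L, undefined = FALSE))
  pairs <- NULL
  for (i in seq_len(nd)) {
    ov_lo <- pmax(events$start_index[i], truth$start)
    ov_hi <- pmin(events$end_index[i], truth$end)
    ov <- pmax(0, ov_hi - ov_lo)
    len_d <- events$end_index[i] - events$start_index[i]
    len_t <- truth$end - truth$start
    good <- which(ov >= min_overlap * len_d & ov >= min_overlap * len_t)
    if (length(good))
      pairs <- rbind(pairs, cbind(i, good, ov[good]))
  }
  n_matched <- 0L
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, 3]), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    for (j in seq_len(nrow(pairs))) {
      d <- pairs[j, 1]; t <- pairs[j, 2]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE; used_t[t] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(precision = n_matched / nd, recall = n_matched / nt,
       n_matched = as.integer(n_matched), undefined = FALSE)
}
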