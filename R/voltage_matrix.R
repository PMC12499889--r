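#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes AUC as the Mann-Whitney rank statistic
#' \eqn{P(s_{pos} > s_{neg}) + \tfrac12 P(s_{pos} = s_{neg})}, which equals
#' the trapezoidal area under the ROC curve. Ties receive half credit via
#' midranks.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels class labels (factor, character or logical).
#' @param positive label of the positive class; defaults to \code{TRUE} for
#'   logical labels, otherwise the first factor level.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.logical(labels)) {
    pos <- labels
  } else {
    labels <- factor(labels)
    if (is.null(positive)) positive <- levels(labels)[1]
    if (!positive %in% levels(labels)) stop("positive label not present")
    pos <- labels == positive
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

ft_subset <- function(ft, idx) {
  out <- ft
  out$x <- ft$x[idx, , drop = FALSE]
  if (!is.null(ft$labels)) out$labels <- droplevels(ft$labels[idx])
  out$voltage <- ft$voltage[idx]
  out$run_id <- ft$run_id[idx]
  out
}

#' Stratified train/evaluation split
#'
#' Seeded stratified split of a labeled feature table; both classes are
#' guaranteed present in both parts.
#'
#' @param table labeled \code{feature_table}.
#' @param train_frac fraction assigned to training (default 0.7).
#' @param seed integer seed.
#' @return list with \code{train} and \code{eval} feature tables plus the
#'   index vectors \code{train_idx} / \code{eval_idx}.
#' @export
split_dataset <- function(table, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$labels))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  lv <- levels(table$labels)
  n <- nrow(table$x)
  train_idx <- with_seed(seed, {
    unlist(lapply(lv, function(l) {
      i <- which(table$labels == l)
      if (length(i) < 2L)
        stop(sprintf("class '%s' has fewer than 2 events; cannot split", l))
      k <- max(1L, min(length(i) - 1L, round(train_frac * length(i))))
      sample(i, k)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  eval_idx <- setdiff(seq_len(n), train_idx)
  list(train = ft_subset(table, train_idx), eval = ft_subset(table, eval_idx),
       train_idx = train_idx, eval_idx = eval_idx)
}

#' Train a binary event classifier
#'
#' Fits a Random Forest (500 trees, sqrt(p) features per split) or an
#' RBF-kernel SVM with Platt-style probability calibration on a labeled
#' feature table. SVM features are standardized with statistics learned from
#' the training table; Random Forest uses raw features. Training is
#' deterministic given the seed.
#'
#' @param table labeled \code{feature_table} (training rows only).
#' @param algo \code{"random_forest"} or \code{"svm"}.
#' @param positive label treated as the positive class (scores are its
#'   predicted probability); defaults to the first factor level.
#' @param seed integer seed.
#' @param min_per_class minimum training events per class (default 20).
#' @param ntree Random Forest tree count.
#' @return object of class \code{vm_classifier}; score new tables with
#'   \code{\link{score_events}}.
#' @export
train_classifier <- function(table, algo = c("random_forest", "svm"),
                             positive = NULL, seed = 1L,
                             min_per_class = 20L, ntree = 500L) {
  algo <- match.arg(algo)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("training table must be labeled")
  tab <- table(table$labels)
  if (length(tab) < 2L)
    stop("training data contain a single class")
  if (any(tab < min_per_class))
    stop(sprintf("fewer than %d training events in class(es): %s",
                 min_per_class,
                 paste(names(tab)[tab < min_per_class], collapse = ", ")))
  if (is.null(positive)) positive <- levels(table$labels)[1]
  if (!positive %in% levels(table$labels)) stop("positive label not present")
  st <- NULL
  xtr <- table
  if (algo == "svm") {
    xtr <- standardize_features(table)
    st <- xtr$standardization
  }
  model <- with_seed(seed, {
    if (algo == "random_forest") {
      randomForest::randomForest(x = xtr$x, y = xtr$labels, ntree = ntree)
    } else {
      e1071::svm(x = as.matrix(xtr$x), y = xtr$labels, kernel = "radial",
                 probability = TRUE, scale = FALSE)
    }
  })
  structure(list(model = model, algo = algo, positive = positive,
                 features = names(table$x), featureset = table$featureset,
                 standardization = st, seed = as.integer(seed)),
            class = "vm_classifier")
}

#' Score events with a trained classifier
#'
#' @param object a \code{\link{train_classifier}} model.
#' @param table feature table with the same schema as the training table.
#' @return numeric vector of positive-class probabilities in [0, 1].
#' @export
score_events <- function(object, table) {
  stopifnot(inherits(object, "vm_classifier"), inherits(table, "feature_table"))
  if (!identical(names(table$x), object$features))
    stop("feature schema mismatch between model and table")
  if (object$algo == "random_forest") {
    p <- stats::predict(object$model, newdata = table$x, type = "prob")
    unname(p[, object$positive])
  } else {
    tb <- table
    tb$standardization <- NULL
    ref <- tb; ref$standardization <- object$standardization
    xs <- standardize_features(tb, ref)
    pr <- stats::predict(object$model, newdata = as.matrix(xs$x),
                         probability = TRUE)
    p <- attr(pr, "probabilities")
    unname(p[, object$positive])
  }
}

#' @export
print.vm_classifier <- function(x, ...) {
  cat(sprintf("<vm_classifier> %s on feature set %s (%d features), positive class '%s'\n",
              x$algo, x$featureset, length(x$features), x$positive))
  invisible(x)
}

#' Build the train-voltage by test-voltage AUC matrix
#'
#' For each voltage, a classifier is trained on the training split of that
#' voltage's labeled events; it is then evaluated on the held-out evaluation
#' split of every voltage (including its own, the diagonal). The result is a
#' square AUC grid over the ordered voltage list — the voltage matrix.
#'
#' @param events event data.frame with an \code{analyte} label column and a
#'   \code{voltage} column (e.g. two \code{\link{simulate_events}} results
#'   row-bound).
#' @param spec a \code{\link{feature_set_spec}}.
#' @param algo \code{"random_forest"} or \code{"svm"}.
#' @param voltages ordered voltage list; default the order of appearance.
#' @param positive positive-class label; default first analyte encountered.
#' @param train_frac training fraction per voltage (stratified).
#' @param seed integer seed (splits and model fits are derived from it).
#' @param min_per_class classifier floor passed to
#'   \code{\link{train_classifier}}.
#' @return object of class \code{voltage_matrix_result}: \code{auc} and
#'   \code{n_events} matrices (rows = train voltage, columns = test
#'   voltage), \code{models} (one per train voltage), \code{eval_tables},
#'   \code{algo}, \code{feature_set}, \code{positive}, \code{seed}.
#' @export
build_voltage_matrix <- function(events, spec, algo = c("random_forest", "svm"),
                                 voltages = NULL, positive = NULL,
                                 train_frac = 0.7, seed = 1L,
                                 min_per_class = 20L) {
  algo <- match.arg(algo)
  stopifnot(inherits(spec, "feature_set_spec"))
  if (!"analyte" %in% names(events)) stop("events must carry an 'analyte' column")
  if (is.null(voltages)) voltages <- unique(events$voltage)
  if (is.null(positive)) positive <- events$analyte[1]
  nv <- length(voltages)
  splits <- vector("list", nv); models <- vector("list", nv)
  names(splits) <- names(models) <- as.character(voltages)
  for (i in seq_len(nv)) {
    ev <- events[events$voltage == voltages[i], , drop = FALSE]
    if (nrow(ev) == 0L)
      stop(sprintf("no events at voltage %g mV", voltages[i]))
    ft <- build_feature_table(ev, spec, labels = ev$analyte)
    # per-voltage seeds derive from the voltage value, so cells do not depend
    # on the ordering of the voltage list
    splits[[i]] <- split_dataset(ft, train_frac,
                                 seed = derive_seed(seed, voltages[i], "split", "vm"))
    models[[i]] <- train_classifier(splits[[i]]$train, algo = algo,
                                    positive = positive,
                                    seed = derive_seed(seed, voltages[i], "fit", "vm"),
                                    min_per_class = min_per_class)
  }
  aucm <- matrix(NA_real_, nv, nv,
                 dimnames = list(train = voltages, test = voltages))
  nm <- matrix(NA_integer_, nv, nv,
               dimnames = list(train = voltages, test = voltages))
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      evtab <- splits[[j]]$eval
      sc <- score_events(models[[i]], evtab)
      aucm[i, j] <- auc(sc, evtab$labels, positive = positive)
      nm[i, j] <- nrow(evtab$x)
    }
  }
  structure(list(auc = aucm, n_events = nm, models = models,
                 eval_tables = lapply(splits, `[[`, "eval"),
                 train_voltages = voltages, test_voltages = voltages,
                 algo = algo, feature_set = spec$name,
                 positive = positive, seed = as.integer(seed)),
            class = "voltage_matrix_result")
}

#' @export
print.voltage_matrix_result <- function(x, digits = 3, ...) {
  cat(sprintf("<voltage_matrix_result> %s, feature set %s, positive '%s'\n",
              x$algo, x$feature_set, x$positive))
  print(round(x$auc, digits))
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic importance: the mean AUC drop on the evaluation table when
#' one feature column is permuted, averaged over \code{repeats} independent
#' permutations. Negative drops are clipped at 0 for reporting; raw means
#' are retained.
#'
#' @param model a \code{\link{train_classifier}} model.
#' @param table labeled evaluation \code{feature_table}.
#' @param repeats permutations per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame of class \code{importance_profile} with columns
#'   \code{feature}, \code{importance} (clipped), \code{raw_drop},
#'   ordered as the feature set.
#' @export
permutation_importance <- function(model, table, repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "vm_classifier"), inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("evaluation table must be labeled")
  if (repeats < 1L) stop("repeats must be >= 1")
  base <- auc(score_events(model, table), table$labels, positive = model$positive)
  feats <- names(table$x)
  drops <- with_seed(seed, {
    vapply(feats, function(f) {
      mean(vapply(seq_len(repeats), function(r) {
        tb <- table
        tb$x[[f]] <- sample(tb$x[[f]])
        base - auc(score_events(model, tb), tb$labels, positive = model$positive)
      }, numeric(1)))
    }, numeric(1))
  })
  out <- data.frame(feature = feats, importance = pmax(drops, 0),
                    raw_drop = drops, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "repeats") <- as.integer(repeats)
  attr(out, "algo") <- model$algo
  attr(out, "base_auc") <- base
  class(out) <- c("importance_profile", "data.frame")
  out
}
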