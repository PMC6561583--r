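#' Stratified train/test split with cross-validation folds
#'
#' Trials are split 70/30 stratified on the supplied class labels, and the
#' training portion is further assigned to five stratified
#' cross-validation folds. The same seed always yields the same split.
#'
#' @param n_trials total number of trials.
#' @param labels integer class labels (1..5), length `n_trials`; the
#'   stratification variable (conventionally the PC1 quintile).
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.7).
#' @param n_folds number of CV folds (default 5).
#' @return List of class `split_record`: `train`, `test` (trial indices),
#'   `folds` (fold id per training trial), `seed`.
#' @export
split_trials <- function(n_trials, labels, seed, train_frac = 0.7,
                         n_folds = 5) {
  if (length(labels) != n_trials) stop("labels length must equal n_trials")
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("every class needs at least ", n_folds, " trials; smallest has ",
         min(counts))
  set.seed(seed)
  train <- integer(0); test <- integer(0)
  folds <- integer(0)
  for (g in sort(unique(labels))) {
    idx <- sample(which(labels == g))
    n_tr <- round(train_frac * length(idx))
    tr <- idx[seq_len(n_tr)]
    train <- c(train, tr)
    test <- c(test, idx[-seq_len(n_tr)])
    folds <- c(folds, rep_len(seq_len(n_folds), n_tr))
  }
  o <- order(train)
  structure(list(train = train[o], test = sort(test), folds = folds[o],
                 seed = seed, n_folds = n_folds),
            class = "split_record")
}

#' Fit the per-component state classifiers
#'
#' One multiclass support-vector classifier per retained evoked component
#' maps the pre-stimulus features (power ratio in `[0, 1]`, activation in
#' mV, used raw) to the component's quintile label. The multiclass scheme
#' is one-vs-one over radial-basis-kernel SVMs with kernel scale 3
#' (`gamma = 1/9`) and box constraint 1. Class posteriors (Platt scaling)
#' are decoded by picking the class whose quintile-average weight is
#' nearest the posterior-mean weight: because predictions are consumed as
#' reconstruction weights, this minimizes the expected weight error and
#' degrades gracefully to the middle quintile when the features carry no
#' information (instead of an arbitrary vote winner at an extreme
#' quintile). Cross-validation predictions on the training folds are
#' recorded for feature selection; the test split is never touched during
#' fitting.
#'
#' @param features data.frame or matrix of per-trial features (a `trial`
#'   column, if present, is dropped).
#' @param scheme a `quintile_scheme` providing the per-component labels.
#' @param basis the `evoked_basis` the scheme was built from.
#' @param split a `split_record`.
#' @param kernel_scale RBF kernel scale (feature units); `gamma` is its
#'   inverse square.
#' @param cost SVM box constraint.
#' @param Y optional full evoked matrix (trials x samples); when given, the
#'   fVE of the cross-validation predictions on the training split is
#'   computed and stored as `cv_fve`.
#' @return List of class `state_classifier`: fitted `svms` (one per
#'   component), `cv_pred` (CV labels for training trials), `cv_fve`
#'   (fVE of the CV predictions on the training split, the model-selection
#'   score), plus the feature names, basis, scheme and split.
#' @export
fit_state_classifier <- function(features, scheme, basis, split,
                                 kernel_scale = 3, cost = 1, Y = NULL) {
  x <- .feature_matrix(features)
  bad <- which(!stats::complete.cases(x) | !apply(is.finite(x), 1, all))
  if (length(bad))
    stop("non-finite features for trial(s): ", paste(bad, collapse = ", "))
  labels <- scheme$labels
  if (nrow(x) != nrow(labels)) stop("feature/label row mismatch")
  nc <- ncol(labels)
  gamma <- 1 / kernel_scale^2
  tr <- split$train
  svms <- vector("list", nc)
  cv_pred <- matrix(NA_integer_, length(tr), nc)
  for (k in seq_len(nc)) {
    yk <- factor(labels[, k], levels = 1:5)
    gm <- scheme$group_means[, k]
    set.seed(split$seed + 1000L * k)
    svms[[k]] <- e1071::svm(x[tr, , drop = FALSE], yk[tr],
                            kernel = "radial", gamma = gamma, cost = cost,
                            scale = FALSE, probability = TRUE)
    for (f in seq_len(split$n_folds)) {
      hold <- split$folds == f
      set.seed(split$seed + 1000L * k + f)
      fit_f <- e1071::svm(x[tr[!hold], , drop = FALSE], yk[tr[!hold]],
                          kernel = "radial", gamma = gamma, cost = cost,
                          scale = FALSE, probability = TRUE)
      cv_pred[hold, k] <-
        .decode_posterior(fit_f, x[tr[hold], , drop = FALSE], gm)
    }
  }
  cv_fve <- NA_real_
  if (!is.null(Y)) {
    if (inherits(Y, "evoked_matrix")) Y <- Y$Y
    yhat_cv <- reconstruct_evoked(basis, labels = cv_pred, scheme = scheme)
    cv_fve <- compute_fve(Y[tr, , drop = FALSE], yhat_cv)
  }
  structure(list(svms = svms, feature_names = colnames(x),
                 kernel_scale = kernel_scale, cost = cost,
                 cv_pred = cv_pred, cv_fve = cv_fve,
                 basis = basis, scheme = scheme, split = split),
            class = "state_classifier")
}

.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), "trial"), drop = FALSE]
    features <- as.matrix(features)
  }
  features
}

# Posterior-mean decoding of a one-vs-one SVM: predict the class whose
# quintile-average weight is nearest the probability-weighted mean weight.
.decode_posterior <- function(fit, x, group_means) {
  p <- attr(predict(fit, x, probability = TRUE), "probabilities")
  p <- p[, as.character(1:5), drop = FALSE]
  wbar <- as.numeric(p %*% group_means)
  vapply(wbar, function(w) which.min(abs(group_means - w)), integer(1))
}

#' Predict quintile labels and evoked responses
#'
#' @param object a `state_classifier`.
#' @param features per-trial features with the same columns used in
#'   fitting.
#' @param ... unused.
#' @return List with `labels` (trials x components) and `yhat`
#'   (reconstructed responses).
#' @export
predict.state_classifier <- function(object, features, ...) {
  x <- .feature_matrix(features)
  if (!is.null(object$feature_names) &&
      !identical(colnames(x), object$feature_names))
    stop("feature configuration mismatch: expected columns ",
         paste(object$feature_names, collapse = ", "))
  nc <- length(object$svms)
  labels <- matrix(NA_integer_, nrow(x), nc)
  for (k in seq_len(nc))
    labels[, k] <- .decode_posterior(object$svms[[k]], x,
                                     object$scheme$group_means[, k])
  list(labels = labels,
       yhat = reconstruct_evoked(object$basis, labels = labels,
                                 scheme = object$scheme))
}

#' Evaluate a fitted classifier on held-out trials
#'
#' Computes the summed fVE of the per-component reconstructions on the test
#' split, with its jackknife standard error.
#'
#' @param model a `state_classifier`.
#' @param features full per-trial feature table (all trials).
#' @param Y full evoked matrix (trials x samples).
#' @return List of class `fve_report`: `fve`, `se`, `n_test`, `pred_labels`.
#' @export
evaluate_classifier <- function(model, features, Y) {
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  te <- model$split$test
  x <- .feature_matrix(features)
  pred <- predict(model, x[te, , drop = FALSE])
  fve <- compute_fve(Y[te, , drop = FALSE], pred$yhat)
  se <- jackknife_se(Y[te, , drop = FALSE], pred$yhat,
                     model$scheme$labels[te, 1])
  structure(list(fve = fve, se = se, n_test = length(te),
                 pred_labels = pred$labels),
            class = "fve_report")
}

#' Jackknife standard error of an fVE estimate
#'
#' The test set is stratified across the five response quintiles, so each
#' resample drops five trials, one from each quintile, and fVE is
#' recomputed on the remainder; this repeats until every trial has been
#' dropped once. The sample standard deviation of the resampled fVE values
#' is the reported uncertainty.
#'
#' @param Y_test held-out responses (trials x samples).
#' @param Yhat_test matching predictions.
#' @param strat_labels quintile label (1..5) of each held-out trial; class
#'   counts may differ by at most one.
#' @return Standard error (scalar). The resampled fVE values are attached
#'   as attribute `"resamples"`.
#' @export
jackknife_se <- function(Y_test, Yhat_test, strat_labels) {
  counts <- table(factor(strat_labels, levels = sort(unique(strat_labels))))
  if (max(counts) - min(counts) > 1)
    stop("jackknife_se requires a stratified test set ",
         "(class counts differ by more than 1)")
  groups <- split(seq_along(strat_labels), strat_labels)
  n_rs <- max(lengths(groups))
  fves <- vapply(seq_len(n_rs), function(j) {
    drop <- unlist(lapply(groups, function(g) if (j <= length(g)) g[j]),
                   use.names = FALSE)
    keep <- setdiff(seq_along(strat_labels), drop)
    compute_fve(Y_test[keep, , drop = FALSE],
                Yhat_test[keep, , drop = FALSE])
  }, numeric(1))
  se <- stats::sd(fves)
  attr(se, "resamples") <- fves
  se
}

#' Trial-shuffle null distribution of fVE
#'
#' The quintile labels are randomly permuted across the recording's trials
#' and treated as the true assignment: the class-conditional mean weights
#' are recomputed under the permuted labeling, the classifier's predicted
#' classes on the held-out trials are mapped through that null table, and
#' fVE is computed against the real held-out responses. Because the null
#' table's entries are means of randomly chosen weights, the
#' reconstruction carries no information and the resulting fVE scatters
#' tightly around zero.
#'
#' @param model a fitted `state_classifier` (fit on unshuffled data).
#' @param features full per-trial feature table.
#' @param Y full evoked matrix (trials x samples).
#' @param basis the `evoked_basis` (weights used for the null tables).
#' @param n_shuffles number of permutations.
#' @param seed integer seed.
#' @return List with `fve` (per-shuffle values), `mean`, `sd`.
#' @export
shuffle_null <- function(model, features, Y, basis, n_shuffles = 50,
                         seed = 1) {
  if (inherits(Y, "evoked_matrix")) Y <- Y$Y
  te <- model$split$test
  x <- .feature_matrix(features)
  pred <- predict(model, x[te, , drop = FALSE])$labels
  w <- basis$weights
  lab <- model$scheme$labels
  Y_te <- Y[te, , drop = FALSE]
  nc <- ncol(lab)
  n <- nrow(lab)
  set.seed(seed)
  fves <- vapply(seq_len(n_shuffles), function(s) {
    perm <- sample(n)
    what <- matrix(0, length(te), nc)
    for (k in seq_len(nc)) {
      lab_sh <- lab[perm, k]
      null_means <- vapply(1:5, function(q) mean(w[lab_sh == q, k]),
                           numeric(1))
      what[, k] <- null_means[pred[, k]]
    }
    yhat <- reconstruct_evoked(basis, weights = what)
    compute_fve(Y_te, yhat)
  }, numeric(1))
  list(fve = fves, mean = mean(fves), sd = stats::sd(fves))
}
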