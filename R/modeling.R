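# Cost-sensitive training of the five base learners, optional bagging, and
# stratified k-fold cross-validation.
#
# Cost handling is by instance reweighting: substrate instances receive the
# false-negative cost, non-substrates the false-positive cost, and weights
# are rescaled to sum to n.  Learners with native case-weight support
# (decision tree, random forest) consume the weights directly; the others
# (naive Bayes, k-NN, linear SVM) are trained on a seeded weighted resample
# of size n.  Bagging draws B bootstrap replicates of the weighted training
# distribution and aggregates by majority vote, with ties going to the
# substrate (minority) class.

#' The available base learners
#' @export
QP_LEARNERS <- c("naive_bayes", "knn", "decision_tree", "random_forest",
                 "linear_svm")

#' Misclassification cost specification
#'
#' @param fn_cost cost of predicting non-substrate for a true substrate.
#' @param fp_cost cost of predicting substrate for a true non-substrate.
#' @return Object of class `cost_spec`.
#' @export
cost_spec <- function(fn_cost = 1, fp_cost = 1) {
  if (fn_cost <= 0 || fp_cost <= 0) stop("costs must be positive")
  structure(list(fn_cost = fn_cost, fp_cost = fp_cost), class = "cost_spec")
}

.cost_weights <- function(y, cost) {
  w <- ifelse(y == "substrate", cost$fn_cost, cost$fp_cost)
  w * length(w) / sum(w)
}

.as_labels <- function(y) factor(as.character(y),
                                 levels = c("substrate", "non-substrate"))

#' Train a (cost-sensitive, optionally bagged) classifier
#'
#' @param X numeric descriptor matrix (training rows).
#' @param y labels (`"substrate"` / `"non-substrate"`), aligned with `X`.
#' @param features descriptor names to train on (subset of `colnames(X)`).
#' @param learner one of `r paste0('"', QP_LEARNERS, '"', collapse = ", ")`.
#' @param cost a [cost_spec()].
#' @param bagging `NULL` for a single learner, or the number of bootstrap
#'   replicates B.
#' @param seed integer seed controlling resampling, bootstrap draws and any
#'   stochastic learner internals.
#' @param hyper named list overriding learner hyperparameters
#'   (`knn_k`, `rf_num_trees`, `svm_cost`, `tree_cp`, `tree_minbucket`).
#' @return Object of class `qsar_model`.
#' @export
train_model <- function(X, y, features = colnames(X),
                        learner = QP_LEARNERS,
                        cost = cost_spec(), bagging = NULL, seed = 1L,
                        hyper = list()) {
  learner <- match.arg(learner)
  y <- .as_labels(y)
  if (anyNA(y)) stop("labels must be 'substrate' or 'non-substrate'")
  if (nlevels(droplevels(y)) < 2)
    stop("training data contain a single class")
  missing_f <- setdiff(features, colnames(X))
  if (length(missing_f))
    stop("feature(s) not in X: ", paste(missing_f, collapse = ", "))
  X <- X[, features, drop = FALSE]
  w <- .cost_weights(y, cost)
  hp <- utils::modifyList(list(knn_k = 1L, rf_num_trees = 100L, svm_cost = 1,
                               tree_cp = 0.01, tree_minbucket = 2L), hyper)
  fits <- if (is.null(bagging)) {
    list(.fit_base(X, y, w, learner, seed, hp))
  } else {
    if (bagging < 1) stop("bagging must request at least one replicate")
    lapply(seq_len(bagging), function(b) {
      idx <- .seeded_sample_int(nrow(X), nrow(X), prob = w,
                                seed = seed * 1000L + b)
      .fit_base(X[idx, , drop = FALSE], y[idx], rep(1, length(idx)),
                learner, seed + b, hp)
    })
  }
  structure(list(learner = learner, features = features, cost = cost,
                 bagging = bagging, seed = seed, hyper = hp, fits = fits),
            class = "qsar_model")
}

.seeded_sample_int <- function(n, k, prob = NULL, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
           get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n, k, replace = TRUE, prob = prob)
}

.fit_base <- function(X, y, w, learner, seed, hp) {
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  # an extreme cost can resample away one class entirely; the limiting
  # classifier is then the constant one
  if (learner %in% c("naive_bayes", "linear_svm", "knn")) {
    idx_chk <- .resample_if_weighted(w, seed)
    if (nlevels(droplevels(y[idx_chk])) < 2)
      return(list(kind = "constant",
                  label = as.character(y[idx_chk][1])))
  }
  switch(learner,
    decision_tree = {
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                   control = rpart::rpart.control(cp = hp$tree_cp,
                                                  minbucket = hp$tree_minbucket))
    },
    random_forest = ranger::ranger(
      x = df, y = y, num.trees = hp$rf_num_trees,
      mtry = max(1L, floor(sqrt(ncol(df)))),
      case.weights = w, seed = seed),
    naive_bayes = {
      idx <- .resample_if_weighted(w, seed)
      e1071::naiveBayes(df[idx, , drop = FALSE], y[idx])
    },
    linear_svm = {
      idx <- .resample_if_weighted(w, seed)
      e1071::svm(df[idx, , drop = FALSE], y[idx], kernel = "linear",
                 cost = hp$svm_cost, scale = FALSE)
    },
    knn = {
      idx <- .resample_if_weighted(w, seed)
      list(kind = "knn", train = as.matrix(df[idx, , drop = FALSE]),
           cl = y[idx], k = hp$knn_k)
    })
}

# identity when all weights are equal; otherwise a seeded weighted bootstrap
.resample_if_weighted <- function(w, seed) {
  if (max(w) - min(w) < 1e-12) return(seq_along(w))
  .seeded_sample_int(length(w), length(w), prob = w, seed = seed)
}

.predict_base <- function(fit, learner, X) {
  if (is.list(fit) && identical(fit$kind, "constant"))
    return(.as_labels(rep(fit$label, nrow(X))))
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  out <- switch(learner,
    decision_tree = stats::predict(fit, df, type = "class"),
    random_forest = stats::predict(fit, data = df)$predictions,
    naive_bayes = stats::predict(fit, df),
    linear_svm = stats::predict(fit, df),
    knn = class::knn(fit$train, as.matrix(df), fit$cl, k = fit$k))
  .as_labels(out)
}

#' Predict class labels
#'
#' @param object a `qsar_model`.
#' @param newdata descriptor matrix containing the model's feature columns.
#' @param ... unused.
#' @return Factor of predicted labels; bagged models vote by majority with
#'   ties going to the substrate class.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, colnames(newdata))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  X <- newdata[, object$features, drop = FALSE]
  if (!nrow(X))
    return(factor(character(0), levels = c("substrate", "non-substrate")))
  votes <- vapply(object$fits, function(f)
    as.character(.predict_base(f, object$learner, X)), character(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  pred <- apply(votes, 1, function(v) {
    ns <- sum(v == "substrate")
    if (ns * 2 >= length(v)) "substrate" else "non-substrate"
  })
  .as_labels(pred)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model: %s, cost %g:%g%s, %d feature(s)>\n", x$learner,
              x$cost$fn_cost, x$cost$fp_cost,
              if (!is.null(x$bagging)) sprintf(", bagging B=%d", x$bagging) else "",
              length(x$features)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# cross-validation
# ---------------------------------------------------------------------------

# stratified fold assignment: within each class, a seeded shuffle dealt one
# by one into the currently smallest fold, so class ratios are preserved
# within one member per fold and total fold sizes differ by at most one
stratified_folds <- function(y, k, seed = 1L) {
  y <- .as_labels(y)
  fold <- integer(length(y))
  totals <- integer(k)
  for (cl in levels(y)) {
    members <- which(y == cl)
    if (length(members) < k)
      stop("class '", cl, "' has fewer members (", length(members),
           ") than folds (", k, ")")
    perm <- members[.seeded_perm(length(members),
                                 seed + match(cl, levels(y)))]
    per_class <- integer(k)
    for (m in perm) {
      eligible <- which(per_class == min(per_class))
      f <- eligible[which.min(totals[eligible])]
      fold[m] <- f
      totals[f] <- totals[f] + 1L
      per_class[f] <- per_class[f] + 1L
    }
  }
  fold
}

.seeded_perm <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
           get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Stratified k-fold cross-validation with pooled confusion matrix
#'
#' Folds are stratified by class; per-fold confusion matrices are summed
#' before the statistics are computed (pooled cross-validation).
#'
#' @inheritParams train_model
#' @param k number of folds (the study used 5 and 10).
#' @param nested if `TRUE`, feature selection ([best_first_select()]) is
#'   re-run inside each training fold instead of using `features`
#'   (leakage-aware variant; the default protocol selects once on the full
#'   training set before cross-validation).
#' @return A `qsar_metrics` object for the pooled confusion matrix, with a
#'   `folds` attribute recording the fold assignment.
#' @export
cross_validate <- function(X, y, features = colnames(X),
                           learner = QP_LEARNERS, cost = cost_spec(),
                           bagging = NULL, k = 5L, seed = 1L,
                           hyper = list(), nested = FALSE) {
  learner <- match.arg(learner)
  y <- .as_labels(y)
  fold <- stratified_folds(y, k, seed)
  pooled <- new_confusion(0, 0, 0, 0)
  for (f in seq_len(k)) {
    tr <- fold != f
    fold_features <- if (nested) {
      sel <- best_first_select(X[tr, , drop = FALSE], y[tr])
      if (length(sel$features)) sel$features else colnames(X)
    } else features
    model <- train_model(X[tr, , drop = FALSE], y[tr], fold_features, learner,
                         cost, bagging, seed = seed + 100L * f, hyper = hyper)
    pred <- predict(model, X[!tr, , drop = FALSE])
    pooled <- pooled + confusion(y[!tr], pred)
  }
  out <- classification_metrics(pooled)
  attr(out, "folds") <- fold
  out
}

#' Grid search over misclassification costs
#'
#' Evaluates each candidate cost by cross-validation and returns the
#' candidate maximizing the selection metric (G-mean by default, the
#' standard scalar summary for imbalanced two-class problems).
#'
#' @inheritParams cross_validate
#' @param candidates list of [cost_spec()] objects.
#' @param metric name of the `qsar_metrics` field to maximize.
#' @return List with `best` (a `cost_spec`), `best_metrics` and `report`
#'   (one row per candidate).
#' @export
cost_grid_search <- function(X, y, features = colnames(X),
                             learner = QP_LEARNERS, candidates,
                             metric = "g_mean", k = 5L, seed = 1L,
                             bagging = NULL, hyper = list()) {
  learner <- match.arg(learner)
  if (!length(candidates)) stop("no cost candidates supplied")
  rows <- list()
  best <- NULL; best_val <- -Inf; best_metrics <- NULL
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    m <- cross_validate(X, y, features, learner, cand, bagging, k, seed,
                        hyper)
    val <- m[[metric]]
    rows[[i]] <- data.frame(fn_cost = cand$fn_cost, fp_cost = cand$fp_cost,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            g_mean = m$g_mean, mcc = m$mcc,
                            selected = FALSE)
    if (val > best_val) { best <- cand; best_val <- val; best_metrics <- m }
  }
  report <- do.call(rbind, rows)
  report$selected <- report$fn_cost == best$fn_cost &
                     report$fp_cost == best$fp_cost
  list(best = best, best_metrics = best_metrics, report = report)
}
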