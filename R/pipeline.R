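# The end-to-end workflow: curation -> labelling -> descriptors ->
# train/test split -> CFS feature selection -> cost-sensitive training ->
# imbalance-aware evaluation -> applicability-domain fit.

#' Run the full classification workflow
#'
#' @param records list of molecule records (with PCC values), or a path to
#'   an SD file when `activity` is also given.
#' @param activity optional path to an `id,pcc` CSV joined onto `records`.
#' @param charge_variant `"neutral"` or `"charged"` curation variant.
#' @param threshold PCC labelling threshold.
#' @param split `"random"`, `"maccs"` or `"descriptors"`.
#' @param fraction training fraction.
#' @param learner,cost,bagging,hyper passed to [train_model()].
#' @param cv_folds if non-`NULL`, additionally cross-validate the selected
#'   model on the training set with this many folds.
#' @param seed integer seed for the random split and learner internals.
#' @param panel descriptor panel.
#' @return List with the curation report, labeled dataset, z-scored
#'   descriptor matrix and parameters, split, selected features, fitted
#'   model, test metrics, optional cross-validation metrics, and the
#'   applicability-domain model fitted on the training compounds.
#' @export
run_pipeline <- function(records, activity = NULL,
                         charge_variant = c("neutral", "charged"),
                         threshold = -0.25,
                         split = c("random", "maccs", "descriptors"),
                         fraction = 0.8,
                         learner = "random_forest",
                         cost = cost_spec(150, 3.5),
                         bagging = NULL, hyper = list(),
                         cv_folds = NULL, seed = 1L,
                         panel = "core") {
  charge_variant <- match.arg(charge_variant)
  split <- match.arg(split)
  if (is.character(records)) records <- read_structures(records, "sdf")
  if (!is.null(activity)) records <- join_activity(records, activity)

  cur <- run_curation(records, curation_config(charge_variant = charge_variant))
  ds <- label_by_pcc(cur$dataset, threshold)
  X <- descriptor_matrix(ds, panel = panel)
  norm <- zscore(X)
  Z <- norm$X

  sp <- switch(split,
    random = split_random_stratified(ds, fraction, seed),
    maccs = split_diverse_maxmin(ds, fraction, "fingerprint"),
    descriptors = split_diverse_maxmin(ds, fraction, "descriptor", X = Z))
  tr <- match(sp$train_ids, rownames(Z))
  te <- match(sp$test_ids, rownames(Z))
  ytr <- ds$labels[tr]; yte <- ds$labels[te]

  sel <- best_first_select(Z[tr, , drop = FALSE], ytr)
  model <- train_model(Z[tr, , drop = FALSE], ytr, sel$features, learner,
                       cost, bagging, seed, hyper)
  test_metrics <- classification_metrics(
    confusion(yte, predict(model, Z[te, , drop = FALSE])))
  cv_metrics <- if (!is.null(cv_folds))
    cross_validate(Z[tr, , drop = FALSE], ytr, sel$features, learner, cost,
                   bagging, cv_folds, seed, hyper)
  ad <- if (length(sel$features) >= 2)
    fit_ad(Z[tr, sel$features, drop = FALSE], ncomp = 2L)

  list(curation_report = cur$report, dataset = ds, descriptors = X,
       normalization = norm[c("mean", "sd", "constant")], split = sp,
       features = sel$features, feature_merit = sel$merit, model = model,
       test_metrics = test_metrics, cv_metrics = cv_metrics, ad = ad)
}
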