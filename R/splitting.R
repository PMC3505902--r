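# PCC labelling and the three train/test selection strategies: MaxMin
# diversity in MACCS-key space, MaxMin diversity in descriptor space, and
# stratified random selection.

#' Label a dataset by its PCC threshold
#'
#' A compound is a substrate iff its PCC is lower than or equal to the
#' threshold (the boundary itself is a substrate); all others are
#' non-substrates.
#'
#' @param ds a [qsar_dataset()].
#' @param threshold PCC cutoff in `[-1, 0]` (the study used -0.25 and -0.30).
#' @return The dataset with `labels` and `label_threshold` set.
#' @export
label_by_pcc <- function(ds, threshold = -0.25) {
  if (!inherits(ds, "qsar_dataset")) ds <- qsar_dataset(ds)
  if (threshold < -1 || threshold > 0)
    stop("threshold must lie in [-1, 0]")
  pcc <- dataset_pcc(ds)
  if (anyNA(pcc))
    stop("records without a PCC value: ",
         paste(dataset_ids(ds)[is.na(pcc)], collapse = ", "))
  ds$labels <- factor(ifelse(pcc <= threshold, "substrate", "non-substrate"),
                      levels = c("substrate", "non-substrate"))
  ds$label_threshold <- threshold
  ds
}

.new_split <- function(strategy, train_ids, test_ids, fraction, seed = NA) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test sets overlap")
  structure(list(strategy = strategy, train_ids = train_ids,
                 test_ids = test_ids, fraction = fraction, seed = seed),
            class = "qsar_split")
}

#' @export
print.qsar_split <- function(x, ...) {
  cat(sprintf("<qsar_split [%s]: %d train / %d test (fraction %.2f)>\n",
              x$strategy, length(x$train_ids), length(x$test_ids), x$fraction))
  invisible(x)
}

#' Stratified random train/test split
#'
#' Selects `floor(fraction * class size)` training compounds uniformly at
#' random within each class; the remainder forms the test set.
#'
#' @param ds labeled [qsar_dataset()].
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed; the split is reproducible given the seed.
#' @return A `qsar_split`.
#' @export
split_random_stratified <- function(ds, fraction = 0.8, seed = 1L) {
  if (is.null(ds$labels)) stop("dataset must be labeled (see label_by_pcc)")
  ids <- dataset_ids(ds)
  train <- character(0)
  for (cl in levels(ds$labels)) {
    members <- ids[ds$labels == cl]
    if (!length(members)) stop("class '", cl, "' has no members")
    k <- floor(fraction * length(members))
    train <- c(train, .seeded_sample(members, k, seed + match(cl, levels(ds$labels))))
  }
  test <- setdiff(ids, train)
  if (!length(test)) stop("empty test set: lower the training fraction")
  if (!length(train)) stop("empty training set: raise the training fraction")
  .new_split("random_stratified", train, test, fraction, seed)
}

.seeded_sample <- function(x, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(x, k)
}

#' MaxMin diversity train/test split
#'
#' Greedy maximum-diversity selection: the training set starts from the
#' first member of the most distant pair and grows by repeatedly adding the
#' compound whose minimum distance to the current training set is largest
#' (ties broken by input order), until `ceiling(fraction * N)` compounds are
#' selected.  Distances are `1 - Tanimoto` over MACCS keys
#' (`space = "fingerprint"`) or one minus the continuous Tanimoto
#' coefficient over z-scored descriptors rescaled to `[0, 1]`
#' (`space = "descriptor"`; `measure = "euclidean"` is available as an
#' alternative).  The procedure is fully deterministic and ignores class
#' labels.
#'
#' @param ds a [qsar_dataset()].
#' @param fraction training fraction (default 0.8).
#' @param space `"fingerprint"` or `"descriptor"`.
#' @param X z-scored descriptor matrix (descriptor space only; rows must
#'   match the dataset ids).
#' @param fp logical fingerprint matrix (fingerprint space; computed from
#'   the records when omitted).
#' @param measure dissimilarity for descriptor space.
#' @return A `qsar_split`.
#' @export
split_diverse_maxmin <- function(ds, fraction = 0.8,
                                 space = c("fingerprint", "descriptor"),
                                 X = NULL, fp = NULL,
                                 measure = c("tanimoto", "euclidean")) {
  space <- match.arg(space)
  measure <- match.arg(measure)
  if (!inherits(ds, "qsar_dataset")) ds <- qsar_dataset(ds)
  ids <- dataset_ids(ds)
  n <- length(ids)
  if (n < 2) stop("need at least 2 compounds to split")
  if (space == "fingerprint") {
    if (is.null(fp)) fp <- maccs_keys(ds)
    D <- 1 - tanimoto_matrix(fp[ids, , drop = FALSE])
  } else {
    if (is.null(X)) stop("descriptor space requires a z-scored matrix X")
    X <- X[ids, , drop = FALSE]
    if (measure == "tanimoto") {
      R <- apply(X, 2, function(col) {
        rng <- range(col)
        if (diff(rng) < 1e-12) rep(0, length(col))
        else (col - rng[1]) / diff(rng)
      })
      D <- 1 - continuous_tanimoto_matrix(R)
    } else {
      D <- as.matrix(stats::dist(X))
    }
  }
  k <- ceiling(fraction * n)
  if (k >= n) stop("training fraction leaves an empty test set")
  if (k < 1) stop("training fraction selects no compounds")
  sel <- maxmin_pick(D, k)
  .new_split(if (space == "fingerprint") "maccs_diverse" else "descriptor_diverse",
             ids[sel], ids[-sel], fraction)
}

# greedy MaxMin over a full distance matrix; returns selected indices
maxmin_pick <- function(D, k) {
  n <- nrow(D)
  # seed: first member (input order) of the most distant pair
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- unname(best[1, 1])
  mind <- unname(D[sel, ])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    pick <- which.max(mind)            # ties: first index
    sel <- c(sel, pick)
    mind <- pmin(mind, unname(D[pick, ]))
  }
  as.integer(sort(sel))
}
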