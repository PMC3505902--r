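# PCA applicability domain: external compounds are projected onto the
# principal components of the training compounds (in the space of the
# model's selected, z-scored descriptors) and called in-domain when their
# scores fall inside the training score ranges on every retained component.
# A leverage criterion (h > h* = 3 p / n) is available as an alternative.

#' Fit a PCA applicability-domain model
#'
#' @param X_train z-scored training descriptor matrix restricted to the
#'   model's features.
#' @param ncomp number of principal components to retain (>= 2; the study
#'   inspected a two-component score plot).
#' @return Object of class `ad_model`: feature names, centering vector,
#'   orthonormal loadings, per-component score ranges and explained
#'   variances, plus leverage bookkeeping.
#' @export
fit_ad <- function(X_train, ncomp = 2L) {
  if (ncomp < 2) stop("retain at least 2 components")
  if (nrow(X_train) < 3) stop("need at least 3 training compounds")
  if (nrow(X_train) < ncomp)
    stop("fewer compounds than requested components")
  pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  ncomp <- min(ncomp, ncol(pc$rotation))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  XtXinv <- tryCatch(solve(crossprod(scale(X_train, center = pc$center,
                                           scale = FALSE))),
                     error = function(e) NULL)
  structure(list(features = colnames(X_train), center = pc$center,
                 loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 sdev = pc$sdev[seq_len(ncomp)], ncomp = ncomp,
                 score_range = apply(scores, 2, range),
                 n_train = nrow(X_train), XtXinv = XtXinv),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model: %d components over %d features (%d training compounds)>\n",
              x$ncomp, length(x$features), x$n_train))
  invisible(x)
}

#' Check external compounds against an applicability domain
#'
#' @param ad an [fit_ad()] model.
#' @param X_query descriptor matrix of query compounds, transformed with the
#'   TRAINING normalization parameters (see [zscore_apply()]).
#' @param margin fractional widening of each training score range (0 keeps
#'   the exact ranges; 1 doubles each range about its midpoint).
#' @param criterion `"bbox"` (score bounding box, default) or `"leverage"`
#'   (h > 3 p / n flags out-of-domain).
#' @return Data frame with `id`, `in_domain`, and the component scores.
#' @export
check_domain <- function(ad, X_query, margin = 0,
                         criterion = c("bbox", "leverage")) {
  criterion <- match.arg(criterion)
  missing_f <- setdiff(ad$features, colnames(X_query))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  Xq <- X_query[, ad$features, drop = FALSE]
  Xc <- scale(Xq, center = ad$center, scale = FALSE)
  scores <- Xc %*% ad$loadings
  if (criterion == "bbox") {
    lo <- ad$score_range[1, ]; hi <- ad$score_range[2, ]
    half <- (hi - lo) / 2 * margin
    ok <- rep(TRUE, nrow(scores))
    for (j in seq_len(ad$ncomp)) {
      ok <- ok & scores[, j] >= lo[j] - half[j] &
                 scores[, j] <= hi[j] + half[j]
    }
  } else {
    if (is.null(ad$XtXinv))
      stop("leverage criterion unavailable: singular training covariance")
    h <- rowSums((Xc %*% ad$XtXinv) * Xc)
    ok <- h <= 3 * length(ad$features) / ad$n_train
  }
  out <- data.frame(id = if (!is.null(rownames(Xq))) rownames(Xq)
                         else as.character(seq_len(nrow(Xq))),
                    in_domain = ok)
  cbind(out, as.data.frame(scores))
}
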