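# Correlation-based feature-subset selection (CFS) with forward best-first
# search.  The merit of a subset S of k features is
#
#     merit(S) = k * rcf / sqrt(k + k (k - 1) * rff)
#
# where rcf is the mean absolute feature-class correlation over S and rff
# the mean absolute pairwise feature-feature correlation.  Correlations are
# Pearson (point-biserial against the binary class) on the continuous
# z-scored descriptors; a symmetric-uncertainty mode over equal-frequency
# 10-bin discretizations is available for comparison with discretizing
# implementations.

.cfs_correlations <- function(X, y, measure = c("pearson", "symunc")) {
  measure <- match.arg(measure)
  y01 <- as.numeric(y == levels(factor(y))[1])
  if (measure == "pearson") {
    rcf <- abs(suppressWarnings(stats::cor(X, y01)))[, 1]
    rff <- abs(suppressWarnings(stats::cor(X)))
  } else {
    disc <- apply(X, 2, .equal_freq_bins)
    yb <- as.integer(factor(y))
    p <- ncol(X)
    rcf <- vapply(seq_len(p), function(j) .sym_uncertainty(disc[, j], yb),
                  numeric(1))
    rff <- matrix(1, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      rff[i, j] <- rff[j, i] <- .sym_uncertainty(disc[, i], disc[, j])
    }
    names(rcf) <- colnames(X)
  }
  rcf[is.na(rcf)] <- 0          # zero-variance features carry no information
  rff[is.na(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

.equal_freq_bins <- function(v, bins = 10L) {
  qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qs) < 2) return(rep(1L, length(v)))
  as.integer(cut(v, qs, include.lowest = TRUE))
}

.sym_uncertainty <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

.merit_from_cache <- function(idx, cache) {
  k <- length(idx)
  if (k == 0) return(0)
  rcf_bar <- mean(cache$rcf[idx])
  if (k == 1) return(rcf_bar)
  rff_bar <- mean(cache$rff[idx, idx][upper.tri(diag(k))])
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

#' CFS merit of a feature subset
#'
#' @param features character vector of descriptor names (or integer column
#'   indices into `X`).
#' @param X z-scored descriptor matrix (training set).
#' @param y binary class labels aligned with the rows of `X`.
#' @param measure correlation measure, `"pearson"` (default) or `"symunc"`.
#' @return The merit score (dimensionless, 0 for the empty set).
#' @export
cfs_merit <- function(features, X, y, measure = "pearson") {
  idx <- if (is.character(features)) match(features, colnames(X)) else features
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(features[is.na(idx)], collapse = ", "))
  cache <- .cfs_correlations(X, y, measure)
  .merit_from_cache(idx, cache)
}

#' Best-first CFS feature selection
#'
#' Forward best-first search from the empty set: the open subset with the
#' highest merit is expanded by adding each unused feature; search stops
#' after `stale_limit` consecutive expansions that fail to improve on the
#' best subset found.  Fully deterministic; ties are broken by column order.
#'
#' @param X z-scored descriptor matrix (training set).
#' @param y binary labels aligned with rows of `X`.
#' @param stale_limit consecutive non-improving expansions tolerated.
#' @param measure correlation measure, see [cfs_merit()].
#' @return List of class `cfs_result`: `features` (selected names), `merit`,
#'   and `trace` (data frame of visited subsets and merits).
#' @export
best_first_select <- function(X, y, stale_limit = 5L, measure = "pearson") {
  p <- ncol(X)
  if (p < 1) stop("need at least one feature")
  cache <- .cfs_correlations(X, y, measure)
  feat_names <- colnames(X)

  key_of <- function(idx) paste(idx, collapse = ",")
  open <- list(list(idx = integer(0), merit = 0))
  open_keys <- key_of(integer(0))
  visited <- character(0)
  best <- list(idx = integer(0), merit = 0)
  stale <- 0L
  trace <- list()

  while (length(open) && stale < stale_limit) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    at <- which.max(merits)            # ties: earliest inserted
    node <- open[[at]]
    open <- open[-at]; open_keys <- open_keys[-at]
    visited <- c(visited, key_of(node$idx))
    improved <- FALSE
    for (j in setdiff(seq_len(p), node$idx)) {
      child <- sort(c(node$idx, j))
      ck <- key_of(child)
      if (ck %in% visited || ck %in% open_keys) next
      m <- .merit_from_cache(child, cache)
      trace[[length(trace) + 1L]] <-
        data.frame(subset = paste(feat_names[child], collapse = "+"),
                   size = length(child), merit = m)
      open <- c(open, list(list(idx = child, merit = m)))
      open_keys <- c(open_keys, ck)
      if (m > best$merit + 1e-12) {
        best <- list(idx = child, merit = m)
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(features = feat_names[best$idx], merit = best$merit,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(subset = character(0), size = integer(0),
                                         merit = numeric(0))),
            class = "cfs_result")
}

#' @export
print.cfs_result <- function(x, ...) {
  cat(sprintf("<cfs_result: %d feature(s), merit %.4f>\n",
              length(x$features), x$merit))
  if (length(x$features)) cat("  ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
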