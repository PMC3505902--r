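# Correlation-based feature selection and its best-first search.

# independent oracle: the merit formula evaluated from scratch
merit_oracle <- function(idx, X, y) {
  y01 <- as.numeric(y == "substrate")
  k <- length(idx)
  rcf <- mean(abs(vapply(idx, function(j) {
    r <- suppressWarnings(cor(X[, j], y01)); if (is.na(r)) 0 else r
  }, numeric(1))))
  if (k == 1) return(rcf)
  pairs <- utils::combn(idx, 2)
  rff <- mean(abs(apply(pairs, 2, function(p) {
    r <- suppressWarnings(cor(X[, p[1]], X[, p[2]])); if (is.na(r)) 0 else r
  })))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

make_xy <- function(n = 60, p = 6, seed = 1, signal = 2) {
  set.seed(seed)
  y <- factor(rep(c("substrate", "non-substrate"), length.out = n),
              levels = c("substrate", "non-substrate"))
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  for (j in seq_len(signal))
    X[, j] <- X[, j] + ifelse(y == "substrate", 1.2, -1.2) * j / signal
  list(X = X, y = y)
}

test_that("single-feature merit reduces to the absolute class correlation", {
  d <- make_xy()
  y01 <- as.numeric(d$y == "substrate")
  for (j in 1:6)
    expect_equal(cfs_merit(colnames(d$X)[j], d$X, d$y),
                 abs(cor(d$X[, j], y01)))
})

test_that("adding an uncorrelated feature divides a singleton merit by sqrt(2)", {
  # closed form: with r_cf = (|r_f| + 0)/2 and r_ff = 0 the merit becomes
  # 2 * (|r_f|/2) / sqrt(2) = |r_f| / sqrt(2)
  set.seed(7)
  n <- 2000
  y <- factor(rep(c("substrate", "non-substrate"), length.out = n),
              levels = c("substrate", "non-substrate"))
  y01 <- as.numeric(y == "substrate")
  f <- y01 + rnorm(n, 0, 0.8)
  X <- cbind(f = f, null = rnorm(n))
  m1 <- cfs_merit("f", X, y)
  m2 <- cfs_merit(c("f", "null"), X, y)
  expect_lt(m2, m1)
  expect_equal(m2, m1 / sqrt(2), tolerance = 0.05)  # near-zero sample cors
})

test_that("merit equals the brute-force oracle on every subset of 6 features", {
  d <- make_xy(n = 50, p = 6, seed = 3)
  for (k in 1:6) {
    combos <- utils::combn(6, k)
    for (c in seq_len(ncol(combos))) {
      idx <- combos[, c]
      expect_equal(cfs_merit(idx, d$X, d$y), merit_oracle(idx, d$X, d$y),
                   tolerance = 1e-12)
    }
  }
})

test_that("best-first finds the exhaustive-search optimum on small panels", {
  for (seed in c(2, 5, 9)) {
    d <- make_xy(n = 80, p = 8, seed = seed, signal = 3)
    res <- best_first_select(d$X, d$y)
    # exhaustive oracle over all 255 non-empty subsets
    best_m <- 0; best_idx <- integer(0)
    for (k in 1:8) {
      combos <- utils::combn(8, k)
      for (c in seq_len(ncol(combos))) {
        m <- merit_oracle(combos[, c], d$X, d$y)
        if (m > best_m) { best_m <- m; best_idx <- combos[, c] }
      }
    }
    expect_equal(res$merit, best_m, tolerance = 1e-10)
    expect_setequal(res$features, colnames(d$X)[best_idx])
  }
})

test_that("best-first is deterministic and never below the best singleton", {
  d <- make_xy(n = 70, p = 10, seed = 11, signal = 2)
  r1 <- best_first_select(d$X, d$y)
  r2 <- best_first_select(d$X, d$y)
  expect_identical(r1$features, r2$features)
  singles <- vapply(seq_len(10), function(j) cfs_merit(j, d$X, d$y), numeric(1))
  expect_gte(r1$merit, max(singles))
  expect_equal(r1$merit, cfs_merit(r1$features, d$X, d$y))
})

test_that("zero-variance features carry zero merit and are never selected", {
  d <- make_xy(n = 40, p = 4, seed = 13)
  X <- cbind(d$X, dead = rep(3, 40))
  expect_equal(cfs_merit("dead", X, d$y), 0)
  res <- best_first_select(X, d$y)
  expect_false("dead" %in% res$features)
})

test_that("the generative signal descriptors are recovered across replicates", {
  # One fixed synthetic library provides realistic descriptor correlations;
  # replicates redraw the PCC noise with the generator's default effect
  # sizes.  At least 2 of the 3 signal descriptors must appear in at least
  # 90% of 50 seeded replicates.  The third (low-logP surface area) is
  # structurally redundant with donor surface area (N-H nitrogens
  # contribute to both), so the CFS redundancy penalty legitimately prunes
  # it; the two non-redundant descriptors must always be recovered.
  lib <- generate_library(simulation_config(n_compounds = 400, seed = 2024,
                                            dirty = c(inorganic = 0)),
                          out_dir = tempfile())
  Z <- zscore(lib$descriptors)$X
  Zsig <- zscore(lib$descriptors[, QP_SIGNAL_DESCRIPTORS])$X
  beta <- simulation_config()$beta
  hits2 <- 0L
  core <- c("PEOE_VSA_FNEG", "vsa_don")
  core_hits <- 0L
  for (rep in 1:50) {
    set.seed(3000 + rep)
    raw <- as.numeric(Zsig %*% beta) + rnorm(nrow(Z), 0, 0.15)
    pcc <- raw - quantile(raw, 0.13, type = 1) - 0.25
    y <- factor(ifelse(pcc <= -0.25, "substrate", "non-substrate"),
                levels = c("substrate", "non-substrate"))
    sel <- best_first_select(Z, y)
    if (sum(QP_SIGNAL_DESCRIPTORS %in% sel$features) >= 2) hits2 <- hits2 + 1L
    if (all(core %in% sel$features)) core_hits <- core_hits + 1L
  }
  expect_gte(hits2 / 50, 0.90)
  expect_gte(core_hits / 50, 0.90)
})
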