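# The native 2D descriptor engine: counts, polar surface area, partial-
# charge and contribution-binned surface areas, normalization and
# structural keys.

test_that("count descriptors match direct structure inspection", {
  d <- compute_descriptors(mol_of("c1ccccc1"))
  expect_equal(unname(d[c("TPSA", "rings", "a_don", "a_nCl")]), c(0, 1, 0, 0))
  d <- compute_descriptors(mol_of("ClC(Cl)(Cl)Cl"))
  expect_equal(unname(d[c("a_nCl", "rings", "b_count")]), c(4, 0, 4))
  d <- compute_descriptors(mol_of("Oc1ccccc1"))
  expect_equal(unname(d["a_don"]), 1)
  expect_equal(unname(d["TPSA"]), 20.23)
  d <- compute_descriptors(mol_of("NC(=O)c1cc(Br)c(S)c(N)c1"))
  expect_equal(unname(d[c("a_nBr", "a_nN", "a_nO", "a_nS")]), c(1, 2, 1, 1))
})

test_that("logP, MR and TPSA sums reproduce independently computed values", {
  # expected values computed with an independent implementation of the same
  # published contribution tables (frozen)
  cases <- list(
    list("c1ccccc1", 1.6866, 26.442, 0.00),
    list("Oc1ccccc1", 1.3922, 28.107, 20.23),
    list("CCO", -0.0014, 12.760, 20.23),
    list("CC(=O)O", 0.0909, 13.310, 37.30),
    list("c1ccc2ccccc2c1", 2.8398, 43.948, 0.00),
    list("CC(C)Cc1ccc(cc1)C(C)C(=O)O", 3.0732, 61.035, 37.30),
    list("OCC(O)CO", -1.6681, 20.178, 60.69),
    list("CC(=O)OC1=CC=CC=C1C(=O)O", 1.3101, 44.710, 63.60),
    list("c1ccoc1", 1.2796, 18.708, 13.14),
    list("c1cc[nH]c1", 1.0147, 20.793, 15.79),
    list("c1ccncc1", 1.0816, 24.237, 12.89),
    list("ClCCBr", 1.6201, 24.514, 0.00),
    list("O=[N+]([O-])c1ccc(O)cc1", 1.3000, 34.760, 63.37),
    list("CC(=O)Nc1ccccc1", 1.6450, 40.755, 29.10),
    list("CCN(CC)CC", 1.3481, 33.460, 3.24),
    list("CCS(=O)(=O)O", -0.1059, 22.090, 54.37),
    list("NCCc1ccccc1", 1.1878, 39.200, 26.02))
  for (cs in cases) {
    m <- mol_of(cs[[1]])
    x <- qsarpipe:::expand_mol(m)
    cr <- qsarpipe:::crippen_contributions(x)
    expect_equal(sum(cr$logp), cs[[2]], tolerance = 1e-3, label = cs[[1]])
    expect_equal(sum(cr$mr), cs[[3]], tolerance = 1e-2, label = cs[[1]])
    expect_equal(qsarpipe:::mol_tpsa(m), cs[[4]], tolerance = 1e-8,
                 label = cs[[1]])
  }
})

test_that("surface-area bins conserve the total surface", {
  for (smi in c("CC(=O)Oc1ccccc1C(=O)O", "O=[N+]([O-])c1ccc(O)cc1",
                "CCN(CC)CC", "OCC(O)CO", "CCS(=O)(=O)O")) {
    m <- mol_of(smi)
    d <- compute_descriptors(m, panel = "extended")
    total <- d[["VSA"]]
    peoe_bins <- d[c("PEOE_VSA-5", "PEOE_VSA-4", "PEOE_VSA-3", "PEOE_VSA-2",
                     "PEOE_VSA-1", "PEOE_VSA-0", "PEOE_VSA+0", "PEOE_VSA+1",
                     "PEOE_VSA+2", "PEOE_VSA+3", "PEOE_VSA+4", "PEOE_VSA+5")]
    expect_equal(sum(peoe_bins), total, tolerance = 1e-6, label = smi)
    slogp_bins <- d[grep("^SlogP_VSA", names(d))]
    expect_equal(sum(slogp_bins), total, tolerance = 1e-6, label = smi)
    smr_bins <- d[grep("^SMR_VSA", names(d))]
    expect_equal(sum(smr_bins), total, tolerance = 1e-6, label = smi)
    # fractional areas are consistent with their absolute counterparts
    expect_equal(d[["PEOE_VSA_POS"]], d[["PEOE_VSA_FPOS"]] * total,
                 tolerance = 1e-6)
    expect_equal(d[["PEOE_VSA_NEG"]], d[["PEOE_VSA_FNEG"]] * total,
                 tolerance = 1e-6)
    expect_lte(d[["PEOE_VSA_FNEG"]] + d[["PEOE_VSA_FPOS"]], 1 + 1e-9)
    expect_gte(min(d[["PEOE_VSA_FNEG"]], d[["PEOE_VSA_FPOS"]]), 0)
  }
})

test_that("descriptors are deterministic and count chlorines exactly", {
  m <- mol_of("Clc1ccc(CCN)cc1")
  expect_identical(compute_descriptors(m), compute_descriptors(m))
  base <- compute_descriptors(mol_of("c1ccccc1CCN"))
  for (k in 1:3) {
    sub <- compute_descriptors(mol_of(paste0(
      c("Clc1ccccc1CCN", "Clc1ccc(Cl)cc1CCN", "Clc1cc(Cl)cc(Cl)c1CCN")[k])))
    expect_equal(unname(sub["a_nCl"]), unname(base["a_nCl"]) + k)
  }
})

test_that("atoms outside the descriptor parameterization are refused", {
  expect_error(compute_descriptors(mol_of("C[Se]C")), "Se")
})

test_that("Z-scoring matches the closed form and stores reusable parameters", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  z <- zscore(X)
  expect_equal(z$X[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(z$X[, "b"], c(0, 0, 0))
  expect_true(z$constant[["b"]])
  expect_false(z$constant[["a"]])
  expect_equal(colMeans(z$X)[c("a", "c")], c(a = 0, c = 0), tolerance = 1e-9)
  sd_pop <- sqrt(colMeans(sweep(z$X, 2, colMeans(z$X))^2))
  expect_equal(unname(sd_pop[c(1, 3)]), c(1, 1), tolerance = 1e-9)
  # training-parameter transform of a new value equal to the training mean
  newx <- matrix(c(2, 7, 123), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(zscore_apply(newx, z)[1, "a"]), 0)
  expect_equal(unname(zscore_apply(newx, z)[1, "b"]), 0)  # constant stays 0
})

test_that("MACCS keys are deterministic and discriminate ring chemistry", {
  recs <- records_of(c(bz = "c1ccccc1", chx = "C1CCCCC1", bz2 = "c1ccccc1",
                       methane = "C"))
  fp <- maccs_keys(recs)
  expect_equal(dim(fp), c(4, 166))
  expect_identical(fp["bz", ], fp["bz2", ])
  expect_false(identical(fp["bz", ], fp["chx", ]))
  expect_lte(sum(fp["methane", ]), 2)   # near-empty key set
})

test_that("Tanimoto similarity follows its set definition", {
  a <- rep(FALSE, 166); b <- rep(FALSE, 166)
  a[1:4] <- TRUE; b[3:5] <- TRUE
  expect_equal(tanimoto(a, b), 2 / 5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, !a & c(rep(TRUE, 10), rep(FALSE, 156))), 0)
  expect_equal(tanimoto(logical(166), logical(166)), 1)
  expect_error(tanimoto(a, b[-1]), "length")
  # symmetry over random pairs
  set.seed(42)
  for (i in 1:20) {
    u <- runif(166) < 0.2; v <- runif(166) < 0.2
    expect_equal(tanimoto(u, v), tanimoto(v, u))
  }
  # matrix form agrees with the pairwise definition
  recs <- records_of(c(a = "c1ccccc1O", b = "CCOC(=O)C", c = "Clc1ccncc1"))
  fp <- maccs_keys(recs)
  S <- qsarpipe:::tanimoto_matrix(fp)
  for (i in 1:3) for (j in 1:3)
    expect_equal(S[i, j], tanimoto(fp[i, ], fp[j, ]))
})

test_that("partial charges are physically sensible", {
  m <- mol_of("CCO")
  pe <- qsarpipe:::peoe_charges(m)
  expect_equal(sum(pe$q), 0, tolerance = 1e-12)
  o <- which(pe$x$elem == "O")
  expect_lt(pe$q[o], -0.3)              # oxygen strongly negative
  hydrox_h <- which(!pe$x$heavy & pe$x$parent == o)
  ch3_h <- which(!pe$x$heavy & pe$x$parent == 1)
  expect_gt(pe$q[hydrox_h], max(pe$q[ch3_h]))  # O-H proton most acidic
  # charged species conserve their net charge
  m2 <- mol_of("CC(=O)[O-]")
  expect_equal(sum(qsarpipe:::peoe_charges(m2)$q), -1, tolerance = 1e-12)
})
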