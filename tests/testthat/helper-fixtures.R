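# Shared fixture builders: everything is generated in code at test time.

# parse one SMILES into the internal molecule object
mol_of <- function(smi) {
  m <- qsarpipe:::smiles_to_mols(smi)[[1]]
  stopifnot(!is.null(m))
  m
}

# build records from named SMILES (names become ids), optional pcc vector
records_of <- function(smis, pcc = NULL) {
  mols <- qsarpipe:::smiles_to_mols(unname(smis))
  ids <- if (!is.null(names(smis))) names(smis) else sprintf("m%d", seq_along(smis))
  out <- lapply(seq_along(smis), function(i) {
    stopifnot(!is.null(mols[[i]]))
    qsarpipe:::new_record(ids[i], mols[[i]],
                          if (is.null(pcc)) NA_real_ else pcc[i])
  })
  out
}

# a labeled dataset with n_sub substrates and n_non non-substrates; all
# records share one tiny structure (splitting logic only looks at labels/ids)
sized_dataset <- function(n_sub, n_non) {
  mol <- mol_of("CCO")
  n <- n_sub + n_non
  pcc <- c(rep(-0.5, n_sub), rep(0.2, n_non))
  recs <- lapply(seq_len(n), function(i)
    qsarpipe:::new_record(sprintf("c%04d", i), mol, pcc[i]))
  label_by_pcc(qsar_dataset(recs), -0.25)
}

# deterministic synthetic descriptor matrix + labels for model tests:
# two informative columns separate the classes, the rest are noise
separable_data <- function(n_sub = 20, n_non = 60, p_noise = 3, seed = 1,
                           gap = 4) {
  set.seed(seed)
  n <- n_sub + n_non
  X <- matrix(rnorm(n * (2 + p_noise)), n,
              dimnames = list(sprintf("r%03d", seq_len(n)),
                              c("sig1", "sig2", sprintf("noise%d", seq_len(p_noise)))))
  X[seq_len(n_sub), "sig1"] <- X[seq_len(n_sub), "sig1"] + gap
  X[seq_len(n_sub), "sig2"] <- X[seq_len(n_sub), "sig2"] - gap
  y <- factor(c(rep("substrate", n_sub), rep("non-substrate", n_non)),
              levels = c("substrate", "non-substrate"))
  list(X = X, y = y)
}
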