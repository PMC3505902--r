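# The 2D descriptor panel.
#
# All descriptors are connection-table based.  Surface-area descriptors sum
# per-atom van der Waals areas (hydrogens included) over atoms selected by a
# property bin: PEOE partial charge, Wildman-Crippen logP or molar-
# refractivity contribution, or a pharmacophore-style atom typing.  Charge
# bins are half-open [lo, hi); contribution bins follow the conventional
# [lo, hi) reading of the subdivided-surface-area family.

QP_CORE_DESCRIPTORS <- c(
  "a_don", "a_nBr", "a_nCl", "a_nN", "a_nO", "a_nS", "b_count",
  "PEOE_VSA+1", "PEOE_VSA+2", "PEOE_VSA+3", "PEOE_VSA+4",
  "PEOE_VSA_FNEG", "PEOE_VSA_FPOS", "PEOE_VSA_POS", "PEOE_VSA_PPOS",
  "rings", "SlogP_VSA0", "SlogP_VSA1", "SMR_VSA1", "SMR_VSA2", "SMR_VSA4",
  "TPSA", "vsa_base", "vsa_don", "vsa_other")

# extra columns of the extended panel (all natively defined here)
QP_EXTENDED_DESCRIPTORS <- c(
  "a_count", "a_heavy", "a_nF", "a_nI", "a_nP", "a_acc", "logP", "SMR",
  "PEOE_VSA+0", "PEOE_VSA+5", "PEOE_VSA-0", "PEOE_VSA-1", "PEOE_VSA-2",
  "PEOE_VSA-3", "PEOE_VSA-4", "PEOE_VSA-5", "PEOE_VSA_NEG", "PEOE_VSA_PNEG",
  "SlogP_VSA2", "SlogP_VSA3", "SlogP_VSA4", "SlogP_VSA5", "SlogP_VSA6",
  "SlogP_VSA7", "SlogP_VSA8", "SlogP_VSA9",
  "SMR_VSA0", "SMR_VSA3", "SMR_VSA5", "SMR_VSA6", "SMR_VSA7",
  "vsa_acc", "vsa_hyd", "vsa_pol", "VSA")

#' Compute the 2D descriptor panel for one molecule record
#'
#' @param record a molecule record (or a bare internal molecule object).
#' @param panel `"core"` for the core panel or `"extended"` for the core
#'   panel plus additional counts, charge bins and contribution bins.
#' @return Named numeric vector of descriptor values.
#' @export
compute_descriptors <- function(record, panel = c("core", "extended")) {
  panel <- match.arg(panel)
  mol <- if (inherits(record, "qp_mol")) record else record$mol
  bad <- setdiff(unique(mol$atoms$elem), names(.VDW_RADII))
  if (length(bad))
    stop("descriptors are not defined for element(s): ",
         paste(bad, collapse = ", "))

  pe <- peoe_charges(mol)
  x <- pe$x
  q <- pe$q
  vsa <- atom_vsa(x)
  cr <- crippen_contributions(x)
  at <- mol$atoms
  total_vsa <- sum(vsa)

  bin <- function(v, lo, hi) sum(vsa[v >= lo & v < hi])
  elems <- at$elem
  nH_total <- sum(at$nh)

  don_heavy <- which(elems %in% c("N", "O") & at$nh >= 1L)
  acid_o <- find_strong_acid_hydroxyls(mol)
  base_n <- find_basic_nitrogens(mol)
  pure_don <- setdiff(don_heavy, union(acid_o, base_n))
  # donor area includes the polar hydrogens riding on the donor atom
  don_atoms <- c(pure_don, which(!x$heavy & x$parent %in% pure_don))
  acc_heavy <- setdiff(which(elems %in% c("N", "O") & at$nh == 0L), base_n)
  hyd_atoms <- c(which(elems %in% c("C", "F", "Cl", "Br", "I")),
                 which(!x$heavy & x$elem[x$parent] == "C"))
  other_heavy <- which(elems %in% c("S", "P", "Si", "B"))

  d <- c(
    a_don = length(don_heavy),
    a_nBr = sum(elems == "Br"),
    a_nCl = sum(elems == "Cl"),
    a_nN = sum(elems == "N"),
    a_nO = sum(elems == "O"),
    a_nS = sum(elems == "S"),
    b_count = nrow(mol$bonds) + nH_total,
    `PEOE_VSA+1` = bin(q, 0.05, 0.10),
    `PEOE_VSA+2` = bin(q, 0.10, 0.15),
    `PEOE_VSA+3` = bin(q, 0.15, 0.20),
    `PEOE_VSA+4` = bin(q, 0.20, 0.25),
    PEOE_VSA_FNEG = sum(vsa[q < 0]) / total_vsa,
    PEOE_VSA_FPOS = sum(vsa[q > 0]) / total_vsa,
    PEOE_VSA_POS = sum(vsa[q > 0]),
    PEOE_VSA_PPOS = sum(vsa[q > 0.2]),
    rings = nrow(mol$bonds) - n_atoms(mol) + max(mol_components(mol)),
    SlogP_VSA0 = sum(vsa[cr$logp <= -0.40]),
    SlogP_VSA1 = sum(vsa[cr$logp > -0.40 & cr$logp <= -0.20]),
    SMR_VSA1 = bin(cr$mr, 0.11, 0.26),
    SMR_VSA2 = bin(cr$mr, 0.26, 0.35),
    SMR_VSA4 = bin(cr$mr, 0.39, 0.44),
    TPSA = mol_tpsa(mol),
    vsa_base = length(base_n),
    vsa_don = sum(vsa[don_atoms]),
    vsa_other = sum(vsa[other_heavy])
  )
  if (panel == "core") return(d)

  acc_atoms <- acc_heavy
  c(d,
    a_count = n_atoms(mol) + nH_total,
    a_heavy = n_atoms(mol),
    a_nF = sum(elems == "F"),
    a_nI = sum(elems == "I"),
    a_nP = sum(elems == "P"),
    a_acc = length(acc_heavy),
    logP = sum(cr$logp),
    SMR = sum(cr$mr),
    `PEOE_VSA+0` = bin(q, 0.00, 0.05),
    `PEOE_VSA+5` = sum(vsa[q >= 0.25]),
    `PEOE_VSA-0` = bin(q, -0.05, 0.00),
    `PEOE_VSA-1` = bin(q, -0.10, -0.05),
    `PEOE_VSA-2` = bin(q, -0.15, -0.10),
    `PEOE_VSA-3` = bin(q, -0.20, -0.15),
    `PEOE_VSA-4` = bin(q, -0.25, -0.20),
    `PEOE_VSA-5` = sum(vsa[q < -0.25]),
    PEOE_VSA_NEG = sum(vsa[q < 0]),
    PEOE_VSA_PNEG = sum(vsa[q < -0.2]),
    SlogP_VSA2 = sum(vsa[cr$logp > -0.20 & cr$logp <= 0]),
    SlogP_VSA3 = sum(vsa[cr$logp > 0 & cr$logp <= 0.10]),
    SlogP_VSA4 = sum(vsa[cr$logp > 0.10 & cr$logp <= 0.15]),
    SlogP_VSA5 = sum(vsa[cr$logp > 0.15 & cr$logp <= 0.20]),
    SlogP_VSA6 = sum(vsa[cr$logp > 0.20 & cr$logp <= 0.25]),
    SlogP_VSA7 = sum(vsa[cr$logp > 0.25 & cr$logp <= 0.30]),
    SlogP_VSA8 = sum(vsa[cr$logp > 0.30 & cr$logp <= 0.40]),
    SlogP_VSA9 = sum(vsa[cr$logp > 0.40]),
    SMR_VSA0 = bin(cr$mr, 0, 0.11),
    SMR_VSA3 = bin(cr$mr, 0.35, 0.39),
    SMR_VSA5 = bin(cr$mr, 0.44, 0.485),
    SMR_VSA6 = bin(cr$mr, 0.485, 0.56),
    SMR_VSA7 = sum(vsa[cr$mr >= 0.56]),
    vsa_acc = sum(vsa[acc_atoms]),
    vsa_hyd = sum(vsa[hyd_atoms]),
    vsa_pol = sum(vsa[setdiff(which(x$heavy & x$elem %in% c("N", "O")),
                              c(don_heavy, acc_heavy))]),
    VSA = total_vsa)
}

#' Descriptor matrix for a set of records
#'
#' @param records list of molecule records or a [qsar_dataset()].
#' @param panel descriptor panel, see [compute_descriptors()].
#' @return Numeric matrix, compounds in rows (named by record id),
#'   descriptors in columns.
#' @export
descriptor_matrix <- function(records, panel = c("core", "extended")) {
  panel <- match.arg(panel)
  if (inherits(records, "qsar_dataset")) records <- records$records
  rows <- lapply(records, compute_descriptors, panel = panel)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(records, `[[`, character(1), "id")
  X
}

# ---------------------------------------------------------------------------
# Z-score normalization
# ---------------------------------------------------------------------------

#' Z-score a descriptor matrix
#'
#' Centers and scales each column with its mean and population standard
#' deviation.  Constant columns become all-zero and are flagged; the fitted
#' parameters are returned so that external compounds can be transformed
#' with the training parameters via [zscore_apply()].
#'
#' @param X numeric descriptor matrix.
#' @return List with `X` (transformed matrix), `mean`, `sd` and `constant`
#'   (logical flag per column).
#' @export
zscore <- function(X) {
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- sd_pop < 1e-12
  params <- list(mean = mu, sd = sd_pop, constant = constant)
  list(X = zscore_apply(X, params), mean = mu, sd = sd_pop,
       constant = constant)
}

#' @rdname zscore
#' @param params normalization parameters from a previous [zscore()] fit.
#' @export
zscore_apply <- function(X, params) {
  sd_use <- ifelse(params$constant, 1, params$sd)
  Z <- sweep(sweep(X, 2, params$mean), 2, sd_use, "/")
  Z[, params$constant] <- 0
  Z
}
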