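# Partial equalization of orbital electronegativities (PEOE, Gasteiger-
# Marsili) and per-atom van der Waals surface areas on the hydrogen-expanded
# graph.  Both are the raw material of the PEOE_VSA / SlogP_VSA / SMR_VSA
# descriptor families: every atom, hydrogens included, carries a partial
# charge and an approximate exposed surface area, and descriptors are sums
# of areas over atoms binned by one atomic property.

# hydrogen-expanded view: heavy atoms keep their indices, hydrogens are
# appended as extra vertices bonded to their heavy parent
expand_mol <- function(mol) {
  at <- mol$atoms
  nheavy <- nrow(at)
  nh <- at$nh
  nH <- sum(nh)
  elem <- c(at$elem, rep("H", nH))
  arom <- c(at$arom, rep(FALSE, nH))
  charge <- c(at$charge, rep(0L, nH))
  parent <- c(seq_len(nheavy), rep(seq_len(nheavy), nh))
  b <- mol$bonds
  if (nH > 0) {
    hidx <- nheavy + seq_len(nH)
    hparent <- rep(seq_len(nheavy), nh)
    b <- rbind(b[, c("a1", "a2", "order", "arom")],
               data.frame(a1 = hparent, a2 = hidx, order = 1L, arom = FALSE))
  } else {
    b <- b[, c("a1", "a2", "order", "arom")]
  }
  n <- nheavy + nH
  nbr <- rep(list(integer(0)), n)
  ord <- rep(list(integer(0)), n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
    nbr[[i]] <- c(nbr[[i]], j); ord[[i]] <- c(ord[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(elem = elem, arom = arom, charge = charge, parent = parent,
       heavy = c(rep(TRUE, nheavy), rep(FALSE, nH)),
       nheavy = nheavy, bonds = b, nbr = nbr, order = ord)
}

# ---------------------------------------------------------------------------
# PEOE partial charges
# ---------------------------------------------------------------------------

# electronegativity polynomials chi(q) = a + b q + c q^2 per orbital state
# (Gasteiger & Marsili 1980 values; phosphorus from the later extension of
# the same scheme; boron/silicon fall back to sp3 carbon, documented)
.PEOE_PARAMS <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S.sp3  = c(10.14, 9.13, 1.38),
  S.sp2  = c(10.14, 9.13, 1.38),
  P.sp3  = c(8.90, 8.24, 0.96),
  B.sp3  = c(7.98, 9.18, 1.88),
  Si.sp3 = c(7.98, 9.18, 1.88)
)

.peoe_type <- function(elem, arom, orders) {
  if (elem %in% c("H", "F", "Cl", "Br", "I")) return(elem)
  hyb <- if (arom || any(orders == 2)) "sp2" else if (any(orders == 3)) "sp" else "sp3"
  if (elem == "C" && sum(orders == 2) >= 2) hyb <- "sp"  # cumulated diene C
  key <- paste(elem, hyb, sep = ".")
  if (!is.null(.PEOE_PARAMS[[key]])) return(key)
  key3 <- paste(elem, "sp3", sep = ".")
  if (!is.null(.PEOE_PARAMS[[key3]])) return(key3)
  "C.sp3"
}

#' Gasteiger PEOE partial charges
#'
#' Iterative partial equalization of orbital electronegativity with damping
#' factor 1/2 per iteration, seeded from formal charges, run on the
#' hydrogen-expanded graph.
#'
#' @param mol internal molecule object.
#' @param n_iter number of damped iterations (default 6; the scheme is
#'   essentially converged there since the damping factor is 2^-n).
#' @return List with `q` (charges: heavy atoms then hydrogens) and the
#'   expanded graph in `x`.
#' @keywords internal
peoe_charges <- function(mol, n_iter = 6L) {
  x <- expand_mol(mol)
  n <- length(x$elem)
  types <- vapply(seq_len(n), function(i)
    .peoe_type(x$elem[i], x$arom[i], x$order[[i]]), character(1))
  par <- do.call(rbind, .PEOE_PARAMS[types])
  q <- as.numeric(x$charge)
  # electronegativity of the cation: chi(+1), except the fixed H value
  chi_plus <- par[, 1] + par[, 2] + par[, 3]
  chi_plus[x$elem == "H"] <- 20.02
  b <- x$bonds
  if (nrow(b)) for (it in seq_len(n_iter)) {
    damp <- 0.5^it
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(n)
    lo <- ifelse(chi[b$a1] <= chi[b$a2], b$a1, b$a2)
    hi <- ifelse(chi[b$a1] <= chi[b$a2], b$a2, b$a1)
    tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
    for (k in seq_along(tr)) {
      dq[lo[k]] <- dq[lo[k]] + tr[k]
      dq[hi[k]] <- dq[hi[k]] - tr[k]
    }
    q <- q + dq
  }
  list(q = q, x = x)
}

# ---------------------------------------------------------------------------
# van der Waals surface areas (connection-table approximation)
# ---------------------------------------------------------------------------

# Bondi van der Waals radii (Angstrom); B/Si from the extended compilations
.VDW_RADII <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

# single-bond covalent radii used to build ideal bond lengths
.COV_RADII <- c(H = 0.32, B = 0.82, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
                Si = 1.11, P = 1.06, S = 1.02, Cl = 0.99, Br = 1.14, I = 1.33)

# bond-length shortening by bond order (Angstrom)
.BOND_SHORTEN <- c(`1` = 0, `2` = 0.20, `3` = 0.34)
.AROM_SHORTEN <- 0.15

# Exposed sphere area per atom: the full van der Waals sphere minus the
# spherical caps buried in each bonded neighbor, with bond lengths taken
# from covalent radii and a fixed order-dependent shortening, clamped so the
# spheres neither detach nor swallow each other.
atom_vsa <- function(x) {
  ri <- .VDW_RADII[x$elem]
  ri[is.na(ri)] <- 1.70
  rc <- .COV_RADII[x$elem]
  rc[is.na(rc)] <- 0.77
  area <- 4 * pi * ri^2
  b <- x$bonds
  if (nrow(b)) {
    shorten <- ifelse(b$arom, .AROM_SHORTEN, .BOND_SHORTEN[as.character(b$order)])
    d <- rc[b$a1] + rc[b$a2] - shorten
    for (side in 1:2) {
      i <- if (side == 1) b$a1 else b$a2
      j <- if (side == 1) b$a2 else b$a1
      dij <- pmin(pmax(d, abs(ri[i] - ri[j]) + 1e-8), ri[i] + ri[j])
      cap <- (pi * ri[i] / dij) * (ri[j]^2 - (dij - ri[i])^2)
      for (k in seq_along(i)) area[i[k]] <- area[i[k]] - cap[k]
    }
  }
  pmax(area, 0)
}
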