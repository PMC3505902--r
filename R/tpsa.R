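# Topological polar surface area (Ertl, Rovira & Selzer 2000): summed
# fragment contributions of nitrogen and oxygen atoms classified by
# environment (classic N/O parameterization; the phenol hydroxyl, for
# instance, contributes 20.23 A^2).

.tpsa_contribution <- function(x, i, nh_of, three_ring) {
  elem <- x$elem[i]
  nbrs <- x$nbr[[i]]; ords <- x$order[[i]]
  heavy_n <- nbrs[x$heavy[nbrs]]
  heavy_o <- ords[x$heavy[nbrs]]
  nH <- nh_of[i]
  chg <- x$charge[i]
  deg <- length(heavy_n) + nH
  n_single <- sum(heavy_o == 1L) + nH
  n_double <- sum(heavy_o == 2L)
  n_triple <- sum(heavy_o == 3L)

  if (elem == "N") {
    if (x$arom[i]) {
      nring <- sum(.bond_is_arom(x, i, heavy_n))
      nsub <- length(heavy_n) - nring + nH   # exocyclic connections
      if (chg == 0) {
        if (nH >= 1) return(15.79)                       # [nH]
        if (length(heavy_n) == 3 && nring == 2) return(4.93)  # [n](-*)(:*):*
        if (length(heavy_n) >= 3) return(4.41)           # [n](:*)(:*):*
        return(12.89)                                    # [n](:*):*
      } else {
        if (nH >= 1) return(14.14)
        if (length(heavy_n) == 3 && nring == 2) return(3.88)
        return(4.10)
      }
    }
    if (chg == 0) {
      if (n_triple >= 1) {
        if (n_double >= 1) return(13.60)                 # [N](=*)#*
        return(23.79)                                    # nitrile
      }
      if (n_double >= 2) return(11.68)                   # pentavalent N(=*)(=*)-*
      if (n_double == 1) {
        if (nH >= 1) return(23.85)
        return(12.36)
      }
      if (nH == 0) {
        if (three_ring[i]) return(3.01)
        return(3.24)
      }
      if (nH == 1) {
        if (three_ring[i]) return(21.94)
        return(12.03)
      }
      return(26.02)                                      # primary amine
    }
    if (chg > 0) {
      if (n_triple >= 1) return(4.36)
      if (n_double >= 1) {
        if (nH == 0) return(3.01)
        if (nH == 1) return(13.97)
        return(25.59)
      }
      if (nH == 0) return(0.00)
      if (nH == 1) return(4.44)
      if (nH == 2) return(16.61)
      return(27.64)
    }
    return(26.02)   # anionic N: closest neutral analogue (rare after curation)
  }

  if (elem == "O") {
    if (x$arom[i]) return(13.14)
    if (chg < 0) return(23.06)
    if (n_double >= 1) return(17.07)
    if (nH >= 1) return(20.23)
    if (three_ring[i]) return(12.53)
    return(9.23)
  }
  0
}

#' Topological polar surface area of a molecule
#'
#' @param mol internal molecule object.
#' @return TPSA in square Angstrom.
#' @keywords internal
mol_tpsa <- function(mol) {
  x <- expand_mol(mol)
  three_ring <- c(in_three_ring(mol), rep(FALSE, length(x$elem) - x$nheavy))
  nh_of <- vapply(seq_along(x$elem), function(i)
    sum(!x$heavy[x$nbr[[i]]]), integer(1))
  polar <- which(x$heavy & x$elem %in% c("N", "O"))
  sum(vapply(polar, function(i) .tpsa_contribution(x, i, nh_of, three_ring),
             numeric(1)))
}
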