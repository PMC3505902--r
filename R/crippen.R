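# Wildman-Crippen atomic contributions to logP and molar refractivity.
#
# The published atom typing (Wildman & Crippen 1999, J. Chem. Inf. Comput.
# Sci. 39:868) is encoded here as ordered graph predicates rather than a
# SMARTS engine: each atom is assigned the first matching type, exactly as
# the published table is meant to be read top-to-bottom.  Only the atomic
# contributions feed descriptors (surface-area sums binned by contribution);
# whole-molecule logP is also exposed as the sum, which is what the original
# method defines.

.CRIPPEN <- list(
  C1 = c(0.1441, 2.503),   C2 = c(0.0000, 2.433),  C3 = c(-0.2035, 2.753),
  C4 = c(-0.2051, 2.731),  C5 = c(-0.2783, 5.007), C6 = c(0.1551, 3.513),
  C7 = c(0.0017, 3.888),   C8 = c(0.08452, 2.464), C9 = c(-0.1444, 2.412),
  C10 = c(-0.0516, 2.488), C11 = c(0.1193, 2.582), C12 = c(-0.0967, 2.576),
  C13 = c(-0.5443, 4.041), C14 = c(0.0000, 3.257), C15 = c(0.2450, 3.564),
  C16 = c(0.1980, 3.180),  C17 = c(0.0000, 3.104), C18 = c(0.1581, 3.350),
  C19 = c(0.2955, 4.346),  C20 = c(0.2713, 3.904), C21 = c(0.1360, 3.509),
  C22 = c(0.4619, 4.067),  C23 = c(0.5437, 3.853), C24 = c(0.1893, 2.673),
  C25 = c(-0.8186, 3.135), C26 = c(0.2640, 4.305), C27 = c(0.2148, 2.693),
  CS = c(0.08129, 3.243),
  H1 = c(0.1230, 1.057),   H2 = c(-0.2677, 1.395), H3 = c(0.2142, 0.9627),
  H4 = c(0.2980, 1.805),   HS = c(0.1125, 1.112),
  N1 = c(-1.0190, 2.262),  N2 = c(-0.7096, 2.173), N3 = c(-1.0270, 2.827),
  N4 = c(-0.5188, 3.000),  N5 = c(0.08387, 1.757), N6 = c(0.1836, 2.428),
  N7 = c(-0.3187, 1.839),  N8 = c(-0.4458, 2.819), N9 = c(0.01508, 1.725),
  N10 = c(-1.9500, 0),     N11 = c(-0.3239, 2.202), N12 = c(-1.1190, 0),
  N13 = c(-0.3396, 0.2604), N14 = c(0.2887, 3.359), NS = c(-0.4806, 2.134),
  O1 = c(0.1552, 1.080),   O2 = c(-0.2893, 0.8238), O3 = c(-0.0684, 1.085),
  O4 = c(-0.4195, 1.182),  O5 = c(0.0335, 3.367),  O6 = c(-0.3339, 0.7774),
  O7 = c(-1.1890, 0),      O8 = c(0.1788, 3.135),  O9 = c(-0.1526, 0),
  O10 = c(0.1129, 0.2215), O11 = c(0.4833, 0.389), O12 = c(-1.3260, 0),
  OS = c(-0.1188, 0.6865),
  F = c(0.4202, 1.108),    Cl = c(0.6895, 5.853),  Br = c(0.8456, 8.927),
  I = c(0.8857, 14.02),    Hal = c(-2.9960, 0),
  P = c(0.8612, 6.920),
  S1 = c(0.6482, 7.591),   S2 = c(-0.0024, 7.365), S3 = c(0.6237, 6.691),
  Me1 = c(-0.3808, 5.754), Me2 = c(-0.0025, 0)
)

# type one heavy atom of the expanded graph
.crippen_heavy_type <- function(x, i, nh_of) {
  elem <- x$elem[i]; arom <- x$arom[i]; chg <- x$charge[i]
  nbrs <- x$nbr[[i]]; ords <- x$order[[i]]
  heavy_n <- nbrs[x$heavy[nbrs]]
  heavy_o <- ords[x$heavy[nbrs]]
  nH <- nh_of[i]
  nel <- x$elem[heavy_n]; narom <- x$arom[heavy_n]
  halset <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
  aliph <- !narom  # aliphatic heavy neighbor

  if (elem == "C") {
    sp3 <- !arom && all(heavy_o == 1L)
    has_arom_nbr <- any(narom)
    if (sp3 && !has_arom_nbr) {
      if (all(nel == "C" & aliph)) {
        return(if (length(heavy_n) <= 2) "C1" else "C2")
      }
      if (any(nel %in% halset & aliph) && all(aliph)) {
        return(if (length(heavy_n) <= 2) "C3" else "C4")
      }
    }
    if (!arom) {
      dbl <- heavy_n[heavy_o == 2L]
      if (length(dbl)) {
        del <- x$elem[dbl]; darom <- x$arom[dbl]
        if (any(del != "C" & !darom)) return("C5")
        if (any(del == "C" & darom)) return("C26")       # [C]=c
        if (any(del == "C" & !darom)) {
          if (any(narom)) return("C26")                  # C(=C)(a)...
          if (all(!narom)) return("C6")
        }
      }
      if (any(heavy_o == 3L)) return("C7")
    }
    if (sp3 && has_arom_nbr) {
      deg <- length(heavy_n)
      if (deg == 1 && nH == 3) {
        return(if (x$elem[heavy_n[narom][1]] == "C") "C8" else "C9")
      }
      if (nH == 2) return("C10")
      if (nH == 1) return("C11")
      if (nH == 0) return("C12")
    }
    if (arom) {
      # neighbors joined by aromatic ring bonds vs exocyclic substituents
      subst <- heavy_n[!.bond_is_arom(x, i, heavy_n)]
      ring_nbrs <- setdiff(heavy_n, subst)
      if (nH >= 1) return("C18")
      if (length(subst) == 0 && length(ring_nbrs) >= 3) return("C19")
      if (length(subst)) {
        s <- subst[1]
        so <- heavy_o[match(s, heavy_n)]
        sel <- x$elem[s]; sarom <- x$arom[s]
        if (sel == "F") return("C14")
        if (sel == "Cl") return("C15")
        if (sel == "Br") return("C16")
        if (sel == "I") return("C17")
        if (so == 2 && sel %in% c("C", "N", "O")) return("C25")
        if (sarom) return("C20")
        if (sel == "C") return("C21")
        if (sel == "N") return("C22")
        if (sel == "O") return("C23")
        if (sel == "S") return("C24")
        return("C13")
      }
      return("CS")
    }
    if (sp3 && any(!(nel %in% c("C", halset)) & aliph)) return("C27")
    return("CS")
  }

  if (elem == "N") {
    if (arom) return(if (chg > 0) "N12" else "N11")
    if (chg > 0) {
      if (nH >= 1 && all(heavy_o == 1L)) return("N10")
      if (any(heavy_o == 3L)) return("N14")
      return("N13")   # quaternary or =N+ (nitro and related)
    }
    if (chg < 0) return("N14")
    if (any(heavy_o == 3L)) return("N9")
    dbl <- any(heavy_o == 2L)
    if (dbl) {
      if (nH >= 1 || length(heavy_n) == 1) return("N5")
      return("N6")
    }
    if (nH == 2) return(if (any(narom)) "N3" else "N1")
    if (nH == 1) return(if (any(narom)) "N4" else "N2")
    if (length(heavy_n) == 3) return(if (any(narom)) "N8" else "N7")
    return("NS")
  }

  if (elem == "O") {
    if (arom) return("O1")
    if (chg < 0) {
      n1 <- if (length(heavy_n)) heavy_n[1] else NA
      if (!is.na(n1)) {
        if (x$elem[n1] == "N") return("O5")
        if (x$elem[n1] == "S") return("O6")
        if (x$elem[n1] == "C") {
          co <- x$nbr[[n1]]; coo <- x$order[[n1]]
          if (any(x$elem[co] == "O" & coo == 2L)) return("O12")
        }
      }
      return("O7")
    }
    if (nH >= 1) return("O2")
    dbl <- heavy_n[heavy_o == 2L]
    if (length(dbl)) {
      p <- dbl[1]; pel <- x$elem[p]
      if (pel %in% c("N", "O")) return("O5")
      if (pel == "S") return("O6")
      if (pel == "C") {
        if (x$arom[p]) return("O8")
        others <- setdiff(x$nbr[[p]], i)
        others <- others[x$heavy[others]]
        oel <- x$elem[others]; oarom <- x$arom[others]
        p_nH <- nh_of[p]
        if (any(oarom)) return("O10")
        if (p_nH >= 1 || any(oel == "C")) return("O9")
        if (length(others) && all(oel != "C")) return("O11")
        return("O9")
      }
      return("OS")
    }
    if (length(heavy_n) == 2) {
      return(if (any(narom)) "O4" else "O3")
    }
    return("OS")
  }

  if (elem == "S") {
    if (chg != 0) return("S2")
    if (any(heavy_o == 2L & nel %in% c("N", "O", "P", "S"))) return("S2")
    if (arom) return("S3")
    return("S1")
  }
  if (elem == "P") return("P")
  if (elem %in% c("F", "Cl", "Br", "I")) {
    return(if (chg == 0) elem else "Hal")
  }
  if (elem %in% c("B", "Si")) return("Me1")
  "Me1"
}

# is the bond between aromatic atom i and neighbor j an aromatic ring bond?
.bond_is_arom <- function(x, i, js) {
  b <- x$bonds
  vapply(js, function(j) {
    k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))[1]
    isTRUE(b$arom[k])
  }, logical(1))
}

# type a hydrogen by its heavy parent's environment
.crippen_h_type <- function(x, parent, nh_of) {
  pel <- x$elem[parent]
  if (pel %in% c("C", "H")) return("H1")
  if (pel == "N") return("H3")
  if (pel == "O") {
    pn <- x$nbr[[parent]]
    pn <- pn[x$heavy[pn]]
    if (!length(pn)) return("H2")           # water
    q <- pn[1]; qel <- x$elem[q]
    if (qel == "N") return("H3")
    if (qel %in% c("O", "S")) return("H4")
    if (qel == "C") {
      if (x$arom[q]) return("H2")
      qo <- x$order[[q]]; qn <- x$nbr[[q]]
      if (any(qo == 2L & x$elem[qn] %in% c("C", "N", "O", "S"))) return("H4")
      if (all(qo == 1L)) return("H2")
      return("HS")
    }
    return("H2")                            # O bonded to P, S(=O), ...
  }
  "H2"                                      # H on S, P, ...
}

# per-atom Crippen types for an expanded graph; returns character vector
crippen_types <- function(x) {
  nh_of <- integer(length(x$elem))
  for (i in seq_along(x$elem)) {
    nb <- x$nbr[[i]]
    nh_of[i] <- sum(!x$heavy[nb])
  }
  out <- character(length(x$elem))
  for (i in seq_along(x$elem)) {
    out[i] <- if (x$heavy[i]) .crippen_heavy_type(x, i, nh_of)
              else .crippen_h_type(x, x$parent[i], nh_of)
  }
  out
}

# per-atom logP and MR contributions for an expanded graph
crippen_contributions <- function(x) {
  ty <- crippen_types(x)
  m <- do.call(rbind, .CRIPPEN[ty])
  list(type = ty, logp = m[, 1], mr = m[, 2])
}
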