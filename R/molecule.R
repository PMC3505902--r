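# Internal 2D molecular-graph representation.
#
# A `qp_mol` is a light heavy-atom graph: hydrogens are stored as per-atom
# counts (`nh`), never as graph vertices.  Structures enter through OpenBabel
# (which kekulizes aromatic input), so bond orders are always 1/2/3;
# aromaticity is re-perceived on the kekulized graph and stored as atom/bond
# flags.  Stereochemistry is dropped at parse time by construction: neither
# wedge flags nor stereo parities are read, which realizes the "clear stereo"
# step of the curation protocol.

# default valences used for implicit-hydrogen assignment; multivalent S/P get
# the smallest standard valence that accommodates the explicit bond-order sum
.QP_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

# elements for which descriptors are defined (curation step 4 enforces this)
QP_ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                         "Cl", "Br", "I")

# metals: alkali/alkaline-earth/transition/post-transition + lanthanides and
# actinides.  Anything not listed here and not in QP_ALLOWED_ELEMENTS (Se, Te,
# As, noble gases, ...) is a "special atom" removed at curation step 4.
QP_METALS <- c(
  "Li", "Na", "K", "Rb", "Cs", "Fr", "Be", "Mg", "Ca", "Sr", "Ba", "Ra",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Al", "Ga", "In", "Sn", "Tl", "Pb", "Bi", "Po",
  "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
  "Tm", "Yb", "Lu", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk",
  "Cf", "Es", "Fm", "Md", "No", "Lr", "Ge", "Sb"
)

qp_mol <- function(atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  structure(list(atoms = atoms, bonds = bonds), class = "qp_mol")
}

n_atoms <- function(mol) nrow(mol$atoms)
n_heavy_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.qp_mol <- function(x, ...) {
  cat(sprintf("<qp_mol: %d heavy atoms, %d bonds, formula %s>\n",
              n_atoms(x), n_heavy_bonds(x), mol_formula(x)))
  invisible(x)
}

# adjacency: list over atoms of data.frame(nbr, order)
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(integer(0)), n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]; o <- b$order[k]
      adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
      adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
    }
  }
  list(nbr = adj, order = ord)
}

# sum of explicit bond orders per atom (kekulized orders)
bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
      s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
    }
  }
  s
}

# implicit hydrogens from default valences with formal-charge adjustment
.implicit_h <- function(elem, charge, order_sum) {
  vals <- .QP_VALENCE[[elem]]
  if (is.null(vals)) return(0L)
  if (elem %in% c("N", "P", "O", "S", "B")) {
    vals <- vals + charge
  } else if (elem == "C") {
    vals <- vals - abs(charge)
  } else if (charge != 0) {
    vals <- vals + charge              # e.g. halogen anions -> valence 0
  }
  vals <- vals[vals >= order_sum]
  if (!length(vals)) return(0L)
  as.integer(min(vals) - order_sum)
}

recompute_hydrogens <- function(mol) {
  os <- bond_order_sum(mol)
  mol$atoms$nh <- vapply(seq_len(n_atoms(mol)), function(i) {
    .implicit_h(mol$atoms$elem[i], mol$atoms$charge[i], os[i])
  }, integer(1))
  mol
}

# ring membership by iterative removal of degree-1 vertices
ring_membership <- function(mol) {
  n <- n_atoms(mol)
  if (!nrow(mol$bonds)) return(rep(FALSE, n))
  alive <- rep(TRUE, n)
  b <- mol$bonds
  repeat {
    deg <- integer(n)
    keep <- alive[b$a1] & alive[b$a2]
    if (any(keep)) {
      t1 <- table(factor(b$a1[keep], levels = seq_len(n)))
      t2 <- table(factor(b$a2[keep], levels = seq_len(n)))
      deg <- as.integer(t1) + as.integer(t2)
    }
    leaves <- alive & deg <= 1
    if (!any(leaves)) break
    alive[leaves] <- FALSE
  }
  alive
}

# connected components (heavy-atom graph); returns integer component id
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adjacency(mol)$nbr
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# subset a molecule to a set of atom indices, remapping bonds
mol_subset <- function(mol, idx) {
  idx <- sort(idx)
  map <- integer(n_atoms(mol)); map[idx] <- seq_along(idx)
  b <- mol$bonds
  keep <- b$a1 %in% idx & b$a2 %in% idx
  b <- b[keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  rownames(b) <- NULL
  qp_mol(mol$atoms[idx, , drop = FALSE][, , drop = FALSE], b)
}

mol_formula <- function(mol) {
  at <- mol$atoms
  counts <- tapply(rep(1L, nrow(at)), at$elem, sum)
  nh <- sum(at$nh)
  elems <- names(counts)
  # Hill order
  ord <- c(intersect(c("C", "H"), c(elems, if (nh > 0) "H")),
           sort(setdiff(elems, c("C", "H"))))
  parts <- character(0)
  for (e in unique(ord)) {
    k <- if (e == "H") nh + sum(counts[names(counts) == "H"]) else counts[[e]]
    if (is.na(k) || k == 0) next
    parts <- c(parts, paste0(e, if (k > 1) k else ""))
  }
  paste0(parts, collapse = "")
}

net_charge <- function(mol) sum(mol$atoms$charge)

contains_carbon <- function(mol) any(mol$atoms$elem == "C")

# ---------------------------------------------------------------------------
# parsing: raw molblock lines -> qp_mol
# ---------------------------------------------------------------------------

# old-style atom-line charge codes (V2000 field 5); 4 = doublet radical
.CHG_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
               `6` = -2L, `7` = -3L)

# Parse a single V2000 molblock given as a character vector of lines.
# Returns a qp_mol (with explicit hydrogens folded into `nh`) or NULL if the
# block cannot be interpreted.  V3000 blocks are rejected.
parse_molblock <- function(lines) {
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  if (grepl("V3000", counts)) stop("V3000 connection tables are not supported")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) return(NULL)
  if (length(lines) < 4 + na + nb) return(NULL)
  atom_lines <- lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  if (any(elem == "")) return(NULL)
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  code[is.na(code)] <- 0L
  charge <- ifelse(code %in% 1:7, .CHG_CODE[as.character(code)], 0L)
  charge <- as.integer(charge)
  if (nb > 0) {
    bond_lines <- lines[(5 + na):(4 + na + nb)]
    a1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    a2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    or <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    if (any(is.na(a1)) || any(is.na(a2)) || any(is.na(or))) return(NULL)
    if (any(a1 < 1 | a1 > na | a2 < 1 | a2 > na | a1 == a2)) return(NULL)
    or[or == 4L] <- 1L  # aromatic order should not survive OB kekulization
  } else {
    a1 <- a2 <- or <- integer(0)
  }
  # property block: "M  CHG" lines override all atom-line codes
  prop <- lines[grepl("^M  CHG", lines)]
  if (length(prop)) {
    charge <- integer(na)
    for (p in prop) {
      flds <- suppressWarnings(as.integer(strsplit(trimws(substr(p, 7, nchar(p))),
                                                   "\\s+")[[1]]))
      k <- flds[1]
      if (is.na(k) || length(flds) < 1 + 2 * k) next
      for (j in seq_len(k)) {
        ai <- flds[2 * j]; ch <- flds[2 * j + 1]
        if (!is.na(ai) && ai >= 1 && ai <= na) charge[ai] <- ch
      }
    }
  }
  atoms <- data.frame(elem = elem, charge = charge, nh = 0L,
                      arom = FALSE, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = a1, a2 = a2, order = or,
                      arom = rep(FALSE, length(a1)))
  mol <- qp_mol(atoms, bonds)
  mol <- fold_explicit_h(mol)
  mol <- recompute_hydrogens(mol)
  # explicit hydrogens already folded count toward nh via valence model; add
  # any surplus explicit H (e.g. on charged atoms the model underestimates)
  if (n_atoms(mol) == 0) return(NULL)
  mol
}

# remove explicit H vertices, remembering their count on the bonded heavy atom
fold_explicit_h <- function(mol) {
  hs <- which(mol$atoms$elem == "H")
  if (!length(hs)) return(mol)
  heavy <- setdiff(seq_len(n_atoms(mol)), hs)
  if (!length(heavy)) {
    # H2 or bare protons: keep a single pseudo-record so counts stay sane
    return(qp_mol(mol$atoms[1, , drop = FALSE], mol$bonds[0, , drop = FALSE]))
  }
  mol_subset(mol, heavy)
}

# ---------------------------------------------------------------------------
# aromaticity: Hueckel test on SSSR-like rings of the kekulized graph
# ---------------------------------------------------------------------------

# enumerate simple rings up to `upper` atoms: for every ring bond, find the
# shortest cycle through it (BFS avoiding the bond itself)
find_rings <- function(mol, upper = 14L) {
  inring <- ring_membership(mol)
  b <- mol$bonds
  rings <- list()
  if (!nrow(b)) return(rings)
  adj <- mol_adjacency(mol)$nbr
  seen <- character(0)
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (!inring[i] || !inring[j]) next
    # BFS from i to j not using bond k
    prev <- integer(n_atoms(mol)); prev[i] <- -1L
    queue <- i
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (prev[w] == 0L && w != i) {
          prev[w] <- v
          if (w == j) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (!found) next
    path <- j
    v <- j
    while (prev[v] != -1L) { v <- prev[v]; path <- c(path, v) }
    if (length(path) > upper) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- path
  }
  rings
}

# pi-electron contribution of a ring atom, or NA if the atom breaks aromaticity
.pi_contribution <- function(mol, i, ring, adj) {
  at <- mol$atoms
  elem <- at$elem[i]; chg <- at$charge[i]
  nbrs <- adj$nbr[[i]]; ords <- adj$order[[i]]
  if (any(ords == 3)) return(NA_real_)
  in_ring_dbl <- any(ords == 2 & nbrs %in% ring)
  exo_dbl <- any(ords == 2 & !(nbrs %in% ring))
  degree <- length(nbrs) + at$nh[i]
  if (elem == "C") {
    if (in_ring_dbl) return(1)
    if (exo_dbl) return(0)           # e.g. cyclopentadienone carbonyl C
    if (chg == 1 && degree == 3) return(0)   # tropylium-type
    if (chg == -1 && degree == 3) return(2)  # cyclopentadienyl-type
    return(NA_real_)                 # sp3 carbon breaks the ring
  }
  if (elem %in% c("N", "P")) {
    if (in_ring_dbl) return(1)       # pyridine-type
    if (exo_dbl) return(1)           # N of N-oxide-like
    if (degree <= 3) return(2)       # pyrrole-type lone pair
    return(NA_real_)
  }
  if (elem %in% c("O", "S")) {
    if (in_ring_dbl) return(1)       # pyrylium-type (rare)
    if (degree == 2) return(2)       # furan/thiophene lone pair
    return(NA_real_)
  }
  NA_real_
}

perceive_aromaticity <- function(mol) {
  mol$atoms$arom <- FALSE
  mol$atoms$ring <- ring_membership(mol)
  mol$bonds$arom <- rep(FALSE, nrow(mol$bonds))
  rings <- find_rings(mol)
  if (!length(rings)) return(mol)
  adj <- mol_adjacency(mol)
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    pis <- vapply(ring, function(i) .pi_contribution(mol, i, ring, adj),
                  numeric(1))
    if (any(is.na(pis))) next
    ne <- sum(pis)
    if (ne %% 4 == 2) {
      mol$atoms$arom[ring] <- TRUE
      inb <- mol$bonds$a1 %in% ring & mol$bonds$a2 %in% ring
      mol$bonds$arom[inb] <- TRUE
    }
  }
  mol
}

# atoms that are members of a 3-membered ring (needed by the polar-surface
# fragment table, which treats aziridine/oxirane specially)
in_three_ring <- function(mol) {
  n <- n_atoms(mol)
  out <- rep(FALSE, n)
  b <- mol$bonds
  if (nrow(b) < 3) return(out)
  adj <- mol_adjacency(mol)$nbr
  for (k in seq_len(nrow(b))) {
    common <- intersect(adj[[b$a1[k]]], adj[[b$a2[k]]])
    if (length(common)) out[c(b$a1[k], b$a2[k], common)] <- TRUE
  }
  out
}

# ---------------------------------------------------------------------------
# molblock writer (V2000, charges via M CHG)
# ---------------------------------------------------------------------------

# 2D layout is irrelevant for any connection-table descriptor; a simple ring
# of coordinates keeps viewers from stacking atoms at the origin
.placeholder_coords <- function(n) {
  th <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  cbind(round(cos(th), 4), round(sin(th), 4))
}

molblock_text <- function(mol, id = "", data = list()) {
  na <- n_atoms(mol); nb <- nrow(mol$bonds)
  xy <- .placeholder_coords(na)
  header <- c(id, "  qsarpipe          2D", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        xy[, 1], xy[, 2], 0, mol$atoms$elem)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                                mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
                else character(0)
  chg_idx <- which(mol$atoms$charge != 0L)
  chg_lines <- character(0)
  while (length(chg_idx)) {
    take <- chg_idx[seq_len(min(8, length(chg_idx)))]
    chg_idx <- chg_idx[-seq_len(min(8, length(chg_idx)))]
    chg_lines <- c(chg_lines,
                   paste0("M  CHG", sprintf("%3d", length(take)),
                          paste0(sprintf("%4d%4d", take,
                                         mol$atoms$charge[take]),
                                 collapse = "")))
  }
  props <- character(0)
  for (nm in names(data)) {
    props <- c(props, paste0(">  <", nm, ">"), as.character(data[[nm]]), "")
  }
  c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", props, "$$$$")
}

# serialize a list of records (see pipeline_io.R) to one SDF string
records_to_sdf_text <- function(records, with_pcc = TRUE) {
  unlist(lapply(records, function(r) {
    data <- list()
    if (with_pcc && !is.null(r$pcc) && !is.na(r$pcc)) data$pcc <- r$pcc
    molblock_text(r$mol, r$id, data)
  }))
}

# ---------------------------------------------------------------------------
# OpenBabel bridges (batched)
# ---------------------------------------------------------------------------

# run a function over OBMol handles for a vector of molblock-line records
ob_apply <- function(sdf_lines, f) {
  txt <- paste0(paste(sdf_lines, collapse = "\n"), "\n")
  ChemmineOB::forEachMol("SDF", txt, function(m) f(m))
}

# standard InChI for each record; tautomer-insensitive for mobile hydrogens
# on heteroatoms, which realizes tautomer-canonical duplicate identity
mol_inchi <- function(records) {
  if (!length(records)) return(character(0))
  sdf_lines <- records_to_sdf_text(records, with_pcc = FALSE)
  res <- ob_apply(sdf_lines, function(m) ChemmineOB::prop_OB(list(m))$InChI)
  out <- unlist(res)
  if (length(out) != length(records))
    stop("InChI generation dropped ", length(records) - length(out), " record(s)")
  out
}

# canonical SMILES (diagnostic/reporting only; identity uses InChI)
mol_cansmi <- function(records) {
  if (!length(records)) return(character(0))
  sdf_lines <- records_to_sdf_text(records, with_pcc = FALSE)
  unlist(ob_apply(sdf_lines, function(m) ChemmineOB::prop_OB(list(m))$cansmi))
}
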