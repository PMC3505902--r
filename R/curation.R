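# Multistep structure curation.
#
# The protocol is applied in a fixed printed order:
#   1 inorganics (no carbon)          2 mixtures (counter-ion stripping)
#   3 organometallics                 4 unsupported elements (Se, Te, ...)
#   5 chemotype standardization       6 duplicates (conflicting activities)
#   7 permanent charges
# with an optional final protonation step that ionizes strong acids and
# bases.  Every step emits an audit entry (input count, removed ids with
# reasons) and the whole report satisfies count conservation.

#' Curation configuration
#'
#' @param allowed_elements elements descriptors are defined for; everything
#'   outside this set (and not a metal, which step 3 removes first) is
#'   removed at step 4.
#' @param metal_elements element symbols treated as metals at step 3.
#' @param pcc_duplicate_tolerance maximum pairwise PCC difference within a
#'   duplicate group for the group to be collapsed to one entry rather than
#'   deleted outright.
#' @param charge_variant `"neutral"` keeps the standardized neutral forms;
#'   `"charged"` additionally ionizes strong acids and bases after step 7.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(allowed_elements = QP_ALLOWED_ELEMENTS,
                            metal_elements = QP_METALS,
                            pcc_duplicate_tolerance = 1e-6,
                            charge_variant = c("neutral", "charged")) {
  charge_variant <- match.arg(charge_variant)
  if (length(intersect(allowed_elements, metal_elements)))
    stop("allowed_elements and metal_elements must be disjoint")
  structure(list(allowed_elements = allowed_elements,
                 metal_elements = metal_elements,
                 pcc_duplicate_tolerance = pcc_duplicate_tolerance,
                 charge_variant = charge_variant),
            class = "curation_config")
}

.report_entry <- function(step, input_n, removed_ids, reasons) {
  list(step = step, input = input_n, removed = length(removed_ids),
       removed_ids = removed_ids, reasons = reasons)
}

.apply_removal <- function(records, step, drop, reasons) {
  ids <- vapply(records, `[[`, character(1), "id")
  entry <- .report_entry(step, length(records), ids[drop], reasons[drop])
  list(records = records[!drop], entry = entry)
}

#' @rdname run_curation
#' @export
remove_inorganics <- function(records) {
  drop <- !vapply(records, function(r) contains_carbon(r$mol), logical(1))
  .apply_removal(records, "remove_inorganics", drop,
                 rep("no carbon atom", length(records)))
}

#' @rdname run_curation
#' @export
resolve_mixtures <- function(records) {
  reasons <- rep("", length(records))
  drop <- logical(length(records))
  for (i in seq_along(records)) {
    mol <- records[[i]]$mol
    comp <- mol_components(mol)
    if (max(comp) == 1L) next
    has_c <- vapply(seq_len(max(comp)), function(k)
      any(mol$atoms$elem[comp == k] == "C"), logical(1))
    if (sum(has_c) == 1L) {
      keep <- which(comp == which(has_c))
      records[[i]]$mol <- perceive_aromaticity(mol_subset(mol, keep))
      records[[i]]$provenance <- c(records[[i]]$provenance,
                                   "mixture: stripped inorganic component(s)")
    } else {
      drop[i] <- TRUE
      reasons[i] <- if (sum(has_c) > 1L) "mixture of several organic components"
                    else "mixture without an organic component"
    }
  }
  .apply_removal(records, "resolve_mixtures", drop, reasons)
}

#' @rdname run_curation
#' @export
remove_organometallics <- function(records, config = curation_config()) {
  drop <- vapply(records, function(r)
    any(r$mol$atoms$elem %in% config$metal_elements), logical(1))
  .apply_removal(records, "remove_organometallics", drop,
                 rep("contains metal atom", length(records)))
}

#' @rdname run_curation
#' @export
remove_special_atoms <- function(records, config = curation_config()) {
  reasons <- vapply(records, function(r) {
    bad <- setdiff(unique(r$mol$atoms$elem), config$allowed_elements)
    if (length(bad)) paste("unsupported element(s):", paste(bad, collapse = ","))
    else ""
  }, character(1))
  .apply_removal(records, "remove_special_atoms", nzchar(reasons), reasons)
}

#' @rdname run_curation
#' @export
standardize_record <- function(record) {
  mol <- record$mol
  before <- mol$bonds$order
  mol <- normalize_functional_groups(mol)
  mol <- neutralize_charges(mol)
  mol <- recompute_hydrogens(mol)
  # charge/hydrogen adjustments cannot change ring aromaticity; only a bond
  # rewrite (nitro/azide normalization) forces re-perception
  if (!identical(before, mol$bonds$order)) mol <- perceive_aromaticity(mol)
  record$mol <- mol
  record
}

standardize_records <- function(records) {
  reasons <- rep("", length(records))
  for (i in seq_along(records)) {
    out <- tryCatch(standardize_record(records[[i]]), error = function(e) e)
    if (inherits(out, "error")) {
      reasons[i] <- paste("standardization failed:", conditionMessage(out))
    } else records[[i]] <- out
  }
  .apply_removal(records, "standardize", nzchar(reasons), reasons)
}

#' @rdname run_curation
#' @export
deduplicate <- function(records, tolerance = 1e-6) {
  if (!length(records))
    return(list(records = records,
                entry = .report_entry("deduplicate", 0L, character(0), character(0))))
  keys <- mol_inchi(records)
  pccs <- vapply(records, `[[`, numeric(1), "pcc")
  drop <- logical(length(records))
  reasons <- rep("", length(records))
  for (key in unique(keys[duplicated(keys)])) {
    grp <- which(keys == key)
    p <- pccs[grp]
    conflict <- if (all(is.na(p))) FALSE
                else if (any(is.na(p))) TRUE
                else diff(range(p)) > tolerance
    if (conflict) {
      drop[grp] <- TRUE
      reasons[grp] <- "duplicate structure with conflicting PCC values"
    } else {
      drop[grp[-1]] <- TRUE
      reasons[grp[-1]] <- "duplicate structure (identical PCC); first kept"
    }
  }
  .apply_removal(records, "deduplicate", drop, reasons)
}

#' @rdname run_curation
#' @export
remove_permanent_charges <- function(records) {
  drop <- vapply(records, function(r) net_charge(r$mol) != 0L, logical(1))
  .apply_removal(records, "remove_permanent_charges", drop,
                 rep("non-zero net formal charge", length(records)))
}

#' Ionize strong acids and bases
#'
#' Substructure-rule based: carboxylic, sulfonic, sulfinic,
#' sulfate/sulfamate and phosphonic/phosphate groups lose one proton each
#' (first ionization only for phosphorus/sulfur centers); basic nitrogens
#' (aliphatic amines, amidines, guanidines -- not amides, anilines or
#' aromatic ring nitrogens) gain one.  Other records pass unchanged.
#'
#' @param records list of curated (neutral) molecule records.
#' @return The records with adjusted protonation states.
#' @export
assign_charge_states <- function(records) {
  for (i in seq_along(records)) {
    mol <- records[[i]]$mol
    acid_o <- find_strong_acid_hydroxyls(mol)
    for (a in acid_o) {
      mol$atoms$charge[a] <- mol$atoms$charge[a] - 1L
      mol$atoms$nh[a] <- max(0L, mol$atoms$nh[a] - 1L)
    }
    base_n <- find_basic_nitrogens(mol)
    for (a in base_n) {
      mol$atoms$charge[a] <- mol$atoms$charge[a] + 1L
      mol$atoms$nh[a] <- mol$atoms$nh[a] + 1L
    }
    if (length(acid_o) || length(base_n)) {
      records[[i]]$mol <- mol
      records[[i]]$provenance <- c(records[[i]]$provenance,
                                   sprintf("charged: %d deprotonation(s), %d protonation(s)",
                                           length(acid_o), length(base_n)))
    }
  }
  records
}

#' Run the complete curation protocol
#'
#' Applies the seven cleaning steps in their fixed order, then (for
#' `charge_variant = "charged"`) the protonation step, and returns the
#' curated dataset together with a per-step audit report.
#'
#' @param records list of molecule records (see [read_structures()]).
#' @param config a [curation_config()].
#' @return List with elements `dataset` (a [qsar_dataset()]) and `report`
#'   (class `curation_report`: per-step entries plus final count).
#' @export
run_curation <- function(records, config = curation_config()) {
  steps <- list()
  s <- remove_inorganics(records);                steps <- c(steps, list(s$entry))
  s <- resolve_mixtures(s$records);               steps <- c(steps, list(s$entry))
  s <- remove_organometallics(s$records, config); steps <- c(steps, list(s$entry))
  s <- remove_special_atoms(s$records, config);   steps <- c(steps, list(s$entry))
  s <- standardize_records(s$records);            steps <- c(steps, list(s$entry))
  s <- deduplicate(s$records, config$pcc_duplicate_tolerance)
  steps <- c(steps, list(s$entry))
  s <- remove_permanent_charges(s$records);       steps <- c(steps, list(s$entry))
  records <- s$records
  if (config$charge_variant == "charged") records <- assign_charge_states(records)
  report <- structure(list(steps = steps,
                           initial = if (length(steps)) steps[[1]]$input else 0L,
                           final = length(records),
                           charge_variant = config$charge_variant),
                      class = "curation_report")
  list(dataset = qsar_dataset(records), report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report (", x$charge_variant, " variant)\n", sep = "")
  for (s in x$steps)
    cat(sprintf("  %-26s in %4d  removed %3d\n", s$step, s$input, s$removed))
  cat(sprintf("  final: %d compounds\n", x$final))
  invisible(x)
}

#' @export
as.data.frame.curation_report <- function(x, ...) {
  data.frame(step = vapply(x$steps, `[[`, character(1), "step"),
             input = vapply(x$steps, `[[`, integer(1), "input"),
             removed = vapply(x$steps, function(s) length(s$removed_ids), integer(1)))
}

# ---------------------------------------------------------------------------
# substructure rules (explicit graph predicates; no SMARTS engine)
# ---------------------------------------------------------------------------

# nitro N(=O)=O -> [N+](=O)[O-]; azide N=N=N -> N=[N+]=[N-]
normalize_functional_groups <- function(mol) {
  adj <- mol_adjacency(mol)
  at <- mol$atoms
  for (i in seq_len(n_atoms(mol))) {
    if (at$elem[i] != "N" || at$charge[i] != 0L) next
    dbl_o <- adj$nbr[[i]][adj$order[[i]] == 2 & at$elem[adj$nbr[[i]]] == "O" &
                            at$charge[adj$nbr[[i]]] == 0L]
    dbl_o <- dbl_o[vapply(dbl_o, function(o) length(adj$nbr[[o]]) == 1L, logical(1))]
    if (length(dbl_o) >= 2) {      # pentavalent nitro depiction
      o <- dbl_o[1]
      mol$atoms$charge[i] <- 1L
      mol$atoms$charge[o] <- -1L
      k <- which((mol$bonds$a1 == i & mol$bonds$a2 == o) |
                   (mol$bonds$a1 == o & mol$bonds$a2 == i))
      mol$bonds$order[k] <- 1L
      at <- mol$atoms
      next
    }
    dbl_n <- adj$nbr[[i]][adj$order[[i]] == 2 & at$elem[adj$nbr[[i]]] == "N"]
    if (length(dbl_n) >= 2) {      # pentavalent azide depiction: center N
      term <- dbl_n[vapply(dbl_n, function(x) length(adj$nbr[[x]]) == 1L, logical(1))]
      if (length(term)) {
        mol$atoms$charge[i] <- 1L
        mol$atoms$charge[term[1]] <- -1L
        at <- mol$atoms
      }
    }
  }
  mol
}

# Protonate anions / deprotonate protic cations, but only while that moves
# the net charge toward zero: balanced zwitterions (betaines, nitro groups,
# N-oxides) are left intact, and ylide-internal charges are additionally
# protected by the opposite-charge-neighbor guard.
neutralize_charges <- function(mol) {
  repeat {
    net <- net_charge(mol)
    if (net == 0L) break
    adj <- mol_adjacency(mol)
    at <- mol$atoms
    changed <- FALSE
    for (i in seq_len(n_atoms(mol))) {
      ch <- at$charge[i]
      nbr_charges <- at$charge[adj$nbr[[i]]]
      if (net < 0L && ch < 0L && at$elem[i] %in% c("O", "S", "N", "C")) {
        if (any(nbr_charges > 0L)) next
        mol$atoms$charge[i] <- ch + 1L
        mol$atoms$nh[i] <- mol$atoms$nh[i] + 1L
        changed <- TRUE
        break
      }
      if (net > 0L && ch > 0L && at$elem[i] %in% c("N", "S", "O") &&
          at$nh[i] >= 1L) {
        if (any(nbr_charges < 0L)) next
        mol$atoms$charge[i] <- ch - 1L
        mol$atoms$nh[i] <- mol$atoms$nh[i] - 1L
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  mol
}

# O-H oxygens of strong acid groups: O(H) single-bonded to C/S/P that carries
# at least one O double bond; one hydroxyl per acid center (first ionization)
find_strong_acid_hydroxyls <- function(mol) {
  adj <- mol_adjacency(mol)
  at <- mol$atoms
  centers_used <- integer(0)
  out <- integer(0)
  for (i in seq_len(n_atoms(mol))) {
    if (at$elem[i] != "O" || at$charge[i] != 0L || at$nh[i] < 1L) next
    if (length(adj$nbr[[i]]) != 1L || adj$order[[i]][1] != 1L) next
    x <- adj$nbr[[i]][1]
    if (!(at$elem[x] %in% c("C", "S", "P"))) next
    has_dbl_o <- any(adj$order[[x]] == 2 & at$elem[adj$nbr[[x]]] == "O")
    if (!has_dbl_o) next
    if (x %in% centers_used) next
    centers_used <- c(centers_used, x)
    out <- c(out, i)
  }
  out
}

# basic nitrogens: aliphatic amines (primary/secondary/tertiary sp3 N with no
# aromatic neighbor and no neighbor double-bonded to O/N/S, i.e. no amides),
# plus the imine nitrogen of amidines/guanidines
find_basic_nitrogens <- function(mol) {
  adj <- mol_adjacency(mol)
  at <- mol$atoms
  out <- integer(0)
  for (i in seq_len(n_atoms(mol))) {
    if (at$elem[i] != "N" || at$charge[i] != 0L || at$arom[i]) next
    nbrs <- adj$nbr[[i]]; ords <- adj$order[[i]]
    if (all(ords == 1L)) {
      if (length(nbrs) + at$nh[i] != 3L) next        # already quaternary etc.
      if (any(at$arom[nbrs])) next                   # aniline-type
      if (!all(at$elem[nbrs] == "C")) next           # hydrazines, hydroxylamines
      deactivated <- any(vapply(nbrs, function(c) {
        any(adj$order[[c]] == 2 & at$elem[adj$nbr[[c]]] %in% c("O", "N", "S"))
      }, logical(1)))
      if (deactivated) next                          # amide/amidine sp3 N
      out <- c(out, i)
    } else if (any(ords == 2L)) {
      c_at <- nbrs[ords == 2L][1]
      if (at$elem[c_at] != "C" || at$arom[c_at]) next
      other_n <- any(at$elem[adj$nbr[[c_at]]] == "N" &
                       adj$order[[c_at]] == 1L)
      if (other_n) out <- c(out, i)                  # amidine/guanidine =N
    }
  }
  out
}
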