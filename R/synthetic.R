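# Synthetic compound libraries with a known generative signal.
#
# Molecules are assembled from a seeded fragment grammar (aromatic and
# aliphatic scaffolds with up to three substituents) and deduplicated by
# InChI so every library member is structurally unique.  A continuous PCC
# value is then generated from three named descriptors -- fractional
# negative surface charge, hydrogen-bond-donor surface area and
# low-logP surface area -- with negative coefficients plus Gaussian noise,
# and the intercept is calibrated so a target fraction of the library falls
# at or below the substrate threshold.  Deliberately dirty records
# (inorganics, bad mixtures, salts, organometallics, unsupported elements,
# permanent ions, conflicting duplicates) can be appended, each annotated
# with its intended curation fate, so the curation protocol is testable
# record by record.

#' Descriptors carrying the generative signal in synthetic libraries
#'
#' The three descriptor names through which [generate_library()] injects
#' the class signal: fractional negative surface charge, donor surface
#' area and low-logP surface area.
#' @export
QP_SIGNAL_DESCRIPTORS <- c("PEOE_VSA_FNEG", "vsa_don", "SlogP_VSA0")

.QP_SCAFFOLDS <- list(
  function(s) paste0("c1cc", s[1], "cc", s[2], "c1", s[3]),
  function(s) paste0("c1cc", s[1], "c2cc", s[2], "cc", s[3], "c2c1"),
  function(s) paste0("c1cc", s[1], "nc", s[2], "c1", s[3]),
  function(s) paste0("CC", s[1], "CC", s[2], "C", s[3]),
  function(s) paste0("CCC", s[1], "CCC", s[2], "C", s[3]),
  function(s) paste0("C1CC", s[1], "CC", s[2], "C1", s[3]),
  function(s) paste0("c1cc", s[1], "ccc1CC", s[2], "C", s[3]),
  function(s) paste0("c1cc", s[1], "ccc1C1CC", s[2], "CC1", s[3])
)

.QP_SUBSTITUENTS <- c("Cl", "Br", "F", "O", "N", "C(=O)O", "S(=O)(=O)O",
                      "[N+](=O)[O-]", "SC", "C", "CC", "OC", "C(=O)N")

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a strongly imbalanced library in
#' which roughly 13% of clean compounds fall at or below PCC -0.25
#' (matching the 154/1204 substrate share), with the substrate class
#' enriched in fractional negative surface charge, donor surface area and
#' low-logP surface area through negative generative coefficients.
#'
#' @param n_compounds number of clean (unique, curatable) compounds.
#' @param seed integer seed; the whole library is a deterministic function
#'   of the configuration.
#' @param substrate_fraction target fraction with PCC at or below the
#'   threshold.
#' @param threshold PCC labelling threshold used for calibration.
#' @param beta generative coefficients (PCC scale per descriptor z-score)
#'   for `r paste(QP_SIGNAL_DESCRIPTORS, collapse = ", ")`; all negative.
#' @param noise_sd standard deviation of the Gaussian PCC noise.
#' @param dirty named integer vector of dirty-record counts; categories
#'   `inorganic`, `mixture`, `salt`, `organometallic`, `special_atom`,
#'   `permanent_ion`, `duplicate_conflict` (counted in pairs).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 2000L, seed = 1L,
                              substrate_fraction = 0.13,
                              threshold = -0.25,
                              beta = c(-0.15, -0.10, -0.08),
                              noise_sd = 0.15,
                              dirty = c(inorganic = 2L, mixture = 2L,
                                        salt = 1L, organometallic = 2L,
                                        special_atom = 1L, permanent_ion = 1L,
                                        duplicate_conflict = 1L)) {
  stopifnot(n_compounds > 0, noise_sd > 0,
            substrate_fraction > 0, substrate_fraction < 1,
            length(beta) == 3)
  structure(list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
                 substrate_fraction = substrate_fraction,
                 threshold = threshold, beta = beta, noise_sd = noise_sd,
                 dirty = dirty), class = "simulation_config")
}

# one random substituted scaffold SMILES
.random_smiles <- function(m) {
  scaf <- sample.int(length(.QP_SCAFFOLDS), m, replace = TRUE)
  nsub <- sample(0:3, m, replace = TRUE, prob = c(0.1, 0.35, 0.35, 0.2))
  vapply(seq_len(m), function(i) {
    s <- rep("", 3)
    if (nsub[i] > 0) {
      slots <- sample.int(3, nsub[i])
      subs <- sample(.QP_SUBSTITUENTS, nsub[i], replace = TRUE)
      s[slots] <- paste0("(", subs, ")")
    }
    # a trailing slot on the final ring-closure atom needs no parentheses
    .QP_SCAFFOLDS[[scaf[i]]](s)
  }, character(1))
}

# grow a pool of structurally unique records (InChI identity)
.grow_unique_library <- function(n) {
  records <- list()
  seen <- character(0)
  rounds <- 0L
  while (length(records) < n) {
    rounds <- rounds + 1L
    if (rounds > 12L)
      stop("could not generate ", n, " unique structures; the fragment ",
           "grammar is exhausted -- reduce n_compounds")
    m <- max(200L, ceiling((n - length(records)) * 1.6))
    smis <- .random_smiles(m)
    mols <- smiles_to_mols(smis)
    ok <- which(!vapply(mols, is.null, logical(1)))
    if (!length(ok)) next
    batch <- lapply(ok, function(i)
      new_record(sprintf("tmp%d", i), mols[[i]]))
    keys <- mol_inchi(batch)
    for (j in seq_along(batch)) {
      if (keys[j] %in% seen) next
      seen <- c(seen, keys[j])
      records[[length(records) + 1L]] <- batch[[j]]
      if (length(records) == n) break
    }
  }
  for (i in seq_along(records)) records[[i]]$id <- sprintf("SYN%05d", i)
  records
}

.DIRTY_TEMPLATES <- list(
  inorganic = list(smiles = c("OS(=O)(=O)O", "OP(=O)(O)O"),
                   fate = "remove:inorganic"),
  mixture = list(smiles = c("c1ccccc1.Cc1ccccc1", "CCO.OCC(O)CO"),
                 fate = "remove:mixture"),
  salt = list(smiles = c("NCC1(CC)CCCC1.Cl", "OC(c1ccccc1)c1ccccc1.Cl"),
              fate = "strip:salt"),
  organometallic = list(smiles = c("C[Hg]C", "C[Sn](C)(C)Cl"),
                        fate = "remove:organometallic"),
  special_atom = list(smiles = c("C[Se]C", "CC[As](C)C"),
                      fate = "remove:special_atom"),
  permanent_ion = list(smiles = c("C[N+](C)(C)C", "Cc1cc[n+](C)cc1"),
                       fate = "remove:permanent_charge"),
  duplicate_conflict = list(smiles = c("ClC(Cl)(Br)Br"),
                            fate = "remove:duplicate_conflict")
)

#' Generate annotated dirty fixture records
#'
#' @param config a [simulation_config()]; only the `dirty` counts are used.
#' @return List of records; attribute `truth` is a data frame with `id`,
#'   `category` and `expected_fate` per record (conflicting duplicates are
#'   emitted as pairs whose PCC values differ by far more than any
#'   deduplication tolerance).
#' @export
make_dirty_fixtures <- function(config = simulation_config()) {
  counts <- config$dirty
  records <- list()
  truth <- list()
  add <- function(smi, id, cat, fate, pcc) {
    mol <- smiles_to_mols(smi)[[1]]
    if (is.null(mol)) stop("internal dirty template failed to parse: ", smi)
    r <- new_record(id, mol, pcc)
    records[[length(records) + 1L]] <<- r
    truth[[length(truth) + 1L]] <<- data.frame(id = id, category = cat,
                                               expected_fate = fate)
  }
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (is.na(k) || k < 1) next
    tmpl <- .DIRTY_TEMPLATES[[cat]]
    if (is.null(tmpl)) stop("unknown dirty category: ", cat)
    for (i in seq_len(k)) {
      smi <- tmpl$smiles[((i - 1) %% length(tmpl$smiles)) + 1]
      if (cat == "duplicate_conflict") {
        add(smi, sprintf("DIRTY_%s_%da", cat, i), cat, tmpl$fate, -0.40)
        add(smi, sprintf("DIRTY_%s_%db", cat, i), cat, tmpl$fate, -0.10)
      } else {
        add(smi, sprintf("DIRTY_%s_%d", cat, i), cat, tmpl$fate, -0.05 * i)
      }
    }
  }
  attr(records, "truth") <- if (length(truth)) do.call(rbind, truth)
                            else data.frame(id = character(0),
                                            category = character(0),
                                            expected_fate = character(0))
  records
}

#' Generate a synthetic compound library with activities
#'
#' Writes three files to `out_dir`: `structures.sdf` (clean compounds plus
#' dirty records), `activity.csv` (`id,pcc`) and `truth.json` (generative
#' coefficients, calibrated intercept, signal descriptor names, per-record
#' dirty fates and the substrate fraction achieved).  Identical
#' configurations produce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the file paths, the clean records, their
#'   descriptor matrix, the generated PCC values and the truth list.
#' @export
generate_library <- function(config = simulation_config(),
                             out_dir = tempfile("qsarlib")) {
  old <- if (exists(".Random.seed", envir = globalenv()))
           get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  records <- .grow_unique_library(config$n_compounds)
  X <- descriptor_matrix(records, panel = "core")
  Z <- zscore(X[, QP_SIGNAL_DESCRIPTORS, drop = FALSE])$X
  lin <- as.numeric(Z %*% config$beta)
  eps <- stats::rnorm(length(records), 0, config$noise_sd)
  raw <- lin + eps
  beta0 <- config$threshold -
    stats::quantile(raw, config$substrate_fraction, names = FALSE, type = 1)
  pcc <- pmin(1, pmax(-1, beta0 + raw))
  achieved <- mean(pcc <= config$threshold)
  if (abs(achieved - config$substrate_fraction) > 0.02)
    stop(sprintf(paste0("calibration failed: achieved substrate fraction ",
                        "%.3f vs target %.3f; increase n_compounds or ",
                        "noise_sd"), achieved, config$substrate_fraction))
  for (i in seq_along(records)) records[[i]]$pcc <- pcc[i]

  dirty <- make_dirty_fixtures(config)
  truth_dirty <- attr(dirty, "truth")
  all_records <- c(records, dirty)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sdf_path <- file.path(out_dir, "structures.sdf")
  csv_path <- file.path(out_dir, "activity.csv")
  truth_path <- file.path(out_dir, "truth.json")
  writeLines(unlist(lapply(all_records, function(r)
    molblock_text(r$mol, r$id))), sdf_path)
  utils::write.csv(
    data.frame(id = vapply(all_records, `[[`, character(1), "id"),
               pcc = sprintf("%.10f", vapply(all_records, `[[`,
                                             numeric(1), "pcc"))),
    csv_path, row.names = FALSE, quote = FALSE)
  truth <- list(seed = config$seed, n_clean = length(records),
                beta = config$beta, beta0 = beta0,
                noise_sd = config$noise_sd,
                signal_descriptors = QP_SIGNAL_DESCRIPTORS,
                threshold = config$threshold,
                substrate_fraction_achieved = achieved,
                dirty_records = truth_dirty)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(structures = sdf_path, activity = csv_path,
                 truth_file = truth_path, records = records,
                 descriptors = X, pcc = pcc, truth = truth))
}
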