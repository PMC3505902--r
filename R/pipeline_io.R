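# Reading and writing the formats the pipeline touches: SD files (V2000),
# SMILES lists, and id/activity CSV tables.
#
# A "record" is a list with elements
#   id         compound identifier (e.g. an NSC number), non-empty string
#   mol        qp_mol molecular graph
#   pcc        Pearson correlation coefficient in [-1, 1], or NA
#   provenance character vector of curation-step annotations
# Datasets bundle records with an optional PCC labelling.

new_record <- function(id, mol, pcc = NA_real_, provenance = character(0)) {
  structure(list(id = as.character(id), mol = mol, pcc = pcc,
                 provenance = provenance), class = "qp_record")
}

#' @export
print.qp_record <- function(x, ...) {
  cat(sprintf("<record %s: %s, pcc=%s>\n", x$id, mol_formula(x$mol),
              ifelse(is.na(x$pcc), "NA", format(x$pcc))))
  invisible(x)
}

#' Bundle curated records into a dataset
#'
#' @param records list of molecule records as returned by
#'   [read_structures()] or [run_curation()].
#' @param label_threshold PCC cutoff used to label the records, or `NULL`
#'   if the dataset is unlabeled.
#' @param labels factor with levels `c("substrate", "non-substrate")`,
#'   aligned 1:1 with `records`, or `NULL`.
#' @return An object of class `qsar_dataset`.
#' @export
qsar_dataset <- function(records, label_threshold = NULL, labels = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids in dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(labels)) {
    if (length(labels) != length(records))
      stop("labels must align 1:1 with records")
    labels <- factor(as.character(labels),
                     levels = c("substrate", "non-substrate"))
  }
  structure(list(records = records, label_threshold = label_threshold,
                 labels = labels), class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset: %d compounds%s>\n", length(x$records),
              if (!is.null(x$labels))
                sprintf(", %d substrates / %d non-substrates (PCC <= %g)",
                        sum(x$labels == "substrate"),
                        sum(x$labels == "non-substrate"),
                        x$label_threshold)
              else ""))
  invisible(x)
}

#' @export
length.qsar_dataset <- function(x) length(x$records)

dataset_ids <- function(ds) vapply(ds$records, `[[`, character(1), "id")
dataset_pcc <- function(ds) vapply(ds$records, `[[`, numeric(1), "pcc")

#' @export
as.data.frame.qsar_dataset <- function(x, ...) {
  df <- data.frame(id = dataset_ids(x), pcc = dataset_pcc(x),
                   stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$label <- as.character(x$labels)
  df
}

# ---------------------------------------------------------------------------
# structure input
# ---------------------------------------------------------------------------

#' Read chemical structures from an SD file or a SMILES list
#'
#' SD files must use V2000 connection tables; V3000 input is rejected.
#' SMILES files carry one record per line, `SMILES[<whitespace>ID]`.
#' Records that cannot be parsed are skipped, not fatal: the returned list
#' carries a `skipped` attribute (data frame of record index and reason) and
#' a message reports the skip count.
#'
#' @param path input file.
#' @param format `"sdf"` or `"smiles"`.
#' @return List of molecule records; attribute `skipped` describes records
#'   that failed to parse.
#' @export
read_structures <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  records <- switch(format,
                    sdf = .read_sdf(path),
                    smiles = .read_smiles(path))
  skipped <- attr(records, "skipped")
  if (nrow(skipped))
    message(nrow(skipped), " record(s) skipped while reading ", path)
  if (!length(records)) stop("no parseable records in ", path)
  records
}

.read_sdf <- function(path) {
  blocks <- ChemmineR::sdfstr2list(ChemmineR::read.SDFstr(path))
  records <- list()
  skipped <- list()
  seen_ids <- character(0)
  for (k in seq_along(blocks)) {
    lines <- blocks[[k]]
    mol <- tryCatch(parse_molblock(lines), error = function(e) {
      if (grepl("V3000", conditionMessage(e))) stop(e)
      NULL
    })
    if (is.null(mol)) {
      skipped[[length(skipped) + 1L]] <- data.frame(index = k,
                                                    reason = "unparseable molblock")
      next
    }
    mol <- perceive_aromaticity(mol)
    id <- trimws(lines[1])
    if (id == "" || id %in% seen_ids) id <- .unique_id(id, k, seen_ids)
    seen_ids <- c(seen_ids, id)
    pcc <- .sdf_field(lines, "pcc")
    records[[length(records) + 1L]] <- new_record(id, mol, pcc)
  }
  attr(records, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                              else data.frame(index = integer(0), reason = character(0))
  records
}

.unique_id <- function(id, k, seen) {
  base <- if (id == "") sprintf("mol%d", k) else id
  cand <- base
  n <- 1L
  while (cand %in% seen) { n <- n + 1L; cand <- sprintf("%s.%d", base, n) }
  cand
}

.sdf_field <- function(lines, name) {
  hit <- grep(paste0("^> *<", name, ">"), lines)
  if (!length(hit) || hit[1] + 1 > length(lines)) return(NA_real_)
  suppressWarnings(as.numeric(trimws(lines[hit[1] + 1])))
}

.read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no parseable records in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(toks, `[[`, character(1), 1)
  ids <- vapply(seq_along(toks), function(i) {
    if (length(toks[[i]]) >= 2) toks[[i]][[2]] else sprintf("mol%d", i)
  }, character(1))
  mols <- smiles_to_mols(smi)
  ok <- !vapply(mols, is.null, logical(1))
  records <- mapply(function(m, id) new_record(id, m), mols[ok], ids[ok],
                    SIMPLIFY = FALSE)
  attr(records, "skipped") <-
    data.frame(index = which(!ok),
               reason = rep("unparseable SMILES", sum(!ok)))
  records
}

# batch SMILES -> qp_mol via OpenBabel (kekulized V2000 round-trip);
# falls back to per-line conversion to localize failures
smiles_to_mols <- function(smiles) {
  n <- length(smiles)
  if (!n) return(list())
  input <- paste0(paste(smiles, "\t", sprintf("m%d", seq_len(n))), collapse = "\n")
  sdftxt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(input, "\n"),
                              options = data.frame(names = character(0),
                                                   args = character(0))),
    error = function(e) "")
  blocks <- .split_sdf_text(sdftxt)
  if (length(blocks) == n) {
    return(lapply(blocks, function(b) {
      m <- parse_molblock(b)
      if (!is.null(m)) perceive_aromaticity(m) else NULL
    }))
  }
  # one or more entries failed inside the batch: retry one by one
  lapply(seq_len(n), function(i) {
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles[i], "\tm\n"),
                                options = data.frame(names = character(0),
                                                     args = character(0))),
      error = function(e) "")
    b <- .split_sdf_text(txt)
    if (length(b) != 1) return(NULL)
    m <- parse_molblock(b[[1]])
    if (!is.null(m)) perceive_aromaticity(m) else NULL
  })
}

.split_sdf_text <- function(txt) {
  if (!nzchar(txt)) return(list())
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, head(ends, -1) + 1L)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

# ---------------------------------------------------------------------------
# activity joining
# ---------------------------------------------------------------------------

#' Join a PCC activity table onto structure records
#'
#' The table must be a CSV with a header and columns `id,pcc`; ids are
#' matched as exact strings.  Unmatched ids on either side are reported in
#' the `diagnostics` attribute of the result (mirroring the source archive,
#' where some listed compounds have no structure).
#'
#' @param records list of molecule records.
#' @param table path to the activity CSV.
#' @return The records, with `pcc` filled in where ids match; attribute
#'   `diagnostics` lists `unmatched_record_ids` and `unmatched_table_ids`.
#' @export
join_activity <- function(records, table) {
  tab <- utils::read.csv(table, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "pcc") %in% names(tab)))
    stop("activity table must have columns 'id' and 'pcc'")
  pcc <- suppressWarnings(as.numeric(tab$pcc))
  bad <- which(is.na(pcc) & nzchar(trimws(tab$pcc)))
  if (length(bad))
    stop("non-numeric pcc value in activity table at row(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicated id(s) in activity table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  ids <- vapply(records, `[[`, character(1), "id")
  m <- match(ids, tab$id)
  for (i in seq_along(records)) {
    if (!is.na(m[i])) records[[i]]$pcc <- pcc[m[i]]
  }
  attr(records, "diagnostics") <- list(
    unmatched_record_ids = ids[is.na(m)],
    unmatched_table_ids = setdiff(tab$id, ids))
  records
}

# ---------------------------------------------------------------------------
# output
# ---------------------------------------------------------------------------

#' Write a dataset to an SD file or CSV
#'
#' SDF output stores the structure, the `pcc` value and (when the dataset is
#' labeled) the class label as data fields; CSV output has columns
#' `id,pcc[,label]`.  Both round-trip: reading the file back preserves ids,
#' formulas, formal charges and PCC values.
#'
#' @param ds a [qsar_dataset()] (or a bare list of records).
#' @param path output file.
#' @param format `"sdf"` or `"csv"`.
#' @export
write_dataset <- function(ds, path, format = c("sdf", "csv")) {
  format <- match.arg(format)
  if (!inherits(ds, "qsar_dataset")) ds <- qsar_dataset(ds)
  if (!length(ds$records)) stop("cannot write an empty dataset")
  if (format == "csv") {
    utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  lines <- unlist(lapply(seq_along(ds$records), function(i) {
    r <- ds$records[[i]]
    data <- list()
    if (!is.na(r$pcc)) data$pcc <- format(r$pcc, digits = 15)
    if (!is.null(ds$labels)) data$label <- as.character(ds$labels[i])
    molblock_text(r$mol, r$id, data)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
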