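# MACCS structural keys (166 public key definitions, via OpenBabel's
# implementation of the key set) and the Tanimoto coefficient.

#' MACCS structural-key fingerprints
#'
#' @param records list of molecule records (or a [qsar_dataset()]).
#' @return Logical matrix with one row per record and 166 key columns.
#' @export
maccs_keys <- function(records) {
  if (inherits(records, "qsar_dataset")) records <- records$records
  if (!length(records))
    return(matrix(logical(0), nrow = 0, ncol = 166))
  sdf_lines <- records_to_sdf_text(records, with_pcc = FALSE)
  res <- ob_apply(sdf_lines, function(m)
    ChemmineOB::fingerprint_OB(list(m), "MACCS"))
  if (length(res) != length(records))
    stop("fingerprint generation dropped ",
         length(records) - length(res), " record(s)")
  fp <- do.call(rbind, lapply(res, function(v) as.logical(v[seq_len(166)])))
  rownames(fp) <- vapply(records, `[[`, character(1), "id")
  fp
}

#' Tanimoto similarity between two bit vectors
#'
#' Defined as |A intersect B| / |A union B|; two empty fingerprints are
#' defined as identical (similarity 1).
#'
#' @param a,b logical vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints have different lengths: ", length(a), " vs ", length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

# all-pairs Tanimoto similarity for a logical fingerprint matrix
tanimoto_matrix <- function(fp) {
  m <- fp * 1L
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  uni <- outer(pop, pop, "+") - inter
  s <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  s[uni == 0] <- 1
  s
}

# continuous Tanimoto on real-valued non-negative vectors (rows of X):
# <a,b> / (|a|^2 + |b|^2 - <a,b>); identical zero vectors give 1
continuous_tanimoto_matrix <- function(X) {
  ip <- tcrossprod(X)
  sq <- rowSums(X^2)
  den <- outer(sq, sq, "+") - ip
  s <- ifelse(den <= 0, 1, ip / ifelse(den <= 0, 1, den))
  s
}
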