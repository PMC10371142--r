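# Descriptor battery and paired SPPO:OP featurization.
#
# The battery is the toolkit's full 2D descriptor list (version-pinned via
# chem_toolkit_version()) plus an oxime-group count, since the reactivation
# chemistry hinges on the nucleophilic C=N-OH group. Descriptor failures are
# errors, never silent NaN.

#' Names of the descriptor battery
#'
#' @return Character vector of descriptor names in their fixed, toolkit-pinned
#'   order. Includes TPSA, MolLogP, MolWt, NumHDonors,
#'   NumAromaticHeterocycles, qed (quantitative drug-likeness estimate) and
#'   NumOximeGroups.
#' @export
descriptor_names <- function() {
  if (is.null(the$descriptor_names)) {
    res <- chem_call("descriptor_names")
    the$descriptor_names <- vapply(res$names, identity, character(1))
  }
  the$descriptor_names
}

#' Compute the 2D descriptor battery for a set of molecules
#'
#' @param smiles Character vector of SMILES (or a compound `data.frame` from
#'   [compound_records()], whose `id` column then names the rows).
#' @return A numeric matrix, one row per molecule, columns in
#'   [descriptor_names()] order. All values finite; a non-finite descriptor or
#'   unparseable molecule is an error naming both.
#' @export
descriptor_matrix <- function(smiles) {
  ids <- NULL
  if (is.data.frame(smiles)) {
    ids <- smiles$id
    smiles <- smiles$smiles
  }
  stopifnot(is.character(smiles), length(smiles) > 0L)
  # descriptors are computed on the canonical form: a few battery members
  # depend on float summation order over atoms, so canonicalizing first makes
  # the vector bit-identical across SMILES spellings of the same molecule
  canon <- canonical_smiles(smiles, strict = FALSE)
  query <- ifelse(is.na(canon), smiles, canon)
  res <- chem_call("descriptors", list(smiles = as.list(unname(query))))
  if (length(res$errors)) {
    msgs <- vapply(res$errors, function(e) {
      paste0("molecule ", e$index, " (", e$smiles, "): ", e$message)
    }, character(1))
    stop("descriptor computation failed:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  names <- vapply(res$names, identity, character(1))
  mat <- do.call(rbind, lapply(res$rows, function(r) {
    vapply(r, as.numeric, numeric(1))
  }))
  colnames(mat) <- names
  rownames(mat) <- if (is.null(ids)) smiles else ids
  mat
}

#' Compute descriptors for a single molecule
#'
#' @param smiles One SMILES string.
#' @return Named numeric vector over the full battery.
#' @examples
#' \dontrun{compute_descriptors("C")[["MolWt"]]  # 16.043}
#' @export
compute_descriptors <- function(smiles) {
  if (is.data.frame(smiles)) {
    stopifnot(nrow(smiles) == 1L)
    smiles <- smiles$smiles
  }
  stopifnot(length(smiles) == 1L)
  descriptor_matrix(smiles)[1L, ]
}

#' Concatenate reactivator and challenge descriptors into a pair vector
#'
#' Pair features are the SPPO battery followed by the OP battery, names
#' prefixed `sppo__` / `op__` so downstream feature-importance reports
#' attribute each descriptor unambiguously.
#'
#' @param sppo,op Named numeric descriptor vectors over the same battery.
#' @return Named numeric vector of length `2 * length(sppo)`.
#' @export
build_pair_features <- function(sppo, op) {
  if (!identical(names(sppo), names(op))) {
    stop("sppo and op descriptor batteries do not match", call. = FALSE)
  }
  out <- c(sppo, op)
  names(out) <- c(paste0("sppo__", names(sppo)), paste0("op__", names(op)))
  out
}

#' Pair-feature matrix for many (SPPO, OP) rows
#'
#' @param sppo_mat,op_mat Descriptor matrices (rows indexed by compound id).
#' @param sppo_ids,op_ids Equal-length id vectors selecting one row of each
#'   matrix per pair.
#' @return Numeric matrix with one row per pair (rownames
#'   `"<sppo>:<op>"`) and `2 * ncol(sppo_mat)` prefixed columns.
#' @export
pair_feature_matrix <- function(sppo_mat, op_mat, sppo_ids, op_ids) {
  stopifnot(length(sppo_ids) == length(op_ids),
            identical(colnames(sppo_mat), colnames(op_mat)))
  miss_s <- setdiff(sppo_ids, rownames(sppo_mat))
  miss_o <- setdiff(op_ids, rownames(op_mat))
  if (length(miss_s) || length(miss_o)) {
    stop("unresolvable id(s): ",
         paste(c(miss_s, miss_o), collapse = ", "), call. = FALSE)
  }
  out <- cbind(sppo_mat[sppo_ids, , drop = FALSE],
               op_mat[op_ids, , drop = FALSE])
  colnames(out) <- c(paste0("sppo__", colnames(sppo_mat)),
                     paste0("op__", colnames(op_mat)))
  rownames(out) <- paste0(sppo_ids, ":", op_ids)
  out
}
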