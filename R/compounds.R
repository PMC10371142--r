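# Compound records: the minimal structure table every module consumes.
# A compound record set is a plain data.frame with columns
# id, smiles (canonical), role ("SPPO", "OP" or "UNKNOWN") and name.

COMPOUND_ROLES <- c("SPPO", "OP", "UNKNOWN")

#' Build a validated compound table
#'
#' @param id Character vector of unique identifiers.
#' @param smiles SMILES strings; canonicalized on construction, unparseable
#'   entries are an error naming the offending rows.
#' @param role One of `"SPPO"`, `"OP"`, `"UNKNOWN"` (recycled).
#' @param name Optional free-text names (recycled).
#' @return A `data.frame` with columns `id`, `smiles`, `role`, `name`.
#' @export
compound_records <- function(id, smiles, role = "UNKNOWN", name = NA_character_) {
  stopifnot(length(id) == length(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate compound ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  role <- rep_len(as.character(role), length(id))
  if (!all(role %in% COMPOUND_ROLES)) {
    stop("role must be one of ", paste(COMPOUND_ROLES, collapse = ", "),
         call. = FALSE)
  }
  canon <- canonical_smiles(as.character(smiles), strict = FALSE)
  if (anyNA(canon)) {
    bad <- which(is.na(canon))
    stop("unparseable SMILES for id(s) ",
         paste(id[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), "): ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(id = id, smiles = canon, role = role,
             name = rep_len(as.character(name), length(id)),
             stringsAsFactors = FALSE)
}

#' Read compound structures from CSV or SDF
#'
#' CSV files may carry a header row with columns `id,smiles[,role,name]`
#' (any order), or be headerless `smiles[,name]` pairs, in which case ids
#' `cmpd_1..cmpd_n` are assigned. SDF records take their id from the molecule
#' title block (or `sdf_1..` when untitled).
#'
#' @param path File to read.
#' @param format `"csv"` or `"sdf"`; guessed from the extension by default.
#' @param role Role assigned when the file carries none.
#' @return A compound `data.frame` (see [compound_records()]).
#' @export
read_compounds <- function(path, format = c("auto", "csv", "sdf"),
                           role = "UNKNOWN") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  if (format == "sdf") {
    res <- chem_call("sdf_read",
                     list(sdf_text = paste(readLines(path, warn = FALSE),
                                           collapse = "\n")))
    if (length(res$errors)) {
      bad <- vapply(res$errors, function(e) e$index, numeric(1))
      stop("unparseable SDF record(s) at position(s) ",
           paste(bad, collapse = ", "), " in ", path, call. = FALSE)
    }
    if (!length(res$records)) stop("no valid molecules in ", path,
                                   call. = FALSE)
    nm <- vapply(res$records, function(r) r$name, character(1))
    ids <- ifelse(nzchar(nm), nm,
                  paste0("sdf_", vapply(res$records, function(r) r$index,
                                        numeric(1))))
    return(compound_records(ids,
                            vapply(res$records, function(r) r$smiles,
                                   character(1)),
                            role = role, name = ifelse(nzchar(nm), nm, NA)))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("(^|,)\\s*\"?smiles\"?\\s*(,|$)", tolower(first))
  if (has_header) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("CSV lacks a smiles column",
                                       call. = FALSE)
    if (!nrow(df)) stop("no valid molecules in ", path, call. = FALSE)
    id <- if ("id" %in% names(df)) df$id else paste0("cmpd_", seq_len(nrow(df)))
    rl <- if ("role" %in% names(df)) df$role else role
    nm <- if ("name" %in% names(df)) df$name else NA_character_
    compound_records(id, df$smiles, role = rl, name = nm)
  } else {
    df <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    if (!nrow(df)) stop("no valid molecules in ", path, call. = FALSE)
    nm <- if (ncol(df) >= 2L) as.character(df[[2L]]) else NA_character_
    compound_records(paste0("cmpd_", seq_len(nrow(df))), df[[1L]],
                     role = role, name = nm)
  }
}

#' The five-organophosphate challenge panel
#'
#' Structures of the panel the reactivation screen targets: PIMP and NEMP
#' (sarin and VX surrogates), paraoxon (PXN, the active metabolite of
#' parathion), DFP, and GV (2-[dimethylamino(fluoro)phosphoryl]oxy-N,N-
#' dimethylethanamine — prediction-only, no assay data exists for it).
#' Shipped as `inst/extdata/op_panel.csv`.
#'
#' @param ids Optional subset of panel ids to return.
#' @return A compound `data.frame` with `role == "OP"`.
#' @export
op_panel <- function(ids = NULL) {
  path <- system.file("extdata", "op_panel.csv", package = "oximescreen")
  ops <- read_compounds(path, format = "csv")
  if (!is.null(ids)) {
    miss <- setdiff(ids, ops$id)
    if (length(miss)) stop("unknown OP id(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    ops <- ops[match(ids, ops$id), , drop = FALSE]
  }
  ops
}
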