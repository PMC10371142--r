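# Task layers over the classifier core: reactivation class binning and
# SPPO:OP pair-dataset assembly; logBB thresholding and BBB dataset assembly.

REACTIVATION_CLASSES <- c("No", "Low", "High")
BBB_CLASSES <- c("BBB-", "BBB+")

#' Bin percent reactivation into No / Low / High
#'
#' In vitro percent reactivation is discretized as: roughly zero (within
#' `zero_tolerance` of 0) is *No* reactivation, up to and including 40% is
#' *Low*, strictly above 40% is *High*. The 40% cutoff reflects where overt
#' protective effects appear in vivo. Small negative values (assay noise when
#' reactivated activity sits below the inhibited baseline) are accepted down
#' to -10% and binned *No* when within tolerance.
#'
#' @param percent Numeric vector of percent reactivation, in [-10, 110].
#' @param zero_tolerance Half-width of the "approximately zero" band, in
#'   percentage points (default 0.5).
#' @return Ordered factor with levels `No < Low < High`.
#' @export
bin_reactivation <- function(percent, zero_tolerance = 0.5) {
  stopifnot(is.numeric(percent), zero_tolerance >= 0)
  if (anyNA(percent) || any(percent < -10 | percent > 110)) {
    bad <- which(is.na(percent) | percent < -10 | percent > 110)
    stop("reactivation percent out of the assay range [-10, 110] at ",
         "position(s) ", paste(head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  cls <- ifelse(abs(percent) <= zero_tolerance, "No",
                ifelse(percent <= 40, "Low", "High"))
  # negative values beyond tolerance are not interpretable as reactivation
  neg <- which(percent < -zero_tolerance)
  if (length(neg)) {
    stop("negative reactivation beyond zero_tolerance at position(s) ",
         paste(head(neg, 10), collapse = ", "), call. = FALSE)
  }
  factor(cls, levels = REACTIVATION_CLASSES, ordered = TRUE)
}

#' Bin logBB into BBB+ / BBB-
#'
#' @param logbb Numeric log10 brain-to-blood concentration ratios (finite).
#' @param threshold Decision threshold (default 0). Values strictly above it
#'   are `BBB+`; the boundary itself is assigned `BBB-` (no brain penetration
#'   is claimed on a tie).
#' @return Factor with levels `BBB-`, `BBB+`.
#' @export
bin_logbb <- function(logbb, threshold = 0) {
  stopifnot(is.numeric(logbb))
  if (anyNA(logbb) || any(!is.finite(logbb))) {
    stop("logBB must be finite", call. = FALSE)
  }
  factor(ifelse(logbb > threshold, "BBB+", "BBB-"), levels = BBB_CLASSES)
}

#' Read a reactivation measurement table
#'
#' Expects CSV columns `sppo_id`, `op_id`, `reactivation_percent` (plus an
#' optional `replicate` column, in which case replicate rows of the same
#' pairing are averaged with the arithmetic mean).
#'
#' @param path CSV file.
#' @return A `data.frame` of one row per (sppo_id, op_id, value-set) pairing.
#' @export
read_reactivation_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sppo_id", "op_id", "reactivation_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measurement table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if ("replicate" %in% names(df)) {
    df <- stats::aggregate(reactivation_percent ~ sppo_id + op_id, df, mean)
  }
  df[, need]
}

#' Assemble the labeled SPPO:OP pair dataset
#'
#' Joins each measurement to its SPPO and OP structures, computes paired
#' descriptors, variance-filters and min-max scales them, and bins the
#' percent reactivation into classes. One labeled sample per measurement row.
#'
#' @param measurements `data.frame` with `sppo_id`, `op_id`,
#'   `reactivation_percent` (see [read_reactivation_measurements()]).
#' @param sppos,ops Compound `data.frame`s resolving the ids.
#' @param zero_tolerance Passed to [bin_reactivation()].
#' @param variance_threshold Passed to [variance_filter()] (applied to the
#'   per-chemical descriptor table before pairing and scaling).
#' @param scale Min-max scale the pair features over all assembled rows
#'   (default `TRUE`). For leakage-free evaluation, pass `FALSE` and scale
#'   with [minmax_scale()] fit on the training partition.
#' @return List with `features` (a `feature_table` over pair rows
#'   `"<sppo>:<op>"`), `labels` (ordered factor), `measurements` (the joined
#'   rows incl. `pair_id` and `class`), and `tally` (class counts).
#' @export
assemble_reactivation_dataset <- function(measurements, sppos, ops,
                                          zero_tolerance = 0.5,
                                          variance_threshold = 0,
                                          scale = TRUE) {
  need <- c("sppo_id", "op_id", "reactivation_percent")
  stopifnot(all(need %in% names(measurements)))
  if (!nrow(measurements)) stop("empty measurement table", call. = FALSE)
  miss_s <- setdiff(measurements$sppo_id, sppos$id)
  miss_o <- setdiff(measurements$op_id, ops$id)
  if (length(miss_s) || length(miss_o)) {
    stop("unresolvable id(s): ",
         paste(head(c(miss_s, miss_o), 10), collapse = ", "), call. = FALSE)
  }
  pair_id <- paste0(measurements$sppo_id, ":", measurements$op_id)
  dup <- duplicated(pair_id)
  if (any(dup)) {
    classes <- bin_reactivation(measurements$reactivation_percent,
                                zero_tolerance)
    conflicts <- unique(pair_id[dup][vapply(pair_id[dup], function(p) {
      length(unique(classes[pair_id == p])) > 1L
    }, logical(1))])
    if (length(conflicts)) {
      stop("duplicate pairings with conflicting classes: ",
           paste(head(conflicts, 10), collapse = ", "), call. = FALSE)
    }
    keep <- !dup
    measurements <- measurements[keep, , drop = FALSE]
    pair_id <- pair_id[keep]
  }
  labels <- bin_reactivation(measurements$reactivation_percent,
                             zero_tolerance)

  # per-chemical battery, variance-filtered once across SPPOs and OPs so
  # both halves of the pair vector share one surviving-descriptor set
  used_s <- sppos[sppos$id %in% measurements$sppo_id, , drop = FALSE]
  used_o <- ops[ops$id %in% measurements$op_id, , drop = FALSE]
  chem <- descriptor_matrix(rbind(used_s, used_o))
  chem_ft <- variance_filter(feature_table(chem), variance_threshold)
  kept <- colnames(chem_ft$matrix)
  pairs <- pair_feature_matrix(chem_ft$matrix[used_s$id, , drop = FALSE],
                               chem_ft$matrix[used_o$id, , drop = FALSE],
                               measurements$sppo_id, measurements$op_id)
  rownames(pairs) <- pair_id
  ft <- feature_table(pairs, dropped_columns = chem_ft$dropped_columns)
  if (scale) ft <- minmax_scale(ft)
  measurements$pair_id <- pair_id
  measurements$class <- as.character(labels)
  list(features = ft, labels = labels, measurements = measurements,
       tally = table(labels), per_chemical_columns = kept)
}

#' Assemble the labeled BBB permeability dataset
#'
#' @param data `data.frame` with compound ids, SMILES and measured logBB.
#'   Column names are mapped via `columns` so published regression tables can
#'   be ingested as-is.
#' @param threshold logBB decision threshold (default 0).
#' @param columns Named mapping `c(id=, smiles=, logbb=)` to the table's
#'   column names.
#' @param variance_threshold,scale As in [assemble_reactivation_dataset()].
#' @return List with `features` (a `feature_table`), `labels` (factor
#'   `BBB-`/`BBB+`), `table` (with `class`), and `tally`.
#' @export
assemble_bbb_dataset <- function(data, threshold = 0,
                                 columns = c(id = "compound_id",
                                             smiles = "smiles",
                                             logbb = "logBB"),
                                 variance_threshold = 0, scale = TRUE) {
  miss <- setdiff(unname(columns), names(data))
  if (length(miss)) stop("BBB table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(data)) stop("empty BBB table", call. = FALSE)
  cmp <- compound_records(data[[columns[["id"]]]],
                          data[[columns[["smiles"]]]])
  labels <- bin_logbb(data[[columns[["logbb"]]]], threshold)
  chem <- descriptor_matrix(cmp)
  ft <- variance_filter(feature_table(chem), variance_threshold)
  if (scale) ft <- minmax_scale(ft)
  out <- data.frame(id = cmp$id, smiles = cmp$smiles,
                    logbb = data[[columns[["logbb"]]]],
                    class = as.character(labels), stringsAsFactors = FALSE)
  list(features = ft, labels = labels, table = out, tally = table(labels))
}

#' Per-OP reactivation prediction and the broad-spectrum flag
#'
#' A candidate is *broad spectrum* when the model predicts *High*
#' reactivation against every organophosphate in the panel.
#'
#' @param artifact An `oxime_classifier` trained on pair features.
#' @param candidates Compound `data.frame` (or character SMILES vector) of
#'   reactivator candidates.
#' @param ops OP panel compound `data.frame` (default [op_panel()]).
#' @param scaler Optional stored min-max scaler applied to the pair features
#'   (use the scaler the training table was built with).
#' @param chem_columns The per-chemical descriptor columns surviving the
#'   training-time variance filter; defaults to all.
#' @return `data.frame` with one row per candidate: `id`, one class column
#'   per OP, and `broad_spectrum`.
#' @export
predict_broad_spectrum <- function(artifact, candidates, ops = op_panel(),
                                   scaler = NULL, chem_columns = NULL) {
  if (is.character(candidates)) {
    candidates <- compound_records(paste0("cand_", seq_along(candidates)),
                                   candidates, role = "SPPO")
  }
  if (!nrow(ops)) stop("empty OP panel", call. = FALSE)
  chem <- descriptor_matrix(rbind(candidates[, c("id", "smiles", "role",
                                                 "name")], ops))
  if (!is.null(chem_columns)) chem <- chem[, chem_columns, drop = FALSE]
  grid <- expand.grid(sppo = candidates$id, op = ops$id,
                      stringsAsFactors = FALSE)
  pairs <- pair_feature_matrix(chem[candidates$id, , drop = FALSE],
                               chem[ops$id, , drop = FALSE],
                               grid$sppo, grid$op)
  if (!is.null(scaler)) pairs <- apply_scaler(pairs, scaler)
  pred <- predict(artifact, pairs)
  out <- data.frame(id = candidates$id, stringsAsFactors = FALSE)
  for (op in ops$id) {
    out[[op]] <- pred[match(paste0(candidates$id, ":", op), rownames(pairs))]
  }
  out$broad_spectrum <- apply(out[, ops$id, drop = FALSE], 1L,
                              function(r) all(r == "High"))
  out
}
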