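# Task-level model bundles: assemble a dataset, split it with k-means
# stratification, fit the scaler on the training partition only, select the
# reduced descriptor set, grid-search the booster, evaluate on the hold-out,
# and (by default) refit a deployment model on all labeled data with the
# winning configuration.

train_eval_bundle <- function(ft_raw, labels, grid, rs_sizes, nfold,
                              train_on_all, seed) {
  # cluster on a scaling of the full table (labels play no role there),
  # but fit the *modeling* scaler on the training partition only
  cluster_mat <- minmax_scale(ft_raw)$matrix
  split <- stratified_split(cluster_mat, labels, test_fraction = 0.2,
                            seed = seed)
  tr_ids <- split_ids(split, "train_val")
  te_ids <- split_ids(split, "test")
  ft_scaled <- minmax_scale(ft_raw, fit_rows = tr_ids)
  x_tr <- ft_scaled$matrix[tr_ids, , drop = FALSE]
  x_te <- ft_scaled$matrix[te_ids, , drop = FALSE]
  y <- stats::setNames(as.character(labels), rownames(ft_raw$matrix))

  subset <- NULL
  if (!is.null(rs_sizes)) {
    subset <- select_reduced_set(x_tr, y[tr_ids], sizes = rs_sizes,
                                 nfold = nfold, seed = seed)
  }
  eval_artifact <- train_classifier(x_tr, y[tr_ids], feature_subset = subset,
                                    grid = grid, nfold = nfold, seed = seed)
  evaluation <- evaluate_classifier(eval_artifact, x_te, y[te_ids])

  if (train_on_all) {
    scaler_all <- minmax_scale(ft_raw)$scaler
    x_all <- apply_scaler(ft_raw$matrix, scaler_all)
    deploy <- train_classifier(
      x_all, y, feature_subset = subset,
      grid = as.data.frame(eval_artifact$hyperparams), nfold = nfold,
      seed = seed)
    scaler <- scaler_all
  } else {
    deploy <- eval_artifact
    scaler <- ft_scaled$scaler
  }
  list(artifact = deploy, eval_artifact = eval_artifact,
       evaluation = evaluation, split = split, subset = subset,
       scaler = scaler)
}

#' Train and evaluate the AChE reactivation classifier
#'
#' Assembles the SPPO:OP pair dataset, holds out 20% by k-means-stratified
#' sampling, optionally selects the reduced descriptor set on the training
#' partition, grid-searches the booster, reports hold-out metrics, and refits
#' a deployment model on all labeled pairs (the held-out split exists for
#' evaluation; screening uses everything unless `train_on_all = FALSE`).
#'
#' @param measurements,sppos,ops As in [assemble_reactivation_dataset()].
#' @param grid,nfold,seed Passed to [train_classifier()].
#' @param rs_sizes Candidate reduced-set sizes, or `NULL` to use the full
#'   descriptor set.
#' @param train_on_all Deploy a refit on all labeled data (default `TRUE`).
#' @param zero_tolerance Passed to [bin_reactivation()].
#' @return A model bundle: `artifact` (deployment classifier),
#'   `eval_artifact`, `evaluation` (hold-out report), `split`, `subset`,
#'   `scaler` (pair-feature scaler for screening), `chem_columns`
#'   (per-chemical descriptors surviving the variance filter), `tally`.
#' @export
train_reactivation_model <- function(measurements, sppos, ops,
                                     grid = default_grid(),
                                     rs_sizes = c(4L, 6L, 9L, 14L, 20L,
                                                  30L, 50L),
                                     nfold = 5L, train_on_all = TRUE,
                                     zero_tolerance = 0.5, seed = 1L) {
  ds <- assemble_reactivation_dataset(measurements, sppos, ops,
                                      zero_tolerance = zero_tolerance,
                                      scale = FALSE)
  bundle <- train_eval_bundle(ds$features, ds$labels, grid, rs_sizes, nfold,
                              train_on_all, seed)
  bundle$chem_columns <- ds$per_chemical_columns
  bundle$tally <- ds$tally
  bundle$dataset <- ds
  bundle
}

#' Train and evaluate the BBB permeability classifier
#'
#' Same procedure as the reactivation model, on single-molecule descriptors
#' with classes from logBB thresholding.
#'
#' @param data,threshold,columns As in [assemble_bbb_dataset()].
#' @param grid,rs_sizes,nfold,train_on_all,seed As in
#'   [train_reactivation_model()].
#' @return A model bundle (see [train_reactivation_model()]); `chem_columns`
#'   are the surviving single-molecule descriptors.
#' @export
train_bbb_model <- function(data, threshold = 0,
                            columns = c(id = "compound_id",
                                        smiles = "smiles", logbb = "logBB"),
                            grid = default_grid(),
                            rs_sizes = c(4L, 6L, 9L, 14L, 20L, 30L, 50L),
                            nfold = 5L, train_on_all = TRUE, seed = 1L) {
  ds <- assemble_bbb_dataset(data, threshold = threshold, columns = columns,
                             scale = FALSE)
  bundle <- train_eval_bundle(ds$features, ds$labels, grid, rs_sizes, nfold,
                              train_on_all, seed)
  bundle$chem_columns <- colnames(ds$features$matrix)
  bundle$tally <- ds$tally
  bundle$threshold <- threshold
  bundle
}

#' Predict BBB classes for new molecules
#'
#' @param bundle A [train_bbb_model()] result.
#' @param smiles Character vector (or compound `data.frame`).
#' @return Character vector of `"BBB+"` / `"BBB-"`.
#' @export
predict_bbb <- function(bundle, smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  d <- descriptor_matrix(smiles)[, bundle$chem_columns, drop = FALSE]
  predict(bundle$artifact, apply_scaler(d, bundle$scaler))
}
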