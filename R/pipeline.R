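# End-to-end screening funnel: enumerate -> broad-spectrum reactivation ->
# BBB permeability -> synthesizability, with per-stage survivor accounting
# and full provenance in the outputs.

#' Synthesizability screening backends
#'
#' Retrosynthesis is deliberately pluggable: the screen's verdicts depend on
#' an external tool and its building-block catalog.
#'
#' * `"always_pass"` — every candidate passes (for funnel dry-runs).
#' * `"heuristic"` — a documented fragment-complexity rule:
#'   `0.004 * MolWt + 0.4 * RingCount`, thresholded (default 4); small
#'   acyclic molecules pass easily, polycyclic cages fail.
#' * `"external"` — shells out to `params$command`, writing
#'   `{"smiles": [...]}` JSON on stdin and expecting
#'   `{"verdicts": [true, false, ...]}` on stdout; an unavailable or failing
#'   command is an explicit error, never a silent pass.
#'
#' @param name Backend name.
#' @param params Backend parameters (`threshold` for the heuristic,
#'   `command` and optional `args` for the external adapter).
#' @return A `synth_backend` object for [screen_synthesizability()].
#' @export
synth_backend <- function(name = c("always_pass", "heuristic", "external"),
                          params = list()) {
  name <- match.arg(name)
  if (name == "external" && !nzchar(params$command %||% "")) {
    stop("external backend requires params$command", call. = FALSE)
  }
  structure(list(name = name, params = params), class = "synth_backend")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen candidates for synthesizability
#'
#' @param smiles Character vector of candidate SMILES (or a compound
#'   `data.frame`).
#' @param backend A [synth_backend()].
#' @return Logical vector of verdicts, one per candidate, with the backend
#'   identity in the `"backend"` attribute.
#' @export
screen_synthesizability <- function(smiles, backend = synth_backend()) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(inherits(backend, "synth_backend"), is.character(smiles))
  verdicts <- switch(backend$name,
    always_pass = rep(TRUE, length(smiles)),
    heuristic = {
      thr <- backend$params$threshold %||% 4
      d <- descriptor_matrix(smiles)
      score <- 0.004 * d[, "MolWt"] + 0.4 * d[, "RingCount"]
      unname(score <= thr)
    },
    external = {
      cmd <- backend$params$command
      if (!nzchar(Sys.which(cmd)) && !file.exists(cmd)) {
        stop("external synthesizability backend unavailable: ", cmd,
             call. = FALSE)
      }
      req <- tempfile(fileext = ".json")
      on.exit(unlink(req), add = TRUE)
      jsonlite::write_json(list(smiles = smiles), req, auto_unbox = FALSE)
      out <- suppressWarnings(system2(cmd,
                                      as.character(backend$params$args %||%
                                                     character()),
                                      stdout = TRUE, stderr = TRUE,
                                      stdin = req))
      status <- attr(out, "status")
      res <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "\n")),
                      error = function(e) NULL)
      if (!is.null(status) && status != 0 || is.null(res$verdicts) ||
          length(res$verdicts) != length(smiles)) {
        stop("external synthesizability backend failed: ",
             paste(out, collapse = " "), call. = FALSE)
      }
      as.logical(res$verdicts)
    })
  attr(verdicts, "backend") <- backend$name
  verdicts
}

#' Pipeline configuration
#'
#' @param sppos,measurements,bbb_data Input tables (compound records,
#'   reactivation measurements, logBB table) or paths to their CSV files.
#' @param op_panel_ids The challenge panel (default all five OPs).
#' @param rules Optional [enumeration_rules()]; derived from the decomposed
#'   inputs when `NULL`.
#' @param n_values Linker lengths when rules are derived.
#' @param grid,rs_sizes,nfold Training controls passed to the classifier
#'   core.
#' @param select_features Run reduced-set selection (default `TRUE`).
#' @param train_on_all Deploy models refit on all labeled data after the
#'   held-out evaluation (default `TRUE`); `FALSE` deploys the 80%-trained
#'   models.
#' @param backend A [synth_backend()].
#' @param logbb_threshold BBB decision threshold.
#' @param seed Seed driving every stochastic step.
#' @param output_dir Optional directory for the artifact files.
#' @param max_combinations Enumeration guard.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sppos, measurements, bbb_data,
                            op_panel_ids = c("PIMP", "NEMP", "PXN", "DFP",
                                             "GV"),
                            rules = NULL, n_values = 3:5,
                            grid = default_grid(),
                            rs_sizes = c(4L, 6L, 9L, 14L, 20L, 30L, 50L),
                            nfold = 5L, select_features = TRUE,
                            train_on_all = TRUE,
                            backend = synth_backend("heuristic"),
                            logbb_threshold = 0, seed = 1L,
                            output_dir = NULL, max_combinations = 2e6) {
  if (!length(op_panel_ids)) stop("empty OP panel", call. = FALSE)
  cfg <- list(sppos = sppos, measurements = measurements,
              bbb_data = bbb_data, op_panel_ids = op_panel_ids,
              rules = rules, n_values = n_values, grid = grid,
              rs_sizes = rs_sizes, nfold = nfold,
              select_features = select_features,
              train_on_all = train_on_all, backend = backend,
              logbb_threshold = logbb_threshold, seed = as.integer(seed),
              output_dir = output_dir, max_combinations = max_combinations)
  class(cfg) <- "pipeline_config"
  cfg
}

load_table <- function(x, reader = read.csv) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input path not found: ", x, call. = FALSE)
    reader(x, stringsAsFactors = FALSE)
  } else x
}

# polynomial rolling hash over the serialized config, for provenance stamping
config_hash <- function(cfg) {
  bytes <- serialize(cfg[setdiff(names(cfg), "output_dir")], NULL,
                     ascii = TRUE)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full screening funnel
#'
#' Stages, in order: decompose the input SPPOs and enumerate the virtual
#' library under the generation rules; train (and evaluate on a k-means
#' stratified 20% hold-out) the reactivation and BBB classifiers; flag
#' broad-spectrum candidates (predicted High against every panel OP); screen
#' those for BBB permeability; screen the remainder for synthesizability.
#' Every candidate's terminal stage is recorded and per-stage survivor counts
#' and fractions reported.
#'
#' @param config A [pipeline_config()].
#' @return List with `records` (one row per candidate: per-OP classes,
#'   `broad_spectrum`, `bbb_class`, `synthesizable`, `stage_reached`),
#'   `summary` (stage counts/fractions, model metrics, config hash),
#'   `library`, `reactivation`, `bbb` (model bundles), `rgroup_summary`
#'   (over the final targets, when any survive).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  sppos <- load_table(config$sppos)
  if (!is.data.frame(sppos) || !nrow(sppos)) {
    stop("stage enumerate: empty SPPO input", call. = FALSE)
  }
  if (is.null(sppos$role)) sppos <- compound_records(sppos$id, sppos$smiles,
                                                     role = "SPPO")
  measurements <- load_table(config$measurements)
  if (!nrow(measurements)) stop("stage reactivation: empty measurement table",
                                call. = FALSE)
  bbb_data <- load_table(config$bbb_data)
  if (!nrow(bbb_data)) stop("stage bbb: empty logBB table", call. = FALSE)
  panel <- op_panel(config$op_panel_ids)

  # --- stage 1: decompose and enumerate -------------------------------
  decs <- decompose(sppos)
  rules <- config$rules %||% rules_from_pool(fragment_pool(decs),
                                             n_values = config$n_values)
  library <- enumerate_candidates(rules, exclude = sppos$smiles,
                                  max_combinations = config$max_combinations)
  if (!nrow(library$records)) stop("stage enumerate: no candidates",
                                   call. = FALSE)

  # --- stage 2: reactivation model ------------------------------------
  react <- train_reactivation_model(
    measurements, sppos, panel, grid = config$grid,
    rs_sizes = if (config$select_features) config$rs_sizes else NULL,
    nfold = config$nfold, train_on_all = config$train_on_all, seed = seed)

  # --- stage 3: BBB model ---------------------------------------------
  bbb <- train_bbb_model(
    bbb_data, threshold = config$logbb_threshold, grid = config$grid,
    rs_sizes = if (config$select_features) config$rs_sizes else NULL,
    nfold = config$nfold, train_on_all = config$train_on_all,
    seed = seed + 1L)

  # --- stage 4: screen ------------------------------------------------
  cand <- library$records
  bs <- predict_broad_spectrum(
    react$artifact,
    compound_records(cand$id, cand$smiles, role = "SPPO"),
    ops = panel, scaler = react$scaler, chem_columns = react$chem_columns)
  records <- data.frame(candidate_id = cand$id, smiles = cand$smiles,
                        bs[, panel$id, drop = FALSE],
                        broad_spectrum = bs$broad_spectrum,
                        bbb_class = NA_character_,
                        synthesizable = NA,
                        stage_reached = "enumerated",
                        stringsAsFactors = FALSE, check.names = FALSE)
  records$stage_reached[records$broad_spectrum] <- "broad_spectrum"

  surv_bs <- which(records$broad_spectrum)
  if (length(surv_bs)) {
    bbb_pred <- predict_bbb(bbb, records$smiles[surv_bs])
    records$bbb_class[surv_bs] <- bbb_pred
    pass_bbb <- surv_bs[bbb_pred == "BBB+"]
    records$stage_reached[pass_bbb] <- "bbb_pass"
    if (length(pass_bbb)) {
      synth <- screen_synthesizability(records$smiles[pass_bbb],
                                       config$backend)
      records$synthesizable[pass_bbb] <- synth
      records$stage_reached[pass_bbb[synth]] <- "final"
    }
  }

  counts <- c(enumerated = nrow(records),
              broad_spectrum = sum(records$broad_spectrum),
              bbb_pass = sum(records$stage_reached %in%
                               c("bbb_pass", "final")),
              final = sum(records$stage_reached == "final"))
  fr <- function(a, b) if (b > 0) a / b else NA_real_
  summary <- list(
    stage_counts = as.list(counts),
    stage_fractions = list(
      broad_spectrum_of_enumerated = fr(counts[["broad_spectrum"]],
                                        counts[["enumerated"]]),
      bbb_pass_of_broad_spectrum = fr(counts[["bbb_pass"]],
                                      counts[["broad_spectrum"]]),
      final_of_bbb_pass = fr(counts[["final"]], counts[["bbb_pass"]])),
    reactivation_metrics = react$evaluation[c("overall_accuracy", "macro_f1")],
    bbb_metrics = bbb$evaluation[c("overall_accuracy", "macro_f1")],
    synthesizability_backend = config$backend$name,
    op_panel = panel$id,
    seed = seed,
    config_hash = config_hash(config),
    toolkit = list(rdkit = chem_toolkit_version(),
                   xgboost = as.character(utils::packageVersion("xgboost")))
  )

  rg_sum <- if (counts[["final"]] > 0)
    rgroup_summary(records$smiles[records$stage_reached == "final"]) else NULL

  out <- list(records = records, summary = summary, library = library,
              reactivation = react, bbb = bbb, rgroup_summary = rg_sum)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  finals <- result$records[result$records$stage_reached == "final", ,
                           drop = FALSE]
  con <- gzfile(file.path(dir, "survivors.smi.gz"), "w")
  writeLines(paste(finals$smiles, finals$candidate_id, sep = "\t"), con)
  close(con)
  jl <- vapply(seq_len(nrow(result$records)), function(i) {
    as.character(jsonlite::toJSON(as.list(result$records[i, ]),
                                  auto_unbox = TRUE, na = "null"))
  }, character(1))
  writeLines(jl, file.path(dir, "screening_records.jsonl"))
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$rgroup_summary)) {
    write.csv(result$rgroup_summary, file.path(dir, "rgroup_summary.csv"),
              row.names = FALSE)
  }
  save_classifier(result$reactivation$artifact,
                  file.path(dir, "reactivation_model"))
  save_classifier(result$bbb$artifact, file.path(dir, "bbb_model"))
  write.csv(result$reactivation$evaluation$confusion,
            file.path(dir, "reactivation_confusion.csv"))
  write.csv(result$bbb$evaluation$confusion,
            file.path(dir, "bbb_confusion.csv"))
  invisible(dir)
}

#' R-group frequency summary of screening survivors
#'
#' Decomposes the given structures and tabulates fragment frequencies per
#' position, sorted descending — the structural picture of what makes the
#' surviving candidates work.
#'
#' @param smiles Character vector (or compound `data.frame`) of decomposable
#'   structures; must be nonempty.
#' @return `data.frame` with `position`, `fragment`, `count`, ordered by
#'   position then descending count.
#' @export
rgroup_summary <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  if (!length(smiles)) stop("empty target set", call. = FALSE)
  decs <- decompose(smiles)
  pool_rows <- list()
  for (d in decs) {
    for (key in names(d$rgroups)) {
      pool_rows[[length(pool_rows) + 1L]] <- c(position = key,
                                               fragment = d$rgroups[[key]])
    }
  }
  df <- as.data.frame(do.call(rbind, pool_rows), stringsAsFactors = FALSE)
  tab <- stats::aggregate(rep(1L, nrow(df)),
                          by = list(position = df$position,
                                    fragment = df$fragment), FUN = sum)
  names(tab)[3] <- "count"
  tab[order(tab$position, -tab$count, tab$fragment), , drop = FALSE]
}
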