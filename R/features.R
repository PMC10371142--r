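# FeatureTable: a descriptor matrix plus the provenance of its scaling and
# variance filtering, so unseen candidates can be transformed identically at
# screening time.

#' Construct a feature table
#'
#' @param matrix Numeric matrix with rownames (sample ids) and colnames
#'   (descriptor names).
#' @param scaler Optional per-column `list(min=, max=)` from [minmax_scale()].
#' @param dropped_columns Names removed by [variance_filter()].
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, scaler = NULL, dropped_columns = character()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (length(intersect(colnames(matrix), dropped_columns))) {
    stop("columns and dropped_columns overlap", call. = FALSE)
  }
  structure(list(matrix = matrix, scaler = scaler,
                 dropped_columns = as.character(dropped_columns)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " descriptors", if (!is.null(x$scaler)) ", min-max scaled" else "",
      if (length(x$dropped_columns))
        paste0(", ", length(x$dropped_columns), " dropped") else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.feature_table <- function(x, ...) x$matrix

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Drop low-variance descriptors
#'
#' Columns whose variance over all rows is `<= threshold` are removed and
#' recorded in `dropped_columns`; surviving column order is preserved. The
#' default (0) drops exactly-constant descriptors.
#'
#' @param x A `feature_table`.
#' @param threshold Non-negative variance cutoff.
#' @return The filtered `feature_table`.
#' @export
variance_filter <- function(x, threshold = 0) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  v <- apply(x$matrix, 2L, var)
  drop <- colnames(x$matrix)[v <= threshold]
  feature_table(x$matrix[, setdiff(colnames(x$matrix), drop), drop = FALSE],
                scaler = x$scaler,
                dropped_columns = c(x$dropped_columns, drop))
}

#' Min-max scale a feature table to [0, 1]
#'
#' Per column, `x -> (x - min) / (max - min)` with min/max taken over
#' `fit_rows` only (all rows by default). Rows outside `fit_rows` — e.g. a
#' held-out test partition, or screening candidates transformed later with
#' [apply_scaler()] — may land outside `[0, 1]` and are clipped. Constant
#' columns map to 0.
#'
#' @param x A `feature_table` (unscaled).
#' @param fit_rows Row ids (or indices) the scaler is fit on.
#' @return The scaled `feature_table` with `scaler` recorded.
#' @export
minmax_scale <- function(x, fit_rows = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.null(x$scaler)) stop("feature table is already scaled", call. = FALSE)
  if (nrow(x$matrix) == 0L) stop("empty feature table", call. = FALSE)
  if (is.null(fit_rows)) fit_rows <- rownames(x$matrix)
  if (is.numeric(fit_rows)) fit_rows <- rownames(x$matrix)[fit_rows]
  if (!length(fit_rows)) stop("fit_rows is empty", call. = FALSE)
  miss <- setdiff(fit_rows, rownames(x$matrix))
  if (length(miss)) stop("unknown fit row(s): ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  sub <- x$matrix[fit_rows, , drop = FALSE]
  sc <- list(min = apply(sub, 2L, min), max = apply(sub, 2L, max))
  feature_table(apply_scaler(x$matrix, sc), scaler = sc,
                dropped_columns = x$dropped_columns)
}

#' Apply a stored min-max scaler to new samples
#'
#' @param matrix Numeric matrix whose columns match the scaler's.
#' @param scaler A `list(min=, max=)` as stored by [minmax_scale()].
#' @param clip Clip transformed values into [0, 1] (default `TRUE`).
#' @return The transformed matrix.
#' @export
apply_scaler <- function(matrix, scaler, clip = TRUE) {
  if (inherits(matrix, "feature_table")) matrix <- matrix$matrix
  stopifnot(identical(colnames(matrix), names(scaler$min)),
            identical(colnames(matrix), names(scaler$max)))
  rng <- scaler$max - scaler$min
  out <- sweep(matrix, 2L, scaler$min, "-")
  # constant columns (range 0) map to 0 by convention
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Invert a min-max scaling
#'
#' Recovers original values from a scaled matrix (exact for entries that were
#' not clipped; constant columns return their fitted minimum).
#'
#' @param x A scaled `feature_table` or a matrix plus explicit `scaler`.
#' @param scaler Required when `x` is a bare matrix.
#' @return Numeric matrix on the original scale.
#' @export
inverse_scale <- function(x, scaler = NULL) {
  if (inherits(x, "feature_table")) {
    scaler <- x$scaler
    x <- x$matrix
  }
  if (is.null(scaler)) stop("no scaler available", call. = FALSE)
  rng <- scaler$max - scaler$min
  sweep(sweep(x, 2L, rng, "*"), 2L, scaler$min, "+")
}

#' Write a feature table as CSV plus a JSON provenance manifest
#'
#' @param x A `feature_table`.
#' @param path CSV destination; the manifest goes to `<path>.manifest.json`.
#' @param seed Optional seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(row_id = rownames(x$matrix), x$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  manifest <- list(
    toolkit = list(name = "rdkit", version = chem_toolkit_version()),
    columns = colnames(x$matrix),
    dropped_columns = x$dropped_columns,
    scaler = if (!is.null(x$scaler))
      list(min = as.list(x$scaler$min), max = as.list(x$scaler$max)),
    seed = seed
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path (manifest expected alongside).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$row_id
  man_path <- paste0(path, ".manifest.json")
  scaler <- NULL
  dropped <- character()
  if (file.exists(man_path)) {
    man <- jsonlite::fromJSON(man_path)
    dropped <- as.character(man$dropped_columns)
    if (!is.null(man$scaler)) {
      scaler <- list(min = unlist(man$scaler$min), max = unlist(man$scaler$max))
      scaler$min <- scaler$min[colnames(mat)]
      scaler$max <- scaler$max[colnames(mat)]
    }
  }
  feature_table(mat, scaler = scaler, dropped_columns = dropped)
}
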