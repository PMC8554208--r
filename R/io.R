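# CSV I/O for labelled descriptor tables and stacked-model persistence.

#' Read a labelled descriptor table from CSV
#'
#' Expects a header row, an id column first, numeric descriptor columns and
#' a binary (0/1) label column.
#'
#' @param path CSV file path.
#' @param label_column Name of the label column (default `"label"`).
#' @return A `labeled_table`.
#' @export
read_feature_table <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("expected id column, at least one feature and a label column",
         call. = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path,
         call. = FALSE)
  ids <- as.character(df[[1L]])
  label <- df[[label_column]]
  if (!all(label %in% c(0, 1)))
    stop("label column '", label_column, "' must contain only 0/1",
         call. = FALSE)
  feat_cols <- setdiff(names(df)[-1L], label_column)
  for (cn in feat_cols) {
    col <- df[[cn]]
    if (!is.numeric(col))
      stop("feature column '", cn, "' is not numeric", call. = FALSE)
    if (anyNA(col))
      stop("missing value in feature column '", cn, "', row ",
           which(is.na(col))[[1L]], call. = FALSE)
  }
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  structure(list(ids = ids, features = X, label = as.integer(label),
                 spec = NULL),
            class = "labeled_table")
}

#' Write a labelled descriptor table to CSV
#'
#' Inverse of [read_feature_table()]: id column first, then features, then
#' the label column; a write/read round trip preserves all values and the
#' row order.
#'
#' @param table A `labeled_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "labeled_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Persist a fitted stacking ensemble to a directory
#'
#' Writes the evolved tree as a plain-text s-expression
#' (`fnt_tree.txt`), a JSON manifest (seeds, protocol, threshold, the
#' c1..c9 column order) and the fitted base learners (`learners.rds`).
#'
#' @param model An `fnt_stack`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_fnt_stack <- function(model, dir) {
  stopifnot(inherits(model, "fnt_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(fnt_serialize(model$tree), file.path(dir, "fnt_tree.txt"))
  manifest <- list(package = "fntstack",
                   columns = names(model$learners),
                   n_inputs = model$tree$n_inputs,
                   threshold = model$threshold,
                   stacking = model$stacking,
                   evolution_seed = model$evolution$control$seed,
                   best_fitness = model$evolution$best_fitness)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model$learners, file.path(dir, "learners.rds"))
  invisible(dir)
}

#' Load a stacking ensemble saved by [save_fnt_stack()]
#'
#' @param dir Directory written by [save_fnt_stack()].
#' @return An `fnt_stack` (without the training confidence matrix).
#' @export
load_fnt_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tree <- fnt_deserialize(paste(readLines(file.path(dir, "fnt_tree.txt")),
                                collapse = " "),
                          n_inputs = manifest$n_inputs)
  learners <- readRDS(file.path(dir, "learners.rds"))
  structure(list(tree = tree, evolution = NULL, learners = learners,
                 confidence_matrix = NULL, y = NULL,
                 threshold = manifest$threshold,
                 stacking = manifest$stacking, call = NULL),
            class = "fnt_stack")
}
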