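#' Feature table: subjects x predictors with an explicit missingness mask
#'
#' The central data container of the pipeline. Values are held as a numeric
#' matrix; the same-shaped logical `mask` records which cells are observed
#' (`TRUE`) versus missing. Keeping the mask explicit (rather than `NA`s
#' alone) lets the imputation stage guarantee that observed entries are never
#' touched, and lets synthetic cohorts carry both the complete and the masked
#' view of the same data.
#'
#' @param values Numeric matrix (or data frame of numerics), subjects in rows.
#' @param mask Logical matrix of the same shape; `TRUE` = observed. Defaults
#'   to `!is.na(values)`.
#' @param meta Per-feature metadata: a data frame with columns `name`,
#'   `domain`, `type` (one of `"continuous"`, `"binary"`, `"ordinal"`).
#'   Defaults are derived from column names.
#' @param subject_ids Character vector of row identifiers.
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, mask = NULL, meta = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    stop("feature_table: mask shape must equal values shape")
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature_table: feature names must be unique")
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(
      name = colnames(values),
      domain = "unspecified",
      type = "continuous"
    )
  }
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("name", "domain", "type") %in% names(meta)),
            identical(meta$name, colnames(values)))
  if (is.null(subject_ids)) subject_ids <- sprintf("s%04d", seq_len(nrow(values)))
  values[!mask] <- NA_real_
  structure(
    list(values = values, mask = mask, meta = meta,
         subject_ids = as.character(subject_ids)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  miss <- mean(!x$mask)
  cat(sprintf(
    "<feature_table> %d subjects x %d features (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * miss
  ))
  cat("domains:", paste(unique(x$meta$domain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Convert a feature table to a tibble
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with a leading `subject_id` column; missing cells are `NA`.
#' @importFrom tibble as_tibble
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  vals <- x$values
  vals[!x$mask] <- NA_real_
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids),
    tibble::as_tibble(as.data.frame(vals))
  )
}

#' @export
as.matrix.feature_table <- function(x, ...) {
  v <- x$values
  v[!x$mask] <- NA_real_
  rownames(v) <- x$subject_ids
  v
}

# Subset rows/columns of a feature table, keeping mask and meta aligned.
ft_subset <- function(ft, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(ft$values))
  if (is.null(cols)) cols <- seq_len(ncol(ft$values))
  if (is.character(cols)) cols <- match(cols, colnames(ft$values))
  feature_table(
    ft$values[rows, cols, drop = FALSE],
    ft$mask[rows, cols, drop = FALSE],
    ft$meta[cols, , drop = FALSE],
    ft$subject_ids[rows]
  )
}

ft_replace_values <- function(ft, values) {
  feature_table(values, ft$mask, ft$meta, ft$subject_ids)
}

#' Construct a binary case/not-case target
#'
#' @param labels Integer vector of 0/1 labels.
#' @param source_items Names of the symptom items the target was built from.
#' @return A `binary_target` with fields `labels`, `positive_rate`,
#'   `source_items`.
#' @export
binary_target <- function(labels, source_items = character()) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  structure(
    list(labels = labels, positive_rate = mean(labels),
         source_items = source_items),
    class = "binary_target"
  )
}

#' @export
print.binary_target <- function(x, ...) {
  cat(sprintf("<binary_target> %d subjects, %d cases (%.1f%%)\n",
              length(x$labels), sum(x$labels), 100 * x$positive_rate))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes the feature table as CSV (header = feature names, empty cell =
#' missing), each target as a two-column CSV (`subject_id`, `label`) and the
#' ground truth (if given) as JSON.
#'
#' @param table A `feature_table`.
#' @param targets Named list of `binary_target`s.
#' @param dir Output directory, created if needed.
#' @param ground_truth Optional list (from [generate_cohort()]).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(table, targets, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as_tibble(table), file.path(dir, "features.csv"),
                   row.names = FALSE, na = "")
  for (nm in names(targets)) {
    utils::write.csv(
      data.frame(subject_id = table$subject_ids, label = targets[[nm]]$labels),
      file.path(dir, paste0("target_", nm, ".csv")), row.names = FALSE
    )
  }
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a feature table written by [write_cohort()]
#'
#' @param path Path to a CSV with a `subject_id` column; empty cells are
#'   treated as missing.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$subject_id
  df$subject_id <- NULL
  feature_table(as.matrix(df), subject_ids = ids)
}
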