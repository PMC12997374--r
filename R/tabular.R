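#' Clinical tabular dataset container
#'
#' A light container for mixed nominal/numeric clinical tables with a binary
#' class label, an explicit missing marker (`NA`), and per-column metadata.
#' The layout mirrors the UCI chronic-kidney-disease panel: numeric
#' laboratory measurements plus small-category nominal findings, with `"?"`
#' denoting missing cells in the on-disk CSV dialect.
#'
#' @param values data.frame of n rows by m feature columns. Numeric columns
#'   are `numeric`, nominal columns are `character`; missing cells are `NA`.
#' @param col_meta data.frame with one row per feature column and columns
#'   `name` (character), `kind` (`"numeric"` or `"nominal"`) and `levels`
#'   (list column: character vector of allowed categories for nominal
#'   columns, `NULL` for numeric ones).
#' @param labels integer/numeric vector of 0/1 class labels, length n
#'   (1 = positive / disease class).
#' @param informative_idx optional integer vector of ground-truth
#'   informative feature indices (synthetic fixtures only).
#' @param synthetic logical vector of length n flagging rows created by
#'   oversampling; such rows must never appear in evaluation splits.
#'
#' @return An object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(values, col_meta, labels,
                            informative_idx = NULL,
                            synthetic = rep(FALSE, nrow(values))) {
  stopifnot(is.data.frame(values), is.data.frame(col_meta))
  if (nrow(col_meta) != ncol(values))
    stop("col_meta must describe every feature column")
  if (!all(col_meta$kind %in% c("numeric", "nominal")))
    stop("column kind must be 'numeric' or 'nominal'")
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("labels length must equal number of rows")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  nominal <- which(col_meta$kind == "nominal")
  for (j in nominal) {
    lv <- col_meta$levels[[j]]
    if (is.null(lv) || length(lv) == 0)
      stop("nominal column '", col_meta$name[j], "' needs a nonempty level set")
  }
  if (!is.null(informative_idx)) {
    informative_idx <- sort(as.integer(informative_idx))
    if (any(informative_idx < 1L) || any(informative_idx > ncol(values)))
      stop("informative_idx out of range")
  }
  structure(
    list(values = values, col_meta = col_meta, labels = labels,
         informative_idx = informative_idx,
         synthetic = as.logical(synthetic)),
    class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  n_nom <- sum(x$col_meta$kind == "nominal")
  cat(sprintf(
    "<tabular_dataset> %d rows, %d features (%d numeric, %d nominal)\n",
    nrow(x$values), ncol(x$values), ncol(x$values) - n_nom, n_nom))
  cat(sprintf("  positives: %d / %d (%.1f%%); missing cells: %.2f%%\n",
              sum(x$labels), length(x$labels),
              100 * mean(x$labels),
              100 * mean(is.na(as.matrix(x$values)))))
  if (!is.null(x$informative_idx))
    cat("  informative features:",
        paste(x$col_meta$name[x$informative_idx], collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$values)

#' Subset rows of a tabular dataset
#'
#' @param ds a [tabular_dataset()].
#' @param i row index (integer or logical).
#' @return The row-subset `tabular_dataset`.
#' @export
ds_rows <- function(ds, i) {
  tabular_dataset(ds$values[i, , drop = FALSE], ds$col_meta,
                  ds$labels[i], ds$informative_idx, ds$synthetic[i])
}

#' Write / read the UCI-dialect CSV representation
#'
#' The on-disk dialect uses a header row of attribute abbreviations, `"?"`
#' for missing cells, and a final `class` column coded `1`/`0`.
#'
#' @param ds a [tabular_dataset()].
#' @param path file path.
#' @return `write_ckd_csv` returns `path` invisibly; `read_ckd_csv` returns
#'   a `tabular_dataset` (column kinds inferred from `col_meta` if given,
#'   otherwise by type sniffing).
#' @export
write_ckd_csv <- function(ds, path) {
  out <- ds$values
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- "?"
    out[[j]] <- v
  }
  out$class <- ds$labels
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ckd_csv
#' @param col_meta optional column metadata; when `NULL`, columns that parse
#'   fully as numbers are treated as numeric and the rest as nominal with
#'   levels equal to the observed categories.
#' @export
read_ckd_csv <- function(path, col_meta = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "?", check.names = FALSE)
  if (!"class" %in% names(raw)) stop("no 'class' column in ", path)
  labels <- as.integer(raw$class)
  raw$class <- NULL
  if (is.null(col_meta)) {
    kinds <- vapply(raw, function(v) {
      obs <- v[!is.na(v)]
      if (length(obs) && !anyNA(suppressWarnings(as.numeric(obs))))
        "numeric" else "nominal"
    }, character(1))
    col_meta <- data.frame(name = names(raw), kind = kinds,
                           stringsAsFactors = FALSE)
    col_meta$levels <- lapply(seq_along(raw), function(j)
      if (kinds[j] == "nominal") sort(unique(raw[[j]][!is.na(raw[[j]])]))
      else NULL)
  }
  for (j in seq_along(raw))
    if (col_meta$kind[j] == "numeric") raw[[j]] <- as.numeric(raw[[j]])
  tabular_dataset(raw, col_meta, labels)
}
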