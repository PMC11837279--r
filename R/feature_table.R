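#' Labelled numeric feature table
#'
#' A `feature_table` is the package's central container: an `n x d` numeric
#' matrix of raw sensor readings (heterogeneous units, e.g. MQ-series gas
#' channels in the hundreds next to temperature in the tens), one channel
#' name per column, and one class label per row drawn from a finite label
#' set.
#'
#' @param values numeric matrix (`n x d`), no missing values.
#' @param labels character vector of length `n`; every element must belong
#'   to `classes`.
#' @param channels character vector of `d` unique channel names; defaults
#'   to `colnames(values)`.
#' @param classes the declared label set; defaults to the sorted unique
#'   labels observed.
#' @return an object of class `feature_table` with fields `values`,
#'   `channels`, `labels`, `classes`.
#' @export
feature_table <- function(values, labels, channels = colnames(values),
                          classes = sort(unique(labels))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("feature_table needs at least one row and one channel")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  channels <- as.character(channels)
  if (length(channels) != ncol(values))
    stop("length(channels) must equal ncol(values)")
  if (anyDuplicated(channels))
    stop("channel names must be unique: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (anyNA(values))
    stop("feature_table values must not contain missing cells")
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("length(labels) must equal nrow(values)")
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("label(s) outside the declared label set: ",
         paste(bad, collapse = ", "))
  colnames(values) <- channels
  structure(
    list(values = values, channels = channels, labels = labels,
         classes = as.character(classes)),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d rows x %d channels\n",
              nrow(x$values), length(x$channels)))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  tab <- table(factor(x$labels, levels = x$classes))
  cat("classes: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Row subset of a feature table
#'
#' @param table a [feature_table()].
#' @param idx integer or logical row index.
#' @return a `feature_table` with the selected rows (declared label set
#'   unchanged).
#' @export
subset_rows <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$values[idx, , drop = FALSE], table$labels[idx],
                channels = table$channels, classes = table$classes)
}

#' Read a labelled CSV feature table
#'
#' Expects the package's CSV dialect: comma separated, dot decimal, header
#' row of channel names plus one class column. Rows containing missing
#' feature cells are dropped with a message reporting how many; a feature
#' cell that is present but does not parse as a real number is an error
#' naming the offending row(s).
#'
#' @param path CSV file path.
#' @param class_column name of the class column (default `"Class"`).
#' @param label_map optional named character vector mapping raw printed
#'   labels to canonical classes, e.g. `c(V = "P", Y = "A")` for the
#'   corpus-luteum table or `c(U = "O", A = "L")` for the follicle table.
#' @param classes optional declared label set (after mapping); defaults to
#'   the labels observed.
#' @return a [feature_table()]; row order of retained rows is preserved.
#' @export
read_feature_table <- function(path, class_column = "Class",
                               label_map = NULL, classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  if (!class_column %in% names(df))
    stop("format error: class column '", class_column,
         "' absent from ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  lab_raw <- df[[class_column]]
  feats <- df[setdiff(names(df), class_column)]
  if (ncol(feats) < 1L) stop("format error: no feature columns in ", path)

  parsed <- vapply(feats, function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(df)))
  parsed <- matrix(parsed, nrow = nrow(df),
                   dimnames = list(NULL, names(feats)))
  # present-but-unparseable cells are a hard error, missing cells drop the row
  unparseable <- !is.na(as.matrix(feats)) & is.na(parsed)
  if (any(unparseable)) {
    rows <- sort(unique(which(unparseable, arr.ind = TRUE)[, 1L]))
    stop("unparseable numeric cell(s) in row(s): ",
         paste(rows, collapse = ", "))
  }
  missing_row <- rowSums(is.na(parsed)) > 0L | is.na(lab_raw)
  if (any(missing_row)) {
    message(sum(missing_row), " row(s) with missing cells rejected")
    parsed <- parsed[!missing_row, , drop = FALSE]
    lab_raw <- lab_raw[!missing_row]
  }
  if (nrow(parsed) < 1L) stop("no complete rows left after rejecting ",
                              sum(missing_row), " incomplete row(s)")
  labels <- canonicalize_labels(lab_raw, label_map)
  if (is.null(classes)) classes <- sort(unique(labels))
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("label error: unknown label(s) ", paste(bad, collapse = ", "),
         " (declared set: ", paste(classes, collapse = ", "), ")")
  feature_table(parsed, labels, channels = names(feats), classes = classes)
}

canonicalize_labels <- function(labels, label_map) {
  if (is.null(label_map)) return(labels)
  stopifnot(!is.null(names(label_map)))
  hit <- labels %in% names(label_map)
  labels[hit] <- unname(label_map[labels[hit]])
  labels
}

#' Write a feature table as CSV
#'
#' Values are serialized at full double precision (`%.17g`) so that
#' `read_feature_table(write_feature_table(t))` reproduces `t$values`
#' bit-identically.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param class_column header for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, class_column = "Class") {
  stopifnot(inherits(table, "feature_table"))
  vals <- apply(table$values, 2L, function(col) sprintf("%.17g", col))
  vals <- matrix(vals, nrow = nrow(table$values))
  lines <- c(paste(c(table$channels, class_column), collapse = ","),
             paste(apply(cbind(vals, table$labels), 1L, paste,
                         collapse = ","),
                   collapse = NULL))
  writeLines(lines, path)
  invisible(path)
}

#' Path to a packaged fixture
#'
#' The package ships the two 19-row representative sensor tables and the
#' corresponding published candidate-rule sets as plain-text fixtures.
#'
#' @param name one of `"follicle_table4.csv"`, `"cl_table5.csv"`,
#'   `"rules_table7.json"`, `"rules_table12.json"`; with no argument,
#'   lists the available fixture files.
#' @return the file path (or the vector of available names).
#' @export
sunrule_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "sunrule")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no fixture '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "))
  path
}

#' Default label maps for the packaged fixtures
#'
#' The corpus-luteum table prints row labels \{Y, V\} while its rules
#' conclude \{A = absent, P = present\}; the follicle table prints
#' \{A, U\} against classes \{L = under 1.5 cm, O = over 1.5 cm\}. The
#' follicle glyph mapping is a documented convention (U to O, A to L),
#' not stated by the data source.
#'
#' @param which `"cl"` or `"follicle"`.
#' @return a named character vector usable as `label_map`.
#' @export
fixture_label_map <- function(which = c("cl", "follicle")) {
  which <- match.arg(which)
  switch(which,
         cl = c(V = "P", Y = "A"),
         follicle = c(U = "O", A = "L"))
}
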