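#' Interval classification rule
#'
#' A conjunction of inclusive per-channel bounds implying a class:
#' `if ((lo1 <= ch1 <= hi1) and ...) Then CLASS`. Bounds are stored in
#' raw sensor units so printed rules can be checked directly against raw
#' tables.
#'
#' @param consequent predicted class label.
#' @param conditions data frame with columns `channel` (character),
#'   `lower`, `upper` (numeric); at least one row, channels distinct,
#'   `lower <= upper` per row.
#' @return an object of class `interval_rule`.
#' @export
interval_rule <- function(consequent, conditions) {
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "lower", "upper") %in% names(conditions)))
  conditions <- conditions[c("channel", "lower", "upper")]
  conditions$channel <- as.character(conditions$channel)
  conditions$lower <- as.numeric(conditions$lower)
  conditions$upper <- as.numeric(conditions$upper)
  if (nrow(conditions) < 1L)
    stop("an interval rule needs at least one condition")
  if (anyDuplicated(conditions$channel))
    stop("channels must be distinct within a rule: ",
         paste(unique(conditions$channel[duplicated(conditions$channel)]),
               collapse = ", "))
  bad <- conditions$lower > conditions$upper
  if (any(bad))
    stop("lower > upper for channel(s): ",
         paste(conditions$channel[bad], collapse = ", "))
  structure(list(consequent = as.character(consequent),
                 conditions = conditions),
            class = "interval_rule")
}

#' @export
print.interval_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Number of conditions in a rule
#' @param rule an [interval_rule()].
#' @return integer condition count.
#' @export
n_conditions <- function(rule) nrow(rule$conditions)

#' Does a rule's antecedent fire on one row?
#'
#' True iff every condition holds with inclusive bounds
#' (`lower <= value <= upper`); a value exactly on a bound fires.
#'
#' @param rule an [interval_rule()].
#' @param row named numeric vector covering every rule channel.
#' @return logical scalar.
#' @export
antecedent_fires <- function(rule, row) {
  miss <- setdiff(rule$conditions$channel, names(row))
  if (length(miss))
    stop("unknown channel(s) in row: ", paste(miss, collapse = ", "))
  v <- row[rule$conditions$channel]
  all(v >= rule$conditions$lower & v <= rule$conditions$upper)
}

#' Rows of a table on which a rule fires
#'
#' Vectorized antecedent evaluation.
#'
#' @param rule an [interval_rule()].
#' @param table a [feature_table()] containing every rule channel.
#' @return logical vector of length `nrow(table$values)`.
#' @export
rule_fires <- function(rule, table) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(rule$conditions$channel, table$channels)
  if (length(miss))
    stop("unknown channel(s) in table: ", paste(miss, collapse = ", "),
         " (available: ", paste(table$channels, collapse = ", "), ")")
  fires <- rep(TRUE, nrow(table$values))
  for (k in seq_len(nrow(rule$conditions))) {
    col <- table$values[, rule$conditions$channel[k]]
    fires <- fires & col >= rule$conditions$lower[k] &
      col <= rule$conditions$upper[k]
  }
  fires
}

#' Confusion counts of a rule on a table
#'
#' Canonical confusion semantics for a single rule treated as a binary
#' classifier for its consequent class: a row where the antecedent fires
#' and the label matches the consequent is a TP; fires without a match is
#' an FP; no fire with a match is an FN; no fire and no match is a TN.
#' Counts always sum to the number of rows.
#'
#' @inheritParams rule_fires
#' @return a `confusion_counts` object with fields `TP`, `TN`, `FP`,
#'   `FN`, `n`.
#' @export
confusion <- function(rule, table) {
  if (nrow(table$values) == 0L) {
    fires <- logical(0L); pos <- logical(0L)
  } else {
    fires <- rule_fires(rule, table)
    pos <- table$labels == rule$consequent
  }
  structure(list(TP = sum(fires & pos), FP = sum(fires & !pos),
                 FN = sum(!fires & pos), TN = sum(!fires & !pos),
                 n = length(fires)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$n))
  invisible(x)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`, the fitness used throughout the
#' rule search.
#'
#' @param counts a [confusion()] result (or any list with the four
#'   fields).
#' @return accuracy in `[0, 1]`.
#' @export
rule_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total < 1L)
    stop("undefined fitness: all confusion counts are zero")
  (counts$TP + counts$TN) / total
}

fmt_num <- function(x) {
  # shortest fixed-notation rendering that round-trips the double
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "fg", width = 1L,
                   drop0trailing = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1L))
}

#' Render a rule in the standard text form
#'
#' Produces `if((lo ≤ CH ≤ hi) and (...)) Then CLASS`; numbers
#' are rendered with the shortest decimal form that round-trips, so
#' `parse_rule(format_rule(r))` reproduces `r` exactly.
#'
#' @param rule an [interval_rule()].
#' @return character scalar.
#' @export
format_rule <- function(rule) {
  conds <- sprintf("(%s \u2264 %s \u2264 %s)",
                   fmt_num(rule$conditions$lower),
                   rule$conditions$channel,
                   fmt_num(rule$conditions$upper))
  sprintf("if(%s) Then %s", paste(conds, collapse = " and "),
          rule$consequent)
}

#' Parse the standard rule text form
#'
#' Accepts the grammar
#' `if((lo ≤ CH ≤ hi)[ and (lo ≤ CH ≤ hi)]*) Then CLASS`
#' with either the Unicode less-or-equal sign or ASCII `<=`, and
#' tolerates extra whitespace. Malformed input is an error reporting the
#' character position where parsing failed.
#'
#' @param text character scalar.
#' @return an [interval_rule()].
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  fail <- function(pos, what)
    stop(sprintf("rule parse error at position %d: expected %s in %s",
                 pos, what, sQuote(s)), call. = FALSE)
  m <- regexec("^if\\((.*)\\)[[:space:]]+Then[[:space:]]+(\\S+)$", s)
  g <- regmatches(s, m)[[1L]]
  if (length(g) == 0L) fail(1L, "'if(...) Then CLASS' shape")
  body <- g[2L]; consequent <- g[3L]
  le <- "(?:\u2264|<=)"
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  cond_re <- paste0("^\\(\\s*(", num, ")\\s*", le,
                    "\\s*([^\\s\u2264<]+)\\s*", le,
                    "\\s*(", num, ")\\s*\\)")
  offset <- 4L  # skip 'if(' when reporting positions
  rest <- body
  conds <- list()
  repeat {
    cm <- regexec(cond_re, rest, perl = TRUE)
    cg <- regmatches(rest, cm)[[1L]]
    if (length(cg) == 0L)
      fail(offset + (nchar(body) - nchar(rest)),
           "'(lo \u2264 CH \u2264 hi)' condition")
    conds[[length(conds) + 1L]] <-
      data.frame(channel = cg[3L], lower = as.numeric(cg[2L]),
                 upper = as.numeric(cg[4L]), stringsAsFactors = FALSE)
    rest <- substr(rest, attr(cm[[1L]], "match.length")[1L] + 1L,
                   nchar(rest))
    if (!nzchar(rest)) break
    am <- regexec("^\\s+and\\s+", rest)
    ag <- regmatches(rest, am)[[1L]]
    if (length(ag) == 0L)
      fail(offset + (nchar(body) - nchar(rest)), "' and ' separator")
    rest <- substr(rest, attr(am[[1L]], "match.length")[1L] + 1L,
                   nchar(rest))
  }
  interval_rule(consequent, do.call(rbind, conds))
}

#' Read / write rule sets as JSON
#'
#' The JSON schema is an object with a `rules` array, each element
#' `{consequent, conditions: [{channel, lower, upper}]}`; extra fields
#' are preserved on read as attributes `group` and `cnd` when present.
#'
#' @param path JSON file path.
#' @return `read_rules`: a list of [interval_rule()] objects.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- if (!is.null(doc$rules)) doc$rules else doc
  lapply(rules, function(r) {
    conds <- do.call(rbind, lapply(r$conditions, function(cc)
      data.frame(channel = cc$channel, lower = cc$lower, upper = cc$upper,
                 stringsAsFactors = FALSE)))
    out <- interval_rule(r$consequent, conds)
    if (!is.null(r$group)) attr(out, "group") <- r$group
    if (!is.null(r$cnd)) attr(out, "cnd") <- r$cnd
    out
  })
}

#' @rdname read_rules
#' @param rules list of [interval_rule()] objects (optionally with
#'   numeric metadata in an `accuracy` attribute).
#' @export
write_rules <- function(rules, path) {
  payload <- list(rules = lapply(rules, function(r) {
    out <- list(consequent = r$consequent,
                conditions = lapply(seq_len(nrow(r$conditions)), function(k)
                  list(channel = r$conditions$channel[k],
                       lower = r$conditions$lower[k],
                       upper = r$conditions$upper[k])))
    if (!is.null(attr(r, "accuracy"))) out$accuracy <- attr(r, "accuracy")
    out
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
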