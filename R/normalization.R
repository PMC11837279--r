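#' Fit per-channel min-max normalization
#'
#' Records each channel's observed extrema and the target interval
#' `[N_b, N_h]` (default `[0, 1]`). The optimiser searches in normalized
#' coordinates while rules are reported in raw sensor units, so the
#' mapping must invert exactly; see [invert_normalization()].
#'
#' Constant channels (max equal to min) are flagged: they map every value
#' to `N_b` and are excluded from rule search, since an interval on a
#' constant channel carries no information.
#'
#' @param table a [feature_table()]; conventionally the training
#'   partition only, so held-out rows may normalize outside the target
#'   interval (they are deliberately not clipped).
#' @param target numeric length-2, the target interval `c(N_b, N_h)`.
#' @return a `normalization_spec`: channels, per-channel `min`/`max`,
#'   `target`, and a logical `constant` flag per channel.
#' @export
fit_normalization <- function(table, target = c(0, 1)) {
  stopifnot(inherits(table, "feature_table"),
            length(target) == 2L, is.numeric(target),
            target[2L] > target[1L])
  mins <- apply(table$values, 2L, min)
  maxs <- apply(table$values, 2L, max)
  structure(
    list(channels = table$channels,
         min = stats::setNames(mins, table$channels),
         max = stats::setNames(maxs, table$channels),
         target = as.numeric(target),
         constant = stats::setNames(maxs == mins, table$channels)),
    class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf("normalization_spec: %d channels -> [%g, %g]\n",
              length(x$channels), x$target[1L], x$target[2L]))
  if (any(x$constant))
    cat("constant channels:",
        paste(x$channels[x$constant], collapse = ", "), "\n")
  invisible(x)
}

check_channel <- function(spec, channel) {
  if (!channel %in% spec$channels)
    stop("unknown channel '", channel, "' (known: ",
         paste(spec$channels, collapse = ", "), ")")
}

#' Map raw values to normalized coordinates
#'
#' Affine map of a channel's raw values onto the target interval. Values
#' outside the fitted extrema map outside the interval (no clipping).
#'
#' @param spec a [fit_normalization()] result.
#' @param x numeric vector of raw values.
#' @param channel channel name.
#' @return numeric vector of normalized values.
#' @export
apply_normalization <- function(spec, x, channel) {
  stopifnot(inherits(spec, "normalization_spec"))
  check_channel(spec, channel)
  nb <- spec$target[1L]; nh <- spec$target[2L]
  if (spec$constant[[channel]]) return(rep(nb, length(x)))
  nb + (x - spec$min[[channel]]) /
    (spec$max[[channel]] - spec$min[[channel]]) * (nh - nb)
}

#' Map normalized coordinates back to raw units
#'
#' Exact inverse of [apply_normalization()] on non-constant channels
#' (round trip within 1e-9 relative tolerance); constant channels return
#' the constant raw value.
#'
#' @inheritParams apply_normalization
#' @param y numeric vector of normalized values.
#' @return numeric vector of raw values.
#' @export
invert_normalization <- function(spec, y, channel) {
  stopifnot(inherits(spec, "normalization_spec"))
  check_channel(spec, channel)
  nb <- spec$target[1L]; nh <- spec$target[2L]
  if (spec$constant[[channel]]) return(rep(spec$min[[channel]], length(y)))
  spec$min[[channel]] + (y - nb) / (nh - nb) *
    (spec$max[[channel]] - spec$min[[channel]])
}

#' Normalize every channel of a table
#'
#' @inheritParams apply_normalization
#' @param table a [feature_table()] whose channels all appear in `spec`.
#' @return an `n x d` numeric matrix in normalized coordinates.
#' @export
normalize_table <- function(spec, table) {
  stopifnot(inherits(table, "feature_table"))
  out <- vapply(table$channels, function(ch)
    apply_normalization(spec, table$values[, ch], ch),
    numeric(nrow(table$values)))
  matrix(out, nrow = nrow(table$values),
         dimnames = list(NULL, table$channels))
}
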