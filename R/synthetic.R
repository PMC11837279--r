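#' Default raw-unit channel scales
#'
#' Emulates an electronic-nose feature table: most channels behave like
#' MQ-series metal-oxide gas sensors (baselines of tens to hundreds,
#' spreads of several hundred raw units), with every sixth channel on a
#' temperature/humidity-like scale (spread a few tens), so channel
#' families differ in scale by well over 10x.
#'
#' @param d number of channels.
#' @return data frame with columns `channel`, `offset`, `spread`.
#' @export
default_channel_scales <- function(d) {
  j <- seq_len(d)
  temp_like <- j %% 6L == 0L
  data.frame(
    channel = ifelse(temp_like, paste0("TMP", j), paste0("GS", j)),
    offset = ifelse(temp_like, 20, 50 + 13 * j),
    spread = ifelse(temp_like, 22, 420 + 50 * (j %% 5L)),
    stringsAsFactors = FALSE)
}

#' Planted-rule generator specification
#'
#' Describes a synthetic two-class sensor table: `d` channels with
#' uniform marginals on heterogeneous raw scales and a mild shared-factor
#' correlation, labelled by a planted conjunction of per-channel
#' intervals (stated in normalized `[0, 1]` coordinates) plus leakage and
#' label noise. A row inside every planted interval is positive; a row
#' outside is positive with probability `base_rate`; finally each label
#' flips independently with probability `label_noise`.
#'
#' When `class_ratio` (the target positive fraction) is given,
#' `base_rate` is solved from the planted rule's coverage; a target below
#' the coverage is infeasible and errors.
#'
#' @param n rows (>= 10).
#' @param d channels.
#' @param channel_scales data frame `channel`/`offset`/`spread`; default
#'   [default_channel_scales()].
#' @param planted_conditions data frame `channel` (integer index or
#'   name), `lower`, `upper` in normalized coordinates; default the
#'   two-condition benchmark rule: channel 2 in \[0.3, 0.6\] and channel
#'   5 in \[0.2, 0.7\].
#' @param base_rate probability a non-covered row is positive
#'   (default 0.05).
#' @param label_noise flip probability `epsilon` in `[0, 0.5)` (default
#'   0.1).
#' @param class_ratio optional target positive fraction; overrides
#'   `base_rate`.
#' @param latent_weight shared-factor weight in `[0, 1)` inducing
#'   channel correlation (default 0.3; 0 gives independent channels and
#'   exact product-measure coverage).
#' @param positive_label,negative_label class labels.
#' @param seed integer seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n = 400L, d = 6L,
                           channel_scales = default_channel_scales(d),
                           planted_conditions = data.frame(
                             channel = c(2L, 5L),
                             lower = c(0.3, 0.2),
                             upper = c(0.6, 0.7)),
                           base_rate = 0.05, label_noise = 0.1,
                           class_ratio = NULL, latent_weight = 0.3,
                           positive_label = "P", negative_label = "N",
                           seed = 1L) {
  stopifnot(n >= 10L, d >= 1L, nrow(channel_scales) == d,
            label_noise >= 0, label_noise < 0.5,
            latent_weight >= 0, latent_weight < 1,
            base_rate >= 0, base_rate < 1)
  pc <- as.data.frame(planted_conditions)
  if (is.character(pc$channel))
    pc$channel <- match(pc$channel, channel_scales$channel)
  stopifnot(!anyNA(pc$channel), all(pc$channel >= 1L), all(pc$channel <= d),
            all(pc$lower >= 0), all(pc$upper <= 1),
            all(pc$upper > pc$lower))
  coverage <- prod(pc$upper - pc$lower)
  if (!is.null(class_ratio)) {
    stopifnot(class_ratio > 0, class_ratio < 1)
    base_rate <- (class_ratio - coverage) / (1 - coverage)
    if (base_rate < 0)
      stop("infeasible class_ratio ", class_ratio,
           ": planted rule coverage is already ", signif(coverage, 4L))
  }
  structure(list(n = as.integer(n), d = as.integer(d),
                 channel_scales = channel_scales,
                 planted_conditions = pc, base_rate = base_rate,
                 label_noise = label_noise, coverage = coverage,
                 latent_weight = latent_weight,
                 positive_label = positive_label,
                 negative_label = negative_label,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# CDF of (1-w)*U + w*Z for independent U, Z ~ U(0,1): piecewise quadratic.
# Applying it per channel restores exact uniform marginals while keeping
# the rank correlation induced by the shared factor Z.
mixture_cdf <- function(t, w) {
  a <- max(1 - w, w); b <- min(1 - w, w)
  if (b == 0) return(t)
  out <- numeric(length(t))
  lo <- t < b; mid <- t >= b & t < a; hi <- t >= a
  out[lo] <- t[lo]^2 / (2 * a * b)
  out[mid] <- (t[mid] - b / 2) / a
  out[hi] <- 1 - (1 - t[hi])^2 / (2 * a * b)
  out
}

generate_features <- function(spec) {
  z <- stats::runif(spec$n)
  u <- matrix(NA_real_, spec$n, spec$d)
  w <- spec$latent_weight
  for (j in seq_len(spec$d))
    u[, j] <- mixture_cdf((1 - w) * stats::runif(spec$n) + w * z, w)
  u
}

raw_from_unit <- function(spec, u) {
  raw <- sweep(sweep(u, 2L, spec$channel_scales$spread, `*`),
               2L, spec$channel_scales$offset, `+`)
  colnames(raw) <- spec$channel_scales$channel
  raw
}

truth_rules <- function(spec) {
  pc <- spec$planted_conditions
  sc <- spec$channel_scales[pc$channel, ]
  list(
    normalized = interval_rule(spec$positive_label, data.frame(
      channel = sc$channel, lower = pc$lower, upper = pc$upper,
      stringsAsFactors = FALSE)),
    raw = interval_rule(spec$positive_label, data.frame(
      channel = sc$channel,
      lower = sc$offset + sc$spread * pc$lower,
      upper = sc$offset + sc$spread * pc$upper,
      stringsAsFactors = FALSE)))
}

#' Generate a planted-rule dataset
#'
#' @param spec a [generator_spec()].
#' @return list with `table` (a [feature_table()] in raw units),
#'   `truth` (the planted rule in raw units), `truth_normalized` (same
#'   rule in generator coordinates), `coverage` (planted interval
#'   measure under independent channels) and `covered` (logical
#'   ground-truth coverage per row).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  u <- generate_features(spec)
  pc <- spec$planted_conditions
  covered <- rep(TRUE, spec$n)
  for (k in seq_len(nrow(pc)))
    covered <- covered & u[, pc$channel[k]] >= pc$lower[k] &
      u[, pc$channel[k]] <= pc$upper[k]
  pos <- covered | stats::runif(spec$n) < spec$base_rate
  if (spec$label_noise > 0)
    pos <- xor(pos, stats::runif(spec$n) < spec$label_noise)
  labels <- ifelse(pos, spec$positive_label, spec$negative_label)
  tab <- feature_table(raw_from_unit(spec, u), labels,
                       classes = sort(c(spec$positive_label,
                                        spec$negative_label)))
  tr <- truth_rules(spec)
  list(table = tab, truth = tr$raw, truth_normalized = tr$normalized,
       coverage = spec$coverage, covered = covered)
}

#' Generate a null (label-independent) dataset
#'
#' Features are drawn exactly as in [generate()], but labels are i.i.d.
#' Bernoulli draws at the requested positive fraction, independent of
#' the features: no interval rule can beat the majority-class frequency
#' by more than sampling error.
#'
#' @param spec a [generator_spec()].
#' @param positive_fraction positive-label probability (default 0.3, so
#'   the negative class is the roughly 70% majority, mirroring the
#'   imbalance of the motivating datasets).
#' @return list with `table` and `positive_fraction`.
#' @export
make_null <- function(spec, positive_fraction = 0.3) {
  stopifnot(inherits(spec, "generator_spec"),
            positive_fraction > 0, positive_fraction < 1)
  set.seed(spec$seed)
  u <- generate_features(spec)
  pos <- stats::runif(spec$n) < positive_fraction
  labels <- ifelse(pos, spec$positive_label, spec$negative_label)
  tab <- feature_table(raw_from_unit(spec, u), labels,
                       classes = sort(c(spec$positive_label,
                                        spec$negative_label)))
  list(table = tab, positive_fraction = positive_fraction)
}

#' Interval overlap (Jaccard) between two rules
#'
#' Mean over the union of the two rules' channels of
#' `|intersection| / |union|` of the per-channel intervals; a channel
#' used by only one rule contributes 0. Used to score recovery of a
#' planted rule.
#'
#' @param rule,reference [interval_rule()] objects in the same units.
#' @param per_channel return the per-channel vector instead of the mean.
#' @return numeric in `[0, 1]`.
#' @export
rule_jaccard <- function(rule, reference, per_channel = FALSE) {
  chans <- union(rule$conditions$channel, reference$conditions$channel)
  jac <- vapply(chans, function(ch) {
    a <- rule$conditions[rule$conditions$channel == ch, ]
    b <- reference$conditions[reference$conditions$channel == ch, ]
    if (nrow(a) == 0L || nrow(b) == 0L) return(0)
    inter <- max(0, min(a$upper, b$upper) - max(a$lower, b$lower))
    uni <- max(a$upper, b$upper) - min(a$lower, b$lower)
    if (uni <= 0) return(1)  # two identical point intervals
    inter / uni
  }, numeric(1L))
  names(jac) <- chans
  if (per_channel) jac else mean(jac)
}
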