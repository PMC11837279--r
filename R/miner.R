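#' Rule-miner configuration
#'
#' Wraps the optimiser settings together with the rule-specific knobs:
#' the activation threshold `delta` (an attribute `j` joins the decoded
#' rule iff its activation score strictly exceeds `delta`), the number of
#' independent optimiser islands per class (the "parallel" scheme: no
#' migration, union of results), how many top rules to keep, the held-out
#' fraction and the number of repeated independent experiments.
#'
#' @param n_pop,pollination_rate,elimination_rate,iterations,phi,step_law
#'   passed to [sfoa_config()] (published defaults: 30 / 2.5% / 20% /
#'   300).
#' @param delta activation threshold in (0, 1); default 0.5.
#' @param islands number of independent optimiser processes per class
#'   (default 2).
#' @param rules_kept number of best rules retained per class (default 4,
#'   mirroring the published candidate tables).
#' @param split_fraction held-out test share in (0, 1); default 0.2.
#' @param experiments number of repeated independent runs for
#'   [run_experiment()] (default 10; the published settings table says 5,
#'   the text says ten).
#' @param seed base integer seed; island/run seeds are derived from it.
#' @param target normalization target interval.
#' @return a `miner_config` list.
#' @export
miner_config <- function(n_pop = 30L, pollination_rate = 0.025,
                         elimination_rate = 0.20, iterations = 300L,
                         phi = 0.05, delta = 0.5, islands = 2L,
                         rules_kept = 4L, split_fraction = 0.2,
                         experiments = 10L, seed = 1L,
                         target = c(0, 1), step_law = NULL) {
  stopifnot(delta > 0, delta < 1, islands >= 1L, rules_kept >= 1L,
            split_fraction > 0, split_fraction < 1, experiments >= 1L)
  structure(list(n_pop = as.integer(n_pop),
                 pollination_rate = pollination_rate,
                 elimination_rate = elimination_rate,
                 iterations = as.integer(iterations), phi = phi,
                 delta = delta, islands = as.integer(islands),
                 rules_kept = as.integer(rules_kept),
                 split_fraction = split_fraction,
                 experiments = as.integer(experiments),
                 seed = as.integer(seed), target = as.numeric(target),
                 step_law = step_law),
            class = "miner_config")
}

# deterministic derived seeds, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483647)
}

#' Per-class search subspace
#'
#' Per-channel extrema (in normalized coordinates) of the rows bearing
#' `class_label`. These bound the candidate lower/upper-bound coordinates
#' of that class's miners, so intervals never stray outside the region
#' where the class is observed; fitness is still computed on the full
#' training table.
#'
#' @param table a [feature_table()].
#' @param class_label a class present in `table`.
#' @param spec a [fit_normalization()] result covering the table's
#'   channels.
#' @return list with numeric vectors `lower` and `upper` (length `d`,
#'   named by channel).
#' @export
class_subspace <- function(table, class_label, spec) {
  if (!class_label %in% table$labels)
    stop("class '", class_label, "' absent from table")
  norm <- normalize_table(spec, subset_rows(table,
                                            table$labels == class_label))
  list(lower = apply(norm, 2L, min), upper = apply(norm, 2L, max))
}

#' Decode a continuous solution into an interval rule
#'
#' A solution is a `3d` vector: activation scores `y_t` (first `d`
#' coordinates), candidate lower bounds `y_a` and upper bounds `y_h`
#' (normalized units). Attribute `j` is active iff `y_t[j] > delta`
#' (strict) and the channel is not constant; active bounds are swapped
#' when `y_a[j] > y_h[j]` and mapped back to raw units.
#'
#' @param solution numeric vector of length `3d`.
#' @param delta activation threshold.
#' @param spec a [fit_normalization()] result (defines `d`, channel
#'   names, constant-channel exclusions and the raw-unit mapping).
#' @param target_class consequent of the decoded rule.
#' @return an [interval_rule()], or an error of class
#'   `sunrule_empty_antecedent` when no attribute is active (callers
#'   assign fitness 0).
#' @export
decode_solution <- function(solution, delta, spec, target_class) {
  d <- length(spec$channels)
  stopifnot(length(solution) == 3L * d)
  active <- solution[seq_len(d)] > delta & !spec$constant
  if (!any(active))
    stop(structure(class = c("sunrule_empty_antecedent", "error",
                             "condition"),
                   list(message = "no active attribute in solution",
                        call = NULL)))
  conds <- lapply(which(active), function(j) {
    lo <- solution[d + j]; hi <- solution[2L * d + j]
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    data.frame(channel = spec$channels[j],
               lower = invert_normalization(spec, lo, spec$channels[j]),
               upper = invert_normalization(spec, hi, spec$channels[j]),
               stringsAsFactors = FALSE)
  })
  interval_rule(target_class, do.call(rbind, conds))
}

#' Fast fitness closure over a training table
#'
#' Builds a function mapping an encoded `3d` solution to its training
#' accuracy (the objective of the search). Evaluation runs entirely in
#' normalized coordinates, which is equivalent to decoding to raw units
#' because min-max normalization is strictly increasing on non-constant
#' channels; empty-antecedent solutions score 0.
#'
#' @param train_table training [feature_table()].
#' @param target_class consequent class being mined.
#' @param delta activation threshold.
#' @param spec a [fit_normalization()] result fitted on the training
#'   partition.
#' @return function `solution -> accuracy in [0, 1]`.
#' @export
make_fitness <- function(train_table, target_class, delta, spec) {
  norm <- normalize_table(spec, train_table)
  cols <- lapply(seq_len(ncol(norm)), function(j) norm[, j])
  pos <- train_table$labels == target_class
  neg <- !pos
  n <- length(pos)
  d <- length(spec$channels)
  searchable <- !spec$constant
  function(solution) {
    active <- which(solution[seq_len(d)] > delta & searchable)
    if (length(active) == 0L) return(0)
    fires <- rep(TRUE, n)
    for (j in active) {
      lo <- solution[d + j]; hi <- solution[2L * d + j]
      if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
      cj <- cols[[j]]
      fires <- fires & cj >= lo & cj <= hi
    }
    (sum(fires & pos) + sum(!fires & neg)) / n
  }
}

#' Mine interval rules for one class
#'
#' Runs `config$islands` independent optimiser processes (distinct
#' derived seeds unless `island_seeds` is given) over the `3d` encoding,
#' with activation coordinates in `[0, 1]` and bound coordinates
#' confined to the class subspace. The union of the final island
#' populations is decoded, deduplicated (exact condition equality after
#' rounding bounds to 6 significant digits), scored on the training
#' table, and sorted by training accuracy (descending), then condition
#' count (ascending), then discovery order.
#'
#' @param train_table training [feature_table()].
#' @param class_label class to mine rules for.
#' @param config a [miner_config()].
#' @param spec optional [fit_normalization()] result; fitted on
#'   `train_table` when omitted.
#' @param island_seeds optional explicit per-island seeds.
#' @return data frame with columns `rule` (list of [interval_rule()]),
#'   `text`, `train_accuracy`, `n_conditions`, at most
#'   `config$rules_kept` rows.
#' @export
mine_rules <- function(train_table, class_label, config,
                       spec = NULL, island_seeds = NULL) {
  stopifnot(inherits(config, "miner_config"))
  if (is.null(spec)) spec <- fit_normalization(train_table, config$target)
  if (!class_label %in% train_table$labels)
    stop("class '", class_label, "' absent from training table")
  d <- length(spec$channels)
  sub <- class_subspace(train_table, class_label, spec)
  # degenerate subspace dimensions get a sliver of width so the box is valid
  width <- sub$upper - sub$lower
  eps <- pmax(1e-9, 1e-9 * abs(sub$upper))
  hi <- ifelse(width <= 0, sub$upper + eps, sub$upper)
  box_lower <- c(rep(0, d), sub$lower, sub$lower)
  box_upper <- c(rep(1, d), hi, hi)
  if (is.null(island_seeds))
    island_seeds <- vapply(seq_len(config$islands), function(k)
      derive_seed(config$seed, 1000L + k), integer(1L))
  fitness_fn <- make_fitness(train_table, class_label, config$delta, spec)

  solutions <- list()
  for (k in seq_along(island_seeds)) {
    # step cap from the normalized data interval (printed settings give
    # (1-0)/(2*30) = 1/60), not from each subspace dimension's width
    sc <- sfoa_config(box_lower, box_upper, n_pop = config$n_pop,
                      pollination_rate = config$pollination_rate,
                      elimination_rate = config$elimination_rate,
                      iterations = config$iterations, phi = config$phi,
                      seed = island_seeds[k], step_law = config$step_law,
                      d_max = (config$target[2L] - config$target[1L]) /
                        (2 * config$n_pop))
    res <- sfoa_optimize(fitness_fn, sc)
    ord <- order(res$fitness, decreasing = TRUE)  # best of island first
    solutions <- c(solutions,
                   lapply(ord, function(i) res$population[i, ]))
  }

  rules <- list(); acc <- numeric(); key <- character()
  for (sol in solutions) {
    rule <- tryCatch(
      decode_solution(sol, config$delta, spec, class_label),
      sunrule_empty_antecedent = function(e) NULL)
    if (is.null(rule)) next
    k <- paste(rule$consequent,
               paste(rule$conditions$channel,
                     signif(rule$conditions$lower, 6L),
                     signif(rule$conditions$upper, 6L),
                     collapse = "|"), sep = "::")
    if (k %in% key) next
    key <- c(key, k)
    rules <- c(rules, list(rule))
    acc <- c(acc, rule_accuracy(confusion(rule, train_table)))
  }
  if (length(rules) == 0L)
    return(data.frame(text = character(), train_accuracy = numeric(),
                      n_conditions = integer()))
  nc <- vapply(rules, n_conditions, integer(1L))
  ord <- order(-acc, nc, seq_along(rules))
  keep <- ord[seq_len(min(config$rules_kept, length(ord)))]
  out <- data.frame(text = vapply(rules[keep], format_rule, character(1L)),
                    train_accuracy = acc[keep],
                    n_conditions = nc[keep],
                    stringsAsFactors = FALSE)
  out$rule <- rules[keep]
  out
}

#' Score rules on a held-out table
#'
#' @param rules list of [interval_rule()] objects, or a [mine_rules()]
#'   result.
#' @param test_table held-out [feature_table()].
#' @return data frame with `text`, `test_accuracy` and confusion counts,
#'   input order preserved.
#' @export
test_rules <- function(rules, test_table) {
  if (is.data.frame(rules)) rules <- rules$rule
  stopifnot(length(rules) >= 1L)
  rows <- lapply(rules, function(r) {
    cc <- confusion(r, test_table)
    data.frame(text = format_rule(r), test_accuracy = rule_accuracy(cc),
               TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified train/test split
#'
#' Samples `round(test_fraction * n_c)` test rows within each class so
#' class ratios are preserved (at least one training row per class is
#' always retained).
#'
#' @param table a [feature_table()].
#' @param test_fraction held-out share in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` feature tables and the `test`
#'   row indices.
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test_idx <- integer()
  for (cl in unique(table$labels)) {
    rows <- which(table$labels == cl)
    k <- min(round(test_fraction * length(rows)), length(rows) - 1L)
    if (k > 0L) test_idx <- c(test_idx, sample(rows, k))
  }
  test_idx <- sort(test_idx)
  list(train = subset_rows(table, setdiff(seq_len(nrow(table$values)),
                                          test_idx)),
       test = subset_rows(table, test_idx),
       test_idx = test_idx)
}

#' Majority-class (ZeroR) accuracy for a class
#'
#' The accuracy of the full-observed-range rule concluding
#' `class_label`: exactly that class's relative frequency when the class
#' is the majority, and more generally the frequency of `class_label`
#' among the rows (all rows fire).
#'
#' @param table a [feature_table()].
#' @param class_label class of interest.
#' @return relative frequency of `class_label` in `table`.
#' @export
zero_r_accuracy <- function(table, class_label) {
  mean(table$labels == class_label)
}

#' Full-observed-range rule for a class
#'
#' The ZeroR-equivalent interval rule: one condition per (non-constant)
#' channel spanning the observed extrema.
#'
#' @inheritParams zero_r_accuracy
#' @return an [interval_rule()].
#' @export
zero_r_rule <- function(table, class_label) {
  interval_rule(class_label, data.frame(
    channel = table$channels,
    lower = apply(table$values, 2L, min),
    upper = apply(table$values, 2L, max),
    stringsAsFactors = FALSE))
}

#' Class-support-weighted mean accuracy
#'
#' @param accuracies per-class accuracy vector.
#' @param support per-class row counts (same order).
#' @return weighted mean.
#' @export
weighted_accuracy <- function(accuracies, support) {
  stopifnot(length(accuracies) == length(support), sum(support) > 0)
  sum(accuracies * support) / sum(support)
}
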