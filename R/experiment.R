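#' Repeated independent mining experiments
#'
#' Runs `config$experiments` independent experiments. Each experiment
#' uses a fresh stratified 80/20-style split (fresh split seed) and
#' fresh search seeds, mines rules for every class on the training
#' partition, and records the held-out accuracy of the top-ranked rule
#' per class. Reported per class: Best / Worst / Mean / Median / Std of
#' those top-rule test accuracies, the layout used for repeated-run
#' summaries of this kind of rule miner.
#'
#' @param table full [feature_table()].
#' @param config a [miner_config()] with `experiments >= 1`.
#' @param classes classes to mine (default: every declared class).
#' @param run_seeds optional integer vector of per-run base seeds
#'   (length `config$experiments`); by default distinct seeds are
#'   derived from `config$seed`. Passing the same seed for every run
#'   makes the runs identical (std 0).
#' @return list with `stats` (data frame: class, best, worst, mean,
#'   median, std) and `runs` (matrix of per-run top-rule test accuracies,
#'   experiments x classes).
#' @export
run_experiment <- function(table, config, classes = NULL,
                           run_seeds = NULL) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "miner_config"))
  if (is.null(classes)) classes <- table$classes
  if (is.null(run_seeds))
    run_seeds <- vapply(seq_len(config$experiments), function(r)
      derive_seed(config$seed, r), integer(1L))
  stopifnot(length(run_seeds) == config$experiments)
  runs <- matrix(NA_real_, config$experiments, length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(config$experiments)) {
    split_seed <- derive_seed(run_seeds[r], 2L)
    sp <- stratified_split(table, config$split_fraction, split_seed)
    spec <- fit_normalization(sp$train, config$target)
    for (ci in seq_along(classes)) {
      run_cfg <- config
      run_cfg$seed <- derive_seed(run_seeds[r], 3L + 7919L * ci)
      mined <- mine_rules(sp$train, classes[ci], run_cfg, spec = spec)
      if (nrow(mined) == 0L) next
      runs[r, ci] <- test_rules(mined$rule[1L], sp$test)$test_accuracy
    }
  }
  stats <- data.frame(
    class = classes,
    best = apply(runs, 2L, max, na.rm = TRUE),
    worst = apply(runs, 2L, min, na.rm = TRUE),
    mean = apply(runs, 2L, mean, na.rm = TRUE),
    median = apply(runs, 2L, stats::median, na.rm = TRUE),
    std = apply(runs, 2L, function(x)
      if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(stats = stats, runs = runs)
}
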