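# small planted dataset shared by several blocks
planted_small <- function(seed = 42, n = 200, noise = 0, base = 0) {
  generate(generator_spec(n = n, d = 6, base_rate = base,
                          label_noise = noise, seed = seed))
}

test_that("decode applies the strict threshold and swap-on-decode", {
  vals <- cbind(a = c(0, 10), b = c(0, 100), c = c(5, 5))
  tab <- feature_table(vals, c("X", "Y"))
  spec <- fit_normalization(tab)

  sol <- c(0.7, 0.3, 0.51,   # activations
           0.1, 0.9, 0.2,    # lower coords
           0.4, 0.95, 0.3)   # upper coords
  r <- decode_solution(sol, 0.5, spec, "X")
  expect_equal(r$conditions$channel, "a")  # b below delta, c constant
  expect_equal(r$conditions$lower, 1)      # 0.1 * range 10
  expect_equal(r$conditions$upper, 4)

  # activation exactly at delta stays inactive (strict inequality)
  sol2 <- sol; sol2[1] <- 0.5
  expect_error(decode_solution(sol2, 0.5, spec, "X"),
               class = "sunrule_empty_antecedent")

  # swapped bounds decode in sorted order
  sol3 <- c(0.9, 0.1, 0.1, 0.8, 0, 0, 0.2, 0, 0)
  r3 <- decode_solution(sol3, 0.5, spec, "X")
  expect_equal(r3$conditions$lower, 2)
  expect_equal(r3$conditions$upper, 8)
})

test_that("fitness closure equals accuracy of the decoded rule", {
  dat <- planted_small()
  tab <- dat$table
  spec <- fit_normalization(tab)
  fit <- make_fitness(tab, "P", 0.5, spec)
  d <- length(spec$channels)
  set.seed(8)
  for (rep in 1:25) {
    sol <- stats::runif(3 * d)
    rule <- tryCatch(decode_solution(sol, 0.5, spec, "P"),
                     sunrule_empty_antecedent = function(e) NULL)
    if (is.null(rule)) {
      expect_equal(fit(sol), 0)
    } else {
      expect_equal(fit(sol), rule_accuracy(confusion(rule, tab)),
                   tolerance = 1e-12)
    }
  }
  # empty antecedent scores 0
  expect_equal(fit(rep(0, 3 * d)), 0)
})

test_that("full-range solution scores the majority frequency", {
  dat <- planted_small()
  tab <- dat$table
  spec <- fit_normalization(tab)
  fit <- make_fitness(tab, "P", 0.5, spec)
  d <- length(spec$channels)
  sol <- c(rep(1, d), rep(0, d), rep(1, d))  # all active, full range
  expect_equal(fit(sol), mean(tab$labels == "P"))
})

test_that("published-rule fitness matches the rule engine", {
  cl <- load_cl()
  spec <- fit_normalization(cl)
  fit <- make_fitness(cl, "P", 0.5, spec)
  d <- length(spec$channels)
  # encode the single-condition T2620 rule in normalized coordinates
  sol <- c(ifelse(spec$channels == "T2620", 1, 0),
           apply_normalization(spec, 739, "T2620") *
             (spec$channels == "T2620"),
           ifelse(spec$channels == "T2620",
                  apply_normalization(spec, 963, "T2620"), 1))
  expect_equal(fit(sol), 11 / 19, tolerance = 1e-12)
})

test_that("class_subspace returns per-class extrema", {
  cl <- load_cl()
  spec <- fit_normalization(cl)
  sub <- class_subspace(cl, "P", spec)
  # raw extrema of the 12 presence rows: TEMP1 in [31, 41]
  expect_equal(invert_normalization(spec, sub$lower[["TEMP1"]], "TEMP1"),
               31)
  expect_equal(invert_normalization(spec, sub$upper[["TEMP1"]], "TEMP1"),
               41)
  expect_error(class_subspace(cl, "Z", spec), "absent")

  # single-row class gives a degenerate box
  one <- subset_rows(cl, c(1, 2))
  one$labels <- c("A", "P")
  sub1 <- class_subspace(one, "A", fit_normalization(one))
  expect_equal(sub1$lower, sub1$upper)
})

test_that("mine_rules recovers a planted rule at smoke scale", {
  dat <- planted_small(seed = 3, n = 250)
  cfg <- miner_config(iterations = 120, seed = 3, rules_kept = 4)
  mined <- mine_rules(dat$table, "P", cfg)
  expect_lte(nrow(mined), 4L)
  expect_gte(mined$train_accuracy[1],
             zero_r_accuracy(dat$table, "P"))  # beats ZeroR
  expect_gte(mined$train_accuracy[1], 0.9)
  expect_true(all(diff(mined$train_accuracy) <= 0))  # sorted
  for (r in mined$rule) {
    expect_true(all(r$conditions$lower <= r$conditions$upper))
    expect_false(anyDuplicated(r$conditions$channel) > 0)
  }
})

test_that("islands with identical seeds produce identical rule lists", {
  dat <- planted_small(seed = 5, n = 150)
  cfg <- miner_config(iterations = 60, seed = 5, islands = 2)
  m1 <- mine_rules(dat$table, "P", cfg, island_seeds = c(101L, 101L))
  half <- miner_config(iterations = 60, seed = 5, islands = 1)
  m2 <- mine_rules(dat$table, "P", half, island_seeds = 101L)
  expect_identical(m1$text, m2$text)  # duplicates collapse in dedup
  expect_identical(m1$train_accuracy, m2$train_accuracy)
})

test_that("rules_kept truncates the ranked list", {
  dat <- planted_small(seed = 7, n = 150)
  cfg <- miner_config(iterations = 40, seed = 7, rules_kept = 2)
  mined <- mine_rules(dat$table, "P", cfg)
  expect_lte(nrow(mined), 2L)
})

test_that("test_rules preserves order and handles forced cases", {
  dat <- planted_small(seed = 9, n = 120, noise = 0)
  sp <- stratified_split(dat$table, 0.25, seed = 9)
  res <- test_rules(list(dat$truth), sp$test)
  expect_equal(res$test_accuracy, 1)  # planted truth is perfect

  # rule that never fires on an all-other-class table scores all TN
  negs <- subset_rows(dat$table, dat$table$labels == "N")
  never <- interval_rule("P", data.frame(
    channel = negs$channels[1],
    lower = max(negs$values[, 1]) + 1,
    upper = max(negs$values[, 1]) + 2))
  res2 <- test_rules(list(never), negs)
  expect_equal(res2$test_accuracy, 1)
  expect_equal(res2$TN, nrow(negs$values))
})

test_that("stratified split preserves class ratios and partitions rows", {
  dat <- planted_small(seed = 13, n = 300)
  sp <- stratified_split(dat$table, 0.2, seed = 1)
  n <- nrow(dat$table$values)
  expect_equal(nrow(sp$train$values) + nrow(sp$test$values), n)
  for (cl in dat$table$classes) {
    n_cl <- sum(dat$table$labels == cl)
    expect_equal(sum(sp$test$labels == cl), round(0.2 * n_cl))
  }
  # determinism
  sp2 <- stratified_split(dat$table, 0.2, seed = 1)
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("run_experiment reports order statistics per class", {
  dat <- planted_small(seed = 21, n = 150, noise = 0.05)
  cfg <- miner_config(iterations = 40, experiments = 3, seed = 21,
                      islands = 1)
  res <- run_experiment(dat$table, cfg)
  expect_equal(res$stats$class, dat$table$classes)
  expect_true(all(res$stats$best >= res$stats$median - 1e-12))
  expect_true(all(res$stats$median >= res$stats$worst - 1e-12))
  expect_true(all(res$stats$std >= 0))
  expect_equal(dim(res$runs), c(3L, 2L))

  # identical per-run seeds degenerate to std = 0
  res0 <- run_experiment(dat$table, cfg, run_seeds = rep(11L, 3))
  expect_equal(res0$stats$std, rep(0, 2))
  expect_equal(res0$stats$best, res0$stats$worst)
})

test_that("weighted accuracy is the support-weighted mean", {
  expect_equal(weighted_accuracy(c(0.8, 0.6), c(3, 1)), 0.75)
  expect_error(weighted_accuracy(c(0.8), c(1, 2)))
})
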