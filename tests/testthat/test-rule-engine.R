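test_that("interval_rule validates its invariants", {
  expect_error(interval_rule("C", data.frame(channel = character(),
                                             lower = numeric(),
                                             upper = numeric())),
               "at least one condition")
  expect_error(interval_rule("C", data.frame(channel = c("x", "x"),
                                             lower = c(1, 2),
                                             upper = c(3, 4))),
               "distinct")
  expect_error(interval_rule("C", data.frame(channel = "x",
                                             lower = 5, upper = 2)),
               "lower > upper")
})

test_that("antecedent evaluation uses inclusive bounds", {
  cl <- load_cl()
  rules12 <- read_rules(sunrule_fixture("rules_table12.json"))
  # first published corpus-luteum rule fires on the first table row
  expect_true(antecedent_fires(rules12[[1]], cl$values[1, ]))

  fol <- load_follicle()
  rules7 <- read_rules(sunrule_fixture("rules_table7.json"))
  o4 <- rules7[[8]]  # MQ8 upper bound 206 < first-row MQ8 = 216
  expect_false(antecedent_fires(o4, fol$values[1, ]))

  r <- interval_rule("C", data.frame(channel = "MQ3",
                                     lower = 259, upper = 642))
  expect_true(antecedent_fires(r, c(MQ3 = 642)))  # exactly on the bound
  expect_true(antecedent_fires(r, c(MQ3 = 259)))
  expect_false(antecedent_fires(r, c(MQ3 = 642.0001)))
  expect_error(antecedent_fires(r, c(NH3 = 1)), "unknown channel")
})

test_that("confusion reproduces the published single-condition example", {
  cl <- load_cl()
  rule <- parse_rule("if((739 <= T2620 <= 963)) Then P")
  cc <- confusion(rule, cl)
  # row 2 has T2620 = 963.2, just outside the inclusive upper bound
  expect_equal(cc$TP, 11L)
  expect_equal(cc$FP, 7L)
  expect_equal(cc$FN, 1L)
  expect_equal(cc$TN, 0L)
  expect_equal(rule_accuracy(cc), 11 / 19, tolerance = 1e-12)
})

test_that("confusion handles degenerate tables", {
  cl <- load_cl()
  rule <- zero_r_rule(cl, "P")
  empty <- cl
  empty$values <- cl$values[0, , drop = FALSE]
  empty$labels <- character(0)
  cc <- confusion(rule, empty)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 0L)

  # saturating rule on a one-class table
  onlyp <- subset_rows(cl, cl$labels == "P")
  cc <- confusion(zero_r_rule(onlyp, "P"), onlyp)
  expect_equal(cc$TP, 12L)
  expect_equal(cc$FP + cc$FN + cc$TN, 0L)
})

test_that("accuracy arithmetic and error cases", {
  expect_equal(rule_accuracy(list(TP = 1, TN = 1, FP = 1, FN = 1)), 0.5)
  expect_equal(rule_accuracy(list(TP = 10, TN = 0, FP = 0, FN = 0)), 1)
  expect_error(rule_accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "undefined")
})

test_that("count conservation and coverage monotonicity (random cases)", {
  set.seed(42)
  for (rep in 1:60) {
    tab <- random_table(sample(5:80, 1), sample(2:6, 1))
    rule <- random_rule(tab)
    cc <- confusion(rule, tab)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(tab$values))
    # widening any one interval never loses coverage
    k <- sample.int(nrow(rule$conditions), 1)
    wide <- rule$conditions
    wide$lower[k] <- wide$lower[k] - stats::runif(1, 0, 3)
    wide$upper[k] <- wide$upper[k] + stats::runif(1, 0, 3)
    cw <- confusion(interval_rule(rule$consequent, wide), tab)
    expect_gte(cw$TP + cw$FP, cc$TP + cc$FP)
    expect_equal(cw$TP + cw$TN + cw$FP + cw$FN, nrow(tab$values))
  }
})

test_that("full-range rule accuracy equals class frequency (ZeroR)", {
  set.seed(9)
  for (rep in 1:10) {
    tab <- random_table(sample(10:100, 1), 4)
    cl <- sample(tab$classes, 1)
    acc <- rule_accuracy(confusion(zero_r_rule(tab, cl), tab))
    expect_equal(acc, mean(tab$labels == cl))
    expect_equal(acc, zero_r_accuracy(tab, cl))
  }
})

test_that("vectorized confusion equals the naive per-row oracle", {
  set.seed(1234)
  for (rep in 1:200) {
    tab <- random_table(sample(2:60, 1), sample(1:6, 1))
    rule <- random_rule(tab)
    expect_identical(unclass(confusion(rule, tab))[c("TP", "TN",
                                                     "FP", "FN")],
                     naive_confusion(rule, tab))
  }
})

test_that("format/parse round trip, precision and grammar errors", {
  rules7 <- read_rules(sunrule_fixture("rules_table7.json"))
  for (r in rules7) {
    back <- parse_rule(format_rule(r))
    expect_equal(back$consequent, r$consequent)
    expect_equal(back$conditions, r$conditions)
  }
  # published text form parses to the packaged fixture rule
  l1 <- parse_rule(
    "if((266 ≤ MQ3 ≤ 637) and (516 ≤ NH3 ≤ 847)) Then L")
  expect_equal(l1$conditions, rules7[[1]]$conditions)
  expect_equal(l1$consequent, "L")

  one <- interval_rule("C", data.frame(channel = "X", lower = 1, upper = 2))
  expect_equal(format_rule(one), "if((1 ≤ X ≤ 2)) Then C")

  # non-integer bounds keep full precision through the round trip
  set.seed(5)
  r <- interval_rule("Z", data.frame(channel = c("a", "b"),
                                     lower = stats::runif(2),
                                     upper = 1 + stats::runif(2)))
  expect_equal(parse_rule(format_rule(r))$conditions, r$conditions)

  expect_error(parse_rule("whenever X > 2 Then C"), "position 1")
  expect_error(parse_rule("if((3 <= X <= 2)) Then C"), "lower > upper")
  expect_error(parse_rule("if((1 <= X <= 2) or (3 <= Y <= 4)) Then C"),
               "parse error")
})

test_that("rule JSON round trip preserves rules", {
  rules <- read_rules(sunrule_fixture("rules_table12.json"))
  expect_length(rules, 8L)
  p <- withr::local_tempfile(fileext = ".json")
  write_rules(rules, p)
  back <- read_rules(p)
  for (k in seq_along(rules)) {
    expect_equal(back[[k]]$consequent, rules[[k]]$consequent)
    expect_equal(back[[k]]$conditions, rules[[k]]$conditions)
  }
})
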