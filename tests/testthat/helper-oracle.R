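# Independent brute-force oracles and random-case generators used across
# the suite. The oracle deliberately goes row by row through
# antecedent_fires() and never touches the vectorized confusion() path.

naive_confusion <- function(rule, table) {
  TP <- TN <- FP <- FN <- 0L
  for (i in seq_len(nrow(table$values))) {
    fires <- TRUE
    for (k in seq_len(nrow(rule$conditions))) {
      v <- table$values[i, rule$conditions$channel[k]]
      if (v < rule$conditions$lower[k] || v > rule$conditions$upper[k]) {
        fires <- FALSE
        break
      }
    }
    match <- table$labels[i] == rule$consequent
    if (fires && match) TP <- TP + 1L
    else if (fires && !match) FP <- FP + 1L
    else if (!fires && match) FN <- FN + 1L
    else TN <- TN + 1L
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN)
}

random_table <- function(n, d, classes = c("A", "B")) {
  vals <- matrix(stats::runif(n * d, min = -5, max = 5), n, d)
  colnames(vals) <- paste0("ch", seq_len(d))
  feature_table(vals, sample(classes, n, replace = TRUE),
                classes = classes)
}

random_rule <- function(table) {
  d <- length(table$channels)
  k <- sample.int(d, sample.int(min(3L, d), 1L))
  b1 <- stats::runif(length(k), -5, 5)
  b2 <- stats::runif(length(k), -5, 5)
  interval_rule(sample(table$classes, 1L),
                data.frame(channel = table$channels[k],
                           lower = pmin(b1, b2), upper = pmax(b1, b2)))
}

# 19-row fixtures with documented label maps
load_follicle <- function() {
  read_feature_table(sunrule_fixture("follicle_table4.csv"),
                     label_map = fixture_label_map("follicle"))
}
load_cl <- function() {
  read_feature_table(sunrule_fixture("cl_table5.csv"),
                     label_map = fixture_label_map("cl"))
}
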