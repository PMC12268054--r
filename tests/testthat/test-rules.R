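# Decision tree training, rule evaluation, anchor extraction.

make_rule_data <- function(n = 200, seed = 31) {
  set.seed(seed)
  d <- cbind(
    fr_pyridine = sample(0:3, n, replace = TRUE),
    NumHAcceptors = sample(0:12, n, replace = TRUE),
    MolWt = runif(n, 150, 600),
    noise1 = rnorm(n),
    noise2 = rnorm(n))
  labels <- ifelse(d[, "fr_pyridine"] > 1, "active", "inactive")
  list(d = d, labels = labels)
}

test_that("a separable planted rule is learned perfectly", {
  dat <- make_rule_data()
  tree <- train_activity_tree(dat$d, dat$labels, max_depth = 10, seed = 1)
  expect_equal(tree$training_accuracy, 1.0)

  set.seed(32)
  shuffled <- sample(dat$labels)
  tree2 <- train_activity_tree(dat$d, shuffled, max_depth = 3, seed = 1)
  expect_lt(tree2$training_accuracy, tree$training_accuracy)

  stump <- train_activity_tree(dat$d, dat$labels, max_depth = 1)
  expect_lte(nrow(stump$model$frame), 3)

  expect_error(train_activity_tree(dat$d, rep("active", nrow(dat$d))))
})

test_that("rule evaluation uses exact counting semantics", {
  dat <- make_rule_data()
  r <- rule(rbind(predicate("fr_pyridine", ">", 1),
                  predicate("NumHAcceptors", "<=", 12)))
  st <- evaluate_rule(r, dat$d, dat$labels)
  manual <- dat$d[, "fr_pyridine"] > 1 & dat$d[, "NumHAcceptors"] <= 12
  expect_equal(st$n_match, sum(manual))
  expect_equal(st$n_active, sum(dat$labels[manual] == "active"))
  expect_equal(st$n_active + st$n_inactive, st$n_match)
  expect_equal(st$coverage, sum(manual) / nrow(dat$d))

  taut <- evaluate_rule(rule(predicate("MolWt", ">", -Inf)), dat$d,
                        dat$labels)
  expect_equal(taut$coverage, 1)
  expect_equal(taut$pct_active,
               round(100 * mean(dat$labels == "active"), 2))

  contra <- evaluate_rule(rbind(predicate("MolWt", ">", 300),
                                predicate("MolWt", "<=", 300)),
                          dat$d, dat$labels)
  expect_equal(contra$n_match, 0)
  expect_true(contra$undefined)
  expect_true(is.na(contra$pct_active))

  expect_error(evaluate_rule(rule(predicate("nope", ">", 1)), dat$d,
                             dat$labels), "unknown")
})

test_that("rule evaluation matches a brute-force row filter", {
  set.seed(33)
  for (i in 1:5) {
    n <- sample(50:300, 1)
    p <- 6
    d <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    labels <- sample(c("active", "inactive"), n, replace = TRUE)
    k <- sample(1:3, 1)
    preds <- do.call(rbind, lapply(1:k, function(j)
      predicate(sample(colnames(d), 1),
                sample(c(">", "<="), 1),
                rnorm(1))))
    st <- evaluate_rule(preds, d, labels)
    m <- rep(TRUE, n)
    for (j in seq_len(nrow(preds))) {
      v <- d[, preds$descriptor[j]]
      m <- m & if (preds$op[j] == ">") v > preds$threshold[j]
               else v <= preds$threshold[j]
    }
    expect_equal(st$n_match, sum(m))
    expect_equal(st$n_active, sum(labels[m] == "active"))
  }
})

test_that("adding predicates never increases the match count", {
  dat <- make_rule_data()
  base <- predicate("fr_pyridine", ">", 0)
  st0 <- evaluate_rule(base, dat$d, dat$labels)
  grown <- base
  set.seed(34)
  for (i in 1:5) {
    grown <- rbind(grown, predicate(sample(colnames(dat$d), 1),
                                    sample(c(">", "<="), 1),
                                    rnorm(1, 1, 2)))
    st <- evaluate_rule(grown, dat$d, dat$labels)
    expect_lte(st$n_match, st0$n_match)
    st0 <- st
  }
})

test_that("anchor extraction recovers a planted one-predicate rule", {
  dat <- make_rule_data()
  tree <- train_activity_tree(dat$d, dat$labels, max_depth = 10)
  rules <- extract_anchor_rules(tree, dat$d, dat$labels,
                                precision_threshold = 0.80, seed = 2)
  expect_gt(length(rules), 0)
  top <- rules[[1]]
  expect_equal(top$predicates$descriptor, "fr_pyridine")
  expect_equal(top$predicates$op, ">")
  expect_gte(top$predicates$threshold, 1)
  expect_lt(top$predicates$threshold, 2)
  expect_gte(top$stats$pct_active / 100, 0.80)
  expect_gte(top$anchor_precision, 0.80)
  # every extracted rule honors the precision floor on training data
  for (r in rules) expect_gte(r$stats$pct_active / 100, 0.80)

  expect_warning(
    none <- extract_anchor_rules(tree, dat$d, dat$labels,
                                 precision_threshold = 1.01),
    "threshold")
  expect_equal(length(none), 0)
})

test_that("anchor extraction is deterministic under a fixed seed", {
  dat <- make_rule_data()
  tree <- train_activity_tree(dat$d, dat$labels, max_depth = 6)
  r1 <- extract_anchor_rules(tree, dat$d, dat$labels, seed = 7)
  r2 <- extract_anchor_rules(tree, dat$d, dat$labels, seed = 7)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})
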