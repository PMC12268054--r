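# Structural alerts: environment enumeration and hypergeometric scoring.

test_that("hypergeometric tails match exact combinatorial values", {
  p <- hypergeom_tail(k = 4, n = 4, K = 5, N = 10)
  expect_equal(p$p_enriched, 5 / 210, tolerance = 1e-12)
  expect_equal(p$p_enriched, choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 4, 5, 10)$p_enriched, 1)
  # drawing the whole urn forces k = K
  expect_equal(hypergeom_tail(5, 10, 5, 10)$p_enriched, 1)
  expect_error(hypergeom_tail(5, 4, 5, 10))
  expect_error(hypergeom_tail(2, 3, 1, 10))
})

test_that("tail overlap identity holds across random configurations", {
  set.seed(6)
  for (i in 1:50) {
    N <- sample(5:40, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    k <- if (lo == hi) lo else sample(seq(lo, hi), 1)
    p <- hypergeom_tail(k, n, K, N)
    pk <- choose(K, k) * choose(N - K, n - k) / choose(N, n)
    expect_equal(p$p_enriched + p$p_depleted, 1 + pk, tolerance = 1e-9)
  }
  # p_enriched non-increasing in k
  ps <- vapply(0:5, function(k) hypergeom_tail(k, 5, 10, 20)$p_enriched,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("environment enumeration is presence-based and structure-driven", {
  recs <- make_records(c("C", "C", "c1ccccc1", "c1ccncc1"),
                       c(1, 2, 3, 4), ids = letters[1:4])
  em <- enumerate_environments(recs, max_radius = 3)
  # methane contributes exactly one radius-0 environment
  methane_envs <- names(em$members)[vapply(em$members, function(m)
    1 %in% m, logical(1))]
  expect_equal(length(methane_envs), 1)
  expect_equal(em$keys$radius[em$keys$env_id == methane_envs], 0)
  # duplicates share identical key sets
  expect_equal(vapply(em$members, function(m) 1 %in% m, logical(1)),
               vapply(em$members, function(m) 2 %in% m, logical(1)))
  # benzene and pyridine share some carbon environments but not the
  # nitrogen-centered ones
  in_bz <- vapply(em$members, function(m) 3 %in% m, logical(1))
  in_py <- vapply(em$members, function(m) 4 %in% m, logical(1))
  expect_true(any(in_bz & in_py))
  expect_true(any(in_py & !in_bz))
})

test_that("act_pct reports the carrier active percentage", {
  expect_equal(act_pct(33, 35), 94.29)
  expect_equal(act_pct(0, 30), 0)
  expect_equal(act_pct(51, 51), 100)
  expect_error(act_pct(1, 0))
  expect_error(act_pct(5, 4))
})

test_that("find_alerts applies the support filter and direction call", {
  # 30 pyridines (all active) + 30 alkanes (all inactive): the pyridine
  # environments are perfect active alerts
  smis <- c(rep("c1ccncc1", 30), rep("CCCCCC", 30))
  recs <- make_records(smis, c(rep(10, 30), rep(1000, 30)))
  al <- find_alerts(recs, max_radius = 2, min_support = 30, alpha = 0.05)
  expect_gt(nrow(al), 0)
  expect_true(all(al$n >= 30))
  top <- al[1, ]
  expect_equal(top$act_pct, 100)
  expect_equal(top$direction, "active_alert")
  expect_true(all(al$p_enriched > 0 & al$p_enriched <= 1))

  # support 29 with min_support 30 is excluded
  recs29 <- make_records(c(rep("c1ccncc1", 29), rep("CCCCCC", 31)),
                         c(rep(10, 29), rep(1000, 31)))
  al29 <- find_alerts(recs29, max_radius = 2, min_support = 30)
  pyr_envs <- enumerate_environments(
    make_records("c1ccncc1", 10), max_radius = 2)$keys$env_id
  expect_false(any(al29$env_id %in% pyr_envs & al29$n < 30))
  expect_true(all(al29$n >= 30))

  expect_error(find_alerts(make_records(rep("CCO", 5), rep(10, 5))),
               "both")
})

test_that("find_alerts output is invariant to record order", {
  set.seed(8)
  smis <- c(rep("c1ccncc1", 10), rep("Cc1ccccc1", 10), rep("CCO", 10))
  ic50 <- c(rep(10, 10), rep(1000, 10), rep(10, 5), rep(1000, 5))
  recs <- make_records(smis, ic50)
  a1 <- find_alerts(recs, max_radius = 2, min_support = 10)
  perm <- sample(nrow(recs))
  a2 <- find_alerts(recs[perm, ], max_radius = 2, min_support = 10)
  rownames(a2) <- NULL
  expect_equal(a2, a1)
})

test_that("multiple-testing correction is available", {
  smis <- c(rep("c1ccncc1", 15), rep("CCCCCC", 15))
  recs <- make_records(smis, c(rep(10, 15), rep(1000, 15)))
  raw <- find_alerts(recs, max_radius = 2, min_support = 15, alpha = 1)
  bonf <- find_alerts(recs, max_radius = 2, min_support = 15, alpha = 1,
                      p_adjust = "bonferroni")
  expect_true(all(bonf$p_enriched >= raw$p_enriched - 1e-12))
})
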