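# Chemical space networks.

test_that("top-active selection is deterministic and bounded", {
  recs <- make_records(c("CCO", "CCC", "CCN", "CCCl"), c(5, 5, 50, 2000))
  top1 <- select_top_actives(recs, n = 1)
  expect_equal(nrow(top1), 1)
  # tie at 5 nM broken by canonical SMILES order
  expect_equal(top1$canonical_smiles, min(c("CCO", "CCC")))
  expect_warning(all_of <- select_top_actives(recs, n = 10), "available")
  expect_equal(nrow(all_of), 3)  # only actives
})

test_that("identical molecules form a complete graph", {
  recs <- make_records(rep("c1ccncc1", 3), c(1, 2, 3),
                       ids = c("a", "b", "c"))
  g <- build_csn(recs, threshold = 0.6)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  m <- csn_metrics(g)
  expect_equal(m$density, 1)
  expect_equal(m$n_components, 1)
  expect_equal(unique(igraph::edge_attr(g, "tanimoto")), 1)
})

test_that("an unattainable threshold yields no edges", {
  recs <- make_records(c("CCO", "CCO", "CCN"), c(1, 2, 3),
                       ids = c("a", "b", "c"))
  g <- build_csn(recs, threshold = 1.01, drop_isolated = FALSE)
  expect_equal(igraph::ecount(g), 0)
  m <- csn_metrics(g)
  expect_equal(m$density, 0)
  expect_equal(m$n_components, 3)
  expect_error(build_csn(recs[0, ]))
})

test_that("edge set equals the brute-force all-pairs enumeration", {
  recs <- two_family_records(n_per = 10, seed = 11)
  fps <- fingerprint_matrix(recs$canonical_smiles)
  tm <- tanimoto_matrix(fps)
  g <- build_csn(recs, threshold = 0.5, drop_isolated = FALSE, fps = fps)
  want <- oracle_pairs(tm, 0.5, strict = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  norm <- function(m) {
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  expect_equal(norm(el), norm(want))
  # density closed form
  m <- csn_metrics(g)
  n <- igraph::vcount(g)
  expect_equal(m$density, 2 * igraph::ecount(g) / (n * (n - 1)))
})

test_that("density matches the closed form on a path graph", {
  g <- igraph::make_graph(~ a - b, b - c, c - d)
  g <- igraph::set_vertex_attr(g, "pic50", value = c(9, 8, 7, 6))
  m <- csn_metrics(g)
  expect_equal(m$density, 0.5)
  expect_equal(m$n_components, 1)
  expect_equal(m$components$pic50_min, 6)
  expect_equal(m$components$pic50_max, 9)
})

test_that("raising the threshold is monotone for edges and components", {
  recs <- two_family_records(n_per = 8, seed = 13)
  fps <- fingerprint_matrix(recs$canonical_smiles)
  edges <- c(); comps <- c()
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    g <- build_csn(recs, threshold = th, drop_isolated = FALSE, fps = fps)
    edges <- c(edges, igraph::ecount(g))
    comps <- c(comps, csn_metrics(g)$n_components)
  }
  expect_true(all(diff(edges) <= 0))
  expect_true(all(diff(comps) >= 0))
})

test_that("graph export round-trips through both formats", {
  recs <- make_records(c("Cc1ccccc1", "CCc1ccccc1", "CCO"), c(1, 5, 700),
                       ids = c("a", "b", "c"))
  g <- build_csn(recs, threshold = 0.3, drop_isolated = FALSE)
  for (fmt in c("graphml", "edge_csv")) {
    f <- tempfile(fileext = if (fmt == "graphml") ".graphml" else ".csv")
    export_graph(g, f, format = fmt)
    g2 <- import_graph(f, format = fmt)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_equal(sort(igraph::vertex_attr(g2, "name")),
                 sort(igraph::vertex_attr(g, "name")))
    expect_equal(sort(round(igraph::edge_attr(g2, "tanimoto"), 4)),
                 sort(round(igraph::edge_attr(g, "tanimoto"), 4)))
    m1 <- csn_metrics(g); m2 <- csn_metrics(g2)
    expect_equal(m2$density, m1$density)
    expect_equal(m2$n_components, m1$n_components)
  }
  # edge CSV carries tanimoto at 4 decimals, one row per edge
  f <- tempfile(fileext = ".csv")
  export_graph(g, f, format = "edge_csv")
  lines <- readLines(f)
  expect_equal(length(lines) - 1, igraph::ecount(g))
  expect_match(lines[2], ",[01]\\.[0-9]{4}$")
  # empty graph exports headers only
  g0 <- build_csn(make_records(c("CCO", "c1ccccc1"), c(1, 2),
                               ids = c("a", "b")),
                  threshold = 0.99, drop_isolated = FALSE)
  f0 <- tempfile(fileext = ".csv")
  export_graph(g0, f0, format = "edge_csv")
  expect_equal(length(readLines(f0)), 1)
  expect_error(export_graph(g, tempfile(), format = "dot"))
})
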