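# Curation: standardization, units, labeling, deduplication, SAR helpers.

test_that("standardize_record desalts, converts units and canonicalizes", {
  r <- standardize_record(list(source_id = "a", smiles = "CCO.Cl",
                               ic50_value = 0.05, ic50_unit = "uM"))
  expect_s3_class(r, "compound_record")
  expect_equal(r$canonical_smiles, "CCO")
  expect_equal(r$ic50_nM, 50)
  expect_true(r$desalted)
  expect_true(r$unit_converted)

  r2 <- standardize_record(list(source_id = "b", smiles = "C1=CC=NC=C1",
                                ic50_value = 10, ic50_unit = "nM"))
  expect_equal(r2$canonical_smiles, canonicalize_smiles("c1ccncc1"))
  expect_equal(r2$ic50_nM, 10)
  expect_false(r2$desalted)
})

test_that("standardize_record rejects with machine-readable reasons", {
  bad_smiles <- standardize_record(list(source_id = "x", smiles = "C(",
                                        ic50_value = 5, ic50_unit = "nM"))
  expect_s3_class(bad_smiles, "sar_rejection")
  expect_equal(bad_smiles$reason, "invalid_smiles")

  expect_equal(standardize_record(list(smiles = "CCO", ic50_value = -1,
                                       ic50_unit = "nM"))$reason,
               "bad_activity")
  expect_equal(standardize_record(list(smiles = "CCO", ic50_value = NA,
                                       ic50_unit = "nM"))$reason,
               "bad_activity")
  expect_equal(standardize_record(list(smiles = "CCO", ic50_value = 5,
                                       ic50_unit = "furlongs"))$reason,
               "bad_unit")
})

test_that("activity labeling includes the threshold boundary", {
  expect_equal(label_activity(100), "active")
  expect_equal(label_activity(100.01), "inactive")
  expect_equal(label_activity(2600), "inactive")
  expect_error(label_activity(0))
  # monotone: anything at most as potent as an active is itself active,
  # so labels over sorted potencies are a block of actives then inactives
  set.seed(1)
  x <- sort(10^runif(50, -1, 4))
  labs <- label_activity(x)
  expect_true(!is.unsorted(labs == "inactive"))
})

test_that("pic50 uses the molar convention", {
  expect_equal(pic50(1), 9)
  expect_equal(pic50(100), 7)
  expect_equal(pic50(0.40), 9 - log10(0.40), tolerance = 1e-12)
  expect_equal(round(pic50(0.40), 4), 9.3979)
  set.seed(2)
  x <- 10^runif(20, -2, 5)
  expect_equal(pic50(10 * x), pic50(x) - 1, tolerance = 1e-12)
  expect_true(all(diff(pic50(sort(x))) < 0))
  expect_error(pic50(-5))
})

test_that("fold_change reproduces worked potency ratios", {
  expect_equal(fold_change(4, 720), 180.00)
  expect_equal(fold_change(3.7, 149.3), 40.35)
  expect_equal(fold_change(5, 5), 1.00)
  set.seed(3)
  a <- 10^runif(30, -1, 4); b <- 10^runif(30, -1, 4)
  expect_equal(fold_change(a, b), fold_change(b, a))
  expect_true(all(fold_change(a, b) >= 1))
})

test_that("deduplication merges concordant and drops conflicting records", {
  recs <- make_records(rep("CCO", 2), c(10, 20))
  out <- deduplicate_compounds(recs)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$ic50_nM, 15)
  expect_equal(out$report[["n_merged_duplicates"]], 1)

  conf <- make_records(rep("CCO", 2), c(50, 500))
  out2 <- deduplicate_compounds(conf)
  expect_equal(nrow(out2$records), 0)
  expect_equal(out2$report[["n_dropped_conflicting_duplicates"]], 2)

  single <- make_records("c1ccccc1", 10)
  expect_equal(deduplicate_compounds(single)$records$ic50_nM, 10)

  geom <- deduplicate_compounds(recs, curation_config(duplicate_average = "geom"))
  expect_equal(geom$records$ic50_nM, sqrt(10 * 20))
})

test_that("deduplication is idempotent and reports reconcile", {
  set.seed(4)
  pool <- unname(fixture_smiles[c("ethanol", "benzene", "toluene",
                                  "pyridine", "phenol")])
  for (rep_i in 1:5) {
    n <- sample(3:12, 1)
    recs <- make_records(sample(pool, n, replace = TRUE),
                         10^runif(n, 0, 4))
    once <- deduplicate_compounds(recs)
    twice <- deduplicate_compounds(once$records)
    expect_equal(twice$records, once$records)
    rep1 <- once$report
    expect_equal(rep1[["n_output"]],
                 rep1[["n_input"]] -
                   rep1[["n_dropped_conflicting_duplicates"]] -
                   rep1[["n_merged_duplicates"]])
  }
})

test_that("curate_compounds produces a reconciled report", {
  raw <- data.frame(
    source_id = paste0("r", 1:6),
    smiles = c("CCO.Cl", "c1ccccc1", "C(", "CCO", "c1ccncc1", "CCN"),
    ic50_value = c(0.05, 10, 5, 50, -2, 30),
    ic50_unit = c("uM", "nM", "nM", "nM", "nM", "nM"))
  cur <- curate_compounds(raw)
  r <- cur$report
  expect_equal(r[["n_input"]], 6)
  expect_equal(r[["n_invalid_smiles"]], 1)
  expect_equal(r[["n_rejected_activity"]], 1)
  # CCO.Cl (-> 50 nM) and CCO (50 nM) merge after desalting
  expect_equal(r[["n_merged_duplicates"]], 1)
  expect_equal(r[["n_output"]], 3)
  expect_equal(nrow(cur$records), 3)
  expect_true(all(cur$records$label %in% c("active", "inactive")))
})

test_that("raw compound readers round-trip CSV and SMILES files", {
  df <- data.frame(id = c("a", "b"), smiles = c("CCO", "c1ccccc1"),
                   ic50 = c(10, 2000), unit = c("nM", "nM"),
                   year = c(2010, 2012))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rd <- read_raw_compounds(f)
  expect_equal(rd$source_id, c("a", "b"))
  expect_equal(rd$ic50_value, c(10, 2000))
  expect_equal(rd$year, c(2010, 2012))

  f2 <- tempfile(fileext = ".smi")
  writeLines(c("CCO cpd1 10", "c1ccccc1 cpd2 250"), f2)
  rd2 <- read_raw_compounds(f2)
  expect_equal(rd2$smiles, c("CCO", "c1ccccc1"))
  expect_equal(rd2$ic50_value, c(10, 250))
  expect_equal(rd2$ic50_unit, c("nM", "nM"))
})
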