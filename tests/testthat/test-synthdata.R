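# Synthetic dataset generator and planted ground truth.

test_that("generation is reproducible and structurally valid", {
  cfg <- synth_config(n_families = 3, compounds_per_family = 15,
                      n_planted_cliffs = 2, seed = 41)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$family, b$truth$family)

  expect_equal(nrow(a$records), 45)
  expect_equal(anyDuplicated(a$truth$canonical_smiles), 0)
  # every emitted SMILES survives curation without rejection
  cur <- curate_compounds(a$records)
  expect_equal(nrow(cur$rejections), 0)
  expect_equal(nrow(cur$records), 45)
  # curated canonical structures agree with the generator's ground truth
  expect_setequal(cur$records$canonical_smiles,
                  unname(a$truth$canonical_smiles))
})

test_that("fully active families label active under tight noise", {
  cfg <- synth_config(n_families = 2, compounds_per_family = 10,
                      family_active_prob = c(1, 1),
                      ic50_log10_sd = 0.2, n_planted_cliffs = 0,
                      seed = 42)
  ds <- generate_dataset(cfg)
  cur <- curate_compounds(ds$records)
  expect_true(all(cur$records$label == "active"))
})

test_that("infeasible decoration requests error out", {
  cfg <- synth_config(n_families = 1, compounds_per_family = 5000,
                      seed = 43)
  expect_error(generate_dataset(cfg), "decorations")
  expect_error(synth_config(n_families = 2, compounds_per_family = 10),
               "seed")
})

test_that("planted cliffs satisfy similarity and fold constraints", {
  cfg <- synth_config(n_families = 4, compounds_per_family = 12,
                      n_planted_cliffs = 4, cliff_fold_min = 100,
                      seed = 44)
  ds <- generate_dataset(cfg)
  out <- plant_cliffs(ds$records, ds$truth)
  cp <- out$truth$cliff_pairs
  expect_equal(nrow(cp), 4)
  recs <- out$records
  for (i in seq_len(nrow(cp))) {
    ia <- match(cp$id_a[i], recs$source_id)
    ib <- match(cp$id_b[i], recs$source_id)
    nm_a <- recs$ic50_value[ia] * ifelse(recs$ic50_unit[ia] == "uM", 1000, 1)
    nm_b <- recs$ic50_value[ib] * ifelse(recs$ic50_unit[ib] == "uM", 1000, 1)
    expect_gte(fold_change(nm_a, nm_b), 100)
    expect_true(xor(nm_a <= 100, nm_b <= 100))
    tc <- tanimoto(
      morgan_fingerprint(out$truth$canonical_smiles[[cp$id_a[i]]]),
      morgan_fingerprint(out$truth$canonical_smiles[[cp$id_b[i]]]))
    expect_gt(tc, 0.6)
  }
  # no-op when zero pairs requested
  cfg0 <- synth_config(n_families = 2, compounds_per_family = 8,
                       n_planted_cliffs = 0, seed = 45)
  ds0 <- generate_dataset(cfg0)
  out0 <- plant_cliffs(ds0$records, ds0$truth)
  expect_identical(out0$records, ds0$records)
})

test_that("fragment enrichment hits the target carrier act%", {
  cfg <- synth_config(n_families = 2, compounds_per_family = 40,
                      n_planted_cliffs = 0,
                      planted_fragment_target_act_pct = 95, seed = 46)
  ds <- generate_dataset(cfg)
  out <- plant_fragment_enrichment(ds$records, ds$truth)
  expect_equal(length(out$truth$fragment_carriers), 40)
  expect_false(is.na(out$truth$fragment_smiles))
  cur <- curate_compounds(out$records)
  carr <- cur$records[cur$records$compound_id %in%
                        out$truth$fragment_carriers, ]
  pct <- 100 * mean(carr$label == "active")
  expect_gte(pct, 85)  # target 95 with a little lognormal label noise

  expect_error(plant_fragment_enrichment(ds$records, ds$truth,
                                         family = "nonexistent"),
               "not part")
})

test_that("the study dataset records rule satisfiers from descriptors", {
  cfg <- synth_config(n_families = 4, compounds_per_family = 12,
                      n_planted_cliffs = 1, seed = 47)
  ds <- synth_study_dataset(cfg)
  # satisfiers are exactly the compounds whose descriptor panel satisfies
  # the planted predicate (nitrile carriers), independent of family
  d <- descriptor_panel(unname(ds$truth$canonical_smiles))
  want <- names(ds$truth$family)[d[, "fr_nitrile"] > 0]
  expect_setequal(ds$truth$rule_satisfiers, want)
  expect_gt(length(want), 0)
  # carriers span more than one scaffold family
  expect_gt(length(unique(ds$truth$family[want])), 1)
  # satisfier activity approximates the configured exact fraction
  cur <- curate_compounds(ds$records)$records
  sat <- cur[cur$compound_id %in% want, ]
  expect_gte(100 * mean(sat$label == "active"), 75)
})
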