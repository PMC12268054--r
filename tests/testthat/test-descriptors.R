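# Descriptor panel, physicochemical profile, rule of five.

test_that("heteroaromatic fragment counts match manual enumeration", {
  d <- descriptors("c1ccncc1")
  expect_equal(unname(d["fr_pyridine"]), 1)
  expect_equal(unname(d["fr_Ar_N"]), 1)
  expect_equal(unname(d["NOCount"]), 1)
  expect_equal(unname(d["NumAromaticHeterocycles"]), 1)

  b <- descriptors("c1ccccc1")
  expect_equal(unname(b["fr_pyridine"]), 0)
  expect_equal(unname(b["fr_Ar_N"]), 0)

  bp <- descriptors("c1ccc(-c2ccccn2)nc1")
  expect_equal(unname(bp["fr_pyridine"]), 2)
  expect_equal(unname(bp["fr_Ar_N"]), 2)
})

test_that("count descriptors match brute-force atom/ring enumeration", {
  # manually derived expectations for the fixture panel
  panel <- fixture_smiles[c("pyridine", "bipyridine", "quinoline",
                            "indole", "naphthalene", "benzamide",
                            "furan", "pyridazinone", "anisole",
                            "phenoxyquinoline", "cyclohexane",
                            "acetamide")]
  expected <- rbind(
    #                 fr_pyridine fr_Ar_N NOCount NumAromaticRings
    pyridine         = c(1, 1, 1, 1),
    bipyridine       = c(2, 2, 2, 2),
    quinoline        = c(1, 1, 1, 2),
    indole           = c(0, 1, 1, 2),
    naphthalene      = c(0, 0, 0, 2),
    benzamide        = c(0, 0, 2, 1),
    furan            = c(0, 0, 1, 1),
    pyridazinone     = c(0, 2, 3, 2),
    anisole          = c(0, 0, 1, 1),
    phenoxyquinoline = c(1, 1, 2, 3),
    cyclohexane      = c(0, 0, 0, 0),
    acetamide        = c(0, 0, 2, 0))
  d <- descriptor_panel(panel)
  got <- unname(d[, c("fr_pyridine", "fr_Ar_N", "NOCount",
                      "NumAromaticRings")])
  expect_equal(got, unname(expected))
  # count descriptors are non-negative integers
  counts <- d[, c("fr_pyridine", "fr_Ar_N", "NOCount", "RingCount",
                  "fr_bicyclic", "nN", "nO")]
  expect_true(all(counts >= 0))
  expect_equal(counts, round(counts))
})

test_that("fused-ring and ring-system descriptors are structural", {
  # naphthalene is edge-fused; biphenyl is two systems; the spiro decane
  # shares only one atom, so it is one ring system but not edge-fused
  d <- descriptor_panel(c("c1ccc2ccccc2c1", "c1ccccc1-c2ccccc2",
                          "C1CCC2(CC1)CCCC2"))
  expect_equal(unname(d[, "fr_bicyclic"]), c(1, 0, 0))
  expect_equal(unname(d[, "NumRingSystems"]), c(1, 2, 1))
})

test_that("bulk properties agree with formula expectations", {
  w <- descriptors("O")
  expect_equal(unname(w["NumHDonors"]), 1)
  expect_equal(unname(w["NumHAcceptors"]), 1)
  expect_equal(unname(w["MolWt"]), 18.02, tolerance = 0.01)
  expect_equal(unname(descriptors("CC")["TPSA"]), 0)
})

test_that("rule of five counts violations against the four thresholds", {
  eth <- rule_of_five(descriptors("CCO"))
  expect_equal(eth$n_violations, 0)
  expect_true(eth$pass)

  fake <- c(MolWt = 600, MolLogP = 6, NumHDonors = 2, NumHAcceptors = 4)
  r <- rule_of_five(fake)
  expect_equal(r$n_violations, 2)
  expect_false(r$pass)

  edge <- c(MolWt = 501, MolLogP = 3, NumHDonors = 1, NumHAcceptors = 5)
  r2 <- rule_of_five(edge)
  expect_equal(r2$n_violations, 1)
  expect_true(r2$pass)
})

test_that("physchem profile summarizes per label", {
  recs <- make_records(c("CCO", "c1ccccc1", "c1ccncc1"), c(10, 20, 500))
  prof <- physchem_profile(recs)
  expect_equal(nrow(prof$per_compound), 3)
  # single-compound label: median equals that compound's value
  inact <- prof$summary[prof$summary$label == "inactive" &
                          prof$summary$property == "MolWt", ]
  expect_equal(inact$median, prof$per_compound$MolWt[3])
  expect_equal(inact$q1, inact$q3)
})

test_that("chemical space embedding is deterministic and shape-correct", {
  fps <- fingerprint_matrix(unname(fixture_smiles[c("benzene", "toluene",
                                                    "pyridine", "ethanol",
                                                    "benzene")]))
  xy1 <- embed_chemspace_2d(fps, seed = 3)
  xy2 <- embed_chemspace_2d(fps, seed = 3)
  expect_identical(xy1, xy2)
  expect_equal(dim(xy1), c(5, 2))
  # duplicated fingerprints land on the same point
  dup_dist <- sqrt(sum((xy1[1, ] - xy1[5, ])^2))
  all_d <- as.matrix(dist(xy1))
  expect_lt(dup_dist, stats::median(all_d[upper.tri(all_d)]) / 100 + 1e-9)
  expect_error(embed_chemspace_2d(fps[1, , drop = FALSE]))
})
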