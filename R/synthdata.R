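# Synthetic compound dataset generator with planted ground truth.
#
# Datasets emulate a kinase-inhibitor SAR corpus: several scaffold
# families built by decorating large template cores (pyridazinone,
# quinoline carboxamide, triazolopyrazine, bipyridine amide,
# naphthyridinone, pyrrolopyrimidine, dimethoxyquinoline chemotypes) with
# small substituents, log-normal IC50s straddling the 100 nM activity
# threshold, plus optional planted activity-cliff pairs, a planted
# activity-enriched fragment family, and a planted descriptor rule
# carried by a substituent drawn independently of family (nitrile by
# default), so the rule cuts across chemotypes. All decoration is
# deterministic template string assembly validated by parsing;
# everything is reproducible from the seed.

# the 4-pyridyl substituent uses a high ring-closure digit so it can be
# spliced into any core without colliding with the core's ring numbering
.SYNTH_SUBS <- c("", "(C)", "(CC)", "(F)", "(Cl)", "(Br)", "(OC)", "(N)",
                 "(C#N)", "(O)", "(c9ccncc9)")

.SYNTH_FAMILIES <- list(
  pyridazinone = list(
    core = "O=C1C=CC(=NN1{R1})c1ccc(-c2cc(N3CCOCC3)ncn2)c{R2}c1",
    r1 = c("", "C", "CC", "CCC", "C(C)C", "CCO", "CC#N", "CC(N)=O"),
    active_prob = 0.85),
  quinoline_amide = list(
    core = "O(c1ccnc2ccc{R1}cc12)c1ccc(NC(=O)C2(CC2)C(=O)Nc2ccc(F)cc2)c{R2}c1",
    r1 = .SYNTH_SUBS, active_prob = 0.60),
  triazolopyrazine = list(
    core = "C(c1nnc2cnccn12)c1ccc2ncc{R2}cc2c1{R1}",
    r1 = .SYNTH_SUBS, active_prob = 0.65),
  bipyridine_amide = list(
    core = "O=C(Nc1ccc(-c2ccncc2)cc1{R1})c1ccnc(-c2ccc(F)cc2)c1{R2}",
    r1 = .SYNTH_SUBS, active_prob = 0.70),
  naphthyridinone = list(
    core = "O=C1C=Cc2ccc(-c3ccc(F)c{R2}c3)nc2N1Cc1ccc{R1}cc1",
    r1 = .SYNTH_SUBS, active_prob = 0.50),
  pyrrolopyrimidine = list(
    core = "Nc1ncnc2c1c(-c1ccc(NC(=O)c3cncc(-c4ccccc4)c3)c(Cl)c1{R2})cn2{R1}",
    r1 = c("C", "CC", "CCO", "CCC", "C(C)C", "CCN", "CCOC"),
    active_prob = 0.45),
  dimethoxyquinoline = list(
    core = "COc1cc2nccc(Oc3ccc(CN4CCN(C)CC4)c{R1}c3{R2})c2cc1OC",
    r1 = .SYNTH_SUBS, active_prob = 0.15)
)

.fill_core <- function(core, r1, r2) {
  s <- gsub("{R1}", r1, core, fixed = TRUE)
  gsub("{R2}", r2, s, fixed = TRUE)
}

#' Synthetic dataset configuration
#'
#' Defaults define the package's reference study conditions: six scaffold
#' families of 60 compounds each (the first six chemotypes of the
#' template bank), active IC50s log-normal around 10 nM and inactive
#' around 1000 nM with 0.4 log units of spread (so the two populations
#' straddle the 100 nM label threshold with a little label noise), ten
#' planted cliff pairs at a minimum 100-fold potency gap, the
#' pyridazinone family re-labeled to 95% active as the planted enriched
#' fragment, and `fr_nitrile > 0` as the planted activity rule: the
#' nitrile substituent is drawn independently of scaffold family, and its
#' carriers are re-labeled to an exact 85% active fraction, so the rule
#' is a substituent-borne, cross-family activity driver rather than a
#' proxy for any one chemotype.
#'
#' @param n_families Number of scaffold families (1 to 7).
#' @param compounds_per_family Compounds drawn per family (limited by the
#'   decoration enumeration).
#' @param family_active_prob Per-family probability that a compound is
#'   generated in the active state; `NULL` uses the template defaults.
#' @param ic50_log10_mean_active,ic50_log10_mean_inactive Means of
#'   log10(IC50 in nM) for the two states (defaults 1 and 3).
#' @param ic50_log10_sd Log10 spread (default 0.4).
#' @param n_planted_cliffs Cliff pairs to plant (default 10).
#' @param cliff_fold_min Minimum planted potency ratio (default 100).
#' @param planted_fragment_family Family whose core is the planted
#'   enriched fragment (default `"pyridazinone"`).
#' @param planted_fragment_target_act_pct Target carrier act% (default 95).
#' @param planted_rule A [predicate()] data frame describing the planted
#'   descriptor rule (default `fr_nitrile > 0`, carried by the
#'   nitrile-decorated compounds of every family).
#' @param rule_active_prob Active fraction imposed on the planted rule's
#'   satisfiers (default 0.85).
#' @param seed Mandatory integer seed.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_families = 6, compounds_per_family = 60,
                         family_active_prob = NULL,
                         ic50_log10_mean_active = 1,
                         ic50_log10_mean_inactive = 3,
                         ic50_log10_sd = 0.4,
                         n_planted_cliffs = 10,
                         cliff_fold_min = 100,
                         planted_fragment_family = "pyridazinone",
                         planted_fragment_target_act_pct = 95,
                         planted_rule = predicate("fr_nitrile", ">", 0),
                         rule_active_prob = 0.85,
                         seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_families >= 1, n_families <= length(.SYNTH_FAMILIES),
            compounds_per_family >= 1)
  fams <- names(.SYNTH_FAMILIES)[seq_len(n_families)]
  if (is.null(family_active_prob)) {
    family_active_prob <- vapply(.SYNTH_FAMILIES[fams], `[[`, numeric(1),
                                 "active_prob")
  } else {
    stopifnot(length(family_active_prob) == n_families,
              all(family_active_prob >= 0), all(family_active_prob <= 1))
    names(family_active_prob) <- fams
  }
  structure(list(
    n_families = n_families, families = fams,
    compounds_per_family = compounds_per_family,
    family_active_prob = family_active_prob,
    ic50_log10_mean_active = ic50_log10_mean_active,
    ic50_log10_mean_inactive = ic50_log10_mean_inactive,
    ic50_log10_sd = ic50_log10_sd,
    n_planted_cliffs = n_planted_cliffs,
    cliff_fold_min = cliff_fold_min,
    planted_fragment_family = planted_fragment_family,
    planted_fragment_target_act_pct = planted_fragment_target_act_pct,
    planted_rule = planted_rule,
    rule_active_prob = rule_active_prob,
    seed = as.integer(seed)), class = "synth_config")
}

# all valid unique decorations of a family core, as (raw, canonical)
.family_pool <- function(fam) {
  spec <- .SYNTH_FAMILIES[[fam]]
  combos <- expand.grid(r1 = spec$r1, r2 = .SYNTH_SUBS,
                        stringsAsFactors = FALSE)
  raw <- vapply(seq_len(nrow(combos)), function(i)
    .fill_core(spec$core, combos$r1[i], combos$r2[i]), character(1))
  can <- canonicalize_smiles(raw)
  ok <- !is.na(can) & !duplicated(can)
  data.frame(raw = raw[ok], canonical = can[ok], r1 = combos$r1[ok],
             r2 = combos$r2[ok], stringsAsFactors = FALSE)
}

#' Generate a synthetic compound dataset
#'
#' Builds the scaffold families of the configuration and draws each
#' compound's activity state and IC50. Output records are raw (some
#' IC50s are expressed in uM to exercise unit conversion downstream) and
#' round-trip through [curate_compounds()] without rejections.
#'
#' @param config A [synth_config()].
#' @return List with `records` (raw data frame: `source_id`, `smiles`,
#'   `ic50_value`, `ic50_unit`, `year`) and `truth` (list of class
#'   `"synth_truth"`: per-compound `family` and `canonical_smiles`,
#'   `cliff_pairs`, `fragment_carriers`, `fragment_smiles`,
#'   `rule_satisfiers`, `config`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    recs <- list()
    fam_of <- character(0)
    for (fam in config$families) {
      pool <- .family_pool(fam)
      m <- config$compounds_per_family
      if (m > nrow(pool))
        stop("family ", fam, " supports at most ", nrow(pool),
             " unique decorations (requested ", m, ")")
      pick <- pool[sample(nrow(pool), m), , drop = FALSE]
      # exact stratified counts: the family's active fraction is hit up
      # to rounding, with the identity of the actives randomized
      n_act <- round(m * config$family_active_prob[[fam]])
      active <- rep(FALSE, m)
      active[sample(m, n_act)] <- TRUE
      mu <- ifelse(active, config$ic50_log10_mean_active,
                   config$ic50_log10_mean_inactive)
      ic50 <- 10^stats::rnorm(m, mu, config$ic50_log10_sd)
      recs[[fam]] <- data.frame(
        smiles = pick$raw, canonical = pick$canonical, ic50_nM = ic50,
        year = sample(2004:2022, m, replace = TRUE),
        stringsAsFactors = FALSE)
      fam_of <- c(fam_of, rep(fam, m))
    }
    df <- do.call(rbind, recs)
    rownames(df) <- NULL
    n <- nrow(df)
    ids <- sprintf("SYN%04d", seq_len(n))
    # a deterministic subset carries uM units to exercise conversion
    um <- seq_len(n) %% 7 == 0
    records <- data.frame(
      source_id = ids,
      smiles = df$smiles,
      ic50_value = ifelse(um, df$ic50_nM / 1000, df$ic50_nM),
      ic50_unit = ifelse(um, "uM", "nM"),
      year = df$year,
      stringsAsFactors = FALSE)
    truth <- structure(list(
      family = stats::setNames(fam_of, ids),
      canonical_smiles = stats::setNames(df$canonical, ids),
      cliff_pairs = data.frame(id_a = character(0), id_b = character(0),
                               fold = numeric(0)),
      fragment_carriers = character(0),
      fragment_smiles = NA_character_,
      rule_satisfiers = character(0),
      config = config), class = "synth_truth")
    list(records = records, truth = truth)
  })
}

#' Plant activity-cliff pairs
#'
#' Appends `n_pairs` pairs of single-substituent variants of family
#' cores: the two members of a pair differ in one decoration, sit on
#' opposite sides of the 100 nM threshold with a potency ratio of at
#' least `fold_min`, and their fingerprint Tanimoto similarity is
#' verified to exceed 0.6 at generation time (pairs that cannot satisfy
#' the constraint are skipped with a warning).
#'
#' @param records,truth A [generate_dataset()] output pair.
#' @param n_pairs Number of pairs to plant (default from the config).
#' @param fold_min Minimum potency ratio (default from the config).
#' @return Updated `list(records, truth)`; planted ids are recorded in
#'   `truth$cliff_pairs`.
#' @export
plant_cliffs <- function(records, truth, n_pairs = NULL, fold_min = NULL) {
  config <- truth$config
  n_pairs <- n_pairs %||% config$n_planted_cliffs
  fold_min <- fold_min %||% config$cliff_fold_min
  if (n_pairs == 0) return(list(records = records, truth = truth))
  .with_seed(config$seed + 1L, {
    used <- unname(truth$canonical_smiles)
    fams <- config$families
    next_id <- nrow(records)
    planted <- 0L
    for (i in seq_len(n_pairs)) {
      fam <- fams[(i - 1L) %% length(fams) + 1L]
      pool <- .family_pool(fam)
      free <- pool[!(pool$canonical %in% used), , drop = FALSE]
      done <- FALSE
      # candidate pairs share r1 and differ in r2
      for (r1 in unique(free$r1)) {
        sub <- free[free$r1 == r1, , drop = FALSE]
        if (nrow(sub) < 2) next
        ord <- sample(nrow(sub))
        for (j in seq_len(min(6, length(ord) - 1))) {
          a <- sub[ord[j], ]; b <- sub[ord[j + 1], ]
          tc <- tanimoto(morgan_fingerprint(a$canonical),
                         morgan_fingerprint(b$canonical))
          if (tc > 0.6) {
            ic_a <- 10^stats::rnorm(1, 0.6, 0.2)           # ~2-10 nM
            fold <- fold_min * 10^stats::runif(1, 0.05, 0.6)
            ic_b <- ic_a * fold
            id_a <- sprintf("SYN%04d", next_id + 1L)
            id_b <- sprintf("SYN%04d", next_id + 2L)
            next_id <- next_id + 2L
            records <- rbind(records, data.frame(
              source_id = c(id_a, id_b), smiles = c(a$raw, b$raw),
              ic50_value = c(ic_a, ic_b), ic50_unit = "nM",
              year = sample(2004:2022, 2, replace = TRUE)))
            truth$family <- c(truth$family,
                              stats::setNames(c(fam, fam), c(id_a, id_b)))
            truth$canonical_smiles <- c(
              truth$canonical_smiles,
              stats::setNames(c(a$canonical, b$canonical), c(id_a, id_b)))
            truth$cliff_pairs <- rbind(
              truth$cliff_pairs,
              data.frame(id_a = id_a, id_b = id_b, fold = fold))
            used <- c(used, a$canonical, b$canonical)
            planted <- planted + 1L
            done <- TRUE
          }
          if (done) break
        }
        if (done) break
      }
      if (!done)
        warning("could not plant cliff pair ", i, " in family ", fam)
    }
    rownames(records) <- NULL
    list(records = records, truth = truth)
  })
}

#' Plant an activity-enriched fragment
#'
#' Re-draws the IC50s of the carriers of one family core so that their
#' active percentage approximates `target_act_pct`, making the core a
#' recoverable structural alert. Carriers are identified from the
#' generator's ground truth (every member of the fragment family contains
#' the core by construction).
#'
#' @param records,truth A [generate_dataset()] (optionally
#'   [plant_cliffs()]-extended) output pair.
#' @param family Fragment family name (default from the config); must be
#'   one of the generated families.
#' @param target_act_pct Target carrier act% (default from the config).
#' @return Updated `list(records, truth)` with `truth$fragment_carriers`
#'   and `truth$fragment_smiles` filled in.
#' @export
plant_fragment_enrichment <- function(records, truth, family = NULL,
                                      target_act_pct = NULL) {
  config <- truth$config
  family <- family %||% config$planted_fragment_family
  target_act_pct <- target_act_pct %||% config$planted_fragment_target_act_pct
  if (!family %in% config$families)
    stop("fragment family ", family, " is not part of the generated dataset")
  carriers <- names(truth$family)[truth$family == family]
  if (!length(carriers)) return(list(records = records, truth = truth))
  # planted cliff pairs keep their potencies: their label contrast is the
  # point of the cliff planting
  protected <- unlist(truth$cliff_pairs[c("id_a", "id_b")])
  resample <- setdiff(carriers, protected)
  .with_seed(config$seed + 2L, {
    idx <- match(resample, records$source_id)
    m <- length(idx)
    n_active <- round(m * target_act_pct / 100)
    state <- rep(FALSE, m)
    state[sample(m, n_active)] <- TRUE
    mu <- ifelse(state, config$ic50_log10_mean_active,
                 config$ic50_log10_mean_inactive)
    ic50 <- 10^stats::rnorm(m, mu, config$ic50_log10_sd)
    um <- records$ic50_unit[idx] == "uM"
    records$ic50_value[idx] <- ifelse(um, ic50 / 1000, ic50)
    truth$fragment_carriers <- carriers
    truth$fragment_smiles <- canonicalize_smiles(
      .fill_core(.SYNTH_FAMILIES[[family]]$core, "", ""))
    list(records = records, truth = truth)
  })
}

#' Plant a descriptor activity rule
#'
#' Identifies the satisfiers of the configured descriptor rule from the
#' descriptor panel of the generated structures (not from family labels)
#' and re-draws their IC50s so that an exact `active_prob` fraction of
#' them is active. Planted cliff pairs and fragment carriers keep their
#' potencies (cliff > fragment > rule precedence), so the plantings do
#' not undo each other.
#'
#' @param records,truth A generator output pair.
#' @param rule Predicate data frame (default from the config).
#' @param active_prob Active fraction among satisfiers (default from the
#'   config).
#' @return Updated `list(records, truth)` with `truth$rule_satisfiers`
#'   set to all satisfier ids.
#' @export
plant_rule_activity <- function(records, truth, rule = NULL,
                                active_prob = NULL) {
  config <- truth$config
  rule <- rule %||% config$planted_rule
  active_prob <- active_prob %||% config$rule_active_prob
  d <- descriptor_panel(unname(truth$canonical_smiles))
  sat <- .rule_matches(rule, d)
  satisfiers <- names(truth$family)[sat]
  truth$rule_satisfiers <- satisfiers
  protected <- c(unlist(truth$cliff_pairs[c("id_a", "id_b")]),
                 truth$fragment_carriers)
  resample <- setdiff(satisfiers, protected)
  if (!length(resample)) return(list(records = records, truth = truth))
  .with_seed(config$seed + 3L, {
    idx <- match(resample, records$source_id)
    m <- length(idx)
    n_act <- round(m * active_prob)
    state <- rep(FALSE, m)
    state[sample(m, n_act)] <- TRUE
    mu <- ifelse(state, config$ic50_log10_mean_active,
                 config$ic50_log10_mean_inactive)
    ic50 <- 10^stats::rnorm(m, mu, config$ic50_log10_sd)
    um <- records$ic50_unit[idx] == "uM"
    records$ic50_value[idx] <- ifelse(um, ic50 / 1000, ic50)
    list(records = records, truth = truth)
  })
}

#' Generate the full synthetic study dataset
#'
#' Convenience chain: [generate_dataset()], [plant_cliffs()],
#' [plant_fragment_enrichment()], [plant_rule_activity()].
#'
#' @param config A [synth_config()].
#' @return `list(records, truth)` as above.
#' @export
synth_study_dataset <- function(config) {
  out <- generate_dataset(config)
  out <- plant_cliffs(out$records, out$truth)
  out <- plant_fragment_enrichment(out$records, out$truth)
  plant_rule_activity(out$records, out$truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic ground truth: %d compounds, %d families, %d planted cliff pairs\n",
    length(x$family), length(unique(x$family)), nrow(x$cliff_pairs)))
  cat(sprintf("  fragment family: %s (%d carriers), rule satisfiers: %d\n",
              x$config$planted_fragment_family, length(x$fragment_carriers),
              length(x$rule_satisfiers)))
  invisible(x)
}
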