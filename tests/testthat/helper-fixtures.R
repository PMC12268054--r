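# Shared fixtures and independent oracles for the test suite.

# a small panel of common drug-like and probe molecules
fixture_smiles <- c(
  ethanol     = "CCO",
  water       = "O",
  methane     = "C",
  hexane      = "CCCCCC",
  benzene     = "c1ccccc1",
  toluene     = "Cc1ccccc1",
  pyridine    = "c1ccncc1",
  bipyridine  = "c1ccc(-c2ccccn2)nc1",
  quinoline   = "c1ccc2ncccc2c1",
  phenol      = "Oc1ccccc1",
  anisole     = "COc1ccccc1",
  aniline     = "Nc1ccccc1",
  benzamide   = "NC(=O)c1ccccc1",
  indole      = "c1ccc2[nH]ccc2c1",
  naphthalene = "c1ccc2ccccc2c1",
  pyridazinone = "O=C1C=CC(=NN1)c1ccccc1",
  phenoxyquinoline = "c1ccc(Oc2ccnc3ccccc23)cc1",
  furan       = "c1ccoc1",
  acetamide   = "CC(N)=O",
  cyclohexane = "C1CCCCC1"
)

# quick labeled record table from SMILES + IC50s (assumed nM, curated form)
make_records <- function(smiles, ic50, ids = NULL, threshold = 100) {
  ids <- ids %||% paste0("CPD", seq_along(smiles))
  data.frame(compound_id = ids,
             canonical_smiles = unname(smiles),
             ic50_nM = ic50,
             pic50 = pic50(ic50),
             label = label_activity(ic50, threshold),
             year = NA_integer_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force hypergeometric tails by explicit combinatorial enumeration
oracle_hyper_tails <- function(k, n, K, N) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  pmf <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
  names(pmf) <- lo:hi
  xs <- lo:hi
  list(p_enriched = sum(pmf[xs >= k]), p_depleted = sum(pmf[xs <= k]))
}

# brute-force similar-pair enumeration from a similarity matrix
oracle_pairs <- function(tm, threshold, strict = TRUE) {
  n <- nrow(tm)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- if (strict) tm[i, j] > threshold else tm[i, j] >= threshold
      if (ok) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(0L, 0, 2)
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

# deterministic synthetic two-family compound set for graph/pair oracles
two_family_records <- function(n_per = 8, seed = 5) {
  cfg <- synth_config(n_families = 2, compounds_per_family = n_per,
                      n_planted_cliffs = 0, seed = seed)
  ds <- generate_dataset(cfg)
  curate_compounds(ds$records)$records
}
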