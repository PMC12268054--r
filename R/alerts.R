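# Structural alerts: circular atom environments scored for activity
# enrichment/depletion with exact hypergeometric tail tests.
#
# Environments are the same hashed circular neighborhoods that underlie
# the Morgan fingerprint (unfolded identifiers, so no bit collisions),
# enumerated up to a configurable radius. Counting is presence/absence: a
# compound contributes each distinct environment once, which is what the
# hypergeometric urn model requires.

#' Enumerate circular atom environments in a compound set
#'
#' @param records Curated compound data frame.
#' @param max_radius Maximum environment radius in bonds (default 3).
#' @return List of class `"environment_map"`: `keys` (data frame with
#'   `env_id`, `radius`, `example_smiles` - the substructure SMILES
#'   reconstructed from one carrier, best effort - and
#'   `example_compound`), and `members` (list mapping `env_id` to the
#'   integer indices of the records containing it).
#' @export
enumerate_environments <- function(records, max_radius = 3) {
  smiles <- records$canonical_smiles
  mols <- mol_parse_batch(smiles)
  members <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (i in seq_along(mols)) {
    env <- atom_environments(mols[[i]], max_radius = max_radius)
    seen <- character(0)
    for (r in 0:max_radius) {
      col <- env[, r + 1]
      for (a in seq_along(col)) {
        key <- sprintf("%.0f", col[a])
        if (key %in% seen) next
        seen <- c(seen, key)
        members[[key]] <- c(members[[key]], i)
        # example carrier chosen by smallest canonical SMILES so the
        # output does not depend on record order
        if (is.null(meta[[key]]) || smiles[i] < smiles[meta[[key]]$mol_idx])
          meta[[key]] <- list(radius = r, mol_idx = i, atom = a)
      }
    }
  }
  keys <- ls(envir = members)
  # deterministic order independent of input record order: by radius,
  # then by environment id
  info <- lapply(keys, function(k) meta[[k]])
  ord <- order(vapply(info, `[[`, numeric(1), "radius"), as.numeric(keys))
  keys <- keys[ord]
  info <- info[ord]
  keydf <- data.frame(
    env_id = keys,
    radius = vapply(info, `[[`, numeric(1), "radius"),
    example_compound = as.character(
      records$compound_id[vapply(info, `[[`, numeric(1), "mol_idx")]),
    example_smiles = vapply(seq_along(keys), function(j) {
      m <- mols[[info[[j]]$mol_idx]]
      .environment_smiles(m, info[[j]]$atom, info[[j]]$radius)
    }, character(1)))
  structure(list(keys = keydf,
                 members = stats::setNames(lapply(keys, function(k)
                   sort(unique(members[[k]]))), keys)),
            class = "environment_map")
}

# substructure SMILES of the atoms within `radius` bonds of `atom`
.environment_smiles <- function(mol, atom, radius) {
  sel <- atom
  frontier <- atom
  r <- 0
  while (r < radius && length(frontier)) {
    frontier <- setdiff(unique(unlist(mol$adj[frontier])), sel)
    sel <- c(sel, frontier)
    r <- r + 1
  }
  subgraph_smiles(mol, sel)
}

#' Exact hypergeometric tail probabilities
#'
#' For an urn of `N` compounds of which `K` are active, and an environment
#' present in `n` compounds of which `k` are active: `p_enriched = P(X >=
#' k)` and `p_depleted = P(X <= k)` where `X ~ Hypergeometric(N, K, n)`.
#' Computed with `stats::phyper` (log-space stable).
#'
#' @param k Actives carrying the substructure.
#' @param n Compounds carrying the substructure.
#' @param K Actives in the dataset.
#' @param N Compounds in the dataset.
#' @return List with `p_enriched` and `p_depleted`.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N || k > K ||
      (n - k) > (N - K))
    stop("inconsistent hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")")
  list(p_enriched = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_depleted = stats::phyper(k, K, N - K, n))
}

#' Percentage of actives among carriers
#'
#' @param n_active_with Actives containing the substructure.
#' @param n_total_with Compounds containing the substructure (> 0).
#' @return `100 * k / n`, rounded to 2 decimals.
#' @export
act_pct <- function(n_active_with, n_total_with) {
  if (any(n_total_with <= 0)) stop("zero carrier count")
  if (any(n_active_with < 0) || any(n_active_with > n_total_with))
    stop("invalid active carrier count")
  round(100 * n_active_with / n_total_with, 2)
}

#' Find structural alerts
#'
#' Scores every circular environment carried by at least `min_support`
#' compounds with two-sided hypergeometric tails against the dataset's
#' active/inactive split, and reports those significant at `alpha` as
#' active alerts (enriched among actives) or inactive alerts (depleted).
#'
#' @param records Curated compound data frame containing both labels.
#' @param max_radius Environment radius bound (default 3).
#' @param min_support Minimum carrier count (default 30).
#' @param alpha Significance cut on the smaller tail (default 0.05).
#' @param p_adjust Multiple-testing correction applied to each tail
#'   across tested environments: `"none"` (default), `"bonferroni"`, or
#'   `"BH"`.
#' @param env_map Optional precomputed [enumerate_environments()] result.
#' @return Data frame of class `"alert_table"`, ranked by p-value:
#'   `env_id`, `radius`, `smarts`, `example_smiles`, `n`, `k`, `N`, `K`,
#'   `p_enriched`, `p_depleted`, `act_pct`, `direction`.
#' @export
find_alerts <- function(records, max_radius = 3, min_support = 30,
                        alpha = 0.05, p_adjust = c("none", "bonferroni", "BH"),
                        env_map = NULL) {
  p_adjust <- match.arg(p_adjust)
  labs <- records$label
  if (length(unique(labs)) < 2)
    stop("alerts need both active and inactive compounds")
  if (is.null(env_map))
    env_map <- enumerate_environments(records, max_radius = max_radius)
  N <- nrow(records)
  K <- sum(labs == "active")
  supp <- lengths(env_map$members)
  sel <- which(supp >= min_support)
  if (!length(sel)) {
    out <- data.frame(env_id = character(0), radius = numeric(0),
                      smarts = character(0), example_smiles = character(0),
                      n = integer(0), k = integer(0), N = integer(0),
                      K = integer(0), p_enriched = numeric(0),
                      p_depleted = numeric(0), act_pct = numeric(0),
                      direction = character(0))
    class(out) <- c("alert_table", class(out))
    return(out)
  }
  rows <- lapply(sel, function(j) {
    ids <- env_map$members[[j]]
    n <- length(ids)
    k <- sum(labs[ids] == "active")
    p <- hypergeom_tail(k, n, K, N)
    data.frame(env_id = names(env_map$members)[j],
               radius = env_map$keys$radius[j],
               smarts = env_map$keys$example_smiles[j],
               example_smiles = min(records$canonical_smiles[ids]),
               n = n, k = k, N = N, K = K,
               p_enriched = p$p_enriched, p_depleted = p$p_depleted,
               act_pct = act_pct(k, n))
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_enriched <- stats::p.adjust(out$p_enriched, method = p_adjust)
    out$p_depleted <- stats::p.adjust(out$p_depleted, method = p_adjust)
  }
  out$direction <- ifelse(out$p_enriched <= out$p_depleted,
                          "active_alert", "inactive_alert")
  p_min <- pmin(out$p_enriched, out$p_depleted)
  keep <- p_min <= alpha
  out <- out[keep, , drop = FALSE]
  out <- out[order(p_min[keep], out$env_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alert_table", class(out))
  out
}
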