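# Activity cliffs: similar compound pairs with opposite activity labels,
# and safe-bet / dead-end compound profiles.

#' Enumerate similar compound pairs
#'
#' Every unordered pair of compounds whose Tanimoto similarity passes the
#' threshold (strict `>` by default, matching the cliff definition
#' "Tc above 0.6"), annotated with its kind: `both_active`,
#' `both_inactive`, or `cliff` (opposite labels), and the IC50 fold
#' change.
#'
#' @param records Curated compound data frame.
#' @param threshold Similarity threshold (default 0.6).
#' @param strict Use `>` (default TRUE) or `>=`.
#' @param fps Optional precomputed fingerprint matrix.
#' @return Data frame of pairs: `id_a`, `id_b` (with `id_a < id_b`),
#'   `tanimoto`, `ic50_a_nM`, `ic50_b_nM`, `label_a`, `label_b`, `fold`,
#'   `kind`.
#' @export
enumerate_similar_pairs <- function(records, threshold = 0.6, strict = TRUE,
                                    fps = NULL) {
  n <- nrow(records)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      tanimoto = numeric(0), ic50_a_nM = numeric(0),
                      ic50_b_nM = numeric(0), label_a = character(0),
                      label_b = character(0), fold = numeric(0),
                      kind = character(0))
  if (n < 2) return(empty)
  if (is.null(fps)) fps <- fingerprint_matrix(records$canonical_smiles)
  tm <- tanimoto_matrix(fps)
  pass <- if (strict) tm > threshold else tm >= threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  ids_i <- as.character(records$compound_id[i])
  ids_j <- as.character(records$compound_id[j])
  swap <- ids_j < ids_i
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  out <- data.frame(
    id_a = as.character(records$compound_id[a]),
    id_b = as.character(records$compound_id[b]),
    tanimoto = tm[idx],
    ic50_a_nM = records$ic50_nM[a],
    ic50_b_nM = records$ic50_nM[b],
    label_a = records$label[a],
    label_b = records$label[b],
    fold = fold_change(records$ic50_nM[a], records$ic50_nM[b]),
    kind = ifelse(records$label[a] != records$label[b], "cliff",
                  ifelse(records$label[a] == "active", "both_active",
                         "both_inactive")))
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify similar pairs
#'
#' Partition counts (and fractions) of the pair kinds; the cliff count is
#' the headline number.
#'
#' @param pairs Output of [enumerate_similar_pairs()].
#' @return List of class `"pair_classification"`: `counts` (data frame of
#'   kind, n, fraction) and `n_cliffs`.
#' @export
classify_pairs <- function(pairs) {
  kinds <- c("both_active", "both_inactive", "cliff")
  n <- vapply(kinds, function(k) sum(pairs$kind == k), numeric(1))
  total <- nrow(pairs)
  counts <- data.frame(kind = kinds, n = as.integer(n),
                       fraction = if (total) n / total else rep(0, 3))
  structure(list(counts = counts, n_pairs = total,
                 n_cliffs = as.integer(n[["cliff"]])),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("%d similar pairs, of which %d activity cliffs\n",
              x$n_pairs, x$n_cliffs))
  print(x$counts, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Safe-bet / dead-end compound profiles
#'
#' Per-compound tallies of similar partners in the same and the opposing
#' activity class. An active compound with at least `min_partners`
#' inactive partners is a dead end (small changes keep killing its
#' activity); an inactive compound with at least `min_partners` active
#' partners is a safe bet (its neighborhood is full of actives).
#'
#' @param pairs Output of [enumerate_similar_pairs()].
#' @param min_partners Minimum opposing-class partner count to be
#'   categorized (default 10).
#' @return Data frame sorted by decreasing `n_opposing_partners`:
#'   `compound_id`, `label`, `n_similar_same_class`,
#'   `n_opposing_partners`, `category` (`dead_end`/`safe_bet`/`none`).
#' @export
profile_compounds <- function(pairs, min_partners = 10) {
  if (!nrow(pairs)) {
    return(data.frame(compound_id = character(0), label = character(0),
                      n_similar_same_class = integer(0),
                      n_opposing_partners = integer(0),
                      category = character(0)))
  }
  long <- rbind(
    data.frame(compound_id = pairs$id_a, label = pairs$label_a,
               kind = pairs$kind),
    data.frame(compound_id = pairs$id_b, label = pairs$label_b,
               kind = pairs$kind))
  ids <- unique(long$compound_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    sub <- long[long$compound_id == id, , drop = FALSE]
    opp <- sum(sub$kind == "cliff")
    same <- sum(sub$kind != "cliff")
    lab <- sub$label[1]
    cat_ <- if (opp >= min_partners) {
      if (lab == "active") "dead_end" else "safe_bet"
    } else "none"
    data.frame(compound_id = id, label = lab,
               n_similar_same_class = same, n_opposing_partners = opp,
               category = cat_)
  }))
  out <- out[order(-out$n_opposing_partners, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cliff census per cluster
#'
#' Counts activity-cliff pairs per cluster; a pair contributes to the
#' cluster of each of its members (once per member). Clusters are ranked
#' by cliff count.
#'
#' @param pairs Output of [enumerate_similar_pairs()].
#' @param assignment A [cluster_compounds()] result or integer label
#'   vector, aligned with `records`.
#' @param records The compound data frame the clustering was computed on
#'   (used to map compound ids to clusters).
#' @return Data frame `(cluster_id, n_cliffs)` sorted decreasing; empty
#'   when there are no cliffs.
#' @export
scaffold_cliff_census <- function(pairs, assignment, records) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  cl_of <- stats::setNames(labels, as.character(records$compound_id))
  cliffs <- pairs[pairs$kind == "cliff", , drop = FALSE]
  if (!nrow(cliffs)) {
    return(data.frame(cluster_id = integer(0), n_cliffs = integer(0)))
  }
  touched <- c(cl_of[cliffs$id_a], cl_of[cliffs$id_b])
  tab <- table(touched)
  out <- data.frame(cluster_id = as.integer(names(tab)),
                    n_cliffs = as.integer(tab))
  out <- out[order(-out$n_cliffs, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
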