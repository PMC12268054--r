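# Hierarchical clustering of the fingerprint matrix, silhouette-guided
# cluster-count scanning, per-cluster summaries with MCS scaffolds.
#
# The clustering operates on the raw binary fingerprint vectors with
# Euclidean distance and Ward linkage (hclust "ward.D2", the Ward
# criterion on squared Euclidean distances) - no prior dimensionality
# reduction.

#' Cluster compounds by fingerprint
#'
#' @param fps Fingerprint matrix ([fingerprint_matrix()]).
#' @param n_clusters Number of clusters, between 1 and `nrow(fps)`.
#' @return List of class `"cluster_assignment"`: `labels` (integer cluster
#'   id 1..k per compound), `k`, `linkage` (`"ward"`), `metric`
#'   (`"euclidean"`), and the `hclust` tree.
#' @export
cluster_compounds <- function(fps, n_clusters) {
  n <- nrow(fps)
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters must be in [1, ", n, "]")
  d <- stats::dist(fps, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  structure(list(labels = unname(labels), k = n_clusters,
                 linkage = "ward", metric = "euclidean", tree = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Ward/Euclidean clustering: %d compounds in %d clusters\n",
              length(x$labels), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Silhouette scan over cluster counts
#'
#' Mean silhouette width (Euclidean distances) of the Ward clustering for
#' each candidate k, used to choose a cluster count.
#'
#' @param fps Fingerprint matrix.
#' @param k_values Integer vector of candidate cluster counts; values
#'   outside `[2, n - 1]` are dropped with a warning.
#' @return Data frame `(k, silhouette)` sorted by `k`. A `degenerate`
#'   attribute is set when all fingerprints are identical.
#' @export
silhouette_scan <- function(fps, k_values) {
  n <- nrow(fps)
  k_values <- sort(unique(as.integer(k_values)))
  bad <- k_values < 2 | k_values > n - 1
  if (any(bad)) {
    warning("dropping invalid k values: ",
            paste(k_values[bad], collapse = ", "))
    k_values <- k_values[!bad]
  }
  d <- stats::dist(fps, method = "euclidean")
  degenerate <- all(d == 0)
  if (degenerate) warning("all fingerprints identical; silhouette undefined")
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_values, function(k) {
    if (degenerate) return(NA_real_)
    cl <- stats::cutree(hc, k = k)
    if (length(unique(cl)) < 2) return(NA_real_)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  out <- data.frame(k = k_values, silhouette = sil)
  attr(out, "degenerate") <- degenerate
  out
}

#' Summarize clusters
#'
#' One summary row per non-empty cluster: size, activity composition,
#' IC50 statistics, intracluster similarity (minimum and median pairwise
#' Tanimoto - the median is the "median intracluster similarity" score),
#' and the cluster's MCS scaffold (ring atoms matching ring atoms only).
#' Singleton clusters are recorded with similarity 1 and flagged.
#'
#' @param assignment A [cluster_compounds()] result (or an integer label
#'   vector).
#' @param records Curated compound data frame aligned with the
#'   fingerprints.
#' @param fps Fingerprint matrix.
#' @param compute_mcs Compute the per-cluster MCS scaffold (default TRUE;
#'   the MCS search dominates runtime on large clusters).
#' @param mcs_timeout_s Per-cluster MCS budget in seconds.
#' @return Data frame of class `"cluster_summary"`, sortable by
#'   `pct_active`.
#' @export
summarize_clusters <- function(assignment, records, fps,
                               compute_mcs = TRUE, mcs_timeout_s = 10) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  stopifnot(length(labels) == nrow(records), nrow(records) == nrow(fps))
  tm <- tanimoto_matrix(fps)
  rows <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    m <- length(idx)
    sims <- if (m >= 2) tm[idx, idx][lower.tri(matrix(0, m, m))] else 1
    mcs_res <- if (compute_mcs) {
      mcs(records$canonical_smiles[idx], ring_matches_ring_only = TRUE,
          timeout_s = mcs_timeout_s)
    } else list(smarts = NA_character_, num_atoms = NA_integer_,
                num_bonds = NA_integer_, complete = NA)
    rows[[length(rows) + 1]] <- data.frame(
      cluster_id = cl,
      n_members = m,
      n_active = sum(records$label[idx] == "active"),
      pct_active = round(100 * sum(records$label[idx] == "active") / m, 2),
      ic50_median_nM = stats::median(records$ic50_nM[idx]),
      ic50_min_nM = min(records$ic50_nM[idx]),
      ic50_max_nM = max(records$ic50_nM[idx]),
      sim_min = min(sims),
      sim_median = stats::median(sims),
      singleton = m == 1,
      mcs_smarts = mcs_res$smarts,
      mcs_num_atoms = mcs_res$num_atoms,
      mcs_num_bonds = mcs_res$num_bonds,
      mcs_complete = mcs_res$complete)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_summary", class(out))
  out
}

#' Partition clusters by activity enrichment
#'
#' Splits cluster summaries into activity-enriched (`pct_active` strictly
#' above `high`), activity-depleted (strictly below `low`) and mixed
#' clusters.
#'
#' @param summaries A [summarize_clusters()] data frame.
#' @param high,low Percent cuts (defaults 80 and 20). The cuts are strict:
#'   a cluster at exactly `high` is mixed.
#' @return List with `enriched`, `depleted`, `mixed` (disjoint data
#'   frames).
#' @export
partition_by_activity_enrichment <- function(summaries, high = 80, low = 20) {
  stopifnot(low <= high)
  enriched <- summaries[summaries$pct_active > high, , drop = FALSE]
  depleted <- summaries[summaries$pct_active < low, , drop = FALSE]
  mixed <- summaries[summaries$pct_active <= high &
                       summaries$pct_active >= low, , drop = FALSE]
  list(enriched = enriched, depleted = depleted, mixed = mixed)
}
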