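# 2D chemical-space embedding (visualization-grade only).

#' Embed fingerprints into two dimensions
#'
#' Classical multidimensional scaling of the pairwise Tanimoto distance
#' (1 - similarity) between fingerprints. The embedding is
#' visualization-grade: it supports chemical-space maps but enters no
#' quantitative result. It is fully deterministic; `seed` is accepted for
#' interface stability and recorded in the output attributes.
#'
#' @param fps Fingerprint matrix ([fingerprint_matrix()]), at least 2 rows.
#' @param seed Integer; recorded but not needed (the embedding has no
#'   stochastic component).
#' @return Numeric n x 2 coordinate matrix.
#' @export
embed_chemspace_2d <- function(fps, seed = 1) {
  if (is.null(dim(fps)) || nrow(fps) < 2)
    stop("need at least 2 fingerprints")
  d <- stats::as.dist(1 - tanimoto_matrix(fps))
  xy <- suppressWarnings(stats::cmdscale(d, k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, nrow(xy), 2 - ncol(xy)))
  colnames(xy) <- c("dim1", "dim2")
  rownames(xy) <- rownames(fps)
  attr(xy, "seed") <- seed
  xy
}
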