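# Circular (Morgan/ECFP-style) fingerprints and Tanimoto similarity.
#
# Atom environments are hashed iteratively: the radius-0 invariant of an
# atom combines its atomic number, heavy-atom degree, implicit hydrogen
# count, formal charge and ring membership; at each subsequent radius the
# invariant is re-hashed together with the sorted (bond code, neighbour
# invariant) pairs. Sorting makes the identifiers invariant to the atom
# order of the input SMILES, and aromatic bonds share one bond code so the
# identifiers are independent of kekulization.

.HASH_MOD <- 2147483647  # 2^31 - 1; doubles stay exact throughout

.hash_ints <- function(v) {
  h <- 17
  v <- v %% .HASH_MOD
  for (x in v) h <- (h * 31 + x) %% .HASH_MOD
  h
}

# Environment identifiers per atom and radius.
# Returns an n_atoms x (max_radius + 1) numeric matrix; column r+1 holds the
# radius-r identifiers.
atom_environments <- function(mol, max_radius = 2) {
  stopifnot(max_radius >= 0)
  n <- mol$n
  anum <- .ATOMIC_NUM[mol$elem]
  anum[is.na(anum)] <- 0
  inv <- numeric(n)
  for (a in seq_len(n)) {
    inv[a] <- .hash_ints(c(anum[a], mol$degree[a], mol$nH[a], 0,
                           as.integer(mol$in_ring[a]),
                           as.integer(mol$arom[a])))
  }
  env <- matrix(0, nrow = n, ncol = max_radius + 1)
  env[, 1] <- inv
  if (max_radius >= 1) {
    codes <- mol$bonds$code
    # per-atom neighborhood sizes by radius; an environment whose
    # neighborhood stops growing keeps its identifier (no spurious new
    # environments past an atom's eccentricity)
    nbhd <- matrix(1L, nrow = n, ncol = max_radius + 1)
    for (a in seq_len(n)) {
      reach <- a
      frontier <- a
      for (r in seq_len(max_radius)) {
        frontier <- setdiff(unique(unlist(mol$adj[frontier])), reach)
        reach <- c(reach, frontier)
        nbhd[a, r + 1] <- length(reach)
      }
    }
    for (r in seq_len(max_radius)) {
      prev <- env[, r]
      cur <- numeric(n)
      for (a in seq_len(n)) {
        if (nbhd[a, r + 1] == nbhd[a, r]) {
          cur[a] <- prev[a]
          next
        }
        nb <- mol$adj[[a]]
        pc <- codes[mol$adj_bond[[a]]]
        pi <- prev[nb]
        o <- order(pc, pi)
        cur[a] <- .hash_ints(c(r, prev[a], rbind(pc[o], pi[o])))
      }
      env[, r + 1] <- cur
    }
  }
  env
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Hashes circular atom environments up to `radius` bond steps into a
#' fixed-length binary vector, the representation behind every similarity
#' computation in the package (Tanimoto pairs, clustering, chemical space
#' networks, activity cliffs).
#'
#' @param smiles A single valid, single-fragment SMILES string.
#' @param radius Maximum environment radius in bonds (default 2, the
#'   ECFP4-equivalent setting).
#' @param n_bits Fingerprint length (default 1024).
#' @return An integer 0/1 vector of length `n_bits` with attributes
#'   `radius` and `smiles`, of class `"morgan_fp"`.
#' @examples
#' \dontrun{
#' fp <- morgan_fingerprint("c1ccncc1")
#' sum(fp)  # number of set bits
#' }
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 1024) {
  mol <- mol_parse(smiles)
  env <- atom_environments(mol, max_radius = radius)
  bits <- unique(as.vector(env) %% n_bits) + 1
  fp <- integer(n_bits)
  fp[bits] <- 1L
  structure(fp, radius = radius, smiles = smiles, class = "morgan_fp")
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat(sprintf("Morgan fingerprint: %d bits, radius %d, popcount %d\n",
              length(x), attr(x, "radius"), sum(x)))
  invisible(x)
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius,n_bits See [morgan_fingerprint()].
#' @return Integer 0/1 matrix, one row per molecule (rownames taken from
#'   `names(smiles)` when present).
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 1024) {
  mols <- mol_parse_batch(smiles)
  m <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(mols)) {
    env <- atom_environments(mols[[i]], max_radius = radius)
    m[i, unique(as.vector(env) %% n_bits) + 1] <- 1L
  }
  rownames(m) <- names(smiles)
  attr(m, "radius") <- radius
  m
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the set bits. Two all-zero vectors are
#' defined to have similarity 1 (both featureless); this degenerate case
#' cannot arise from a molecule with at least one heavy atom.
#'
#' @param a,b Binary vectors of equal length (e.g. [morgan_fingerprint()]
#'   output).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param fps Binary fingerprint matrix (rows = molecules), as returned by
#'   [fingerprint_matrix()].
#' @return Symmetric numeric matrix of pairwise similarities with unit
#'   diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  fps <- (fps != 0) * 1L
  inter <- tcrossprod(fps)
  pop <- rowSums(fps)
  uni <- outer(pop, pop, "+") - inter
  tm <- ifelse(uni == 0, 1, inter / uni)
  rownames(tm) <- colnames(tm) <- rownames(fps)
  tm
}
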