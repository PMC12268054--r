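# Murcko scaffolds and maximum common substructure (MCS).
#
# The MCS is a connected common induced substructure computed by seeded
# backtracking over atom mappings (McGregor-style), with atoms required to
# agree on element and - when ring_matches_ring_only - on ring membership,
# and bonds on bond code (aromatic bonds form their own class) and ring
# membership. Multi-molecule MCS folds pairwise over the set, so the
# result can only shrink as molecules are added. The search carries a
# deadline; on timeout the best mapping found so far is returned and
# flagged incomplete.

#' Murcko scaffold of a molecule
#'
#' The ring systems plus the linkers connecting them, with side chains
#' removed; terminal atoms double-bonded to the framework (e.g. carbonyl
#' oxygens) are retained. Acyclic molecules have the empty scaffold.
#'
#' @param smiles One valid SMILES string.
#' @return Canonical SMILES of the scaffold, or `""` for acyclic
#'   molecules.
#' @export
murcko_scaffold <- function(smiles) {
  mol <- mol_parse(smiles)
  if (!length(mol$rings)) return("")
  keep <- rep(TRUE, mol$n)
  repeat {
    deg <- integer(mol$n)
    b <- mol$bonds
    live <- keep[b$a1] & keep[b$a2]
    for (k in which(live)) {
      deg[b$a1[k]] <- deg[b$a1[k]] + 1L
      deg[b$a2[k]] <- deg[b$a2[k]] + 1L
    }
    leaves <- which(keep & deg <= 1 & !mol$in_ring)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
  }
  # re-attach terminal atoms held by a double/triple bond to the framework
  b <- mol$bonds
  repeat {
    add <- which(!keep[b$a1] & keep[b$a2] & b$order >= 2)
    add2 <- which(keep[b$a1] & !keep[b$a2] & b$order >= 2)
    if (!length(add) && !length(add2)) break
    keep[b$a1[add]] <- TRUE
    keep[b$a2[add2]] <- TRUE
  }
  subgraph_smiles(mol, which(keep))
}

# ---- MCS ------------------------------------------------------------------

.pattern_from_mol <- function(mol, atoms = seq_len(mol$n)) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- match(seq_len(mol$n), atoms)  # old -> new (NA if dropped)
  b <- mol$bonds
  kept <- which(!is.na(idx[b$a1]) & !is.na(idx[b$a2]))
  bonds <- data.frame(a1 = idx[b$a1[kept]], a2 = idx[b$a2[kept]],
                      code = b$code[kept], ring = b$ring[kept])
  n <- length(atoms)
  adj <- vector("list", n); adj_bond <- vector("list", n)
  for (i in seq_len(n)) { adj[[i]] <- integer(0); adj_bond[[i]] <- integer(0) }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
      adj[[a1]] <- c(adj[[a1]], a2); adj_bond[[a1]] <- c(adj_bond[[a1]], k)
      adj[[a2]] <- c(adj[[a2]], a1); adj_bond[[a2]] <- c(adj_bond[[a2]], k)
    }
  }
  list(n = n, elem = mol$elem[atoms], in_ring = mol$in_ring[atoms],
       bonds = bonds, adj = adj, adj_bond = adj_bond,
       ref_mol = mol, ref_atoms = atoms)
}

# connected maximum common induced substructure of two patterns;
# returns atom indices of p1 plus a completeness flag
.mcs_pair <- function(p1, p2, rmro = TRUE, deadline = Inf) {
  n1 <- p1$n; n2 <- p2$n
  if (n1 == 0 || n2 == 0)
    return(list(atoms = integer(0), complete = TRUE))
  compat <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) {
    compat[i, ] <- p1$elem[i] == p2$elem &
      (!rmro | p1$in_ring[i] == p2$in_ring)
  }
  # bond lookup for p2: code by atom pair (0 = no bond)
  bcode2 <- matrix(0L, n2, n2)
  bring2 <- matrix(FALSE, n2, n2)
  if (nrow(p2$bonds)) {
    for (k in seq_len(nrow(p2$bonds))) {
      a <- p2$bonds$a1[k]; b <- p2$bonds$a2[k]
      bcode2[a, b] <- bcode2[b, a] <- p2$bonds$code[k]
      bring2[a, b] <- bring2[b, a] <- p2$bonds$ring[k]
    }
  }
  bcode1 <- matrix(0L, n1, n1)
  bring1 <- matrix(FALSE, n1, n1)
  if (nrow(p1$bonds)) {
    for (k in seq_len(nrow(p1$bonds))) {
      a <- p1$bonds$a1[k]; b <- p1$bonds$a2[k]
      bcode1[a, b] <- bcode1[b, a] <- p1$bonds$code[k]
      bring1[a, b] <- bring1[b, a] <- p1$bonds$ring[k]
    }
  }

  env <- new.env(parent = emptyenv())
  env$best <- integer(0)
  env$best_size <- 0L
  env$timed_out <- FALSE

  map1 <- integer(n1)      # p1 atom -> p2 atom (0 unmapped)
  used2 <- logical(n2)
  excluded <- logical(n1)

  consistent <- function(a, b) {
    for (u in p1$adj[[a]]) {
      mu <- map1[u]
      if (mu > 0) {
        c1 <- bcode1[a, u]; c2 <- bcode2[b, mu]
        if (c2 != c1) return(FALSE)
        if (rmro && bring1[a, u] != bring2[b, mu]) return(FALSE)
      }
    }
    for (v in p2$adj[[b]]) {
      if (used2[v]) {
        u <- which(map1 == v)
        if (bcode1[a, u] == 0L) return(FALSE)
      }
    }
    TRUE
  }

  rec <- function(mapped) {
    if (env$timed_out) return()
    if (Sys.time() > deadline) { env$timed_out <- TRUE; return() }
    if (mapped > env$best_size) {
      env$best_size <- mapped
      env$best <- which(map1 > 0)
    }
    # frontier: unmapped, not excluded, adjacent to the mapped region
    frontier <- integer(0)
    for (a in seq_len(n1)) {
      if (map1[a] == 0 && !excluded[a] && any(map1[p1$adj[[a]]] > 0))
        frontier <- c(frontier, a)
    }
    if (!length(frontier)) return()
    ub <- mapped + min(sum(map1 == 0 & !excluded), sum(!used2))
    if (ub <= env$best_size) return()
    # branch on the frontier atom with the fewest candidates
    ncand <- vapply(frontier, function(a) sum(compat[a, ] & !used2),
                    numeric(1))
    a <- frontier[which.min(ncand)]
    for (b in which(compat[a, ] & !used2)) {
      if (consistent(a, b)) {
        map1[a] <<- b; used2[b] <<- TRUE
        rec(mapped + 1L)
        map1[a] <<- 0L; used2[b] <<- FALSE
        if (env$timed_out) return()
      }
    }
    excluded[a] <<- TRUE
    rec(mapped)
    excluded[a] <<- FALSE
  }

  for (a0 in seq_len(n1)) {
    if (env$timed_out) break
    if (env$best_size >= min(n1, n2)) break
    # each mapping is counted once via its lowest p1 atom
    if (a0 > 1) excluded[seq_len(a0 - 1)] <- TRUE
    for (b0 in which(compat[a0, ])) {
      map1[a0] <- b0; used2[b0] <- TRUE
      rec(1L)
      map1[a0] <- 0L; used2[b0] <- FALSE
      if (env$timed_out) break
    }
    excluded[seq_len(n1)] <- FALSE
  }
  list(atoms = env$best, complete = !env$timed_out)
}

#' Maximum common substructure of a set of molecules
#'
#' Connected common induced substructure under the constraint that ring
#' atoms only match ring atoms (and ring bonds only ring bonds) when
#' `ring_matches_ring_only` is `TRUE`. For more than two molecules the
#' MCS is folded pairwise (smallest molecule first), so the reported
#' substructure is common to all members. The search is exact up to the
#' timeout; if the deadline is hit, the best substructure found so far is
#' returned with `complete = FALSE`.
#'
#' @param smiles Character vector of one or more valid SMILES.
#' @param ring_matches_ring_only Restrict matches to equal ring
#'   membership (default `TRUE`).
#' @param timeout_s Search budget in seconds (default 10).
#' @return List of class `"mcs_result"`: `smarts` (SMILES-style pattern of
#'   the common substructure, best effort), `num_atoms`, `num_bonds`,
#'   `complete`.
#' @export
mcs <- function(smiles, ring_matches_ring_only = TRUE, timeout_s = 10) {
  if (!length(smiles)) stop("need at least one molecule")
  mols <- mol_parse_batch(smiles)
  ord <- order(vapply(mols, function(m) m$n, numeric(1)))
  mols <- mols[ord]
  p <- .pattern_from_mol(mols[[1]])
  complete <- TRUE
  deadline <- Sys.time() + timeout_s
  if (length(mols) > 1) {
    for (i in seq(2, length(mols))) {
      if (p$n == 0) break
      res <- .mcs_pair(p, .pattern_from_mol(mols[[i]]),
                       rmro = ring_matches_ring_only, deadline = deadline)
      complete <- complete && res$complete
      p <- .pattern_from_mol(p$ref_mol, p$ref_atoms[res$atoms])
    }
  }
  smarts <- if (p$n > 0) subgraph_smiles(p$ref_mol, p$ref_atoms) else ""
  structure(list(smarts = smarts, num_atoms = p$n,
                 num_bonds = nrow(p$bonds), complete = complete),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("MCS: %s (%d atoms, %d bonds%s)\n",
              if (nzchar(x$smarts)) x$smarts else "<empty>",
              x$num_atoms, x$num_bonds,
              if (x$complete) "" else ", search truncated"))
  invisible(x)
}
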