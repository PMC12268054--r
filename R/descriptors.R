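# Molecular descriptor panel, physicochemical profiling, rule of five.
#
# The panel combines OpenBabel-computed bulk properties (MolWt, MolLogP,
# TPSA, H-bond donors/acceptors, molar refractivity) with graph-derived 2D
# descriptors (ring, heteroatom and fragment counts, Burden-matrix
# eigenvalue descriptors). Names follow the conventional descriptor
# vocabulary (NumHAcceptors, NOCount, fr_pyridine, fr_Ar_N, ...). The
# panel composition is fixed and versioned so descriptor matrices are
# comparable across runs.

DESCRIPTOR_PANEL_VERSION <- "sarscape-panel-1"

.descriptor_names <- function() {
  c("MolWt", "MolLogP", "MolMR", "TPSA", "NumHDonors", "NumHAcceptors",
    "NOCount", "NHOHCount", "HeavyAtomCount", "NumHeteroatoms",
    "NumRotatableBonds", "FractionCSP3", "RingCount", "NumAromaticRings",
    "NumAliphaticRings", "NumAromaticHeterocycles",
    "NumAromaticCarbocycles", "NumRingSystems", "MaxRingSize",
    "fr_pyridine", "fr_pyridazine", "fr_Ar_N", "fr_Ar_NH", "fr_bicyclic",
    "fr_halogen", "fr_ether", "fr_C_O", "fr_amide", "fr_nitrile",
    "BCUT2D_MWHI", "BCUT2D_MWLOW",
    "nC", "nN", "nO", "nS", "nF", "nCl", "nBr", "nI")
}

# ring systems: connected components of the ring-bond subgraph
.ring_systems <- function(mol) {
  if (!length(mol$rings)) return(list())
  sets <- lapply(mol$rings, identity)
  merged <- list()
  for (s in sets) {
    hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged[[hit[1]]] <- union(Reduce(union, merged[hit]), s)
      drop <- setdiff(hit, hit[1])
      if (length(drop)) merged <- merged[-drop]
    } else {
      merged[[length(merged) + 1]] <- s
    }
  }
  merged
}

.graph_descriptors <- function(mol) {
  elem <- mol$elem
  n <- mol$n
  rings <- mol$rings
  ring_arom <- mol$ring_arom
  ring_elems <- lapply(rings, function(r) elem[r])

  # carbons carrying an exocyclic C=O (pyridinone-type rings are not
  # counted as pyridines)
  carbonyl_c <- logical(n)
  if (nrow(mol$bonds)) {
    dbl <- mol$bonds[mol$bonds$order == 2 & !mol$bonds$arom, , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      if (elem[dbl$a1[k]] == "C" && elem[dbl$a2[k]] == "O")
        carbonyl_c[dbl$a1[k]] <- TRUE
      if (elem[dbl$a2[k]] == "C" && elem[dbl$a1[k]] == "O")
        carbonyl_c[dbl$a2[k]] <- TRUE
    }
  }
  arom6_1N <- ring_arom & vapply(seq_along(rings), function(i) {
    e <- ring_elems[[i]]
    length(e) == 6 && sum(e == "N") == 1 && sum(e == "C") == 5 &&
      !any(carbonyl_c[rings[[i]]])
  }, logical(1))
  pyridazine <- ring_arom & vapply(seq_along(rings), function(i) {
    e <- ring_elems[[i]]
    if (length(e) != 6 || sum(e == "N") != 2 || sum(e == "C") != 4)
      return(FALSE)
    # adjacent nitrogens (1,2-diazine)
    ns <- rings[[i]][e == "N"]
    any(mol$bonds$a1 %in% ns & mol$bonds$a2 %in% ns)
  }, logical(1))
  arom_het <- ring_arom & vapply(ring_elems, function(e) any(e != "C"),
                                 logical(1))
  arom_carbo <- ring_arom & vapply(ring_elems, function(e) all(e == "C"),
                                   logical(1))
  # fused ring pairs (sharing an edge, i.e. >= 2 atoms)
  n_fused <- 0L
  if (length(rings) >= 2) {
    for (i in seq_len(length(rings) - 1)) {
      for (j in seq(i + 1, length(rings))) {
        if (length(intersect(rings[[i]], rings[[j]])) >= 2)
          n_fused <- n_fused + 1L
      }
    }
  }

  ar_n <- sum(elem == "N" & mol$arom)
  ar_nh <- sum(elem == "N" & mol$arom & mol$nH > 0)

  b <- mol$bonds
  carbons <- elem == "C"
  sp3_c <- carbons
  if (nrow(b)) {
    unsat <- b$order >= 2 | b$arom
    sp3_c[b$a1[unsat]] <- FALSE
    sp3_c[b$a2[unsat]] <- FALSE
    sp3_c <- sp3_c & carbons
  }
  frac_sp3 <- if (sum(carbons)) sum(sp3_c) / sum(carbons) else 0

  # rotatable: single, acyclic, both ends non-terminal, not an amide C-N
  n_rot <- 0L
  if (nrow(b)) {
    amide_c <- which(elem == "C" & vapply(seq_len(n), function(a) {
      nb <- mol$adj[[a]]; bo <- mol$bonds$order[mol$adj_bond[[a]]]
      any(elem[nb] == "O" & bo == 2)
    }, logical(1)))
    for (k in seq_len(nrow(b))) {
      if (b$order[k] != 1 || b$ring[k]) next
      a1 <- b$a1[k]; a2 <- b$a2[k]
      if (mol$degree[a1] < 2 || mol$degree[a2] < 2) next
      is_amide <- (a1 %in% amide_c && elem[a2] == "N") ||
        (a2 %in% amide_c && elem[a1] == "N")
      if (!is_amide) n_rot <- n_rot + 1L
    }
  }

  # simple fragment counts
  n_ether <- 0L; n_c_o <- 0L; n_amide <- 0L; n_nitrile <- 0L
  for (a in which(elem == "O")) {
    nb <- mol$adj[[a]]; bo <- mol$bonds$order[mol$adj_bond[[a]]]
    if (length(nb) == 2 && all(bo == 1) && all(elem[nb] == "C") &&
        !mol$arom[a]) n_ether <- n_ether + 1L
  }
  for (a in which(elem == "C")) {
    nb <- mol$adj[[a]]; bo <- mol$bonds$order[mol$adj_bond[[a]]]
    dbl_o <- elem[nb] == "O" & bo == 2
    if (any(dbl_o)) {
      n_c_o <- n_c_o + 1L
      if (any(elem[nb] == "N" & bo == 1)) n_amide <- n_amide + 1L
    }
    if (any(elem[nb] == "N" & bo == 3)) n_nitrile <- n_nitrile + 1L
  }

  # Burden matrix eigenvalue descriptors: diagonal = atomic mass,
  # bonded off-diagonal = bond order / 10 (aromatic 0.15), else 0.001
  if (n >= 2) {
    mass <- .ATOMIC_MASS[elem]; mass[is.na(mass)] <- 0
    B <- matrix(0.001, n, n)
    diag(B) <- mass
    if (nrow(b)) {
      w <- ifelse(b$arom, 0.15, b$order / 10)
      for (k in seq_len(nrow(b))) {
        B[b$a1[k], b$a2[k]] <- w[k]
        B[b$a2[k], b$a1[k]] <- w[k]
      }
    }
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    bcut_hi <- max(ev); bcut_lo <- min(ev)
  } else {
    bcut_hi <- bcut_lo <- unname(.ATOMIC_MASS[elem][1])
    if (is.na(bcut_hi)) bcut_hi <- bcut_lo <- 0
  }

  systems <- .ring_systems(mol)
  c(NOCount = sum(elem %in% c("N", "O")),
    NHOHCount = sum(mol$nH[elem %in% c("N", "O")]),
    HeavyAtomCount = n,
    NumHeteroatoms = sum(elem != "C"),
    NumRotatableBonds = n_rot,
    FractionCSP3 = frac_sp3,
    RingCount = length(rings),
    NumAromaticRings = sum(ring_arom),
    NumAliphaticRings = sum(!ring_arom),
    NumAromaticHeterocycles = sum(arom_het),
    NumAromaticCarbocycles = sum(arom_carbo),
    NumRingSystems = length(systems),
    MaxRingSize = if (length(rings)) max(lengths(rings)) else 0,
    fr_pyridine = sum(arom6_1N),
    fr_pyridazine = sum(pyridazine),
    fr_Ar_N = ar_n,
    fr_Ar_NH = ar_nh,
    fr_bicyclic = n_fused,
    fr_halogen = sum(elem %in% c("F", "Cl", "Br", "I")),
    fr_ether = n_ether,
    fr_C_O = n_c_o,
    fr_amide = n_amide,
    fr_nitrile = n_nitrile,
    BCUT2D_MWHI = bcut_hi,
    BCUT2D_MWLOW = bcut_lo,
    nC = sum(elem == "C"), nN = sum(elem == "N"), nO = sum(elem == "O"),
    nS = sum(elem == "S"), nF = sum(elem == "F"), nCl = sum(elem == "Cl"),
    nBr = sum(elem == "Br"), nI = sum(elem == "I"))
}

.propob_batch <- function(smiles) {
  mols <- mol_parse_batch(smiles)
  single <- vapply(mols, function(m) is.null(m$sdf), logical(1))
  out <- matrix(NA_real_, nrow = length(smiles), ncol = 6,
                dimnames = list(NULL, c("MolWt", "MolLogP", "MolMR", "TPSA",
                                        "NumHDonors", "NumHAcceptors")))
  if (any(!single)) {
    sdfs <- lapply(mols[!single], function(m) m$sdf)
    sdfset <- methods::new("SDFset", SDF = sdfs,
                           ID = paste0("p", seq_along(sdfs)))
    p <- ChemmineR::propOB(sdfset)
    out[!single, "MolWt"] <- p$MW
    out[!single, "MolLogP"] <- p$logP
    out[!single, "MolMR"] <- p$MR
    out[!single, "TPSA"] <- p$TPSA
    out[!single, "NumHDonors"] <- p$HBD
    out[!single, "NumHAcceptors"] <- p$HBA1
  }
  if (any(single)) {
    for (i in which(single)) {
      m <- mols[[i]]
      mass <- .ATOMIC_MASS[m$elem]; mass[is.na(mass)] <- 0
      out[i, "MolWt"] <- sum(mass) + 1.008 * sum(m$nH)
      out[i, "MolLogP"] <- 0
      out[i, "MolMR"] <- 0
      out[i, "TPSA"] <- if (m$elem %in% c("N", "O")) 20 else 0
      out[i, "NumHDonors"] <- as.numeric(m$elem %in% c("N", "O") & m$nH > 0)
      out[i, "NumHAcceptors"] <- as.numeric(m$elem %in% c("N", "O"))
    }
  }
  out
}

#' Molecular descriptor panel
#'
#' Computes the package's fixed 2D descriptor panel for a set of molecules.
#' Bulk properties (MolWt, MolLogP, MolMR, TPSA, H-bond donor/acceptor
#' counts) are computed by OpenBabel; ring, fragment and heteroatom counts
#' and the Burden eigenvalue descriptors (`BCUT2D_MWHI`/`BCUT2D_MWLOW`)
#' come from the internal molecular graph. `fr_pyridine` counts aromatic
#' six-membered rings with exactly one nitrogen; `fr_Ar_N` counts aromatic
#' nitrogen atoms; `fr_bicyclic` counts edge-fused ring pairs.
#'
#' @param smiles Character vector of valid SMILES (a single string is
#'   also accepted).
#' @return Numeric matrix, one row per molecule and one column per panel
#'   descriptor, with attribute `panel_version`.
#' @export
descriptor_panel <- function(smiles) {
  mols <- mol_parse_batch(smiles)
  ob <- .propob_batch(smiles)
  g <- t(vapply(mols, .graph_descriptors,
                numeric(length(.graph_descriptors(mols[[1]])))))
  m <- cbind(ob, g)[, .descriptor_names(), drop = FALSE]
  rownames(m) <- names(smiles)
  attr(m, "panel_version") <- DESCRIPTOR_PANEL_VERSION
  m
}

#' Descriptors for a single molecule
#'
#' @param smiles One valid SMILES string.
#' @return Named numeric vector (see [descriptor_panel()]).
#' @export
descriptors <- function(smiles) {
  stopifnot(length(smiles) == 1)
  descriptor_panel(smiles)[1, ]
}

#' Physicochemical profile of a compound set
#'
#' Per-compound values of the nine standard properties (MolWt, MolLogP,
#' TPSA, H-bond donors and acceptors, rotatable bonds, aromatic rings,
#' heavy atoms, fraction of sp3 carbons) plus a per-label median/IQR
#' summary, the profile used to compare active and inactive compounds.
#'
#' @param records Curated compound data frame (needs `canonical_smiles`
#'   and `label`).
#' @return List with `per_compound` (data frame) and `summary` (data frame
#'   of median, Q1, Q3 per property and label), class `"physchem_profile"`.
#' @export
physchem_profile <- function(records) {
  props <- c("MolWt", "MolLogP", "TPSA", "NumHDonors", "NumHAcceptors",
             "NumRotatableBonds", "NumAromaticRings", "HeavyAtomCount",
             "FractionCSP3")
  d <- descriptor_panel(records$canonical_smiles)[, props, drop = FALSE]
  per <- data.frame(compound_id = records$compound_id, label = records$label,
                    d, check.names = FALSE)
  rows <- list()
  for (lab in unique(records$label)) {
    sub <- d[records$label == lab, , drop = FALSE]
    for (p in props) {
      q <- stats::quantile(sub[, p], c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, property = p, q1 = q[1], median = q[2], q3 = q[3])
    }
  }
  structure(list(per_compound = per, summary = do.call(rbind, rows)),
            class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat("Physicochemical profile of", nrow(x$per_compound), "compounds\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rule-of-five check
#'
#' Counts violations of MolWt <= 500, MolLogP <= 5, NumHDonors <= 5,
#' NumHAcceptors <= 10; a compound passes with at most one violation.
#'
#' @param desc Named numeric vector (one molecule) or matrix (one row per
#'   molecule) containing the four descriptors, e.g. from
#'   [descriptor_panel()].
#' @return Data frame with `n_violations` (0-4) and `pass`.
#' @export
rule_of_five <- function(desc) {
  if (is.null(dim(desc))) desc <- t(as.matrix(desc))
  v <- (desc[, "MolWt"] > 500) + (desc[, "MolLogP"] > 5) +
    (desc[, "NumHDonors"] > 5) + (desc[, "NumHAcceptors"] > 10)
  data.frame(n_violations = as.integer(v), pass = v <= 1)
}
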