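# Internal molecular graph layer.
#
# Molecules are parsed from SMILES through OpenBabel (ChemmineOB via
# ChemmineR::smiles2sdf) into a light-weight graph structure used by the
# fingerprint, descriptor, scaffold and MCS code. Aromaticity is perceived
# from the smallest set of smallest rings (ChemmineR::rings); formal charges
# are treated as zero (inputs are desalted neutral organics) and implicit
# hydrogen counts are derived from standard valences.

.mol_cache <- new.env(parent = emptyenv())

.STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                  I = 1, B = 3, Si = 4, Se = 2, H = 1)

.ATOMIC_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                 S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                  Cl = 35.45, Se = 78.971, Br = 79.904, I = 126.904)

# Single heavy atoms come out of smiles2sdf as "invalid" SDFs (no bond
# block), so they are constructed directly.
.single_atom_regex <- "^(\\[[A-Za-z][a-z]?H?[0-9]*[+-]?[0-9]*\\]|Br|Cl|[BCNOPSFI])$"

.mol_single_atom <- function(smiles) {
  elem <- gsub("[^A-Za-z]", "", smiles)
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 if (nchar(elem) > 1) substr(elem, 2, nchar(elem)) else "")
  # strip an explicit H count left over from bracket atoms, e.g. [NH4]
  elem <- sub("H[0-9]*$", "", elem)
  if (elem == "") elem <- "C"
  val <- .STD_VALENCE[elem]
  list(
    smiles = smiles, n = 1L, elem = elem,
    nH = as.integer(if (is.na(val)) 0 else val),
    degree = 0L, in_ring = FALSE, arom = FALSE,
    bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                       ring = logical(0), arom = logical(0),
                       code = integer(0)),
    adj = list(integer(0)), adj_bond = list(integer(0)),
    rings = list(), ring_arom = logical(0),
    sdf = NULL
  )
}

.mol_from_sdf <- function(sdfobj, smiles) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  n <- nrow(ab)
  elem <- gsub("_.*", "", rownames(ab))
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  nb <- nrow(bonds)

  ring_sets <- list()
  ring_arom <- logical(0)
  if (n >= 3 && nb >= 3) {
    rr <- tryCatch(
      ChemmineR::rings(sdfobj, upper = Inf, type = "all", arom = TRUE,
                       inner = TRUE),
      error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    if (length(rr$RINGS)) {
      ring_sets <- lapply(rr$RINGS, function(r) as.integer(sub(".*_", "", r)))
      ring_arom <- as.logical(rr$AROMATIC)
    }
  }

  in_ring <- logical(n)
  arom_atom <- logical(n)
  for (i in seq_along(ring_sets)) {
    in_ring[ring_sets[[i]]] <- TRUE
    if (ring_arom[i]) arom_atom[ring_sets[[i]]] <- TRUE
  }

  # a bond is a ring (resp. aromatic) bond iff both endpoints sit in one
  # common SSSR ring (resp. aromatic ring); SSSR rings are chordless, so
  # membership of both endpoints implies the edge lies on the cycle
  ring_bond <- logical(nb)
  arom_bond <- logical(nb)
  if (nb > 0 && length(ring_sets)) {
    for (i in seq_along(ring_sets)) {
      rs <- ring_sets[[i]]
      hit <- bonds$a1 %in% rs & bonds$a2 %in% rs
      ring_bond <- ring_bond | hit
      if (ring_arom[i]) arom_bond <- arom_bond | hit
    }
  }
  bonds$ring <- ring_bond
  bonds$arom <- arom_bond
  # bond code used for matching/hashing: aromatic bonds collapse to one
  # code so that kekulization is irrelevant
  bonds$code <- ifelse(arom_bond, 4L, bonds$order)

  degree <- integer(n)
  bondsum <- numeric(n)
  adj <- vector("list", n)
  adj_bond <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- integer(0)
    adj_bond[[i]] <- integer(0)
  }
  if (nb > 0) {
    for (b in seq_len(nb)) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      adj[[a1]] <- c(adj[[a1]], a2); adj_bond[[a1]] <- c(adj_bond[[a1]], b)
      adj[[a2]] <- c(adj[[a2]], a1); adj_bond[[a2]] <- c(adj_bond[[a2]], b)
    }
    degree <- vapply(adj, length, integer(1))
    for (b in seq_len(nb)) {
      bondsum[bonds$a1[b]] <- bondsum[bonds$a1[b]] + bonds$order[b]
      bondsum[bonds$a2[b]] <- bondsum[bonds$a2[b]] + bonds$order[b]
    }
  }
  val <- .STD_VALENCE[elem]
  val[is.na(val)] <- 0
  nH <- as.integer(pmax(0, round(val - bondsum)))

  list(smiles = smiles, n = n, elem = elem, nH = nH, degree = degree,
       in_ring = in_ring, arom = arom_atom, bonds = bonds,
       adj = adj, adj_bond = adj_bond,
       rings = ring_sets, ring_arom = ring_arom, sdf = sdfobj)
}

# Parse one SMILES into the internal graph (cached by the literal string).
mol_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles)) stop("empty SMILES")
  hit <- .mol_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  mol <- if (grepl(.single_atom_regex, smiles)) {
    .mol_single_atom(smiles)
  } else {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
    if (!ChemmineR::validSDF(sdf)[1]) stop("invalid SMILES: ", smiles)
    .mol_from_sdf(sdf[[1]], smiles)
  }
  assign(smiles, mol, envir = .mol_cache)
  mol
}

# Parse many SMILES with a single OpenBabel round trip; errors if any is
# invalid (callers that tolerate invalid input pre-screen via
# canonicalize_smiles). Returns list of mol graphs in input order.
mol_parse_batch <- function(smiles) {
  stopifnot(is.character(smiles))
  need <- unique(smiles[!vapply(smiles, function(s)
    !is.null(.mol_cache[[s]]), logical(1))])
  need_multi <- need[!grepl(.single_atom_regex, need)]
  if (length(need_multi)) {
    nm <- paste0("m", seq_along(need_multi))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(need_multi, nm)))
    ok <- ChemmineR::validSDF(sdf)
    if (!all(ok)) stop("invalid SMILES: ",
                       paste(need_multi[!ok], collapse = ", "))
    for (i in seq_along(need_multi)) {
      assign(need_multi[i], .mol_from_sdf(sdf[[i]], need_multi[i]),
             envir = .mol_cache)
    }
  }
  for (s in setdiff(need, need_multi)) assign(s, .mol_single_atom(s),
                                              envir = .mol_cache)
  lapply(smiles, function(s) .mol_cache[[s]])
}

mol_cache_clear <- function() {
  rm(list = ls(envir = .mol_cache), envir = .mol_cache)
  invisible(NULL)
}

# Structural sanity screen applied before OpenBabel parsing: OpenBabel
# silently repairs some malformed strings (e.g. a dangling branch "C("
# becomes methane), so unbalanced parentheses/brackets and odd ring-bond
# digit counts are rejected up front.
.smiles_sane <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0; bracket <- FALSE; digits <- integer(0); pct <- 0
  for (ch in chars) {
    if (bracket) {
      if (ch == "]") bracket <- FALSE
      if (ch == "[") return(FALSE)
      next
    }
    if (ch == "[") { bracket <- TRUE; next }
    if (ch == "]") return(FALSE)
    if (ch == "(") depth <- depth + 1
    else if (ch == ")") { depth <- depth - 1; if (depth < 0) return(FALSE) }
    else if (ch == "%") pct <- 2
    else if (grepl("[0-9]", ch)) {
      if (pct > 0) pct <- pct - 1  # two-digit %nn closures counted as one
      if (pct == 1) next
      digits <- c(digits, as.integer(ch))
    }
  }
  depth == 0 && !bracket &&
    all(table(digits) %% 2 == 0)
}

# Canonical SMILES for a vector of (possibly invalid) SMILES strings via
# OpenBabel. Invalid entries come back as NA. Multi-fragment inputs keep
# their dots.
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  out <- rep(NA_character_, length(smiles))
  nonempty <- which(!is.na(smiles) & nzchar(smiles) &
                      !grepl("[[:space:]]", smiles) &
                      vapply(smiles, function(s)
                        isTRUE(tryCatch(.smiles_sane(s),
                                        error = function(e) FALSE)),
                        logical(1)))
  if (!length(nonempty)) return(out)
  tags <- paste0("t", nonempty)
  input <- paste(paste(smiles[nonempty], tags), collapse = "\n")
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", input),
    error = function(e) "")
  if (nzchar(res)) {
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) == 2 && grepl("^t[0-9]+$", p[2])) {
        idx <- as.integer(sub("^t", "", p[2]))
        out[idx] <- p[1]
      }
    }
  }
  # OpenBabel can emit an empty string for some invalid inputs
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

# SMILES of the induced subgraph on `atom_idx` of a parsed molecule
# (best effort; used for scaffold and alert-environment reporting).
subgraph_smiles <- function(mol, atom_idx) {
  atom_idx <- sort(unique(as.integer(atom_idx)))
  if (!length(atom_idx)) return("")
  if (is.null(mol$sdf)) return(mol$smiles)
  if (length(atom_idx) == mol$n) {
    smi <- canonicalize_smiles(mol$smiles)
    return(if (is.na(smi)) mol$smiles else smi)
  }
  sub <- tryCatch(ChemmineR::atomsubset(mol$sdf, atomrows = atom_idx),
                  error = function(e) NULL)
  if (is.null(sub)) return("")
  smi <- tryCatch(
    as.character(ChemmineR::sdf2smiles(methods::new("SDFset", SDF = list(sub),
                                                    ID = "sub"))),
    error = function(e) "")
  if (!length(smi) || is.na(smi) || !nzchar(smi)) return("")
  can <- canonicalize_smiles(unname(smi))
  if (is.na(can)) unname(smi) else can
}
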