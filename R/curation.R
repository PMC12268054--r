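# Curation: raw SMILES + IC50 records -> standardized, deduplicated,
# activity-labeled compound records.

#' Curation configuration
#'
#' @param activity_threshold_nM IC50 cut (nM) separating actives from
#'   inactives; a compound is active iff IC50 <= threshold. Default 100 nM,
#'   the conventional potency cut for kinase inhibitor series.
#' @param duplicate_average How IC50s of concordant duplicates are combined:
#'   `"arith"` (arithmetic mean, default) or `"geom"` (geometric mean, the
#'   common choice for log-normally distributed potencies).
#' @return A list of class `"curation_config"`.
#' @export
curation_config <- function(activity_threshold_nM = 100,
                            duplicate_average = c("arith", "geom")) {
  stopifnot(is.numeric(activity_threshold_nM), activity_threshold_nM > 0)
  duplicate_average <- match.arg(duplicate_average)
  structure(list(activity_threshold_nM = activity_threshold_nM,
                 duplicate_average = duplicate_average),
            class = "curation_config")
}

.UNIT_TO_NM <- c(nm = 1, um = 1e3, m = 1e9)

.normalize_unit <- function(unit) {
  u <- tolower(gsub("µ", "u", trimws(unit)))
  if (u %in% names(.UNIT_TO_NM)) .UNIT_TO_NM[[u]] else NA_real_
}

.rejection <- function(reason, source_id = NA_character_) {
  structure(list(reason = reason, source_id = source_id),
            class = "sar_rejection")
}

#' @export
print.sar_rejection <- function(x, ...) {
  cat(sprintf("rejected record %s: %s\n", x$source_id, x$reason))
  invisible(x)
}

# Keep the single largest organic fragment of a (canonical, possibly
# dotted) SMILES. Largest = most heavy atoms; ties broken by molecular
# weight, then by canonical SMILES string order. Fragments containing
# carbon outrank those that do not.
.largest_fragment <- function(can_smiles) {
  frags <- strsplit(can_smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1) return(frags)
  mols <- tryCatch(mol_parse_batch(frags), error = function(e) NULL)
  if (is.null(mols)) return(NA_character_)
  heavy <- vapply(mols, function(m) m$n, numeric(1))
  mw <- vapply(mols, function(m) {
    mass <- .ATOMIC_MASS[m$elem]
    mass[is.na(mass)] <- 0
    sum(mass) + 1.008 * sum(m$nH)
  }, numeric(1))
  organic <- vapply(mols, function(m) any(m$elem == "C"), logical(1))
  o <- order(-organic, -heavy, -mw, frags)
  frags[o[1]]
}

#' Standardize one raw compound record
#'
#' Parses the SMILES, strips salts/solvents by keeping the largest organic
#' fragment, canonicalizes, converts the IC50 to nM, and attaches the pIC50
#' and the activity label.
#'
#' @param raw A list or one-row data frame with fields `smiles`,
#'   `ic50_value`, `ic50_unit` (one of `"nM"`, `"uM"`, `"M"`), and
#'   optionally `source_id`, `year`.
#' @param config A [curation_config()].
#' @return A list of class `"compound_record"` with fields `compound_id`,
#'   `canonical_smiles`, `ic50_nM`, `pic50`, `label`, `year` — or an object
#'   of class `"sar_rejection"` whose `reason` is one of
#'   `"invalid_smiles"`, `"bad_activity"`, `"bad_unit"`.
#' @export
standardize_record <- function(raw, config = curation_config()) {
  raw <- as.list(raw)
  sid <- if (!is.null(raw$source_id)) as.character(raw$source_id) else NA_character_
  smi <- raw$smiles
  if (is.null(smi) || is.na(smi) || !nzchar(trimws(smi)))
    return(.rejection("invalid_smiles", sid))
  val <- suppressWarnings(as.numeric(raw$ic50_value))
  if (is.null(raw$ic50_value) || is.na(val) || val <= 0)
    return(.rejection("bad_activity", sid))
  mult <- .normalize_unit(raw$ic50_unit %||% NA_character_)
  if (is.na(mult)) return(.rejection("bad_unit", sid))

  can <- canonicalize_smiles(trimws(smi))
  if (is.na(can)) return(.rejection("invalid_smiles", sid))
  desalted <- grepl(".", can, fixed = TRUE)
  frag <- .largest_fragment(can)
  if (is.na(frag)) return(.rejection("invalid_smiles", sid))
  if (desalted) {
    frag <- canonicalize_smiles(frag)
    if (is.na(frag)) return(.rejection("invalid_smiles", sid))
  }
  ic50 <- val * mult
  structure(list(
    compound_id = sid,
    canonical_smiles = frag,
    ic50_nM = ic50,
    pic50 = pic50(ic50),
    label = label_activity(ic50, config$activity_threshold_nM),
    year = if (!is.null(raw$year)) suppressWarnings(as.integer(raw$year)) else NA_integer_,
    desalted = desalted,
    unit_converted = mult != 1
  ), class = "compound_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label a compound active or inactive
#'
#' Active iff `ic50_nM <= threshold_nM` (the boundary is active).
#'
#' @param ic50_nM Positive IC50 in nM (vectorized).
#' @param threshold_nM Activity threshold in nM (default 100).
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_activity <- function(ic50_nM, threshold_nM = 100) {
  if (any(is.na(ic50_nM)) || any(ic50_nM <= 0)) stop("IC50 must be positive")
  ifelse(ic50_nM <= threshold_nM, "active", "inactive")
}

#' pIC50 from an IC50 in nM
#'
#' `pIC50 = -log10(IC50 in molar) = 9 - log10(IC50 in nM)`.
#'
#' @param ic50_nM Positive IC50 in nM (vectorized).
#' @return Dimensionless pIC50.
#' @export
pic50 <- function(ic50_nM) {
  if (any(is.na(ic50_nM)) || any(ic50_nM <= 0)) stop("IC50 must be positive")
  9 - log10(ic50_nM)
}

#' Fold change between two IC50s
#'
#' The potency ratio max/min, reported at 2-decimal precision, as used in
#' worked SAR comparisons (e.g. 4 nM vs 720 nM is a 180-fold change).
#'
#' @param ic50_a_nM,ic50_b_nM Positive IC50 values (vectorized).
#' @return Ratio `>= 1`, rounded to 2 decimals.
#' @export
fold_change <- function(ic50_a_nM, ic50_b_nM) {
  if (any(is.na(c(ic50_a_nM, ic50_b_nM))) || any(c(ic50_a_nM, ic50_b_nM) <= 0))
    stop("IC50 must be positive")
  round(pmax(ic50_a_nM, ic50_b_nM) / pmin(ic50_a_nM, ic50_b_nM), 2)
}

#' Deduplicate standardized compound records
#'
#' Records sharing a canonical SMILES are merged: if all duplicate labels
#' agree their IC50s are averaged (arithmetic or geometric per the config)
#' and a single record is kept; if the labels conflict, all copies are
#' dropped and counted in the report.
#'
#' @param records A compound records data frame (see [curate_compounds()]).
#' @param config A [curation_config()].
#' @return A list with `records` (deduplicated data frame) and `report`
#'   (named counts: `n_input`, `n_dropped_conflicting_duplicates`,
#'   `n_merged_duplicates`, `n_output`).
#' @export
deduplicate_compounds <- function(records, config = curation_config()) {
  n_in <- nrow(records)
  if (n_in == 0) {
    return(list(records = records,
                report = c(n_input = 0, n_dropped_conflicting_duplicates = 0,
                           n_merged_duplicates = 0, n_output = 0)))
  }
  grp <- split(seq_len(n_in), records$canonical_smiles)
  keep <- logical(n_in)
  dropped <- 0L
  merged <- 0L
  out_rows <- list()
  # preserve first-appearance order of groups
  first_idx <- vapply(grp, min, numeric(1))
  grp <- grp[order(first_idx)]
  for (idx in grp) {
    if (length(idx) == 1) {
      out_rows[[length(out_rows) + 1]] <- records[idx, , drop = FALSE]
      next
    }
    labs <- unique(records$label[idx])
    if (length(labs) > 1) {
      dropped <- dropped + length(idx)
      next
    }
    vals <- records$ic50_nM[idx]
    avg <- if (config$duplicate_average == "geom") exp(mean(log(vals)))
           else mean(vals)
    row <- records[idx[1], , drop = FALSE]
    row$ic50_nM <- avg
    row$pic50 <- pic50(avg)
    row$label <- label_activity(avg, config$activity_threshold_nM)
    out_rows[[length(out_rows) + 1]] <- row
    merged <- merged + (length(idx) - 1L)
  }
  out <- if (length(out_rows)) do.call(rbind, out_rows) else records[0, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       report = c(n_input = n_in,
                  n_dropped_conflicting_duplicates = dropped,
                  n_merged_duplicates = merged,
                  n_output = nrow(out)))
}

#' Curate a raw compound table
#'
#' Runs [standardize_record()] on every row and [deduplicate_compounds()]
#' on the survivors, producing the curated compound table used by every
#' downstream stage, together with a reconciled curation report.
#'
#' @param raw Data frame with columns `smiles`, `ic50_value`, `ic50_unit`
#'   and optionally `source_id`, `year`, `source`.
#' @param config A [curation_config()].
#' @param verbose Log one line per rejected record.
#' @return A list of class `"curation_result"`: `records` (data frame with
#'   `compound_id`, `canonical_smiles`, `ic50_nM`, `pic50`, `label`,
#'   `year`), `report` (counts), and `rejections` (data frame of rejected
#'   source ids and reasons).
#' @export
curate_compounds <- function(raw, config = curation_config(),
                             verbose = FALSE) {
  raw <- as.data.frame(raw)
  n_input <- nrow(raw)
  if (is.null(raw$source_id)) raw$source_id <- paste0("REC", seq_len(n_input))
  # batch canonicalization up front (one OpenBabel call), then per-record
  # standardization reuses the cache
  cans <- canonicalize_smiles(as.character(raw$smiles))
  recs <- list()
  rej <- list()
  n_desalted <- 0L
  n_unit_converted <- 0L
  seen_ids <- character(0)
  for (i in seq_len(n_input)) {
    r <- list(source_id = raw$source_id[i], smiles = raw$smiles[i],
              ic50_value = raw$ic50_value[i], ic50_unit = raw$ic50_unit[i],
              year = if (!is.null(raw$year)) raw$year[i] else NA)
    if (is.na(cans[i])) {
      res <- .rejection("invalid_smiles", as.character(raw$source_id[i]))
    } else {
      res <- standardize_record(r, config)
    }
    if (inherits(res, "sar_rejection")) {
      rej[[length(rej) + 1]] <- data.frame(source_id = res$source_id,
                                           reason = res$reason)
      if (verbose) message("rejected ", res$source_id, ": ", res$reason)
    } else {
      n_desalted <- n_desalted + res$desalted
      n_unit_converted <- n_unit_converted + res$unit_converted
      recs[[length(recs) + 1]] <- data.frame(
        compound_id = res$compound_id, canonical_smiles = res$canonical_smiles,
        ic50_nM = res$ic50_nM, pic50 = res$pic50, label = res$label,
        year = res$year)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(compound_id = character(0), canonical_smiles = character(0),
               ic50_nM = numeric(0), pic50 = numeric(0), label = character(0),
               year = integer(0))
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(source_id = character(0), reason = character(0))
  n_rejected <- nrow(rejections)
  dd <- deduplicate_compounds(records, config)
  report <- c(
    n_input = n_input,
    n_invalid_smiles = sum(rejections$reason == "invalid_smiles"),
    n_rejected_activity = sum(rejections$reason == "bad_activity"),
    n_rejected_unit = sum(rejections$reason == "bad_unit"),
    n_desalted = n_desalted,
    n_unit_converted = n_unit_converted,
    dd$report[c("n_dropped_conflicting_duplicates", "n_merged_duplicates")],
    n_output = unname(dd$report["n_output"])
  )
  structure(list(records = dd$records, report = report,
                 rejections = rejections, config = config),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  r <- x$report
  cat("Curation result\n")
  cat(sprintf("  input records:        %d\n", r["n_input"]))
  cat(sprintf("  invalid SMILES:       %d\n", r["n_invalid_smiles"]))
  cat(sprintf("  bad activity/unit:    %d / %d\n",
              r["n_rejected_activity"], r["n_rejected_unit"]))
  cat(sprintf("  desalted:             %d\n", r["n_desalted"]))
  cat(sprintf("  conflicting dropped:  %d\n",
              r["n_dropped_conflicting_duplicates"]))
  cat(sprintf("  duplicates merged:    %d\n", r["n_merged_duplicates"]))
  cat(sprintf("  curated compounds:    %d (%d active / %d inactive at %g nM)\n",
              r["n_output"], sum(x$records$label == "active"),
              sum(x$records$label == "inactive"),
              x$config$activity_threshold_nM))
  invisible(x)
}

#' Read a raw compound table
#'
#' Readers for the three interchange formats: delimited text with columns
#' `(id, smiles, ic50, unit[, year, source])`, a `.smi` SMILES file
#' (whitespace-separated `smiles id`, IC50s supplied separately), or an SD
#' file with the IC50 in a named data field.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, `"smi"` or `"sdf"` (guessed from the
#'   extension by default).
#' @param ic50_field For `"sdf"`: name of the data field holding the IC50.
#' @param ic50_unit Unit to assume when the file does not carry one
#'   (default `"nM"`).
#' @return Data frame with columns `source_id`, `smiles`, `ic50_value`,
#'   `ic50_unit`, and `year`/`source` when present.
#' @export
read_raw_compounds <- function(path, format = NULL, ic50_field = "IC50",
                               ic50_unit = "nM") {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", smi = "smi",
                     sdf = "sdf", "csv")
  }
  if (format %in% c("csv", "tsv")) {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    names(df) <- tolower(names(df))
    out <- data.frame(
      source_id = as.character(df[[intersect(c("id", "source_id", "compound_id"),
                                             names(df))[1]]]),
      smiles = as.character(df$smiles),
      ic50_value = as.numeric(df[[intersect(c("ic50", "ic50_value", "ic50_nm"),
                                            names(df))[1]]]),
      ic50_unit = if ("unit" %in% names(df)) as.character(df$unit) else
        if ("ic50_unit" %in% names(df)) as.character(df$ic50_unit) else ic50_unit)
    if ("year" %in% names(df)) out$year <- df$year
    if ("source" %in% names(df)) out$source <- df$source
    return(out)
  }
  if (format == "smi") {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    parts <- strsplit(trimws(ln), "[[:space:]]+")
    return(data.frame(
      source_id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                         character(1)),
      smiles = vapply(parts, `[`, character(1), 1),
      ic50_value = vapply(parts, function(p) if (length(p) > 2)
        suppressWarnings(as.numeric(p[3])) else NA_real_, numeric(1)),
      ic50_unit = ic50_unit))
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    vals <- vapply(seq_along(sdf), function(i) {
      db <- ChemmineR::datablock(sdf[[i]])
      if (ic50_field %in% names(db))
        suppressWarnings(as.numeric(db[[ic50_field]])) else NA_real_
    }, numeric(1))
    return(data.frame(source_id = ids, smiles = smi, ic50_value = vals,
                      ic50_unit = ic50_unit))
  }
  stop("unknown format: ", format)
}
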