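# End-to-end pipeline: curate -> fingerprints -> clustering -> CSN ->
# cliffs -> alerts -> rules, driven by a run manifest, with every stage
# artifact written to an output directory.

.default_manifest <- function() {
  list(
    input = NULL,
    seed = 1L,
    output_dir = NULL,
    synthetic = list(n_families = 6, compounds_per_family = 60,
                     n_planted_cliffs = NULL),
    curation = list(threshold_nm = 100, average = "arith"),
    fingerprints = list(radius = 2, n_bits = 1024),
    clustering = list(k = 12, scan = NULL, mcs_timeout_s = 5,
                      compute_mcs = TRUE),
    csn = list(top_n = 100, threshold = 0.6, drop_isolated = TRUE),
    cliffs = list(threshold = 0.6, min_partners = 10),
    alerts = list(max_radius = 3, min_support = 30, alpha = 0.05),
    rules = list(max_depth = 10, precision_threshold = 0.80,
                 n_perturb = 500)
  )
}

.merge_manifest <- function(user, defaults = .default_manifest()) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      defaults[[k]] <- .merge_manifest(user[[k]], defaults[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a run manifest
#'
#' A YAML file with flat per-stage parameter blocks (`curation`,
#' `fingerprints`, `clustering`, `csn`, `cliffs`, `alerts`, `rules`),
#' plus `input` (path to a raw compound CSV; omit to generate the
#' synthetic study dataset), `seed` and `output_dir`. Missing entries
#' take the package defaults.
#'
#' @param path YAML file path.
#' @return Manifest list (class `"run_manifest"`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  structure(.merge_manifest(yaml::read_yaml(path)), class = "run_manifest")
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Run the full SAR landscape pipeline
#'
#' Executes every stage in order, writing the stage artifacts (curated
#' table, curation report, cluster assignment and summaries, chemical
#' space network with metrics, cliff pairs/profiles/census, structural
#' alerts, anchor rules) plus a manifest snapshot to `output_dir`.
#' Re-running with an identical manifest reproduces all artifacts
#' byte for byte.
#'
#' @param manifest Manifest list (e.g. from [read_manifest()]) or path to
#'   a YAML manifest. Missing entries take the package defaults.
#' @param output_dir Overrides the manifest's output directory.
#' @return An object of class `"sar_pipeline"` collecting the stage
#'   results and artifact paths.
#' @export
run_pipeline <- function(manifest = list(), output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  m <- .merge_manifest(unclass(manifest))
  if (!is.null(output_dir)) m$output_dir <- output_dir
  if (is.null(m$output_dir)) stop("output_dir is required")
  if (!is.null(m$input) && !file.exists(m$input))
    stop("input not found: ", m$input)
  dir.create(m$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(m$output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  raw <- stage("input", {
    if (!is.null(m$input)) {
      read_raw_compounds(m$input)
    } else {
      cfg <- if (is.null(m$synthetic$n_planted_cliffs)) {
        synth_config(n_families = m$synthetic$n_families,
                     compounds_per_family = m$synthetic$compounds_per_family,
                     seed = m$seed)
      } else {
        synth_config(n_families = m$synthetic$n_families,
                     compounds_per_family = m$synthetic$compounds_per_family,
                     n_planted_cliffs = m$synthetic$n_planted_cliffs,
                     seed = m$seed)
      }
      ds <- synth_study_dataset(cfg)
      truth <<- ds$truth
      .write_csv(ds$records, out("raw.csv"))
      ds$records
    }
  })

  cfg_cur <- curation_config(activity_threshold_nM = m$curation$threshold_nm,
                             duplicate_average = m$curation$average)
  cur <- stage("curation", curate_compounds(raw, cfg_cur))
  stage("curation", {
    .write_csv(cur$records, out("curated.csv"))
    .write_json(as.list(cur$report), out("curation_report.json"))
  })
  records <- cur$records

  fps <- stage("fingerprints", fingerprint_matrix(
    stats::setNames(records$canonical_smiles, records$compound_id),
    radius = m$fingerprints$radius, n_bits = m$fingerprints$n_bits))

  assignment <- stage("clustering", {
    k <- min(m$clustering$k, nrow(records))
    a <- cluster_compounds(fps, k)
    .write_csv(data.frame(compound_id = records$compound_id,
                          cluster_id = a$labels),
               out("cluster_assignments.csv"))
    if (!is.null(m$clustering$scan)) {
      sc <- silhouette_scan(fps, seq(m$clustering$scan[[1]],
                                     m$clustering$scan[[2]]))
      .write_csv(sc, out("silhouette.csv"))
    }
    a
  })
  summaries <- stage("clustering", {
    s <- summarize_clusters(assignment, records, fps,
                            compute_mcs = isTRUE(m$clustering$compute_mcs),
                            mcs_timeout_s = m$clustering$mcs_timeout_s)
    .write_csv(as.data.frame(s), out("cluster_summaries.csv"))
    s
  })

  csn_m <- stage("csn", {
    top <- select_top_actives(records, n = m$csn$top_n)
    g <- build_csn(top, threshold = m$csn$threshold,
                   drop_isolated = isTRUE(m$csn$drop_isolated))
    export_graph(g, out("csn.graphml"), format = "graphml")
    export_graph(g, out("csn_edges.csv"), format = "edge_csv")
    mt <- csn_metrics(g)
    .write_json(list(n_nodes = mt$n_nodes, n_edges = mt$n_edges,
                     density = mt$density, n_components = mt$n_components,
                     component_sizes = mt$component_sizes),
                out("csn_metrics.json"))
    mt
  })

  cliff_out <- stage("cliffs", {
    pairs <- enumerate_similar_pairs(records, threshold = m$cliffs$threshold,
                                     strict = TRUE, fps = fps)
    .write_csv(pairs, out("cliff_pairs.csv"))
    cls <- classify_pairs(pairs)
    prof <- profile_compounds(pairs, min_partners = m$cliffs$min_partners)
    .write_csv(prof, out("cliff_profiles.csv"))
    census <- scaffold_cliff_census(pairs, assignment, records)
    .write_csv(census, out("cliff_census.csv"))
    list(pairs = pairs, classification = cls, profiles = prof,
         census = census)
  })

  alerts <- stage("alerts", {
    a <- find_alerts(records, max_radius = m$alerts$max_radius,
                     min_support = m$alerts$min_support,
                     alpha = m$alerts$alpha)
    .write_csv(as.data.frame(a), out("alerts.csv"))
    a
  })

  rules_out <- stage("rules", {
    desc <- descriptor_panel(records$canonical_smiles)
    tree <- train_activity_tree(desc, records$label,
                                max_depth = m$rules$max_depth,
                                seed = m$seed)
    rl <- suppressWarnings(extract_anchor_rules(
      tree, desc, records$label,
      precision_threshold = m$rules$precision_threshold,
      n_perturb = m$rules$n_perturb, seed = m$seed))
    tab <- as.data.frame(rl)
    .write_csv(tab, out("rules_table.csv"))
    .write_json(list(
      training_accuracy = tree$training_accuracy,
      max_depth = tree$max_depth,
      hyperparameters = as.list(tree$hyperparameters),
      descriptor_panel = DESCRIPTOR_PANEL_VERSION,
      rules = lapply(rl, function(r) list(
        predicates = r$predicates, target = r$target,
        anchor_precision = r$anchor_precision,
        stats = r$stats[c("n_match", "n_active", "n_inactive",
                          "pct_active", "coverage")]))),
      out("rules.json"))
    list(tree = tree, rules = rl, table = tab)
  })

  snapshot <- m
  snapshot$package_version <- as.character(utils::packageVersion("sarscape"))
  snapshot$descriptor_panel <- DESCRIPTOR_PANEL_VERSION
  yaml::write_yaml(snapshot, out("manifest.yaml"))

  structure(list(manifest = m, output_dir = m$output_dir,
                 curation = cur, records = records,
                 assignment = assignment, cluster_summaries = summaries,
                 csn_metrics = csn_m, cliffs = cliff_out, alerts = alerts,
                 rules = rules_out, truth = truth),
            class = "sar_pipeline")
}

#' @export
print.sar_pipeline <- function(x, ...) {
  cat("SAR landscape pipeline run\n")
  cat("  output:   ", x$output_dir, "\n")
  cat("  compounds:", nrow(x$records), sprintf(
    "(%d active / %d inactive)\n", sum(x$records$label == "active"),
    sum(x$records$label == "inactive")))
  cat("  clusters: ", x$assignment$k, "\n")
  cat(sprintf("  CSN:       %d nodes, %d edges, density %.4f\n",
              x$csn_metrics$n_nodes, x$csn_metrics$n_edges,
              x$csn_metrics$density))
  cat("  cliffs:   ", x$cliffs$classification$n_cliffs, "of",
      x$cliffs$classification$n_pairs, "similar pairs\n")
  cat("  alerts:   ", nrow(x$alerts), "significant environments\n")
  cat("  rules:    ", length(x$rules$rules), "anchor rules, tree accuracy",
      sprintf("%.4f\n", x$rules$tree$training_accuracy))
  invisible(x)
}

#' @export
summary.sar_pipeline <- function(object, ...) {
  print(object)
  cat("\nTop clusters by activity:\n")
  s <- object$cluster_summaries
  print(utils::head(as.data.frame(s)[order(-s$pct_active),
                                     c("cluster_id", "n_members",
                                       "pct_active", "sim_median",
                                       "mcs_smarts")], 5),
        row.names = FALSE)
  if (nrow(object$alerts)) {
    cat("\nTop alerts:\n")
    print(utils::head(as.data.frame(object$alerts)[, c("radius", "n", "k",
                                                       "act_pct",
                                                       "direction")], 5),
          row.names = FALSE)
  }
  if (nrow(object$rules$table)) {
    cat("\nTop rules:\n")
    print(utils::head(object$rules$table, 5), row.names = FALSE)
  }
  invisible(object)
}
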