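# Interpretable activity rules: a depth-limited decision tree on the
# descriptor panel, anchor-style IF-THEN rule extraction from its
# decision paths, and exact empirical rule evaluation.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Train the activity decision tree
#'
#' Fits a depth-limited classification tree (rpart, Gini splits) of
#' activity label on the descriptor matrix. The model exists solely for
#' rule extraction - it is not a virtual-screening predictor - so apart
#' from the depth bound the tree is grown without complexity pruning
#' (`cp = 0`, `minsplit = 2`, `minbucket = 1`), mirroring an
#' unregularized default classifier.
#'
#' @param descriptors Numeric matrix (rows = compounds, named columns),
#'   e.g. [descriptor_panel()] output. No missing values.
#' @param labels Character/factor vector of `"active"`/`"inactive"`.
#' @param max_depth Maximum tree depth (default 10).
#' @param seed Recorded for provenance; tree fitting is deterministic.
#' @return List of class `"activity_tree"`: `model` (rpart fit),
#'   `training_accuracy`, `features`, `max_depth`, `hyperparameters`.
#' @export
train_activity_tree <- function(descriptors, labels, max_depth = 10,
                                seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("need both classes to train the tree")
  if (anyNA(descriptors)) stop("descriptor matrix contains missing values")
  df <- as.data.frame(descriptors, check.names = FALSE)
  df$.label <- factor(labels, levels = c("inactive", "active"))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      control = ctrl)
  pred <- predict(fit, type = "class")
  structure(list(model = fit,
                 training_accuracy = mean(pred == df$.label),
                 features = colnames(descriptors),
                 max_depth = max_depth,
                 seed = seed,
                 hyperparameters = c(cp = 0, minsplit = 2, minbucket = 1,
                                     maxdepth = max_depth)),
            class = "activity_tree")
}

#' @export
print.activity_tree <- function(x, ...) {
  cat(sprintf(
    "Activity decision tree: %d features, max depth %d, training accuracy %.4f\n",
    length(x$features), x$max_depth, x$training_accuracy))
  invisible(x)
}

# ---- rules ----------------------------------------------------------------

#' Descriptor predicate and rule constructors
#'
#' A predicate is a single threshold condition `descriptor > t` or
#' `descriptor <= t`; a rule is a non-redundant conjunction of predicates
#' predicting a class.
#'
#' @param descriptor Descriptor name.
#' @param op `">"` or `"<="`.
#' @param threshold Numeric threshold (applied at full precision;
#'   displayed rounded to 2 decimals).
#' @return `predicate()`: a one-row data frame; `rule()`: an object of
#'   class `"sar_rule"`.
#' @export
predicate <- function(descriptor, op = c(">", "<="), threshold) {
  op <- match.arg(op)
  data.frame(descriptor = descriptor, op = op, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' @rdname predicate
#' @param predicates Data frame of predicates (rbind of [predicate()]
#'   rows).
#' @param target Predicted class (default `"active"`).
#' @export
rule <- function(predicates, target = "active") {
  stopifnot(nrow(predicates) >= 1)
  structure(list(predicates = .merge_predicates(predicates),
                 target = target,
                 anchor_precision = NA_real_, stats = NULL),
            class = "sar_rule")
}

# collapse same-descriptor same-operator predicates to the tightest one
.merge_predicates <- function(pr) {
  keyf <- interaction(pr$descriptor, pr$op, drop = TRUE)
  out <- do.call(rbind, lapply(split(pr, keyf), function(g) {
    g$threshold <- if (g$op[1] == ">") max(g$threshold) else min(g$threshold)
    g[1, , drop = FALSE]
  }))
  out <- out[order(out$descriptor, out$op), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.rule_text <- function(x) {
  paste(sprintf("%s %s %.2f", x$predicates$descriptor, x$predicates$op,
                x$predicates$threshold), collapse = " and ")
}

#' @export
print.sar_rule <- function(x, ...) {
  cat(sprintf("IF %s THEN %s", .rule_text(x), x$target))
  if (!is.na(x$anchor_precision))
    cat(sprintf("  [anchor precision %.2f]", x$anchor_precision))
  if (!is.null(x$stats))
    cat(sprintf("  [n=%d, %.2f%% active, coverage %.2f]",
                x$stats$n_match, x$stats$pct_active, x$stats$coverage))
  cat("\n")
  invisible(x)
}

.rule_matches <- function(predicates, descriptors) {
  m <- rep(TRUE, nrow(descriptors))
  for (i in seq_len(nrow(predicates))) {
    v <- descriptors[, predicates$descriptor[i]]
    m <- m & if (predicates$op[i] == ">") v > predicates$threshold[i]
             else v <= predicates$threshold[i]
  }
  m
}

#' Evaluate a rule on a descriptor matrix
#'
#' Exact counting semantics: a compound matches iff every predicate
#' holds. Reports the number of matches, actives/inactives among them,
#' the percentage of actives (2 decimals) and the dataset coverage.
#'
#' @param x A `"sar_rule"` or a predicate data frame.
#' @param descriptors Numeric descriptor matrix for all records.
#' @param labels Activity labels aligned with `descriptors`.
#' @return List of class `"rule_stats"`: `n_match`, `n_active`,
#'   `n_inactive`, `pct_active` (NA with `undefined = TRUE` when nothing
#'   matches), `coverage`.
#' @export
evaluate_rule <- function(x, descriptors, labels) {
  predicates <- if (inherits(x, "sar_rule")) x$predicates else x
  miss <- setdiff(predicates$descriptor, colnames(descriptors))
  if (length(miss)) stop("unknown descriptor(s): ",
                         paste(miss, collapse = ", "))
  m <- .rule_matches(predicates, descriptors)
  n_match <- sum(m)
  n_active <- sum(labels[m] == "active")
  structure(list(
    n_match = n_match,
    n_active = n_active,
    n_inactive = n_match - n_active,
    pct_active = if (n_match > 0) round(100 * n_active / n_match, 2)
                 else NA_real_,
    undefined = n_match == 0,
    coverage = n_match / nrow(descriptors)),
    class = "rule_stats")
}

#' @export
print.rule_stats <- function(x, ...) {
  if (x$undefined) {
    cat("rule matches no compounds\n")
  } else {
    cat(sprintf("%d compounds match: %d active (%.2f%%), %d inactive; coverage %.2f\n",
                x$n_match, x$n_active, x$pct_active, x$n_inactive,
                x$coverage))
  }
  invisible(x)
}

# decision-path predicates for one rpart leaf
.leaf_predicates <- function(fit, node) {
  pth <- rpart::path.rpart(fit, nodes = node, print.it = FALSE)[[1]]
  pth <- pth[pth != "root"]
  if (!length(pth)) return(NULL)
  out <- lapply(pth, function(s) {
    m <- regmatches(s, regexec("^(.*?)(>=|<)\\s*(-?[0-9.eE+]+)$", s))[[1]]
    if (length(m) != 4) return(NULL)
    # rpart splits at midpoints between observed values, so on the data
    # 'x >= t' is equivalent to 'x > t' and 'x < t' to 'x <= t'
    predicate(m[2], if (m[3] == ">=") ">" else "<=", as.numeric(m[4]))
  })
  do.call(rbind, out)
}

#' Extract anchor-style rules from the activity tree
#'
#' Candidate rules are the root-to-leaf decision paths of leaves
#' predicting the target class. Each candidate is greedily pruned to a
#' minimal conjunction: predicates are removed one at a time, always
#' choosing the removal that maximizes coverage, as long as the rule's
#' empirical precision (fraction of matching compounds in the target
#' class) stays at or above `precision_threshold`. Surviving rules are
#' deduplicated, annotated with a perturbation-based anchor precision
#' (the tree's precision on synthetic samples drawn from the per-
#' descriptor empirical marginals, conditioned on the rule), and ranked
#' by coverage.
#'
#' @param tree An [train_activity_tree()] result.
#' @param descriptors,labels Training data.
#' @param precision_threshold Minimum empirical precision (default 0.80).
#' @param target Class the rules predict (default `"active"`).
#' @param n_perturb Perturbation sample size for the anchor precision
#'   estimate (default 500).
#' @param seed RNG seed for the perturbation sampling.
#' @return List of `"sar_rule"` objects (class `"anchor_rules"`), each
#'   with `stats` and `anchor_precision` filled in; empty (with a
#'   warning) if no rule meets the threshold.
#' @export
extract_anchor_rules <- function(tree, descriptors, labels,
                                 precision_threshold = 0.80,
                                 target = "active", n_perturb = 500,
                                 seed = 1) {
  fit <- tree$model
  frame <- fit$frame
  leaves <- which(frame$var == "<leaf>")
  lev <- attr(fit, "ylevels")
  pred_class <- lev[frame$yval[leaves]]
  nodes <- as.integer(rownames(frame))[leaves][pred_class == target]
  prec_of <- function(st) {
    if (st$undefined) return(-Inf)
    p_active <- st$pct_active / 100
    if (target == "active") p_active else 1 - p_active
  }
  rules <- list()
  for (nd in nodes) {
    pr <- .leaf_predicates(fit, nd)
    if (is.null(pr) || !nrow(pr)) next
    pr <- .merge_predicates(pr)
    st <- evaluate_rule(pr, descriptors, labels)
    if (prec_of(st) < precision_threshold) next
    # greedy pruning toward maximal coverage
    repeat {
      if (nrow(pr) <= 1) break
      best <- NULL
      best_cov <- st$coverage
      for (i in seq_len(nrow(pr))) {
        cand <- pr[-i, , drop = FALSE]
        cst <- evaluate_rule(cand, descriptors, labels)
        if (prec_of(cst) >= precision_threshold && cst$coverage > best_cov) {
          best <- i; best_cov <- cst$coverage
        }
      }
      if (is.null(best)) break
      pr <- pr[-best, , drop = FALSE]
      st <- evaluate_rule(pr, descriptors, labels)
    }
    r <- rule(pr, target = target)
    r$stats <- st
    rules[[length(rules) + 1]] <- r
  }
  if (!length(rules)) {
    warning("no rule meets the precision threshold")
    return(structure(list(), class = "anchor_rules"))
  }
  # deduplicate by predicate signature
  sig <- vapply(rules, function(r) paste(r$predicates$descriptor,
                                         r$predicates$op,
                                         signif(r$predicates$threshold, 10),
                                         collapse = ";"), character(1))
  rules <- rules[!duplicated(sig)]
  rules <- .with_seed(seed, lapply(rules, function(r) {
    r$anchor_precision <- .anchor_precision(r, fit, descriptors, target,
                                            n_perturb)
    r
  }))
  ord <- order(-vapply(rules, function(r) r$stats$coverage, numeric(1)),
               vapply(rules, .rule_text, character(1)))
  structure(rules[ord], class = "anchor_rules")
}

# perturbation-based precision: draw descriptor vectors from the
# per-column empirical marginals, conditioning columns under a predicate
# on the values that satisfy it, and ask how often the tree predicts the
# target class
.anchor_precision <- function(r, fit, descriptors, target, n_perturb) {
  pr <- r$predicates
  synth <- as.data.frame(lapply(colnames(descriptors), function(cn) {
    pool <- descriptors[, cn]
    rows <- which(pr$descriptor == cn)
    for (i in rows) {
      pool <- pool[if (pr$op[i] == ">") pool > pr$threshold[i]
                   else pool <= pr$threshold[i]]
    }
    if (!length(pool)) pool <- descriptors[, cn]
    sample(pool, n_perturb, replace = TRUE)
  }), col.names = colnames(descriptors), check.names = FALSE)
  names(synth) <- colnames(descriptors)
  pred <- predict(fit, newdata = synth, type = "class")
  mean(as.character(pred) == target)
}

#' @export
print.anchor_rules <- function(x, ...) {
  cat(length(x), "anchor rule(s):\n")
  for (r in x) print(r)
  invisible(x)
}

#' Rules as a summary table
#'
#' @param x An `"anchor_rules"` list.
#' @param ... Unused.
#' @return Data frame with one row per rule: anchor text, anchor
#'   precision, coverage, compound counts and active percentage.
#' @export
as.data.frame.anchor_rules <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(anchor = character(0), anchor_precision = numeric(0),
                      coverage = numeric(0), n_compounds = integer(0),
                      n_actives = integer(0), pct_active = numeric(0),
                      n_inactives = integer(0)))
  }
  do.call(rbind, lapply(x, function(r) data.frame(
    anchor = .rule_text(r),
    anchor_precision = r$anchor_precision,
    coverage = round(r$stats$coverage, 2),
    n_compounds = r$stats$n_match,
    n_actives = r$stats$n_active,
    pct_active = r$stats$pct_active,
    n_inactives = r$stats$n_inactive)))
}
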