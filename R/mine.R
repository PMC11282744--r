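# Subgroup mining on top of the survival trees: grow an ensemble of pruned
# trees on different random predictor subsets, scan every node, keep nodes
# whose median (or Q3) time to conversion deviates from the cohort reference
# by at least the deviation floor while covering at least the size floor,
# then confirm each candidate with a log-rank test against its complement
# and, when the rule involves an anti-dementia treatment variable, a Cox
# model adjusted for the number of comorbidities.

#' Mining parameters
#'
#' @param n_trees number of trees in the ensemble.
#' @param subset_fraction fraction of source variables each tree sees
#'   (sampled without replacement; all one-hot columns of a variable travel
#'   together).
#' @param deviation_floor minimum relative deviation
#'   `|q_node - q_ref| / q_ref` for a candidate (default 0.15).
#' @param size_floor minimum subgroup size as a fraction of the cohort
#'   (default 0.06).
#' @param tree tree growth parameters, a [tree_control()].
#' @param prune whether trees are pruned before scanning.
#' @param n_folds folds for the pruning cross-validation.
#' @return a `mine_control` list.
#' @export
mine_control <- function(n_trees = 20L, subset_fraction = 0.7,
                         deviation_floor = 0.15, size_floor = 0.06,
                         tree = tree_control(), prune = TRUE, n_folds = 5L) {
  stopifnot(
    n_trees >= 1, subset_fraction > 0, subset_fraction <= 1,
    deviation_floor >= 0, size_floor >= 0, size_floor <= 1
  )
  structure(
    list(
      n_trees = as.integer(n_trees), subset_fraction = subset_fraction,
      deviation_floor = deviation_floor, size_floor = size_floor,
      tree = tree, prune = prune, n_folds = as.integer(n_folds)
    ),
    class = "mine_control"
  )
}

# subset an encoded matrix to the columns of the given source variables
subset_encoded <- function(encoded, sources) {
  keep <- encoded$feature_meta$source %in% sources
  out <- encoded
  out$values <- encoded$values[, keep, drop = FALSE]
  out$feature_meta <- encoded$feature_meta[keep, , drop = FALSE]
  rownames(out$feature_meta) <- NULL
  out$imputed <- encoded$imputed[intersect(names(encoded$imputed), sources)]
  out
}

#' Grow an ensemble of survival trees on random predictor subsets
#'
#' Tree `i` is grown (and pruned) on a seeded random sample without
#' replacement of `ceiling(subset_fraction * n_sources)` source variables;
#' one-hot columns of a categorical always travel with their source. The
#' whole ensemble is reproducible from `seed`.
#'
#' @param encoded an `encoded_matrix`.
#' @param time,event right-censored outcome.
#' @param control a [mine_control()].
#' @param seed integer seed.
#' @return list of `survival_tree` objects, each with `$predictors`,
#'   `$tree_id` and `$seed` recorded.
#' @export
run_tree_ensemble <- function(encoded, time, event, control = mine_control(),
                              seed = 1L) {
  stopifnot(inherits(encoded, "encoded_matrix"), inherits(control, "mine_control"))
  sources <- unique(encoded$feature_meta$source)
  n_sub <- ceiling(control$subset_fraction * length(sources))
  if (n_sub < 1L) {
    stop("predictor subset too small to contain any variable", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, control$n_trees)
  trees <- vector("list", control$n_trees)
  for (i in seq_len(control$n_trees)) {
    set.seed(tree_seeds[i])
    vars_i <- sort(sample(sources, n_sub))
    enc_i <- subset_encoded(encoded, vars_i)
    tr <- grow_tree(enc_i, time, event, control = control$tree)
    if (control$prune) {
      tr <- prune_tree(tr, enc_i, time, event,
        n_folds = control$n_folds, seed = tree_seeds[i]
      )
    }
    tr$predictors <- vars_i
    tr$tree_id <- i
    tr$seed <- tree_seeds[i]
    trees[[i]] <- tr
  }
  trees
}

# root-to-node path conditions of a tree node
node_rule <- function(tree, id) {
  nd <- tree$nodes
  conds <- list()
  while (!is.na(nd$parent[id])) {
    p <- nd$parent[id]
    conds[[length(conds) + 1L]] <- list(
      feature = nd$feature[p],
      op = if (nd$left[p] == id) "<=" else ">",
      threshold = nd$threshold[p]
    )
    id <- p
  }
  rev(conds)
}

# human-readable rule text using the three-state semantics
rule_text <- function(rule, feature_meta) {
  if (length(rule) == 0L) return("(whole cohort)")
  txt <- vapply(rule, function(cn) {
    j <- match(cn$feature, feature_meta$feature)
    if (!is.na(j) && feature_meta$kind[j] == "three_state_binary") {
      state <- if (cn$threshold == 0.5) {
        if (cn$op == "<=") "known-False" else "True-or-missing"
      } else {
        if (cn$op == "<=") "False-or-missing" else "known-True"
      }
      paste0(cn$feature, ": ", state)
    } else {
      paste0(cn$feature, " ", cn$op, " ", signif(cn$threshold, 6))
    }
  }, character(1))
  paste(txt, collapse = " & ")
}

#' Extract candidate subgroups from tree nodes
#'
#' The cohort reference is the Kaplan-Meier median time to conversion, or
#' the Q3 time (25%-converted) when the median is not reached; every node is
#' compared with the same quantile kind (kind coherence). A node becomes a
#' candidate when its relative deviation from the reference is at least
#' `deviation_floor` and it covers at least `size_floor` of the cohort.
#' Nodes whose quantile of the reference kind is not reached are skipped.
#' Duplicate candidates (identical member sets) are merged keeping the
#' shortest rule; near-duplicates across trees (Jaccard >= 0.9) are flagged
#' but both kept.
#'
#' @param trees list of `survival_tree` (from [run_tree_ensemble()]).
#' @param encoded the `encoded_matrix` of the full cohort (for rule text).
#' @param time,event cohort outcome.
#' @param deviation_floor,size_floor selection floors.
#' @return list of `subgroup` objects (possibly empty).
#' @export
extract_candidates <- function(trees, encoded, time, event,
                               deviation_floor = 0.15, size_floor = 0.06) {
  n <- length(time)
  km <- km_estimate(time, event)
  ref <- quantile_time(km, 0.5)
  kind <- "median"
  if (is.na(ref)) {
    ref <- quantile_time(km, 0.25)
    kind <- "Q3"
  }
  if (is.na(ref)) {
    stop("cohort too censored: neither the median nor the Q3 time is reached",
      call. = FALSE
    )
  }
  cands <- list()
  for (tr in trees) {
    nd <- tr$nodes
    for (id in nd$id) {
      q_node <- if (kind == "median") nd$median[id] else nd$q3[id]
      if (is.na(q_node)) next
      size_fraction <- nd$n[id] / n
      deviation <- (q_node - ref) / ref
      if (abs(deviation) < deviation_floor || size_fraction < size_floor) next
      if (nd$n[id] == n) next # the whole cohort is not a subgroup
      rule <- node_rule(tr, id)
      sg <- structure(
        list(
          rule = rule,
          rule_text = rule_text(rule, encoded$feature_meta),
          members = sort(tr$members[[id]]),
          size = nd$n[id], size_fraction = size_fraction,
          quantile_kind = kind, ttc_value = q_node,
          reference_value = ref, deviation = deviation,
          direction = if (deviation < 0) "earlier" else "later",
          logrank_p = NA_real_, logrank_statistic = NA_real_,
          cox_adjusted = NULL, near_duplicate = FALSE,
          source = list(
            tree = tr$tree_id, node = id,
            predictors = tr$predictors, seed = tr$seed
          )
        ),
        class = "subgroup"
      )
      cands[[length(cands) + 1L]] <- sg
    }
  }
  dedupe_subgroups(cands)
}

dedupe_subgroups <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  keys <- vapply(cands, function(s) paste(s$members, collapse = ","), character(1))
  keep <- list()
  for (k in unique(keys)) {
    grp <- cands[keys == k]
    len <- vapply(grp, function(s) length(s$rule), integer(1))
    keep[[length(keep) + 1L]] <- grp[[which.min(len)]]
  }
  # flag near-duplicates (overlapping but not identical member sets)
  if (length(keep) > 1L) {
    for (a in seq_len(length(keep) - 1L)) {
      for (b in seq((a + 1L), length(keep))) {
        ma <- keep[[a]]$members
        mb <- keep[[b]]$members
        jac <- length(intersect(ma, mb)) / length(union(ma, mb))
        if (jac >= 0.9) {
          keep[[a]]$near_duplicate <- TRUE
          keep[[b]]$near_duplicate <- TRUE
        }
      }
    }
  }
  keep
}

#' Confirm a subgroup against its complement
#'
#' Fills the log-rank test of the subgroup's time to conversion versus the
#' rest of the cohort. When the rule references an anti-dementia-treatment
#' variable (the drug-class flag or a specific agent), a two-covariate Cox
#' model (subgroup indicator + number of comorbidities at index) is fitted
#' so the treatment-linked association can be judged net of comorbidity
#' burden.
#'
#' @param cohort the `stage_cohort` the trees were mined on.
#' @param subgroup a `subgroup` from [extract_candidates()].
#' @param encoded the cohort's `encoded_matrix` (for variable roles).
#' @return the `subgroup` with `logrank_p`, `logrank_statistic` and
#'   (when triggered) `cox_adjusted = list(hazard_ratio, p_value, coef, se)`.
#' @export
confirm_subgroup <- function(cohort, subgroup, encoded) {
  stopifnot(inherits(cohort, "stage_cohort"), inherits(subgroup, "subgroup"))
  n <- nrow(cohort)
  mem <- subgroup$members
  if (length(mem) == 0L || length(mem) >= n) {
    stop("subgroup must be a non-empty proper subset of the cohort",
      call. = FALSE
    )
  }
  inside <- seq_len(n) %in% mem
  lr <- logrank_test(
    cohort$time[inside], cohort$event[inside],
    cohort$time[!inside], cohort$event[!inside]
  )
  subgroup$logrank_p <- lr$p_value
  subgroup$logrank_statistic <- lr$statistic
  if (rule_has_role(subgroup$rule, encoded$feature_meta, "anti_dementia")) {
    cc <- comorbidity_count(cohort)
    fit <- tryCatch(
      cox_fit(
        cohort$time, cohort$event,
        cbind(in_subgroup = as.numeric(inside), n_comorbidities = cc)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      subgroup$cox_adjusted <- list(
        hazard_ratio = fit$hazard_ratio[["in_subgroup"]],
        p_value = fit$p_value[["in_subgroup"]],
        coef = fit$coef[["in_subgroup"]],
        se = fit$se[["in_subgroup"]],
        converged = fit$converged
      )
    }
  }
  subgroup
}

rule_has_role <- function(rule, feature_meta, role) {
  feats <- vapply(rule, `[[`, character(1), "feature")
  src <- feature_meta$source[match(feats, feature_meta$feature)]
  any(feature_meta$role[match(src, feature_meta$source)] == role, na.rm = TRUE)
}

#' Number of TRUE comorbidity flags per cohort row
#' @param cohort a `stage_cohort`.
#' @return integer vector (missing flags count as zero).
#' @export
comorbidity_count <- function(cohort) {
  spec <- attr(cohort, "covariate_spec")
  com <- names(spec)[vapply(spec, function(cs) {
    cs$role == "comorbidity" && cs$kind == "binary"
  }, logical(1))]
  if (length(com) == 0L) return(rep(0L, nrow(cohort)))
  m <- as.data.frame(cohort)[, com, drop = FALSE]
  rowSums(sapply(m, function(col) !is.na(col) & col), na.rm = TRUE)
}

#' Mine conversion-profile subgroups from a stage cohort
#'
#' End-to-end Step-4 procedure: encode (if needed), grow a pruned tree
#' ensemble on random predictor subsets, extract candidate subgroups by the
#' deviation and size floors, confirm each against its complement, and rank
#' by absolute deviation within direction (earlier / later conversion).
#'
#' @param cohort a `stage_cohort`.
#' @param encoded optional pre-computed `encoded_matrix`.
#' @param control a [mine_control()].
#' @param seed integer seed (drives predictor subsets and pruning folds).
#' @return An object of class `subgroup_set`: list with `subgroups` (ranked
#'   list), `summary` (flat data.frame with a Bonferroni column for the
#'   user's judgment; raw p-values are what the procedure reports),
#'   `reference` (quantile kind and value), `transition`, `control`, `seed`.
#' @export
mine <- function(cohort, encoded = NULL, control = mine_control(), seed = 1L) {
  stopifnot(inherits(cohort, "stage_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(encoded)) encoded <- encode_features(cohort)
  trees <- run_tree_ensemble(encoded, cohort$time, cohort$event,
    control = control, seed = seed
  )
  cands <- extract_candidates(trees, encoded, cohort$time, cohort$event,
    deviation_floor = control$deviation_floor,
    size_floor = control$size_floor
  )
  cands <- lapply(cands, function(s) confirm_subgroup(cohort, s, encoded))
  # rank by |deviation|, earlier profiles first within each direction
  if (length(cands)) {
    dirs <- vapply(cands, `[[`, character(1), "direction")
    devs <- abs(vapply(cands, `[[`, numeric(1), "deviation"))
    ord <- order(match(dirs, c("earlier", "later")), -devs)
    cands <- cands[ord]
  }
  n_tests <- max(length(cands), 1L)
  summary <- if (length(cands)) {
    do.call(rbind, lapply(seq_along(cands), function(i) {
      s <- cands[[i]]
      data.frame(
        rank = i, direction = s$direction, rule = s$rule_text,
        n = s$size, size_fraction = s$size_fraction,
        quantile_kind = s$quantile_kind,
        ttc_days = s$ttc_value, ttc_months = s$ttc_value / 30.44,
        deviation = s$deviation,
        logrank_p = s$logrank_p,
        bonferroni_p = min(1, s$logrank_p * n_tests),
        cox_hr = if (is.null(s$cox_adjusted)) NA_real_ else s$cox_adjusted$hazard_ratio,
        cox_p = if (is.null(s$cox_adjusted)) NA_real_ else s$cox_adjusted$p_value,
        near_duplicate = s$near_duplicate,
        tree = s$source$tree, node = s$source$node,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame()
  }
  km <- km_estimate(cohort$time, cohort$event)
  ref <- quantile_time(km, 0.5)
  kind <- if (is.na(ref)) "Q3" else "median"
  if (is.na(ref)) ref <- quantile_time(km, 0.25)
  out <- list(
    subgroups = cands, summary = summary,
    reference = list(kind = kind, value_days = ref, value_months = ref / 30.44),
    transition = attr(cohort, "transition"),
    control = control, seed = seed, n = nrow(cohort), n_trees = length(trees)
  )
  class(out) <- "subgroup_set"
  out
}

#' @export
print.subgroup_set <- function(x, ...) {
  cat(sprintf(
    "Subgroup mining on '%s': n = %d, %d tree(s), reference %s TTC = %.1f months\n",
    x$transition, x$n, x$n_trees, x$reference$kind, x$reference$value_months
  ))
  if (nrow(x$summary) == 0L) {
    cat("  no subgroup met the deviation and size floors\n")
    return(invisible(x))
  }
  df <- x$summary
  for (i in seq_len(nrow(df))) {
    cat(sprintf(
      "  [%d] %s (%s): %s TTC %.1f mo (%+.0f%%), n=%d (%.0f%%), log-rank p=%.3g%s\n",
      df$rank[i], df$direction[i], df$rule[i], df$quantile_kind[i],
      df$ttc_months[i], 100 * df$deviation[i], df$n[i],
      100 * df$size_fraction[i], df$logrank_p[i],
      if (!is.na(df$cox_hr[i])) {
        sprintf(", adj. HR=%.2f (p=%.3g)", df$cox_hr[i], df$cox_p[i])
      } else {
        ""
      }
    ))
  }
  invisible(x)
}

#' Write a subgroup report (JSON + flat delimited table)
#'
#' @param sgs a `subgroup_set`.
#' @param path base path; writes `<path>.json` and `<path>.tsv`.
#' @export
write_subgroups <- function(sgs, path) {
  stopifnot(inherits(sgs, "subgroup_set"))
  jsonlite::write_json(
    list(
      transition = sgs$transition, n = sgs$n, seed = sgs$seed,
      reference = sgs$reference,
      subgroups = lapply(sgs$subgroups, function(s) {
        list(
          rule = s$rule, rule_text = s$rule_text, n = s$size,
          size_fraction = s$size_fraction, quantile_kind = s$quantile_kind,
          ttc_days = s$ttc_value, ttc_months = s$ttc_value / 30.44,
          deviation = s$deviation, direction = s$direction,
          logrank_p = s$logrank_p, cox_adjusted = s$cox_adjusted,
          near_duplicate = s$near_duplicate, source = s$source
        )
      })
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  utils::write.table(sgs$summary, paste0(path, ".tsv"),
    sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
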