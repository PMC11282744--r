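# Descriptive reporting (Step 1), per-variable log-rank screening (Step 3)
# and end-to-end pipeline orchestration with a reproducibility manifest.

#' Descriptive table of a cohort's characteristics
#'
#' Formats each covariate at the index date the way clinical baseline tables
#' do: binary and categorical variables as `count (percent)` of the cohort,
#' continuous variables as `mean +/- SD` together with min / Q1 / median /
#' Q3 / max.
#'
#' @param cohort a `stage_cohort`.
#' @return data.frame with columns `variable`, `level`, `summary`,
#'   `n_missing` plus the numeric pieces (`count`, `percent`, `mean`, `sd`,
#'   `min`, `q1`, `median`, `q3`, `max`). Empty cohort gives an empty table
#'   with a warning.
#' @examples
#' # a binary flag with 585 TRUE out of 1264 formats as "585 (46%)"
#' @export
describe_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "stage_cohort"))
  spec <- attr(cohort, "covariate_spec")
  if (nrow(cohort) == 0L) {
    warning("empty cohort: nothing to describe")
    return(data.frame(
      variable = character(0), level = character(0),
      summary = character(0), n_missing = integer(0)
    ))
  }
  n <- nrow(cohort)
  df <- as.data.frame(cohort)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  for (nm in names(spec)) {
    val <- df[[nm]]
    nmiss <- sum(is.na(val))
    kind <- spec[[nm]]$kind
    if (kind == "binary") {
      cnt <- sum(val, na.rm = TRUE)
      add(
        variable = nm, level = NA_character_,
        summary = sprintf("%d (%.0f%%)", cnt, 100 * cnt / n),
        n_missing = nmiss, count = cnt, percent = 100 * cnt / n,
        mean = NA_real_, sd = NA_real_, min = NA_real_, q1 = NA_real_,
        median = NA_real_, q3 = NA_real_, max = NA_real_
      )
    } else if (kind == "categorical") {
      levs <- spec[[nm]]$levels
      if (is.null(levs)) levs <- sort(unique(stats::na.omit(as.character(val))))
      for (lv in levs) {
        cnt <- sum(val == lv, na.rm = TRUE)
        add(
          variable = nm, level = lv,
          summary = sprintf("%d (%.0f%%)", cnt, 100 * cnt / n),
          n_missing = nmiss, count = cnt, percent = 100 * cnt / n,
          mean = NA_real_, sd = NA_real_, min = NA_real_, q1 = NA_real_,
          median = NA_real_, q3 = NA_real_, max = NA_real_
        )
      }
      if (nmiss > 0) {
        add(
          variable = nm, level = "(missing)",
          summary = sprintf("%d (%.0f%%)", nmiss, 100 * nmiss / n),
          n_missing = nmiss, count = nmiss, percent = 100 * nmiss / n,
          mean = NA_real_, sd = NA_real_, min = NA_real_, q1 = NA_real_,
          median = NA_real_, q3 = NA_real_, max = NA_real_
        )
      }
    } else {
      obs <- val[!is.na(val)]
      qs <- stats::quantile(obs, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      add(
        variable = nm, level = NA_character_,
        summary = sprintf("%.1f +/- %.1f", mean(obs), stats::sd(obs)),
        n_missing = nmiss, count = NA_real_, percent = NA_real_,
        mean = mean(obs), sd = stats::sd(obs),
        min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate log-rank screen
#'
#' For every three-state encoded variable, tests known-TRUE against
#' known-FALSE (rows with a missing value are excluded from that variable's
#' test). Variables with an empty arm or no events are marked not testable.
#'
#' @param cohort a `stage_cohort`.
#' @param encoded its `encoded_matrix` (computed if omitted).
#' @return data.frame: `feature`, `source`, `n_true`, `n_false`,
#'   `statistic`, `p_value`, `testable`.
#' @export
univariate_screen <- function(cohort, encoded = NULL) {
  stopifnot(inherits(cohort, "stage_cohort"))
  if (is.null(encoded)) encoded <- encode_features(cohort)
  meta <- encoded$feature_meta
  idx3 <- which(meta$kind == "three_state_binary")
  rows <- lapply(idx3, function(j) {
    code <- encoded$values[, j]
    t_true <- cohort$time[code == 2]
    e_true <- cohort$event[code == 2]
    t_false <- cohort$time[code == 0]
    e_false <- cohort$event[code == 0]
    ok <- length(t_true) > 0 && length(t_false) > 0 &&
      (sum(e_true) + sum(e_false)) > 0
    if (ok) {
      lr <- logrank_test(t_true, e_true, t_false, e_false)
      data.frame(
        feature = meta$feature[j], source = meta$source[j],
        n_true = length(t_true), n_false = length(t_false),
        statistic = lr$statistic, p_value = lr$p_value, testable = TRUE,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        feature = meta$feature[j], source = meta$source[j],
        n_true = length(t_true), n_false = length(t_false),
        statistic = NA_real_, p_value = NA_real_, testable = FALSE,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      feature = character(0), source = character(0), n_true = integer(0),
      n_false = integer(0), statistic = numeric(0), p_value = numeric(0),
      testable = logical(0)
    )
  }
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' Exactly one input source: either `registry_path` (a delimited registry
#' written by [write_registry()] or real data in the same schema) or
#' `simulate` (a [sim_config()]).
#'
#' @param registry_path path to a registry CSV, or `NULL`.
#' @param simulate a [sim_config()], or `NULL`.
#' @param transitions which conversion questions to analyze.
#' @param age_min,age_max inclusion bounds; @param drop_threshold encoding
#'   missingness cutoff; @param mine a [mine_control()].
#' @param seed integer master seed recorded in every artifact.
#' @return a `run_config` list.
#' @export
run_config <- function(registry_path = NULL, simulate = NULL,
                       transitions = names(TRANSITION_ENTRY),
                       age_min = 50, age_max = 90, drop_threshold = 0.20,
                       mine = mine_control(), seed = 1L) {
  if (is.null(registry_path) == is.null(simulate)) {
    stop("exactly one of 'registry_path' or 'simulate' must be given",
      call. = FALSE
    )
  }
  transitions <- match.arg(transitions, names(TRANSITION_ENTRY), several.ok = TRUE)
  structure(
    list(
      registry_path = registry_path, simulate = simulate,
      transitions = transitions, age_min = age_min, age_max = age_max,
      drop_threshold = drop_threshold, mine = mine, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; recognised keys mirror [run_config()] and
#'   [sim_config()] (under `simulate:`), [mine_control()] (under `mine:`)
#'   and [tree_control()] (under `mine: tree:`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulate <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$planted_effects)) {
      sim_args$planted_effects <- lapply(sim_args$planted_effects, function(pe) {
        planted_effect(pe$condition, pe$hazard_ratio, pe$transition, pe$label)
      })
    }
    if (!is.null(sim_args$covariates)) {
      sim_args$covariates <- lapply(sim_args$covariates, function(cs) do.call(covariate_spec, cs))
    }
    for (nm in c(
      "age_range", "baseline_hazards", "visit_interval", "dropout",
      "stage_distribution"
    )) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    simulate <- do.call(sim_config, sim_args)
  }
  mine_args <- y$mine
  if (!is.null(mine_args$tree)) mine_args$tree <- do.call(tree_control, mine_args$tree)
  mc <- if (is.null(mine_args)) mine_control() else do.call(mine_control, mine_args)
  run_config(
    registry_path = y$registry_path, simulate = simulate,
    transitions = if (is.null(y$transitions)) names(TRANSITION_ENTRY) else unlist(y$transitions),
    age_min = y$age_min %||% 50, age_max = y$age_max %||% 90,
    drop_threshold = y$drop_threshold %||% 0.20,
    mine = mc, seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full discovery pipeline
#'
#' Simulate or ingest a registry, apply inclusion/exclusion, build the
#' requested stage cohorts, encode, describe, screen, mine subgroups and
#' write every artifact (flowchart JSON, baseline table, KM curve tables,
#' per-variable screen, subgroup report) plus a run manifest echoing every
#' parameter and the seed, so a run is reproducible bit for bit from its
#' manifest.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the per-transition results and the paths
#'   of all artifacts.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  if (!is.null(config$simulate)) {
    say("simulating registry (n = ", config$simulate$n_patients, ")")
    registry <- generate_registry(config$simulate)
    write_registry(registry, file.path(out_dir, "registry.csv"))
  } else {
    say("reading registry from ", config$registry_path)
    registry <- read_registry(config$registry_path)
  }

  filt <- apply_inclusion_exclusion(registry,
    age_min = config$age_min,
    age_max = config$age_max
  )
  say(
    "inclusion/exclusion: ", filt$counts$n_input, " -> ",
    filt$counts$n_remaining, " patients [",
    paste(names(filt$counts$exclusions), filt$counts$exclusions,
      sep = "=", collapse = ", "
    ), "]"
  )
  jsonlite::write_json(
    list(
      n_input = filt$counts$n_input,
      exclusions = as.list(filt$counts$exclusions),
      n_remaining = filt$counts$n_remaining
    ),
    file.path(out_dir, "flowchart.json"),
    auto_unbox = TRUE, digits = NA
  )

  results <- list()
  for (trans in config$transitions) {
    say("building cohort: ", trans)
    cohort <- build_cohort(filt$registry, trans)
    if (nrow(cohort) == 0L) {
      say("  empty cohort, skipped")
      next
    }
    tag <- trans
    write_cohort(cohort, file.path(out_dir, paste0(tag, "_cohort.csv")))
    desc <- describe_cohort(cohort)
    utils::write.table(desc, file.path(out_dir, paste0(tag, "_table1.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    km <- km_estimate(cohort$time, cohort$event)
    utils::write.table(as.data.frame(km),
      file.path(out_dir, paste0(tag, "_km.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    encoded <- encode_features(cohort, drop_threshold = config$drop_threshold)
    screen <- univariate_screen(cohort, encoded)
    utils::write.table(screen, file.path(out_dir, paste0(tag, "_screen.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    say(
      "  mining subgroups (", config$mine$n_trees, " trees, n = ",
      nrow(cohort), ")"
    )
    sgs <- mine(cohort, encoded, control = config$mine, seed = config$seed)
    write_subgroups(sgs, file.path(out_dir, paste0(tag, "_subgroups")))
    say("  ", nrow(sgs$summary), " subgroup(s) reported")
    results[[trans]] <- list(
      cohort = cohort, describe = desc, km = km,
      screen = screen, subgroups = sgs
    )
  }

  manifest <- list(
    seed = config$seed,
    input = if (is.null(config$registry_path)) "simulated" else config$registry_path,
    simulate = if (is.null(config$simulate)) NULL else serialize_config(config$simulate),
    transitions = config$transitions,
    thresholds = list(
      age_min = config$age_min, age_max = config$age_max,
      drop_threshold = config$drop_threshold,
      deviation_floor = config$mine$deviation_floor,
      size_floor = config$mine$size_floor,
      mmse_bands = list(
        MCI = "21-30 (strictly above 20)", mild = "20-26",
        moderate = "11-19", severe = "0-10"
      )
    ),
    mine = list(
      n_trees = config$mine$n_trees,
      subset_fraction = config$mine$subset_fraction,
      prune = config$mine$prune, n_folds = config$mine$n_folds,
      tree = unclass(config$mine$tree)
    ),
    flowchart = list(
      n_input = filt$counts$n_input,
      exclusions = as.list(filt$counts$exclusions),
      n_remaining = filt$counts$n_remaining
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(results = results, counts = filt$counts, out_dir = out_dir))
}
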