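# Synthetic memory-clinic registry generator. Patients carry static
# covariates drawn from configurable marginals (defaults follow typical
# memory-centre prevalences), progress through latent stages
# MCI -> mild -> moderate -> severe with exponential sojourns under
# multiplicative (proportional-hazards) planted covariate effects, and are
# observed only at visits spaced 6-12 months apart until administrative end
# of follow-up, nursing-home admission, or death. The latent conversion
# times travel with the registry as a truth payload for recovery tests.

STAGE_LEVELS <- c("MCI", "mild", "moderate", "severe")
TRANSITIONS <- c("mci_to_dementia", "mild_to_moderate_severe", "moderate_to_severe")

#' Declare a simulated covariate
#'
#' @param name covariate name (a valid column name).
#' @param kind one of `"binary"`, `"categorical"`, `"continuous"`.
#' @param prevalence for binary covariates, P(TRUE).
#' @param levels,probs for categorical covariates, level labels and their
#'   probabilities (normalized internally).
#' @param mean,sd for continuous covariates (Gaussian marginal).
#' @param missing_rate probability that the observed value is masked, in
#'   `[0, 1)`.
#' @param role semantic role used downstream: `"comorbidity"` flags are
#'   counted in the comorbidity-adjusted Cox confirmation, `"anti_dementia"`
#'   variables trigger it; other roles (`"drug"`, `"sociodemographic"`,
#'   `"hospitalization"`) are descriptive.
#' @return a `covariate_spec` row (list).
#' @export
covariate_spec <- function(name, kind = c("binary", "categorical", "continuous"),
                           prevalence = NULL, levels = NULL, probs = NULL,
                           mean = NULL, sd = NULL, missing_rate = 0,
                           role = "comorbidity") {
  kind <- match.arg(kind)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)", call. = FALSE)
  }
  if (kind == "binary" && (is.null(prevalence) || prevalence < 0 || prevalence > 1)) {
    stop("binary covariate '", name, "' needs a prevalence in [0, 1]", call. = FALSE)
  }
  if (kind == "categorical") {
    if (is.null(levels) || is.null(probs) || length(levels) != length(probs)) {
      stop("categorical covariate '", name, "' needs matching levels and probs",
        call. = FALSE
      )
    }
    if (any(probs < 0) || sum(probs) <= 0) {
      stop("categorical probabilities must be nonnegative and not all zero",
        call. = FALSE
      )
    }
    probs <- probs / sum(probs)
  }
  if (kind == "continuous" && (is.null(mean) || is.null(sd) || sd < 0)) {
    stop("continuous covariate '", name, "' needs mean and nonnegative sd",
      call. = FALSE
    )
  }
  structure(
    list(
      name = name, kind = kind, prevalence = prevalence, levels = levels,
      probs = probs, mean = mean, sd = sd, missing_rate = missing_rate,
      role = role
    ),
    class = "covariate_spec"
  )
}

#' Default covariate panel
#'
#' Binary comorbidity/history flags, drug-category flags, anti-dementia
#' treatment flags, socio-demographics and a geriatric-hospitalization flag,
#' with marginal prevalences typical of an MCI memory-centre population
#' (depression 54%, hypertension 46%, anxiety 38%, dyslipidemia 26%,
#' vascular cognitive impairment 26%, ...). Education is categorical with a
#' 7% missing rate; way of living has a 1% missing rate.
#' @return list of [covariate_spec()] entries.
#' @export
default_covariates <- function() {
  com <- c(
    depression = 0.54, hypertension = 0.46, anxiety = 0.38,
    dyslipidemia = 0.26, vascular_cognitive_impairment = 0.26,
    heart_disease = 0.17, ocular_diseases = 0.16, stroke = 0.13,
    osteoarthritis = 0.13, hearing_disorders = 0.11, osteoporosis = 0.10,
    diabetes = 0.10
  )
  drugs <- c(antidepressant = 0.28, anxiolytic = 0.11, hypnotic = 0.03, antipsychotic = 0.01)
  ad <- c(anti_dementia = 0.17, donepezil = 0.06, rivastigmine = 0.07, galantamine = 0.02, memantine = 0.02)
  out <- c(
    lapply(names(com), function(nm) covariate_spec(nm, "binary", prevalence = com[[nm]], role = "comorbidity")),
    lapply(names(drugs), function(nm) covariate_spec(nm, "binary", prevalence = drugs[[nm]], role = "drug")),
    lapply(names(ad), function(nm) covariate_spec(nm, "binary", prevalence = ad[[nm]], role = "anti_dementia")),
    list(
      covariate_spec("woman", "binary", prevalence = 0.65, role = "sociodemographic"),
      covariate_spec("living_alone", "binary",
        prevalence = 0.35,
        missing_rate = 0.01, role = "sociodemographic"
      ),
      covariate_spec("education", "categorical",
        levels = c(
          "no_diploma", "primary", "lower_secondary",
          "upper_secondary", "post_secondary"
        ),
        probs = c(0.06, 0.26, 0.22, 0.15, 0.23),
        missing_rate = 0.07, role = "sociodemographic"
      ),
      covariate_spec("geriatric_hospitalization", "binary",
        prevalence = 0.16,
        role = "hospitalization"
      )
    )
  )
  out
}

#' Declare a planted hazard effect
#'
#' @param condition named list defining a conjunction over covariates:
#'   logical values for binary covariates, a level string for categoricals,
#'   or a numeric `c(min, max)` range for continuous covariates.
#' @param hazard_ratio multiplicative effect (> 0) on the transition hazard
#'   for patients satisfying the whole conjunction.
#' @param transition one of `"mci_to_dementia"`, `"mild_to_moderate_severe"`,
#'   `"moderate_to_severe"`.
#' @param label optional short name used in truth summaries.
#' @return a `planted_effect` (list).
#' @export
planted_effect <- function(condition, hazard_ratio, transition, label = NULL) {
  stopifnot(is.list(condition), length(condition) >= 1, !is.null(names(condition)))
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0) {
    stop("'hazard_ratio' must be > 0", call. = FALSE)
  }
  transition <- match.arg(transition, TRANSITIONS)
  if (is.null(label)) {
    label <- paste(
      vapply(seq_along(condition), function(i) {
        paste0(names(condition)[i], "=", paste(condition[[i]], collapse = ":"))
      }, character(1)),
      collapse = " & "
    )
  }
  structure(
    list(
      condition = condition, hazard_ratio = hazard_ratio,
      transition = transition, label = label
    ),
    class = "planted_effect"
  )
}

#' Simulation configuration
#'
#' @param n_patients number of patients to simulate.
#' @param age_range age at first visit drawn uniformly over this range
#'   (default 45-95 so the downstream 50-90 inclusion filter has work to do).
#' @param covariates list of [covariate_spec()]; default [default_covariates()].
#' @param planted_effects list of [planted_effect()].
#' @param baseline_hazards named per-transition exponential rates (1/days).
#'   Defaults give latent median sojourns of about 25, 23 and 55 months for
#'   the three transitions, so the slow moderate-to-severe cohort does not
#'   reach its median within a typical follow-up.
#' @param visit_interval uniform range of the gap between visits, days
#'   (default `c(180, 365)`: 6 months to 1 year).
#' @param dropout named per-visit probabilities `c(nursing_home=, death=)`
#'   applied after each visit.
#' @param followup_end administrative end of the study window, days.
#' @param entry_span patients enter uniformly over `[0, entry_span]` days,
#'   so individual administrative horizons are `followup_end - entry`.
#' @param stage_distribution named probabilities of the latent stage at the
#'   first visit over `MCI`, `mild`, `moderate`.
#' @param excluded_etiology_rate fraction of patients carrying an
#'   excluded-etiology diagnosis (Parkinson, Lewy body, ...) at one visit.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a `sim_config` (list).
#' @export
sim_config <- function(n_patients = 1500,
                       age_range = c(45, 95),
                       covariates = default_covariates(),
                       planted_effects = list(),
                       baseline_hazards = c(
                         mci_to_dementia = log(2) / 760,
                         mild_to_moderate_severe = log(2) / 700,
                         moderate_to_severe = log(2) / 1675
                       ),
                       visit_interval = c(180, 365),
                       dropout = c(nursing_home = 0.025, death = 0.02),
                       followup_end = 2190,
                       entry_span = 1095,
                       stage_distribution = c(MCI = 0.45, mild = 0.30, moderate = 0.25),
                       excluded_etiology_rate = 0.12,
                       seed = 1L) {
  stopifnot(
    n_patients >= 1, length(age_range) == 2, age_range[1] < age_range[2],
    length(visit_interval) == 2, visit_interval[1] > 0,
    visit_interval[1] <= visit_interval[2],
    followup_end > 0, entry_span >= 0, entry_span < followup_end
  )
  if (any(baseline_hazards <= 0) ||
    !all(TRANSITIONS %in% names(baseline_hazards))) {
    stop("'baseline_hazards' needs positive rates for all three transitions",
      call. = FALSE
    )
  }
  if (any(dropout < 0) || sum(dropout) >= 1 ||
    !all(c("nursing_home", "death") %in% names(dropout))) {
    stop("'dropout' needs nursing_home and death probabilities summing below 1",
      call. = FALSE
    )
  }
  if (excluded_etiology_rate < 0 || excluded_etiology_rate >= 1) {
    stop("'excluded_etiology_rate' must be in [0, 1)", call. = FALSE)
  }
  stage_distribution <- stage_distribution / sum(stage_distribution)
  cov_names <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) stop("duplicate covariate names", call. = FALSE)
  for (pe in planted_effects) {
    bad <- setdiff(names(pe$condition), cov_names)
    if (length(bad)) {
      stop(
        "planted effect references undeclared covariate(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), age_range = age_range,
      covariates = covariates, planted_effects = planted_effects,
      baseline_hazards = baseline_hazards, visit_interval = visit_interval,
      dropout = dropout, followup_end = followup_end, entry_span = entry_span,
      stage_distribution = stage_distribution,
      excluded_etiology_rate = excluded_etiology_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Evaluate a planted-effect conjunction on true (unmasked) covariate values.
eval_condition <- function(condition, covdf) {
  sat <- rep(TRUE, nrow(covdf))
  for (nm in names(condition)) {
    want <- condition[[nm]]
    val <- covdf[[nm]]
    sat <- sat & if (is.logical(want)) {
      !is.na(val) & val == want
    } else if (is.character(want)) {
      !is.na(val) & val == want
    } else if (is.numeric(want) && length(want) == 2) {
      !is.na(val) & val >= want[1] & val <= want[2]
    } else {
      stop("unsupported condition value for '", nm, "'", call. = FALSE)
    }
  }
  sat
}

mmse_band <- function(stage) {
  switch(stage,
    MCI = c(21, 30), mild = c(20, 26), moderate = c(11, 19), severe = c(0, 10)
  )
}

#' Generate a synthetic longitudinal registry
#'
#' Draws static covariates from their configured marginals, latent
#' exponential sojourn times per stage with multiplicative planted hazard
#' effects, and a visit schedule with 6-12 month gaps truncated by
#' administrative follow-up, per-visit nursing-home admission and death.
#' The observed diagnosis and MMSE at each visit reflect the latent stage at
#' that date (MMSE uniform within the stage band). Identical configs produce
#' byte-identical registries.
#'
#' @param config a [sim_config()].
#' @return An object of class `ad_registry`: list with `patients` (one row
#'   per patient: id, age, static covariates with missingness applied,
#'   nursing-home/death dates), `visits` (patient_id, visit_day in days
#'   since the patient's first visit, diagnosis, mmse), `truth` (latent
#'   entry stage, per-transition sojourn days, planted-subgroup membership)
#'   and `config`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  n <- config$n_patients

  # --- static covariates (true values) ---
  true_cov <- data.frame(row.names = seq_len(n))
  for (cs in config$covariates) {
    true_cov[[cs$name]] <- switch(cs$kind,
      binary = stats::runif(n) < cs$prevalence,
      categorical = sample(cs$levels, n, replace = TRUE, prob = cs$probs),
      continuous = stats::rnorm(n, cs$mean, cs$sd)
    )
  }
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]))

  # --- latent stage process ---
  entry_stage <- sample(names(config$stage_distribution), n,
    replace = TRUE, prob = config$stage_distribution
  )
  entry_rank <- match(entry_stage, STAGE_LEVELS)
  rates <- matrix(rep(config$baseline_hazards[TRANSITIONS], each = n), nrow = n)
  colnames(rates) <- TRANSITIONS
  membership <- matrix(FALSE, n, length(config$planted_effects))
  for (i in seq_along(config$planted_effects)) {
    pe <- config$planted_effects[[i]]
    sat <- eval_condition(pe$condition, true_cov)
    membership[, i] <- sat
    rates[sat, pe$transition] <- rates[sat, pe$transition] * pe$hazard_ratio
  }
  # sojourn time in each pre-severe stage (NA where the patient enters later)
  sojourn <- matrix(NA_real_, n, 3, dimnames = list(NULL, TRANSITIONS))
  for (j in 1:3) {
    idx <- entry_rank <= j
    sojourn[idx, j] <- stats::rexp(sum(idx), rates[idx, j])
  }
  # latent absolute conversion day (since first visit) into stage j+1
  conv_day <- matrix(NA_real_, n, 3, dimnames = list(
    NULL, c("to_mild", "to_moderate", "to_severe")
  ))
  for (i in seq_len(n)) {
    acc <- 0
    for (j in entry_rank[i]:3) {
      acc <- acc + sojourn[i, j]
      conv_day[i, j] <- acc
    }
  }

  # --- visit schedule ---
  entry_day <- stats::runif(n, 0, config$entry_span)
  horizon <- config$followup_end - entry_day
  p_nh <- config$dropout[["nursing_home"]]
  p_death <- config$dropout[["death"]]
  visits <- vector("list", n)
  nh_date <- rep(NA_real_, n)
  death_date <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    days <- 0
    t <- 0
    repeat {
      u <- stats::runif(1)
      if (u < p_nh + p_death) {
        gap <- stats::runif(1, 30, 180)
        if (u < p_nh) nh_date[i] <- t + gap else death_date[i] <- t + gap
        break
      }
      t <- t + stats::runif(1, config$visit_interval[1], config$visit_interval[2])
      if (t > horizon[i]) break
      days <- c(days, t)
    }
    visits[[i]] <- days
  }

  n_visits <- lengths(visits)
  vis_day <- unlist(visits)
  vis_pid <- rep(seq_len(n), n_visits)
  # latent stage at each visit: entry rank + crossings of conversion days
  stage_rank <- entry_rank[vis_pid]
  for (j in 1:3) {
    crossed <- !is.na(conv_day[vis_pid, j]) & vis_day >= conv_day[vis_pid, j]
    stage_rank[crossed] <- pmax(stage_rank[crossed], j + 1L)
  }
  stage <- STAGE_LEVELS[stage_rank]
  lo <- c(21, 20, 11, 0)[stage_rank]
  hi <- c(30, 26, 19, 10)[stage_rank]
  mmse <- floor(stats::runif(length(stage), lo, hi + 1))
  mmse <- pmin(mmse, hi) # guard the measure-zero upper edge
  diagnosis <- ifelse(stage_rank == 1L, "MCI", "dementia_AD")
  # excluded etiologies: one visit of the affected patients carries the label
  excl <- stats::runif(n) < config$excluded_etiology_rate
  for (i in which(excl)) {
    rows <- which(vis_pid == i)
    diagnosis[rows[sample.int(length(rows), 1)]] <- "excluded_etiology"
  }

  # --- observed covariates: apply missingness ---
  obs_cov <- true_cov
  for (cs in config$covariates) {
    if (cs$missing_rate > 0) {
      obs_cov[[cs$name]][stats::runif(n) < cs$missing_rate] <- NA
    }
  }

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_first_visit = age,
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, obs_cov)
  patients$nursing_home_date <- nh_date
  patients$death_date <- death_date

  truth <- data.frame(
    patient_id = patients$patient_id,
    entry_stage = entry_stage,
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(sojourn))
  if (length(config$planted_effects)) {
    mem <- as.data.frame(membership)
    names(mem) <- paste0("planted_", seq_along(config$planted_effects))
    truth <- cbind(truth, mem)
  }

  out <- list(
    patients = patients,
    visits = data.frame(
      patient_id = patients$patient_id[vis_pid],
      visit_day = vis_day,
      diagnosis = diagnosis,
      mmse = mmse,
      stringsAsFactors = FALSE
    ),
    truth = truth,
    config = config
  )
  class(out) <- "ad_registry"
  out
}

#' @export
print.ad_registry <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry: %d patients, %d visits, %d planted effect(s), seed %d\n",
    nrow(x$patients), nrow(x$visits),
    length(x$config$planted_effects), x$config$seed
  ))
  invisible(x)
}

#' True median latent conversion times by planted subgroup
#'
#' Summarizes the latent (uncensored) sojourn times carried by a synthetic
#' registry: for each transition, the median sojourn overall and inside /
#' outside each planted subgroup. This is the reference that recovery tests
#' compare mined subgroups against.
#'
#' @param registry an `ad_registry` from [generate_registry()].
#' @return data.frame with columns `transition`, `group`, `n`,
#'   `median_days`.
#' @export
registry_truth_summary <- function(registry) {
  stopifnot(inherits(registry, "ad_registry"))
  if (is.null(registry$truth)) {
    stop("registry has no truth payload (not produced by generate_registry)",
      call. = FALSE
    )
  }
  tr <- registry$truth
  pes <- registry$config$planted_effects
  rows <- list()
  for (trans in TRANSITIONS) {
    soj <- tr[[trans]]
    rows[[length(rows) + 1L]] <- data.frame(
      transition = trans, group = "overall",
      n = sum(!is.na(soj)), median_days = stats::median(soj, na.rm = TRUE)
    )
    for (i in seq_along(pes)) {
      if (pes[[i]]$transition != trans) next
      mem <- tr[[paste0("planted_", i)]]
      for (g in c(TRUE, FALSE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transition = trans,
          group = paste0(pes[[i]]$label, if (g) " [in]" else " [out]"),
          n = sum(mem == g & !is.na(soj)),
          median_days = stats::median(soj[mem == g], na.rm = TRUE)
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read a registry as delimited text
#'
#' One CSV row per visit (patient id, ISO-8601 visit date anchored at
#' 2013-01-01, diagnosis, MMSE, static covariate columns repeated per row,
#' nursing-home/death offsets); empty field = missing. The truth payload and
#' config are written to a JSON side-file `<path>.truth.json` so a simulated
#' registry round-trips.
#'
#' @param registry an `ad_registry`.
#' @param path output CSV path.
#' @param origin date of day 0.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, origin = as.Date("2013-01-01")) {
  stopifnot(inherits(registry, "ad_registry"))
  df <- merge(registry$visits, registry$patients, by = "patient_id", sort = FALSE)
  df <- df[order(df$patient_id, df$visit_day), ]
  df$visit_date <- format(origin + round(df$visit_day))
  df$visit_day <- NULL
  front <- c("patient_id", "visit_date", "diagnosis", "mmse")
  df <- df[, c(front, setdiff(names(df), front))]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  side <- list(
    truth = if (is.null(registry$truth)) NULL else as.list(registry$truth),
    config = serialize_config(registry$config),
    origin = format(origin)
  )
  jsonlite::write_json(side, paste0(path, ".truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_registry
#' @param covariate_kinds optional named character vector (`name -> kind`)
#'   for registries written by other software; inferred from the truth
#'   side-file when present, else from column types.
#' @export
read_registry <- function(path, covariate_kinds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("patient_id", "visit_date", "diagnosis", "mmse")
  if (!all(need %in% names(df))) {
    stop("registry file lacks required columns: ",
      paste(setdiff(need, names(df)), collapse = ", "),
      call. = FALSE
    )
  }
  dates <- as.Date(df$visit_date)
  if (anyNA(dates)) stop("malformed visit dates in registry file", call. = FALSE)
  side_path <- paste0(path, ".truth.json")
  truth <- NULL
  config <- NULL
  origin <- min(dates)
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path,
      simplifyVector = TRUE,
      simplifyDataFrame = FALSE, simplifyMatrix = FALSE
    )
    if (!is.null(side$truth)) {
      truth <- as.data.frame(
        lapply(side$truth, function(col) {
          if (is.list(col)) unlist(lapply(col, function(z) if (is.null(z)) NA else z)) else col
        }),
        stringsAsFactors = FALSE
      )
    }
    config <- deserialize_config(side$config)
    origin <- as.Date(side$origin)
  }
  day <- as.numeric(dates - origin)
  static_cols <- setdiff(names(df), c(need, "visit_date"))
  # first row per patient carries the statics
  first <- !duplicated(df$patient_id)
  patients <- df[first, c("patient_id", static_cols), drop = FALSE]
  rownames(patients) <- NULL
  for (nm in setdiff(static_cols, c(
    "age_first_visit",
    "nursing_home_date", "death_date"
  ))) {
    if (!is.null(config)) next # typed via config below
    if (is.character(patients[[nm]]) &&
      all(patients[[nm]] %in% c("TRUE", "FALSE", NA))) {
      patients[[nm]] <- as.logical(patients[[nm]])
    }
  }
  # normalize patient-local day 0
  pid <- df$patient_id
  day0 <- stats::ave(day, pid, FUN = min)
  out <- list(
    patients = patients,
    visits = data.frame(
      patient_id = pid, visit_day = day - day0,
      diagnosis = df$diagnosis, mmse = df$mmse, stringsAsFactors = FALSE
    ),
    truth = truth,
    config = config
  )
  class(out) <- "ad_registry"
  out
}

serialize_config <- function(config) {
  list(
    n_patients = config$n_patients, age_range = config$age_range,
    covariates = lapply(config$covariates, unclass),
    planted_effects = lapply(config$planted_effects, unclass),
    baseline_hazards = as.list(config$baseline_hazards),
    visit_interval = config$visit_interval, dropout = as.list(config$dropout),
    followup_end = config$followup_end, entry_span = config$entry_span,
    stage_distribution = as.list(config$stage_distribution),
    excluded_etiology_rate = config$excluded_etiology_rate, seed = config$seed
  )
}

deserialize_config <- function(x) {
  if (is.null(x)) return(NULL)
  covs <- lapply(x$covariates, function(cs) {
    do.call(covariate_spec, cs[!vapply(cs, is.null, logical(1))])
  })
  pes <- lapply(x$planted_effects, function(pe) {
    planted_effect(as.list(pe$condition), pe$hazard_ratio, pe$transition, pe$label)
  })
  sim_config(
    n_patients = x$n_patients, age_range = unlist(x$age_range),
    covariates = covs, planted_effects = pes,
    baseline_hazards = unlist(x$baseline_hazards),
    visit_interval = unlist(x$visit_interval), dropout = unlist(x$dropout),
    followup_end = x$followup_end, entry_span = x$entry_span,
    stage_distribution = unlist(x$stage_distribution),
    excluded_etiology_rate = x$excluded_etiology_rate, seed = x$seed
  )
}
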