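# Inclusion/exclusion filtering, stage assignment from diagnosis + MMSE, and
# construction of the three overlapping stage cohorts with right-censored
# time to conversion (TTC, in days).

STAGE_RANK <- c(MCI = 1L, mild = 2L, moderate = 3L, severe = 4L)

# entry stage rank per transition; an event is any visit at a strictly more
# advanced stage (mild cohort: moderate OR severe; a mild -> severe jump
# counts once, at the severe visit)
TRANSITION_ENTRY <- c(
  mci_to_dementia = 1L, mild_to_moderate_severe = 2L, moderate_to_severe = 3L
)

#' Flowchart accounting for sequential cohort filters
#'
#' @param n_input number of patients entering the filter cascade.
#' @param exclusions named integer vector of patients removed by each filter,
#'   applied sequentially.
#' @return a `flowchart_counts` object; `$n_remaining` always equals
#'   `n_input - sum(exclusions)`.
#' @examples
#' fc <- flowchart_counts(5210, c(age = 538, excluded_comorbidity = 644))
#' fc$n_remaining # 4028
#' @export
flowchart_counts <- function(n_input, exclusions = integer()) {
  stopifnot(n_input >= 0, all(exclusions >= 0), sum(exclusions) <= n_input)
  exclusions <- stats::setNames(as.integer(exclusions), names(exclusions))
  out <- list(
    n_input = as.integer(n_input),
    exclusions = exclusions,
    n_remaining = as.integer(n_input - sum(exclusions))
  )
  class(out) <- "flowchart_counts"
  out
}

#' @export
print.flowchart_counts <- function(x, ...) {
  cat("Patient flow:\n  input:", x$n_input, "\n")
  for (nm in names(x$exclusions)) {
    cat(sprintf("  excluded (%s): %d\n", nm, x$exclusions[[nm]]))
  }
  cat("  remaining:", x$n_remaining, "\n")
  invisible(x)
}

#' Apply the study inclusion and exclusion criteria
#'
#' Sequential filters on a registry: (1) age at first visit within
#' `[age_min, age_max]`; (2) no excluded-etiology diagnosis (Parkinson's
#' disease, Lewy body dementia, frontotemporal dementia, ...) at any visit;
#' (3) at least `min_visits` visits; (4) at least one MCI or AD-dementia
#' visit. Counts removed at each step are returned so the selection
#' flowchart can be reconstructed.
#'
#' @param registry an `ad_registry`.
#' @param age_min,age_max inclusive age bounds at the first visit.
#' @param min_visits minimum number of visits (default 2).
#' @return list with `registry` (filtered; truth subset accordingly) and
#'   `counts` (a [flowchart_counts()]).
#' @export
apply_inclusion_exclusion <- function(registry, age_min = 50, age_max = 90,
                                      min_visits = 2L) {
  stopifnot(inherits(registry, "ad_registry"))
  pats <- registry$patients
  vis <- registry$visits
  n_input <- nrow(pats)
  if (n_input == 0L) {
    return(list(registry = registry, counts = flowchart_counts(0L)))
  }
  keep <- rep(TRUE, n_input)
  excl <- integer()

  ok_age <- pats$age_first_visit >= age_min & pats$age_first_visit <= age_max
  excl["age"] <- sum(keep & !ok_age)
  keep <- keep & ok_age

  bad_pid <- unique(vis$patient_id[vis$diagnosis == "excluded_etiology"])
  ok_etio <- !(pats$patient_id %in% bad_pid)
  excl["excluded_comorbidity"] <- sum(keep & !ok_etio)
  keep <- keep & ok_etio

  nv <- table(vis$patient_id)
  ok_visits <- as.integer(nv[pats$patient_id]) >= min_visits
  ok_visits[is.na(ok_visits)] <- FALSE
  excl["fewer_than_min_visits"] <- sum(keep & !ok_visits)
  keep <- keep & ok_visits

  ad_pid <- unique(vis$patient_id[vis$diagnosis %in% c("MCI", "dementia_AD")])
  ok_ad <- pats$patient_id %in% ad_pid
  excl["no_mci_or_ad_visit"] <- sum(keep & !ok_ad)
  keep <- keep & ok_ad

  kept_ids <- pats$patient_id[keep]
  out <- registry
  out$patients <- pats[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  out$visits <- vis[vis$patient_id %in% kept_ids, , drop = FALSE]
  rownames(out$visits) <- NULL
  if (!is.null(registry$truth)) {
    out$truth <- registry$truth[registry$truth$patient_id %in% kept_ids, ,
      drop = FALSE
    ]
    rownames(out$truth) <- NULL
  }
  list(registry = out, counts = flowchart_counts(n_input, excl))
}

#' Assign a disease stage from the visit diagnosis and MMSE
#'
#' MCI diagnosis requires MMSE strictly above 20; AD dementia is banded by
#' MMSE into mild (20-26), moderate (11-19) and severe (strictly under 11).
#' An AD-dementia visit with MMSE above 26 falls outside all bands and is
#' flagged `ineligible` rather than silently reassigned, as are MCI visits
#' with MMSE at or below 20 and non-AD diagnosis labels. A missing MMSE at a
#' stage-defining label yields `NA` (stage undetermined).
#'
#' @param diagnosis character vector of visit diagnosis labels
#'   (`"MCI"`, `"dementia_AD"`, `"excluded_etiology"`, `"other"`).
#' @param mmse integer MMSE scores 0-30 (NA allowed).
#' @return character vector over `{"MCI","mild","moderate","severe",
#'   "ineligible", NA}`.
#' @examples
#' assign_stage("dementia_AD", 20) # "mild"
#' assign_stage("dementia_AD", 10) # "severe"
#' assign_stage("MCI", 20) # "ineligible" (strictly above 20 required)
#' @export
assign_stage <- function(diagnosis, mmse) {
  n <- max(length(diagnosis), length(mmse))
  diagnosis <- rep_len(diagnosis, n)
  mmse <- rep_len(mmse, n)
  if (any(!is.na(mmse) & (mmse < 0 | mmse > 30))) {
    stop("MMSE scores must lie in [0, 30]", call. = FALSE)
  }
  out <- rep("ineligible", n)
  staged <- diagnosis %in% c("MCI", "dementia_AD")
  out[staged & is.na(mmse)] <- NA
  mci <- diagnosis == "MCI" & !is.na(mmse)
  out[mci & mmse > 20] <- "MCI"
  dem <- diagnosis == "dementia_AD" & !is.na(mmse)
  out[dem & mmse >= 20 & mmse <= 26] <- "mild"
  out[dem & mmse >= 11 & mmse <= 19] <- "moderate"
  out[dem & mmse < 11] <- "severe"
  out
}

#' Build a stage cohort with right-censored time to conversion
#'
#' For each patient with at least one visit at the transition's entry stage,
#' the index date is the first such visit; the patient converts (event = 1)
#' at the first subsequent visit at a strictly more advanced stage, with
#' TTC = that visit's date minus the index date. Otherwise the patient is
#' censored (event = 0) at the last usable visit, where visits on or after a
#' nursing-home admission or death date are unusable. A later return to a
#' less advanced stage never undoes a conversion (TTC is a first-passage
#' time). Rows with nonpositive follow-up are dropped and counted. Visits
#' whose stage is undetermined (missing MMSE) are skipped and counted.
#'
#' @param registry an `ad_registry` (after [apply_inclusion_exclusion()]).
#' @param transition `"mci_to_dementia"`, `"mild_to_moderate_severe"` or
#'   `"moderate_to_severe"`.
#' @return An object of class `stage_cohort`: a data.frame with
#'   `patient_id`, `index_day`, `time` (days), `event`, `age_at_index`,
#'   `mmse_at_index` and the static covariates; attributes `transition`,
#'   `covariate_spec`, `n_dropped_nonpositive`, `n_undetermined_visits`.
#' @export
build_cohort <- function(registry, transition) {
  stopifnot(inherits(registry, "ad_registry"))
  if (length(transition) != 1L || !transition %in% names(TRANSITION_ENTRY)) {
    stop("'transition' must be one of: ",
      paste(names(TRANSITION_ENTRY), collapse = ", "),
      call. = FALSE
    )
  }
  entry <- TRANSITION_ENTRY[[transition]]
  vis <- registry$visits
  pats <- registry$patients
  stage <- assign_stage(vis$diagnosis, vis$mmse)
  n_undet <- sum(is.na(stage))
  rank <- STAGE_RANK[stage] # NA for ineligible/undetermined
  usable <- !is.na(rank)

  # truncate follow-up at nursing-home admission / death
  if (!is.null(pats$nursing_home_date) || !is.null(pats$death_date)) {
    lim <- pmin(
      if (is.null(pats$nursing_home_date)) Inf else pats$nursing_home_date,
      if (is.null(pats$death_date)) Inf else pats$death_date,
      na.rm = TRUE
    )
    lim[is.na(lim)] <- Inf
    lim_per_visit <- lim[match(vis$patient_id, pats$patient_id)]
    usable <- usable & vis$visit_day < lim_per_visit
  }

  np <- nrow(pats)
  r_pid <- character(np)
  r_index <- r_time <- r_mmse <- numeric(np)
  r_event <- integer(np)
  n_out <- 0L
  n_dropped <- 0L
  ord <- order(vis$patient_id, vis$visit_day)
  vis_pid <- vis$patient_id[ord]
  vis_day <- vis$visit_day[ord]
  vis_rank <- rank[ord]
  vis_mmse <- vis$mmse[ord]
  use <- usable[ord]
  split_idx <- split(seq_along(vis_pid), vis_pid)

  for (pid in pats$patient_id) {
    idx <- split_idx[[pid]]
    idx <- idx[use[idx]]
    if (length(idx) == 0L) next
    rk <- vis_rank[idx]
    dy <- vis_day[idx]
    at_entry <- which(rk == entry)
    if (length(at_entry) == 0L) next
    i0 <- at_entry[1L]
    conv <- which(rk > entry & seq_along(idx) > i0)
    if (length(conv) > 0L) {
      tt <- dy[conv[1L]] - dy[i0]
      ev <- 1L
    } else {
      tt <- dy[length(idx)] - dy[i0]
      ev <- 0L
    }
    if (tt <= 0) {
      n_dropped <- n_dropped + 1L
      next
    }
    n_out <- n_out + 1L
    r_pid[n_out] <- pid
    r_index[n_out] <- dy[i0]
    r_time[n_out] <- tt
    r_event[n_out] <- ev
    r_mmse[n_out] <- vis_mmse[idx][i0]
  }
  keep_rows <- seq_len(n_out)
  core <- data.frame(
    patient_id = r_pid[keep_rows], index_day = r_index[keep_rows],
    time = r_time[keep_rows], event = r_event[keep_rows],
    mmse_at_index = r_mmse[keep_rows], stringsAsFactors = FALSE
  )
  m <- match(core$patient_id, pats$patient_id)
  core$age_at_index <- pats$age_first_visit[m] + core$index_day / 365.25
  cov_cols <- setdiff(
    names(pats),
    c("patient_id", "age_first_visit", "nursing_home_date", "death_date")
  )
  out <- cbind(core, pats[m, cov_cols, drop = FALSE])
  out <- out[order(out$patient_id), , drop = FALSE] # canonical row order
  rownames(out) <- NULL
  attr(out, "transition") <- transition
  attr(out, "covariate_spec") <- cohort_covariate_spec(registry, cov_cols)
  attr(out, "n_dropped_nonpositive") <- n_dropped
  attr(out, "n_undetermined_visits") <- n_undet
  class(out) <- c("stage_cohort", "data.frame")
  out
}

# covariate metadata for encoding: declared spec when the registry carries a
# config, otherwise inferred from column types; age and MMSE at index are
# always appended as continuous.
cohort_covariate_spec <- function(registry, cov_cols) {
  spec <- list()
  if (!is.null(registry$config)) {
    for (cs in registry$config$covariates) {
      if (cs$name %in% cov_cols) spec[[cs$name]] <- cs
    }
  } else {
    for (nm in cov_cols) {
      col <- registry$patients[[nm]]
      kind <- if (is.logical(col)) {
        "binary"
      } else if (is.numeric(col)) "continuous" else "categorical"
      spec[[nm]] <- covariate_spec(nm, kind,
        prevalence = if (kind == "binary") 0.5 else NULL,
        levels = if (kind == "categorical") sort(unique(stats::na.omit(col))) else NULL,
        probs = if (kind == "categorical") {
          rep(1, length(unique(stats::na.omit(col))))
        } else {
          NULL
        },
        mean = if (kind == "continuous") 0 else NULL,
        sd = if (kind == "continuous") 1 else NULL,
        role = "comorbidity"
      )
    }
  }
  spec[["age_at_index"]] <- covariate_spec("age_at_index", "continuous",
    mean = 77, sd = 9, role = "sociodemographic"
  )
  spec[["mmse_at_index"]] <- covariate_spec("mmse_at_index", "continuous",
    mean = 24, sd = 3, role = "cognition"
  )
  spec
}

#' @export
print.stage_cohort <- function(x, ...) {
  cat(sprintf(
    "Stage cohort '%s': %d patients, %d events (%.0f%%)\n",
    attr(x, "transition"), nrow(x), sum(x$event),
    if (nrow(x)) 100 * mean(x$event) else 0
  ))
  invisible(x)
}

#' Write a stage cohort as delimited text
#'
#' @param cohort a `stage_cohort`.
#' @param path output CSV path (empty field = missing).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "stage_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
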