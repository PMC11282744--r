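# Shared fixtures and independent oracles used across the suite.

# Build a minimal registry by hand for pipeline tests.
# visits: list per patient of data.frame(visit_day, diagnosis, mmse)
make_registry <- function(ages, visits, covdf = NULL, nh = NULL, death = NULL) {
  n <- length(ages)
  ids <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(
    patient_id = ids, age_first_visit = ages,
    stringsAsFactors = FALSE
  )
  if (!is.null(covdf)) patients <- cbind(patients, covdf)
  patients$nursing_home_date <- if (is.null(nh)) rep(NA_real_, n) else nh
  patients$death_date <- if (is.null(death)) rep(NA_real_, n) else death
  vis <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(data.frame(patient_id = ids[i], stringsAsFactors = FALSE), visits[[i]])
  }))
  out <- list(patients = patients, visits = vis, truth = NULL, config = NULL)
  class(out) <- "ad_registry"
  out
}

visit_df <- function(days, diagnosis, mmse) {
  data.frame(
    visit_day = days, diagnosis = diagnosis, mmse = mmse,
    stringsAsFactors = FALSE
  )
}

# Build a stage_cohort directly from outcome + covariates (unit-test shortcut
# bypassing the registry machinery).
make_cohort <- function(time, event, covdf, roles = NULL,
                        transition = "mci_to_dementia") {
  df <- data.frame(
    patient_id = sprintf("S%04d", seq_along(time)),
    index_day = rep(0, length(time)), time = time, event = event,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, covdf)
  spec <- lapply(names(covdf), function(nm) {
    col <- covdf[[nm]]
    role <- if (!is.null(roles) && nm %in% names(roles)) roles[[nm]] else "comorbidity"
    if (is.logical(col)) {
      covariate_spec(nm, "binary", prevalence = 0.5, role = role)
    } else if (is.numeric(col)) {
      covariate_spec(nm, "continuous", mean = 0, sd = 1, role = role)
    } else {
      levs <- sort(unique(stats::na.omit(as.character(col))))
      covariate_spec(nm, "categorical",
        levels = levs,
        probs = rep(1, length(levs)), role = role
      )
    }
  })
  names(spec) <- names(covdf)
  attr(df, "transition") <- transition
  attr(df, "covariate_spec") <- spec
  attr(df, "n_dropped_nonpositive") <- 0L
  attr(df, "n_undetermined_visits") <- 0L
  class(df) <- c("stage_cohort", "data.frame")
  df
}

# Random right-censored dataset for cross-checks.
random_surv <- function(n, p_event = 0.7, rate = 1) {
  time <- stats::rexp(n, rate) + 0.01
  event <- stats::rbinom(n, 1, p_event)
  list(time = time, event = event)
}

# --- independent brute-force survival-tree oracle ------------------------
# Recursive exhaustive enumeration using survival::survdiff as the split
# statistic. Mirrors the admissibility rules but shares no code with
# grow_tree. Returns a nested list (feature, threshold, statistic, left,
# right) or NULL for a leaf.
oracle_tree <- function(values, kinds, time, event, depth, max_depth,
                        min_node, min_events) {
  n <- nrow(values)
  if (depth >= max_depth || n < 2 * min_node) {
    return(NULL)
  }
  best <- NULL
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    uv <- sort(unique(v))
    if (length(uv) < 2) next
    if (kinds[j] == "three_state_binary") {
      cand <- c(0.5, 1.5)
      cand <- cand[cand > uv[1] & cand < uv[length(uv)]]
    } else {
      cand <- (uv[-length(uv)] + uv[-1]) / 2
    }
    for (th in cand) {
      left <- v <= th
      if (sum(left) < min_node || sum(!left) < min_node) next
      if (sum(event[left]) < min_events || sum(event[!left]) < min_events) next
      if (sum(event) == 0) next
      sd <- tryCatch(
        survival::survdiff(survival::Surv(time, event) ~ left)$chisq,
        error = function(e) NA_real_
      )
      if (is.na(sd) || sd <= 1e-12) next
      if (is.null(best) || sd > best$statistic + 1e-12) {
        best <- list(feature = j, threshold = th, statistic = sd)
      }
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  left <- values[, best$feature] <= best$threshold
  best$left <- oracle_tree(
    values[left, , drop = FALSE], kinds, time[left], event[left],
    depth + 1, max_depth, min_node, min_events
  )
  best$right <- oracle_tree(
    values[!left, , drop = FALSE], kinds, time[!left], event[!left],
    depth + 1, max_depth, min_node, min_events
  )
  best
}

# Flatten a grown survival_tree into the oracle's nested-list shape for
# structural comparison.
tree_to_nested <- function(tree, id = 1L) {
  nd <- tree$nodes
  if (nd$is_leaf[id]) {
    return(NULL)
  }
  list(
    feature = match(nd$feature[id], colnames_of_tree(tree)),
    threshold = nd$threshold[id],
    statistic = nd$statistic[id],
    left = tree_to_nested(tree, nd$left[id]),
    right = tree_to_nested(tree, nd$right[id])
  )
}

# column order of the encoded matrix the tree was grown on is needed to map
# feature names back to indices; stash it at growth time in tests
colnames_of_tree <- function(tree) attr(tree, "feature_order")

# structural equality of nested split trees (feature, threshold, statistic)
same_tree <- function(a, b, tol = 1e-6) {
  if (is.null(a) && is.null(b)) {
    return(TRUE)
  }
  if (is.null(a) || is.null(b)) {
    return(FALSE)
  }
  a$feature == b$feature &&
    isTRUE(all.equal(a$threshold, b$threshold, tolerance = 1e-9)) &&
    abs(a$statistic - b$statistic) < tol &&
    same_tree(a$left, b$left, tol) && same_tree(a$right, b$right, tol)
}

# hand hypergeometric log-rank tabulation (plain loop over the risk table)
hand_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  g <- rep(c(1, 0), c(length(time_a), length(time_b)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  vsum <- 0
  for (t in ts) {
    at <- time >= t
    n1 <- sum(at & g == 1)
    n0 <- sum(at & g == 0)
    d1 <- sum(time == t & event == 1 & g == 1)
    d0 <- sum(time == t & event == 1 & g == 0)
    d <- d1 + d0
    nn <- n1 + n0
    o_minus_e <- o_minus_e + d1 - d * n1 / nn
    if (nn > 1) vsum <- vsum + d * (n1 / nn) * (n0 / nn) * (nn - d) / (nn - 1)
  }
  o_minus_e^2 / vsum
}
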