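# Ensemble construction, candidate extraction floors, confirmation tests
# and determinism of the full miner.

make_mining_cohort <- function(n = 500, seed = 1, hr_risk = 3, hr_treat = 0.5) {
  set.seed(seed)
  covdf <- data.frame(
    risk = runif(n) < 0.35,
    donepezil = runif(n) < 0.25,
    hypertension = runif(n) < 0.45,
    filler = runif(n) < 0.5
  )
  rate <- 1 / 600 * ifelse(covdf$risk, hr_risk, 1) * ifelse(covdf$donepezil, hr_treat, 1)
  t0 <- rexp(n, rate)
  cens <- runif(n, 400, 2500)
  time <- pmax(pmin(t0, cens), 1)
  event <- as.numeric(t0 <= cens)
  make_cohort(time, event, covdf,
    roles = c(
      risk = "comorbidity", donepezil = "anti_dementia",
      hypertension = "comorbidity", filler = "sociodemographic"
    )
  )
}

test_that("a single full-subset tree reproduces grow_tree + prune_tree", {
  co <- make_mining_cohort(seed = 3)
  enc <- encode_features(co)
  ctrl <- mine_control(n_trees = 1, subset_fraction = 1)
  ens <- run_tree_ensemble(enc, co$time, co$event, ctrl, seed = 9)
  expect_length(ens, 1)
  direct <- grow_tree(enc, co$time, co$event, ctrl$tree)
  direct <- prune_tree(direct, enc, co$time, co$event,
    n_folds = 5, seed = ens[[1]]$seed
  )
  expect_equal(ens[[1]]$nodes, direct$nodes)
})

test_that("ensembles are reproducible and subset sizes follow the ceiling rule", {
  set.seed(19)
  covdf <- as.data.frame(replicate(42, runif(60) < 0.5))
  names(covdf) <- sprintf("v%02d", 1:42)
  enc <- encode_features(covdf)
  time <- rexp(60, 1 / 300) + 1
  event <- rbinom(60, 1, 0.8)
  ctrl <- mine_control(n_trees = 4, subset_fraction = 0.7, tree = tree_control(max_depth = 0))
  e1 <- run_tree_ensemble(enc, time, event, ctrl, seed = 5)
  e2 <- run_tree_ensemble(enc, time, event, ctrl, seed = 5)
  expect_identical(
    lapply(e1, function(t) t$predictors),
    lapply(e2, function(t) t$predictors)
  )
  for (tr in e1) expect_length(tr$predictors, 30) # ceiling(0.7 * 42)
  e3 <- run_tree_ensemble(enc, time, event, ctrl, seed = 6)
  expect_false(identical(
    lapply(e1, function(t) t$predictors),
    lapply(e3, function(t) t$predictors)
  ))
})

test_that("one-hot columns of a categorical travel together in predictor subsets", {
  set.seed(23)
  covdf <- data.frame(
    edu = sample(c("low", "mid", "high"), 80, TRUE),
    b1 = runif(80) < 0.5, b2 = runif(80) < 0.5, b3 = runif(80) < 0.5,
    stringsAsFactors = FALSE
  )
  enc <- encode_features(covdf)
  ctrl <- mine_control(n_trees = 6, subset_fraction = 0.5, tree = tree_control(max_depth = 0))
  ens <- run_tree_ensemble(enc, rexp(80) + 1, rbinom(80, 1, 0.8), ctrl, seed = 2)
  for (tr in ens) {
    expect_length(tr$predictors, 2) # ceiling(0.5 * 4) source variables
    expect_true(all(tr$predictors %in% names(covdf)))
  }
})

test_that("extraction applies the deviation and size floors to every node", {
  co <- make_mining_cohort(n = 600, seed = 7)
  enc <- encode_features(co)
  trees <- run_tree_ensemble(enc, co$time, co$event,
    mine_control(n_trees = 3, subset_fraction = 1, prune = FALSE),
    seed = 4
  )
  cands <- extract_candidates(trees, enc, co$time, co$event,
    deviation_floor = 0.15, size_floor = 0.06
  )
  km <- km_estimate(co$time, co$event)
  ref <- quantile_time(km, 0.5)
  for (s in cands) {
    expect_gte(abs(s$deviation), 0.15)
    expect_gte(s$size_fraction, 0.06)
    expect_equal(s$deviation, (s$ttc_value - ref) / ref, tolerance = 1e-12)
    # every member satisfies every condition of the rule
    for (cn in s$rule) {
      v <- enc$values[s$members, cn$feature]
      if (cn$op == "<=") expect_true(all(v <= cn$threshold))
      if (cn$op == ">") expect_true(all(v > cn$threshold))
    }
  }
  # lowering the deviation floor never removes a candidate
  cands_lo <- extract_candidates(trees, enc, co$time, co$event,
    deviation_floor = 0.05, size_floor = 0.06
  )
  rules_hi <- vapply(cands, `[[`, character(1), "rule_text")
  rules_lo <- vapply(cands_lo, `[[`, character(1), "rule_text")
  expect_true(all(rules_hi %in% rules_lo))
})

test_that("deviation floors match the worked examples", {
  # node median 13 months vs overall 25: |13-25|/25 = 0.48 -> kept (earlier)
  expect_gte(abs((13 - 25) / 25), 0.15)
  # a fast minority leaf is kept while a leaf hugging the overall median is
  # rejected: 30 early converters (~day 115) vs 50 late (~day 1025)
  time <- c(100 + seq_len(30), 1000 + seq_len(50))
  event <- rep(1, 80)
  covdf <- data.frame(g = rep(c(TRUE, FALSE), c(30, 50)))
  enc <- encode_features(covdf)
  tr <- grow_tree(enc, time, event, tree_control(max_depth = 1, min_node_size = 10))
  km_all <- km_estimate(time, event)
  ref <- quantile_time(km_all, 0.5) # lands inside the slow group
  cands <- extract_candidates(list(tr), enc, time, event,
    deviation_floor = 0.15, size_floor = 0.06
  )
  expect_length(cands, 1) # slow leaf deviates < 15% from the reference
  expect_equal(cands[[1]]$direction, "earlier")
  expect_gte(abs((cands[[1]]$ttc_value - ref) / ref), 0.15)
  cands_sz <- extract_candidates(list(tr), enc, time, event,
    deviation_floor = 0.15, size_floor = 0.75
  )
  expect_length(cands_sz, 0) # size floor excludes every leaf
})

test_that("confirmation fills the log-rank test and triggers Cox only for treatment rules", {
  co <- make_mining_cohort(n = 700, seed = 13)
  enc <- encode_features(co)
  trees <- run_tree_ensemble(enc, co$time, co$event,
    mine_control(n_trees = 5, subset_fraction = 1, prune = FALSE),
    seed = 8
  )
  cands <- extract_candidates(trees, enc, co$time, co$event, 0.15, 0.06)
  expect_gt(length(cands), 0)
  for (s in cands) {
    cf <- confirm_subgroup(co, s, enc)
    expect_true(is.finite(cf$logrank_p))
    has_treat <- grepl("donepezil", cf$rule_text)
    expect_equal(!is.null(cf$cox_adjusted), has_treat)
    if (has_treat) {
      expect_gt(cf$cox_adjusted$hazard_ratio, 0)
    }
  }
  bad <- cands[[1]]
  bad$members <- seq_len(nrow(co))
  expect_error(confirm_subgroup(co, bad, enc), "proper subset")
})

test_that("comorbidity counts sum the TRUE comorbidity flags only", {
  covdf <- data.frame(
    hypertension = c(TRUE, FALSE, NA),
    diabetes = c(TRUE, TRUE, FALSE),
    donepezil = c(TRUE, TRUE, TRUE)
  )
  co <- make_cohort(c(100, 200, 300), c(1, 1, 0), covdf,
    roles = c(
      hypertension = "comorbidity", diabetes = "comorbidity",
      donepezil = "anti_dementia"
    )
  )
  expect_equal(unname(comorbidity_count(co)), c(2, 1, 0))
})

test_that("mine is deterministic and a full size floor empties the result", {
  co <- make_mining_cohort(n = 450, seed = 29)
  ctrl <- mine_control(n_trees = 4, tree = tree_control(max_depth = 3))
  s1 <- mine(co, control = ctrl, seed = 77)
  s2 <- mine(co, control = ctrl, seed = 77)
  expect_identical(s1$summary, s2$summary)
  # duplicates were merged: member sets are unique
  keys <- vapply(s1$subgroups, function(s) paste(s$members, collapse = ","), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  s3 <- mine(co, control = mine_control(n_trees = 2, size_floor = 1), seed = 77)
  expect_equal(nrow(s3$summary), 0)
})

test_that("null cohorts rarely yield significant confirmed subgroups", {
  set.seed(37)
  reps <- 12
  clean <- 0
  for (r in seq_len(reps)) {
    n <- 700
    covdf <- data.frame(
      a = runif(n) < 0.4, b = runif(n) < 0.5, c = runif(n) < 0.3,
      d = runif(n) < 0.5, e = runif(n) < 0.2
    )
    t0 <- rexp(n, 1 / 600)
    cens <- runif(n, 300, 2200)
    co <- make_cohort(pmax(pmin(t0, cens), 1), as.numeric(t0 <= cens), covdf)
    sgs <- mine(co,
      control = mine_control(n_trees = 6, tree = tree_control(max_depth = 4)),
      seed = 37 + r
    )
    sig <- sum(sgs$summary$logrank_p < 0.05)
    if (length(sig) == 0 || isTRUE(sig == 0)) clean <- clean + 1
  }
  expect_gte(clean / reps, 0.8)
})

test_that("an over-censored cohort raises the dedicated error", {
  covdf <- data.frame(a = rep(c(TRUE, FALSE), 25))
  co <- make_cohort(rep(1000, 50), rep(0, 50), covdf)
  enc <- encode_features(co)
  tr <- grow_tree(enc, co$time, co$event, tree_control(max_depth = 0))
  expect_error(
    extract_candidates(list(tr), enc, co$time, co$event),
    "too censored"
  )
})
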