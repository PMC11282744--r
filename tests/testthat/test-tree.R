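# Survival-tree growth and pruning: oracle equivalence against exhaustive
# enumeration, determinism, and overfitting control.

test_that("a perfectly separating binary feature wins the root split", {
  set.seed(55)
  n <- 40
  sep <- rep(c(TRUE, FALSE), each = n / 2)
  covdf <- data.frame(
    sep = sep,
    noise1 = sample(c(TRUE, FALSE), n, TRUE),
    noise2 = sample(c(TRUE, FALSE), n, TRUE)
  )
  time <- ifelse(sep, rnorm(n, 100, 5), rnorm(n, 1000, 5))
  event <- rep(1, n)
  enc <- encode_features(covdf)
  sp <- best_split(seq_len(n), enc, time, event,
    min_child_size = 5, min_child_events = 3
  )
  expect_equal(sp$feature, "sep")
})

test_that("constant features admit no split", {
  enc <- encode_features(data.frame(a = rep(TRUE, 30), b = rep(FALSE, 30)))
  sp <- best_split(seq_len(30), enc, rexp(30) + 1, rep(1, 30), 5, 2)
  expect_null(sp)
  tr <- grow_tree(enc, rexp(30) + 1, rep(1, 30), tree_control(min_node_size = 5))
  expect_equal(nrow(tr$nodes), 1)
})

test_that("grow_tree equals exhaustive enumeration on small datasets", {
  skip_if_not_installed("survival")
  set.seed(66)
  for (r in 1:12) {
    n <- sample(15:30, 1)
    covdf <- data.frame(
      f1 = sample(c(TRUE, FALSE, NA), n, TRUE, prob = c(.4, .4, .2)),
      f2 = sample(c(TRUE, FALSE), n, TRUE),
      f3 = round(runif(n, 0, 10))
    )
    time <- round(rexp(n, 1 / 50)) + 1
    event <- rbinom(n, 1, 0.75)
    enc <- encode_features(covdf)
    ctrl <- tree_control(max_depth = 3, min_node_size = 3, min_child_events = 2)
    tr <- grow_tree(enc, time, event, ctrl)
    attr(tr, "feature_order") <- colnames(enc$values)
    ora <- oracle_tree(
      enc$values, enc$feature_meta$kind, time, event,
      depth = 0, max_depth = 3, min_node = 3, min_events = 2
    )
    expect_true(same_tree(tree_to_nested(tr), ora, tol = 1e-6))
  }
})

test_that("the chosen split statistic dominates every admissible alternative", {
  set.seed(77)
  n <- 120
  covdf <- data.frame(
    a = sample(c(TRUE, FALSE), n, TRUE),
    b = sample(c(TRUE, FALSE, NA), n, TRUE),
    c = round(runif(n, 0, 5))
  )
  time <- rexp(n, 1 / 300) + 1
  event <- rbinom(n, 1, 0.7)
  enc <- encode_features(covdf)
  sp <- best_split(seq_len(n), enc, time, event, 10, 3)
  for (j in seq_len(ncol(enc$values))) {
    for (th in split_thresholds(enc, colnames(enc$values)[j])) {
      left <- enc$values[, j] <= th
      if (sum(left) < 10 || sum(!left) < 10) next
      if (sum(event[left]) < 3 || sum(event[!left]) < 3) next
      alt <- logrank_test(time[left], event[left], time[!left], event[!left])
      expect_lte(alt$statistic, sp$statistic + 1e-9)
    }
  }
})

test_that("a depth-0 tree is a single leaf carrying the cohort KM quantiles", {
  set.seed(88)
  time <- rexp(100, 1 / 400) + 1
  event <- rbinom(100, 1, 0.8)
  enc <- encode_features(data.frame(x = sample(c(TRUE, FALSE), 100, TRUE)))
  tr <- grow_tree(enc, time, event, tree_control(max_depth = 0))
  expect_equal(nrow(tr$nodes), 1)
  km <- km_estimate(time, event)
  expect_equal(tr$nodes$median, quantile_time(km, 0.5))
  expect_equal(tr$nodes$q3, quantile_time(km, 0.25))
})

test_that("tree growth is deterministic and children partition their parent", {
  set.seed(99)
  n <- 300
  covdf <- data.frame(
    a = sample(c(TRUE, FALSE), n, TRUE),
    b = sample(c(TRUE, FALSE), n, TRUE),
    c = round(runif(n, 0, 8))
  )
  time <- rexp(n, 1 / 300 * ifelse(covdf$a, 2, 1)) + 1
  event <- rbinom(n, 1, 0.8)
  enc <- encode_features(covdf)
  t1 <- grow_tree(enc, time, event, tree_control(min_node_size = 20))
  t2 <- grow_tree(enc, time, event, tree_control(min_node_size = 20))
  expect_identical(t1$nodes, t2$nodes)
  nd <- t1$nodes
  for (id in nd$id[!nd$is_leaf]) {
    expect_setequal(
      c(t1$members[[nd$left[id]]], t1$members[[nd$right[id]]]),
      t1$members[[id]]
    )
    expect_equal(nd$n[nd$left[id]] + nd$n[nd$right[id]], nd$n[id])
    expect_gte(nd$n[nd$left[id]], t1$control$min_node_size)
    expect_gte(nd$n[nd$right[id]], t1$control$min_node_size)
  }
  # node KM curves are computed from exactly the node's members
  leaf <- nd$id[nd$is_leaf][1]
  km <- km_estimate(time[t1$members[[leaf]]], event[t1$members[[leaf]]])
  expect_equal(nd$median[leaf], quantile_time(km, 0.5))
})

test_that("a planted binary effect yields a depth-1 tree bracketing the truth", {
  set.seed(111)
  n <- 400
  covdf <- data.frame(
    risk = sample(c(TRUE, FALSE), n, TRUE),
    noise = sample(c(TRUE, FALSE), n, TRUE)
  )
  lam <- 1 / 600
  time <- rexp(n, lam * ifelse(covdf$risk, 3, 1)) + 1
  event <- rep(1, n)
  enc <- encode_features(covdf)
  tr <- grow_tree(enc, time, event, tree_control(max_depth = 1))
  expect_equal(tr$nodes$feature[1], "risk")
  meds <- sort(tr$nodes$median[tr$nodes$is_leaf])
  expect_lt(meds[1], tr$nodes$median[1])
  expect_gt(meds[2], tr$nodes$median[1])
})

test_that("pruning returns a rooted subtree and leaves single leaves alone", {
  set.seed(123)
  n <- 250
  covdf <- data.frame(
    a = sample(c(TRUE, FALSE), n, TRUE),
    b = sample(c(TRUE, FALSE), n, TRUE)
  )
  time <- rexp(n, 1 / 400 * ifelse(covdf$a, 3, 1)) + 1
  event <- rbinom(n, 1, 0.9)
  enc <- encode_features(covdf)
  tr <- grow_tree(enc, time, event, tree_control(max_depth = 4, min_node_size = 15))
  pr <- prune_tree(tr, enc, time, event, seed = 2)
  # every pruned-tree node's member set appears in the full tree
  full_sets <- lapply(tr$members, sort)
  for (m in pr$members) {
    expect_true(any(vapply(full_sets, identical, logical(1), sort(m))))
  }
  expect_lte(nrow(pr$nodes), nrow(tr$nodes))
  # a single-leaf tree passes through unchanged
  leaf_tree <- grow_tree(enc, time, event, tree_control(max_depth = 0))
  pr2 <- prune_tree(leaf_tree, enc, time, event, seed = 2)
  expect_equal(nrow(pr2$nodes), 1)
  expect_error(prune_tree(tr, enc, time, event, n_folds = 1), "at least 2")
})

test_that("pruning controls overfitting on noise and keeps strong signals", {
  set.seed(131)
  n_noise_leaf <- 0
  n_signal_kept <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    n <- 300
    covdf <- as.data.frame(replicate(5, runif(n) < 0.4))
    names(covdf) <- paste0("f", 1:5)
    enc <- encode_features(covdf)
    # pure noise
    t0 <- rexp(n, 1 / 500)
    cens <- runif(n, 200, 1500)
    ev <- as.numeric(t0 <= cens)
    tt <- pmax(pmin(t0, cens), 1)
    tr <- grow_tree(enc, tt, ev, tree_control(max_depth = 4))
    pr <- prune_tree(tr, enc, tt, ev, seed = r)
    if (nrow(pr$nodes) == 1) n_noise_leaf <- n_noise_leaf + 1
    # strong planted effect, HR = 4 on f1
    t1 <- rexp(n, 1 / 800 * ifelse(covdf$f1, 4, 1))
    ev1 <- as.numeric(t1 <= cens)
    tt1 <- pmax(pmin(t1, cens), 1)
    tr1 <- grow_tree(enc, tt1, ev1, tree_control(max_depth = 4))
    pr1 <- prune_tree(tr1, enc, tt1, ev1, seed = r)
    if (any(!pr1$nodes$is_leaf & pr1$nodes$feature == "f1")) {
      n_signal_kept <- n_signal_kept + 1
    }
  }
  expect_gte(n_noise_leaf / reps, 0.8)
  expect_gte(n_signal_kept / reps, 0.95)
})
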