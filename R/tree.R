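# Survival trees: recursive partitioning of right-censored data where the
# quality of a split is the two-sample log-rank statistic between the
# children. Cost-complexity pruning uses the split statistic as the node
# "gain" and selects the complexity penalty by k-fold cross-validation.

#' Survival-tree growth parameters
#'
#' @param max_depth maximum depth (root = 0).
#' @param min_node_size minimum members in any node; default
#'   `max(20, ceiling(0.03 * n))`, resolved when the tree is grown, so
#'   leaves stay estimable while smaller than the 6% subgroup size floor.
#' @param min_child_events minimum observed events in each child of a split.
#' @return a `tree_control` list.
#' @export
tree_control <- function(max_depth = 5L, min_node_size = NULL,
                         min_child_events = 5L) {
  stopifnot(max_depth >= 0, min_child_events >= 0)
  if (!is.null(min_node_size) && min_node_size < 1) {
    stop("'min_node_size' must be at least 1", call. = FALSE)
  }
  structure(
    list(
      max_depth = as.integer(max_depth),
      min_node_size = if (is.null(min_node_size)) NULL else as.integer(min_node_size),
      min_child_events = as.integer(min_child_events)
    ),
    class = "tree_control"
  )
}

#' Best log-rank split of a node
#'
#' Evaluates every feature and every candidate threshold (three-state
#' columns: 0.5 and 1.5; continuous columns: midpoints of consecutive
#' distinct attained values) and returns the admissible split maximizing the
#' two-sample log-rank statistic between the children. Ties are broken
#' toward the lowest feature index, then the lowest threshold, so growth is
#' deterministic.
#'
#' @param rows integer indices of the node's members.
#' @param encoded an `encoded_matrix` covering all rows.
#' @param time,event survival outcome aligned with the encoded rows.
#' @param min_child_size,min_child_events admissibility floors for both
#'   children.
#' @return list(`feature`, `threshold`, `statistic`, `n_left`, `n_right`) or
#'   `NULL` when no admissible split exists or every statistic is zero.
#' @export
best_split <- function(rows, encoded, time, event, min_child_size,
                       min_child_events) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  if (nrow(encoded$values) != length(time)) {
    stop("encoded matrix rows do not match the number of observations",
      call. = FALSE
    )
  }
  t_node <- time[rows]
  e_node <- event[rows]
  best <- NULL
  best_stat <- 0
  for (j in seq_len(ncol(encoded$values))) {
    v <- encoded$values[rows, j]
    uv <- sort(unique(v))
    if (length(uv) < 2L) next
    thr <- if (encoded$feature_meta$kind[j] == "three_state_binary") {
      # only 0.5 / 1.5 are legal; keep those separating the attained codes
      c(0.5, 1.5)[c(0.5, 1.5) > uv[1] & c(0.5, 1.5) < uv[length(uv)]]
    } else {
      (uv[-length(uv)] + uv[-1]) / 2
    }
    for (th in thr) {
      left <- v <= th
      nl <- sum(left)
      nr <- length(left) - nl
      if (nl < min_child_size || nr < min_child_size) next
      if (sum(e_node[left]) < min_child_events ||
        sum(e_node[!left]) < min_child_events) {
        next
      }
      s <- lr_stat(t_node, e_node, left)
      if (s > best_stat + 1e-12) {
        best_stat <- s
        best <- list(
          feature = encoded$feature_meta$feature[j], threshold = th,
          statistic = s, n_left = nl, n_right = nr
        )
      }
    }
  }
  best
}

#' Grow a survival tree
#'
#' Recursive binary splitting with [best_split()] until no admissible split
#' remains, `max_depth` is reached, or a node is too small to split. Every
#' node stores its member set, Kaplan-Meier curve summaries (median and Q3 =
#' 25%-converted time) and, for internal nodes, the split condition and its
#' log-rank statistic. Growth is fully deterministic given its inputs.
#'
#' @param encoded an `encoded_matrix`.
#' @param time,event right-censored outcome (days, 0/1).
#' @param control a [tree_control()].
#' @param rows optional subset of rows to grow on (used by pruning folds);
#'   default all rows.
#' @return An object of class `survival_tree`: list with `nodes`
#'   (data.frame: id, parent, depth, is_leaf, feature, threshold, statistic,
#'   left, right, n, n_events, median, q3), `members` (list of row-index
#'   vectors per node id), `control` (with `min_node_size` resolved),
#'   `n` and `pruning` metadata (NULL until pruned).
#' @export
grow_tree <- function(encoded, time, event, control = tree_control(),
                      rows = NULL) {
  stopifnot(inherits(encoded, "encoded_matrix"), inherits(control, "tree_control"))
  check_surv_input(time, event)
  if (is.null(rows)) rows <- seq_along(time)
  n <- length(rows)
  ctrl <- control
  if (is.null(ctrl$min_node_size)) {
    ctrl$min_node_size <- max(20L, ceiling(0.03 * n))
  }

  nodes <- list()
  members <- list()
  new_node <- function(parent, depth, idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(
      id = id, parent = parent, depth = depth, is_leaf = TRUE,
      feature = NA_character_, threshold = NA_real_, statistic = NA_real_,
      left = NA_integer_, right = NA_integer_,
      n = length(idx), n_events = sum(event[idx])
    )
    members[[id]] <<- idx
    id
  }
  root <- new_node(NA_integer_, 0L, rows)
  queue <- root
  while (length(queue)) {
    id <- queue[[1L]]
    queue <- queue[-1L]
    nd <- nodes[[id]]
    idx <- members[[id]]
    if (nd$depth >= ctrl$max_depth) next
    if (length(idx) < 2L * ctrl$min_node_size) next
    sp <- best_split(
      idx, encoded, time, event,
      ctrl$min_node_size, ctrl$min_child_events
    )
    if (is.null(sp)) next
    v <- encoded$values[idx, sp$feature]
    left_idx <- idx[v <= sp$threshold]
    right_idx <- idx[v > sp$threshold]
    lid <- new_node(id, nd$depth + 1L, left_idx)
    rid <- new_node(id, nd$depth + 1L, right_idx)
    nodes[[id]]$is_leaf <- FALSE
    nodes[[id]]$feature <- sp$feature
    nodes[[id]]$threshold <- sp$threshold
    nodes[[id]]$statistic <- sp$statistic
    nodes[[id]]$left <- lid
    nodes[[id]]$right <- rid
    queue <- c(queue, lid, rid)
  }
  ndf <- do.call(rbind, lapply(nodes, function(x) {
    data.frame(x, stringsAsFactors = FALSE)
  }))
  rownames(ndf) <- NULL
  # per-node KM quantiles: median and the 25%-converted ("Q3") time
  ndf$median <- NA_real_
  ndf$q3 <- NA_real_
  for (id in ndf$id) {
    km <- km_estimate(time[members[[id]]], event[members[[id]]])
    ndf$median[id] <- quantile_time(km, 0.5)
    ndf$q3[id] <- quantile_time(km, 0.25)
  }
  out <- list(
    nodes = ndf, members = members, control = ctrl, n = n, pruning = NULL
  )
  class(out) <- "survival_tree"
  out
}

#' @export
print.survival_tree <- function(x, ...) {
  cat(sprintf(
    "Survival tree: %d nodes (%d leaves), n = %d%s\n",
    nrow(x$nodes), sum(x$nodes$is_leaf), x$n,
    if (is.null(x$pruning)) "" else sprintf(", pruned at alpha = %.3g", x$pruning$alpha)
  ))
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Render a survival tree as indented text
#' @param tree a `survival_tree`.
#' @return character vector, one line per node.
#' @export
format_tree <- function(tree) {
  nd <- tree$nodes
  lines <- character(0)
  walk <- function(id, prefix) {
    r <- nd[id, ]
    desc <- sprintf(
      "n=%d events=%d median=%s q3=%s", r$n, r$n_events,
      if (is.na(r$median)) "NR" else format(r$median),
      if (is.na(r$q3)) "NR" else format(r$q3)
    )
    if (r$is_leaf) {
      lines <<- c(lines, paste0(prefix, "* leaf ", desc))
    } else {
      lines <<- c(lines, sprintf(
        "%s+ %s <= %g (logrank %.2f) %s",
        prefix, r$feature, r$threshold, r$statistic, desc
      ))
      walk(r$left, paste0(prefix, "  "))
      walk(r$right, paste0(prefix, "  "))
    }
  }
  walk(1L, "")
  lines
}

# ---- pruning ------------------------------------------------------------

# Weakest-link sequence on the split-statistic gain. Returns steps of
# nondecreasing alpha; step j carries the cumulative set of internal nodes
# collapsed to leaves. alpha of the full tree is 0.
weakest_link_sequence <- function(tree) {
  nd <- tree$nodes
  collapsed <- logical(nrow(nd))
  steps <- list(list(alpha = 0, collapsed = integer(0)))
  repeat {
    act <- nd$id[!nd$is_leaf & !collapsed]
    act <- act[!vapply(act, function(i) has_collapsed_ancestor(i, nd, collapsed), logical(1))]
    if (length(act) == 0L) break
    gs <- vapply(act, function(i) {
      s <- subtree_internal_stats(i, nd, collapsed)
      sum(s) / length(s)
    }, numeric(1))
    a <- min(gs)
    collapsed[act[gs <= a + 1e-12]] <- TRUE
    prev <- steps[[length(steps)]]$collapsed
    steps[[length(steps) + 1L]] <- list(
      alpha = a,
      collapsed = sort(unique(c(prev, act[gs <= a + 1e-12])))
    )
  }
  steps
}

has_collapsed_ancestor <- function(id, nd, collapsed) {
  p <- nd$parent[id]
  while (!is.na(p)) {
    if (collapsed[p]) return(TRUE)
    p <- nd$parent[p]
  }
  FALSE
}

is_collapsed_under <- function(id, nd, collapsed) {
  collapsed[id] || has_collapsed_ancestor(id, nd, collapsed)
}

# split statistics of internal nodes in the active subtree rooted at id
subtree_internal_stats <- function(id, nd, collapsed) {
  if (nd$is_leaf[id] || collapsed[id]) return(numeric(0))
  c(
    nd$statistic[id],
    subtree_internal_stats(nd$left[id], nd, collapsed),
    subtree_internal_stats(nd$right[id], nd, collapsed)
  )
}

# collapse the given internal nodes to leaves and drop their descendants
apply_collapse <- function(tree, collapse_ids) {
  if (length(collapse_ids) == 0L) return(tree)
  nd <- tree$nodes
  orig <- nd # descendant marking must use the pre-collapse structure
  drop <- logical(nrow(nd))
  mark <- function(id) {
    drop[id] <<- TRUE
    if (!orig$is_leaf[id]) {
      mark(orig$left[id])
      mark(orig$right[id])
    }
  }
  for (id in collapse_ids) {
    if (!orig$is_leaf[id]) {
      mark(orig$left[id])
      mark(orig$right[id])
    }
  }
  for (id in setdiff(collapse_ids, which(drop))) {
    nd$is_leaf[id] <- TRUE
    nd$feature[id] <- NA_character_
    nd$threshold[id] <- NA_real_
    nd$statistic[id] <- NA_real_
    nd$left[id] <- NA_integer_
    nd$right[id] <- NA_integer_
  }
  keep <- which(!drop)
  remap <- match(seq_len(nrow(nd)), keep)
  nd <- nd[keep, , drop = FALSE]
  nd$id <- remap[nd$id]
  nd$parent <- remap[nd$parent]
  nd$left <- remap[nd$left]
  nd$right <- remap[nd$right]
  rownames(nd) <- NULL
  tree$nodes <- nd
  tree$members <- tree$members[keep]
  tree
}

# route rows (by index into time/event/encoded) through a tree; returns a
# list of row vectors per node id
route_rows <- function(tree, encoded, rows) {
  nd <- tree$nodes
  reach <- vector("list", nrow(nd))
  assign_node <- function(id, idx) {
    reach[[id]] <<- idx
    if (!nd$is_leaf[id] && length(idx)) {
      v <- encoded$values[idx, nd$feature[id]]
      assign_node(nd$left[id], idx[v <= nd$threshold[id]])
      assign_node(nd$right[id], idx[v > nd$threshold[id]])
    } else if (!nd$is_leaf[id]) {
      assign_node(nd$left[id], integer(0))
      assign_node(nd$right[id], integer(0))
    }
  }
  assign_node(1L, rows)
  reach
}

#' Prune a survival tree by cross-validated cost complexity
#'
#' Weakest-link pruning where a node's gain is its split log-rank statistic:
#' collapsing order is by the smallest per-split average gain, yielding a
#' nested subtree sequence indexed by the complexity penalty alpha. The
#' penalty is chosen by k-fold cross-validation: a fold tree is grown on the
#' training portion, and a candidate subtree is scored by the sum over its
#' retained splits of the held-out log-rank statistic minus the chi-square(1)
#' 0.95 quantile — a split must carry an out-of-fold statistic beyond 3.84
#' to pay for itself, so pure-noise splits are discarded. If no candidate
#' scores above zero the tree collapses to its root. The result is always a
#' rooted subtree of the input.
#'
#' @param tree a grown `survival_tree`.
#' @param encoded,time,event the data the tree was grown on.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param penalty per-split held-out penalty (default
#'   `qchisq(0.95, 1)`).
#' @return the pruned `survival_tree`, with `$pruning` recording the chosen
#'   alpha and the cross-validation table.
#' @export
prune_tree <- function(tree, encoded, time, event, n_folds = 5L, seed = 1L,
                       penalty = stats::qchisq(0.95, 1)) {
  stopifnot(inherits(tree, "survival_tree"))
  if (n_folds < 2L) stop("'n_folds' must be at least 2", call. = FALSE)
  if (sum(!tree$nodes$is_leaf) == 0L) {
    tree$pruning <- list(alpha = 0, cv = NULL)
    return(tree)
  }
  rows_all <- tree$members[[1L]]
  steps <- weakest_link_sequence(tree)
  alphas <- vapply(steps, `[[`, numeric(1), "alpha")
  # candidate penalties between consecutive subtree breakpoints
  cand <- c((alphas[-length(alphas)] + alphas[-1]) / 2, alphas[length(alphas)] + 1)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(rows_all)))
  scores <- matrix(0, n_folds, length(cand))
  for (f in seq_len(n_folds)) {
    train <- rows_all[fold != f]
    val <- rows_all[fold == f]
    if (sum(event[train]) == 0L || length(val) == 0L) next
    ft <- grow_tree(encoded, time, event, control = tree$control, rows = train)
    if (sum(!ft$nodes$is_leaf) == 0L) next
    fsteps <- weakest_link_sequence(ft)
    falphas <- vapply(fsteps, `[[`, numeric(1), "alpha")
    reach <- route_rows(ft, encoded, val)
    internal <- ft$nodes$id[!ft$nodes$is_leaf]
    val_stat <- vapply(internal, function(id) {
      idx <- reach[[id]]
      if (length(idx) < 2L || sum(event[idx]) == 0L) return(0)
      v <- encoded$values[idx, ft$nodes$feature[id]]
      lr_stat(time[idx], event[idx], v <= ft$nodes$threshold[id])
    }, numeric(1))
    names(val_stat) <- internal
    for (ci in seq_along(cand)) {
      j <- max(which(falphas <= cand[ci]))
      coll <- fsteps[[j]]$collapsed
      active <- internal[!vapply(internal, function(i) {
        is_collapsed_under_set(i, ft$nodes, coll)
      }, logical(1))]
      scores[f, ci] <- sum(val_stat[as.character(active)] - penalty)
    }
  }
  avg <- colMeans(scores)
  best <- if (all(avg <= 0)) length(cand) else which(avg == max(avg))
  alpha_star <- cand[max(best)] # ties -> larger penalty, simpler tree
  if (all(avg <= 0)) alpha_star <- Inf
  j <- max(which(alphas <= alpha_star))
  out <- apply_collapse(tree, steps[[j]]$collapsed)
  if (is.infinite(alpha_star)) out <- apply_collapse(out, 1L)
  out$pruning <- list(
    alpha = alpha_star,
    cv = data.frame(alpha = cand, mean_score = avg)
  )
  out
}

is_collapsed_under_set <- function(id, nd, collapsed_ids) {
  if (id %in% collapsed_ids) return(TRUE)
  p <- nd$parent[id]
  while (!is.na(p)) {
    if (p %in% collapsed_ids) return(TRUE)
    p <- nd$parent[p]
  }
  FALSE
}

#' Serialize a survival tree to JSON
#' @param tree a `survival_tree`; @param path output path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "survival_tree"))
  jsonlite::write_json(
    list(
      nodes = tree$nodes,
      control = unclass(tree$control),
      n = tree$n,
      pruning = if (is.null(tree$pruning)) NULL else list(alpha = tree$pruning$alpha)
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
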