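#' Repeated stratified k-fold assignments
#'
#' Within each class, units are shuffled and dealt round-robin into folds,
#' so every fold preserves the class ratio within one unit.  Deterministic
#' given `seed`.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param n_folds Number of folds, default 5.
#' @param n_repeats Number of repeated partitions, default 10.
#' @param seed Integer seed.
#' @return List of length `n_repeats`; each element an integer fold-id
#'   vector parallel to `labels`.
#' @export
stratified_repeated_cv <- function(labels, n_folds = 5, n_repeats = 10,
                                   seed = 1) {
  labels <- factor(labels)
  if (n_folds < 2L) stop("`n_folds` must be >= 2", call. = FALSE)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1", call. = FALSE)
  cnt <- table(labels)
  if (nlevels(labels) < 2L)
    stop("stratification needs at least two classes", call. = FALSE)
  if (any(cnt < n_folds))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 names(cnt)[which.min(cnt)], min(cnt), n_folds),
         call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Fit a pruned binary classification tree
#'
#' CART-style binary tree with Gini impurity, grown deep (`cp = 0`) and then
#' cost-complexity pruned at the complexity value minimizing the inner
#' cross-validated error (rpart's built-in `xval` inner CV; ties resolved
#' toward the smaller tree).  Missing feature values are routed to the
#' majority child (no surrogate splits).  Constant features are never
#' selected because they cannot improve the impurity.
#'
#' @param x Data frame of numeric features.
#' @param y Binary factor of labels; the second level is treated as the
#'   positive class.
#' @param max_depth Maximum tree depth, default 3.
#' @param min_leaf Minimum observations per leaf, default 3.
#' @param inner_folds Inner CV folds for pruning, default 3.
#' @param se_factor Pruning strength: 0 (default) picks the complexity with
#'   the minimum inner-CV error; 1 applies the one-standard-error rule
#'   (smallest tree within one SE of the minimum), pruning harder.
#' @param min_cp Floor on the selected complexity parameter: splits whose
#'   relative impurity improvement falls below this are always pruned,
#'   whatever the inner CV prefers (default 0).
#' @return A `dualpet_tree`: list with the `rpart` fit, the flattened
#'   `structure` table used for prediction/SHAP, `levels` and `positive`.
#' @export
fit_tree <- function(x, y, max_depth = 3, min_leaf = 3, inner_folds = 3,
                     se_factor = 0, min_cp = 0) {
  stopifnot(is.data.frame(x))
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("`y` must have exactly two classes", call. = FALSE)
  # bracket-notation names are not syntactic; rename for the formula
  # interface and map back afterwards
  safe <- paste0("V", seq_along(x))
  name_map <- stats::setNames(colnames(x), safe)
  dat <- x
  colnames(dat) <- safe
  dat$.y <- y
  fit <- rpart::rpart(
    .y ~ ., data = dat, method = "class", parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf, cp = 0,
                                   xval = inner_folds,
                                   usesurrogate = 2, maxsurrogate = 0))
  cp_tab <- fit$cptable
  if (!is.null(cp_tab) && nrow(cp_tab) > 1 && "xerror" %in% colnames(cp_tab)) {
    imin <- which.min(cp_tab[, "xerror"])
    thr <- cp_tab[imin, "xerror"] + se_factor * cp_tab[imin, "xstd"]
    best <- which(cp_tab[, "xerror"] <= thr)[1]   # smallest qualifying tree
    fit <- rpart::prune(fit, cp = max(cp_tab[best, "CP"], min_cp))
  } else if (min_cp > 0) {
    fit <- rpart::prune(fit, cp = min_cp)
  }
  st <- tree_structure(fit)
  hit <- !is.na(st$var)
  st$var[hit] <- unname(name_map[st$var[hit]])
  structure(list(rpart = fit,
                 structure = st,
                 levels = levels(y), positive = levels(y)[2],
                 features = colnames(x)),
            class = "dualpet_tree")
}

# Flatten an rpart classification tree into a node table:
# one row per node with split variable/threshold, children row indices,
# training cover n, probability of the positive (second) class, and the
# majority child used to route missing values.
tree_structure <- function(fit) {
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  nlev <- length(attr(fit, "ylevels"))
  stopifnot(nlev == 2L)
  prob_pos <- fr$yval2[, 1 + nlev + 2]   # P(second class) at each node
  out <- data.frame(node = nodes, is_leaf = fr$var == "<leaf>",
                    var = NA_character_, threshold = NA_real_,
                    left_lt = NA, left = NA_integer_, right = NA_integer_,
                    majority_left = NA, n = fr$n, prob = prob_pos,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$splits) && any(!out$is_leaf)) {
    j <- 1L
    for (i in seq_len(nrow(fr))) {
      if (out$is_leaf[i]) next
      sp <- fit$splits[j, ]
      if (abs(sp[["ncat"]]) != 1)
        stop("categorical splits are not supported", call. = FALSE)
      out$var[i] <- rownames(fit$splits)[j]
      out$threshold[i] <- sp[["index"]]
      out$left_lt[i] <- sp[["ncat"]] == -1   # TRUE: x < threshold goes left
      out$left[i] <- match(nodes[i] * 2L, nodes)
      out$right[i] <- match(nodes[i] * 2L + 1L, nodes)
      out$majority_left[i] <- fr$n[out$left[i]] >= fr$n[out$right[i]]
      j <- j + 1L + fr$ncompete[i] + fr$nsurrogate[i]
    }
  }
  out
}

# Route one observation through a split: TRUE = go left.
split_goes_left <- function(st, i, value) {
  if (is.na(value)) return(st$majority_left[i])
  if (st$left_lt[i]) value < st$threshold[i] else value >= st$threshold[i]
}

#' Predicted positive-class probability of a fitted tree
#'
#' Traverses the package's own node table (missing values routed to the
#' majority child), so predictions are exactly consistent with
#' [tree_shap()] attributions.
#'
#' @param tree A `dualpet_tree`.
#' @param newdata Data frame of feature values.
#' @return Numeric vector of positive-class probabilities.
#' @export
tree_predict <- function(tree, newdata) {
  st <- tree$structure
  vapply(seq_len(nrow(newdata)), function(r) {
    i <- 1L
    while (!st$is_leaf[i]) {
      v <- newdata[[st$var[i]]][r]
      i <- if (split_goes_left(st, i, v)) st$left[i] else st$right[i]
    }
    st$prob[i]
  }, numeric(1))
}

# Path-dependent conditional expectation of the tree output given the
# features in `S` take the sample's values: splits on features outside S
# are averaged over with training-cover weights.
tree_expectation <- function(st, x_row, in_S) {
  rec <- function(i) {
    if (st$is_leaf[i]) return(st$prob[i])
    v <- st$var[i]
    if (!is.null(in_S[[v]]) && in_S[[v]]) {
      if (split_goes_left(st, i, x_row[[v]])) rec(st$left[i]) else rec(st$right[i])
    } else {
      (st$n[st$left[i]] * rec(st$left[i]) +
         st$n[st$right[i]] * rec(st$right[i])) / st$n[i]
    }
  }
  rec(1L)
}

#' Exact SHAP attributions for a single decision tree
#'
#' Shapley values of the tree's predicted positive-class probability under
#' the path-dependent value function: the payoff of a feature coalition S is
#' the tree traversal in which splits on features in S follow the sample and
#' splits on the remaining features average both children with training
#' cover weights.  The Shapley sum is taken over the features actually used
#' by the tree (unused features are null players and receive exactly zero),
#' which keeps the enumeration exact and small.  Local accuracy holds by
#' construction: `base_value + sum(shap) == tree_predict()` for every
#' sample.
#'
#' @param tree A `dualpet_tree`.
#' @param newdata Data frame of samples to explain.
#' @return Numeric matrix (samples x all model features) with attribute
#'   `base_value` (the cover-weighted mean leaf probability).
#' @export
tree_shap <- function(tree, newdata) {
  st <- tree$structure
  missing_feats <- setdiff(stats::na.omit(unique(st$var)), colnames(newdata))
  if (length(missing_feats))
    stop(sprintf("newdata lacks feature(s): %s",
                 paste(missing_feats, collapse = ", ")), call. = FALSE)
  used <- unique(st$var[!st$is_leaf])
  p <- length(used)
  if (p > 15L)
    stop("exact enumeration supported for trees using <= 15 features",
         call. = FALSE)
  phi <- matrix(0, nrow(newdata), length(tree$features),
                dimnames = list(NULL, tree$features))
  base <- tree_expectation(st, NULL, stats::setNames(list(), character(0)))
  if (p == 0L) {
    attr(phi, "base_value") <- base
    return(phi)
  }
  n_masks <- bitwShiftL(1L, p)
  fact <- factorial(0:p)
  for (r in seq_len(nrow(newdata))) {
    x_row <- lapply(newdata[r, used, drop = FALSE], identity)
    names(x_row) <- used
    # v(S) for every coalition mask over the used features
    v <- numeric(n_masks)
    for (mask in 0:(n_masks - 1L)) {
      in_S <- as.list(bitwAnd(bitwShiftR(mask, 0:(p - 1L)), 1L) == 1L)
      names(in_S) <- used
      v[mask + 1L] <- tree_expectation(st, x_row, in_S)
    }
    sizes <- vapply(0:(n_masks - 1L),
                    function(m) sum(bitwAnd(bitwShiftR(m, 0:(p - 1L)), 1L)),
                    numeric(1))
    for (k in seq_len(p)) {
      bit <- bitwShiftL(1L, k - 1L)
      masks_wo <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L) - 1L
      s <- sizes[masks_wo + 1L]
      w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
      phi[r, used[k]] <- sum(w * (v[bitwOr(masks_wo, bit) + 1L] -
                                    v[masks_wo + 1L]))
    }
  }
  attr(phi, "base_value") <- base
  phi
}

#' Dichotomize survival at a fixed horizon
#'
#' `"short"` when death occurs before the horizon, `"long"` when the unit is
#' observed (dead or alive) at or beyond the horizon, and `NA` (excluded,
#' with the count reported by callers) when censored alive before the
#' horizon.
#'
#' @param os_days Nonnegative follow-up times (days).
#' @param os_event Event indicators (1 = death).
#' @param horizon_days Horizon, default 183 days (6 months).
#' @return Factor with levels `c("long", "short")` (short = positive class),
#'   `NA` for excluded units.
#' @export
survival_to_binary <- function(os_days, os_event, horizon_days = 183) {
  if (any(os_days < 0)) stop("negative survival time", call. = FALSE)
  lab <- ifelse(os_days >= horizon_days, "long",
                ifelse(os_event == 1, "short", NA))
  factor(lab, levels = c("long", "short"))
}

# Rank-based AUROC (probability a positive outranks a negative, ties 0.5).
auroc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  if (!length(sp) || !length(sn)) return(NA_real_)
  cmp <- outer(sp, sn, "-")
  mean((cmp > 0) + 0.5 * (cmp == 0))
}

balanced_accuracy <- function(scores, labels, positive, cutoff = 0.5) {
  pred_pos <- scores >= cutoff
  sens <- mean(pred_pos[labels == positive])
  spec <- mean(!pred_pos[labels != positive])
  (sens + spec) / 2
}

#' Cross-validated tree fitting with validation-fold SHAP
#'
#' Runs repeated stratified k-fold cross-validation: per fold, a pruned tree
#' is fit on the training split and exact SHAP attributions are computed for
#' the held-out validation samples, together with fold performance (AUROC
#' and balanced accuracy).  Deterministic given `seed`.
#'
#' @param x Data frame of numeric features.
#' @param y Binary factor; second level = positive class.
#' @param n_folds,n_repeats CV layout, default 5 x 10.
#' @param seed Integer seed.
#' @param max_depth,min_leaf,inner_folds Passed to [fit_tree()].
#' @return A `cv_shap` list: `folds` (each with `shap`, `x_val`, `idx`,
#'   `auroc`, `balanced_accuracy`, `base_value`), `features`, `positive`.
#' @export
run_cv_shap <- function(x, y, n_folds = 5, n_repeats = 10, seed = 1,
                        max_depth = 3, min_leaf = 3, inner_folds = 3) {
  y <- factor(y)
  assign_list <- stratified_repeated_cv(y, n_folds, n_repeats, seed)
  folds <- list()
  for (r in seq_along(assign_list)) {
    fold_id <- assign_list[[r]]
    for (f in seq_len(n_folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      tree <- fit_tree(x[train, , drop = FALSE], y[train],
                       max_depth = max_depth, min_leaf = min_leaf,
                       inner_folds = inner_folds)
      x_val <- x[test, , drop = FALSE]
      shap <- tree_shap(tree, x_val)
      scores <- tree_predict(tree, x_val)
      folds[[length(folds) + 1L]] <- list(
        repeat_id = r, fold = f, idx = test, shap = shap, x_val = x_val,
        scores = scores,
        auroc = auroc(scores, y[test], levels(y)[2]),
        balanced_accuracy = balanced_accuracy(scores, y[test], levels(y)[2]),
        base_value = attr(shap, "base_value"))
    }
  }
  structure(list(folds = folds, features = colnames(x),
                 positive = levels(y)[2]),
            class = "cv_shap")
}

#' Aggregate per-fold SHAP attributions into a stability report
#'
#' Mean absolute SHAP per feature is the mean of `|attribution|` over all
#' validation samples pooled across folds and repeats.  Each fold votes a
#' direction per feature: the sign of the within-fold Pearson correlation
#' between feature value and attribution (folds where either is constant
#' abstain).  `sign_agreement` is the fraction of voting folds matching the
#' modal direction; features with agreement >= 0.80 are flagged stable.
#'
#' @param cv A `cv_shap` object from [run_cv_shap()].
#' @return An `attribution_report`: list with `features` (data frame:
#'   `feature`, `mean_abs_shap`, `rank`, `direction`, `sign_agreement`,
#'   `n_votes`, `stable`) and `performance` (per-fold AUROC / balanced
#'   accuracy).
#' @export
aggregate_attributions <- function(cv) {
  stopifnot(inherits(cv, "cv_shap"))
  feats <- cv$features
  abs_sum <- stats::setNames(numeric(length(feats)), feats)
  n_samp <- 0L
  votes <- matrix(NA_real_, length(cv$folds), length(feats),
                  dimnames = list(NULL, feats))
  for (k in seq_along(cv$folds)) {
    fd <- cv$folds[[k]]
    abs_sum <- abs_sum + colSums(abs(fd$shap))
    n_samp <- n_samp + nrow(fd$shap)
    for (f in feats) {
      xv <- fd$x_val[[f]]; sv <- fd$shap[, f]
      ok <- !is.na(xv)
      if (sum(ok) >= 2 && stats::sd(xv[ok]) > 0 && stats::sd(sv[ok]) > 0) {
        cc <- stats::cor(xv[ok], sv[ok])
        if (!is.na(cc) && cc != 0) votes[k, f] <- sign(cc)
      }
    }
  }
  mean_abs <- abs_sum / n_samp
  direction <- rep(NA_real_, length(feats))
  agreement <- rep(NA_real_, length(feats))
  n_votes <- integer(length(feats))
  for (j in seq_along(feats)) {
    v <- votes[, j]
    v <- v[!is.na(v)]
    n_votes[j] <- length(v)
    if (length(v)) {
      direction[j] <- if (sum(v > 0) >= sum(v < 0)) 1 else -1
      agreement[j] <- mean(v == direction[j])
    }
  }
  ord <- order(-mean_abs)
  rank <- integer(length(feats)); rank[ord] <- seq_along(feats)
  perf <- data.frame(
    repeat_id = vapply(cv$folds, `[[`, numeric(1), "repeat_id"),
    fold = vapply(cv$folds, `[[`, numeric(1), "fold"),
    auroc = vapply(cv$folds, `[[`, numeric(1), "auroc"),
    balanced_accuracy = vapply(cv$folds, `[[`, numeric(1),
                               "balanced_accuracy"))
  structure(list(
    features = data.frame(feature = feats, mean_abs_shap = unname(mean_abs),
                          rank = rank, direction = direction,
                          sign_agreement = agreement, n_votes = n_votes,
                          stable = !is.na(agreement) & agreement >= 0.80,
                          stringsAsFactors = FALSE),
    performance = perf), class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report>\n")
  top <- x$features[order(x$features$rank), ]
  print(utils::head(top, 10), row.names = FALSE)
  cat(sprintf("mean AUROC %.3f over %d folds\n",
              mean(x$performance$auroc, na.rm = TRUE),
              nrow(x$performance)))
  invisible(x)
}
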