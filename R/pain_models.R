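# Modeling stage: clinician-guided random-forest classification of pain
# vs pain-free days under group-aware 3-fold CV, regression-tree
# correlation, an unguided isolation-forest baseline, information-gain
# marker ranking, and a paired permutation comparison.

#' Assemble a modeling-ready feature matrix
#'
#' Restricts a marker data.frame (from [cohort_feature_matrix()] or
#' [build_feature_rows()]) to labeled days and splits it into the design
#' matrix, the binary response (pain = positive class), and the grouping
#' vector used for leakage-free cross-validation: every row carries the
#' pain event it belongs to (pain days) or was matched to (controls), so
#' all days tied to one event stay in one fold.
#'
#' @param features data.frame with meta columns `participant_id`, `date`,
#'   `label`, `event_id` followed by marker columns.
#' @return An object of class `feature_matrix`: list with `X` (numeric
#'   matrix), `y` (factor, levels `pain_free`, `pain`), `groups`
#'   (character), `meta` (the meta columns).
#' @export
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("label", "event_id") %in% names(features)))
  features <- features[features$label %in% c("pain", "pain_free"), ,
                       drop = FALSE]
  meta_cols <- intersect(c("participant_id", "date", "label", "event_id"),
                         names(features))
  X <- as.matrix(features[, setdiff(names(features), meta_cols),
                          drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values")
  y <- factor(features$label, levels = c("pain_free", "pain"))
  structure(list(X = X, y = y, groups = as.character(features$event_id),
                 meta = features[, meta_cols, drop = FALSE]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d days x %d markers (%d pain, %d pain-free, %d groups)\n",
              nrow(x$X), ncol(x$X), sum(x$y == "pain"),
              sum(x$y == "pain_free"), length(unique(x$groups))))
  invisible(x)
}

#' Group-aware fold assignment
#'
#' Assigns whole groups (pain events with their matched controls) to
#' folds, balancing fold sizes greedily after a seeded shuffle, so no
#' group is split across folds. Because each group holds both the event's
#' pain days and its matched pain-free days, class balance follows from
#' the group structure.
#'
#' @param groups character vector, one group id per row.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per row.
#' @export
make_group_folds <- function(groups, n_folds = 3L, seed = 1L) {
  ug <- unique(groups)
  if (length(ug) < n_folds)
    stop("need at least ", n_folds, " distinct groups")
  sizes <- table(groups)[ug]
  set.seed(seed)
  ord <- sample(length(ug))
  ug <- ug[ord]; sizes <- sizes[ord]
  ord2 <- order(-sizes)
  fold_of <- integer(length(ug)); names(fold_of) <- ug
  load <- numeric(n_folds)
  for (g in ord2) {
    f <- which.min(load)
    fold_of[g] <- f
    load[f] <- load[f] + sizes[g]
  }
  unname(fold_of[groups])
}

# area under the ROC curve from scores (Mann-Whitney form)
.auroc <- function(scores, y_pos) {
  n1 <- sum(y_pos); n0 <- sum(!y_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve (step integration over the
# ranked list; ties handled by grouping equal scores)
.auprc <- function(scores, y_pos) {
  n1 <- sum(y_pos)
  if (n1 == 0) return(NA_real_)
  ord <- order(-scores)
  yy <- y_pos[ord]; ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))
  tp_g <- tapply(as.numeric(yy), grp, sum)
  n_g <- tapply(rep(1, length(yy)), grp, sum)
  tp <- cumsum(tp_g); n <- cumsum(n_g)
  prec <- tp / n
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

# confusion-matrix summary with pain as the positive class
.classification_metrics <- function(pred_pos, y_pos) {
  tp <- sum(pred_pos & y_pos); fn <- sum(!pred_pos & y_pos)
  fp <- sum(pred_pos & !y_pos); tn <- sum(!pred_pos & !y_pos)
  list(confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("pain", "pain_free"),
                                          truth = c("pain", "pain_free"))),
       accuracy = (tp + tn) / length(y_pos),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Cross-validated random-forest pain-day classifier
#'
#' Fits a random forest on each training split of a group-aware
#' `n_folds`-fold partition and scores the held-out days with the
#' ensemble's positive-class vote fraction. All metrics are computed on
#' the pooled out-of-fold predictions: accuracy, sensitivity and
#' specificity at the 0.5 vote threshold, AUROC and AUPRC from the
#' scores.
#'
#' @param data a `feature_matrix`.
#' @param n_trees trees per forest (the companion setting of 150 trees is
#'   recorded in the report's config for reference).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return An object of class `evaluation_report`.
#' @export
train_classifier_cv <- function(data, n_trees = 100L, n_folds = 3L,
                                seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  if (nlevels(droplevels(data$y)) < 2L)
    stop("degenerate labels: need both pain and pain-free days")
  folds <- make_group_folds(data$groups, n_folds, seed)
  n <- nrow(data$X)
  score <- numeric(n)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    if (nlevels(droplevels(data$y[!te])) < 2L)
      stop("degenerate labels: a training split lost one class")
    set.seed(seed + f)
    fit <- randomForest::randomForest(x = data$X[!te, , drop = FALSE],
                                      y = droplevels(data$y[!te]),
                                      ntree = n_trees)
    pr <- stats::predict(fit, data$X[te, , drop = FALSE], type = "prob")
    score[te] <- pr[, "pain"]
    m <- .classification_metrics(score[te] >= 0.5,
                                 data$y[te] == "pain")
    per_fold[[f]] <- data.frame(fold = f, n = sum(te),
                                accuracy = m$accuracy)
  }
  y_pos <- data$y == "pain"
  pred_pos <- score >= 0.5
  m <- .classification_metrics(pred_pos, y_pos)
  structure(list(accuracy = m$accuracy,
                 sensitivity = m$sensitivity,
                 specificity = m$specificity,
                 auroc = .auroc(score, y_pos),
                 auprc = .auprc(score, y_pos),
                 confusion = m$confusion,
                 scores = score,
                 predictions = ifelse(pred_pos, "pain", "pain_free"),
                 y = as.character(data$y),
                 groups = data$groups,
                 folds = folds,
                 per_fold = do.call(rbind, per_fold),
                 config = list(model = "random_forest",
                               n_trees = n_trees,
                               n_trees_alternative = 150L,
                               n_folds = n_folds, seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report: accuracy %.3f, sensitivity %.3f,",
                     " specificity %.3f, AUROC %.3f, AUPRC %.3f\n"),
              x$accuracy, x$sensitivity, x$specificity, x$auroc, x$auprc))
  invisible(x)
}

#' Regression-tree correlation with pain indication
#'
#' Fits a regression tree (CART, ANOVA splitting) to the binary pain
#' indicator on each training split of the same group-aware partition and
#' correlates the pooled out-of-fold predictions with the indicator.
#'
#' @param data a `feature_matrix`.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Pearson correlation (0 when the predictions have zero
#'   variance).
#' @export
fit_regression_correlation <- function(data, n_folds = 3L, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  folds <- make_group_folds(data$groups, n_folds, seed)
  yn <- as.numeric(data$y == "pain")
  pred <- numeric(nrow(data$X))
  for (f in seq_len(n_folds)) {
    te <- folds == f
    df <- as.data.frame(data$X[!te, , drop = FALSE])
    names(df) <- paste0("m", seq_len(ncol(df)))
    df$.y <- yn[!te]
    set.seed(seed + f)
    fit <- rpart::rpart(.y ~ ., data = df, method = "anova")
    nd <- as.data.frame(data$X[te, , drop = FALSE])
    names(nd) <- paste0("m", seq_len(ncol(nd)))
    pred[te] <- stats::predict(fit, nd)
  }
  if (stats::sd(pred) == 0 || stats::sd(yn) == 0) return(0)
  stats::cor(pred, yn)
}

# ---- isolation forest -------------------------------------------------
# Compact isolation forest (random axis-aligned splits, subsampled trees,
# path-length anomaly score); no pre-installed R package provides one.

.iforest_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

# grow one isolation tree as a flat node table
.itree_grow <- function(X, depth_limit) {
  nodes <- list()
  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(size = length(idx))
    if (depth >= depth_limit || length(idx) <= 1L) return(id)
    # pick a feature with spread, if any
    feats <- sample(ncol(X))
    sp <- NA_integer_
    for (fcand in feats) {
      r <- range(X[idx, fcand])
      if (r[2] > r[1]) { sp <- fcand; break }
    }
    if (is.na(sp)) return(id)
    r <- range(X[idx, sp])
    cut <- stats::runif(1, r[1], r[2])
    left <- idx[X[idx, sp] < cut]
    right <- idx[X[idx, sp] >= cut]
    l <- build(left, depth + 1L)
    rr <- build(right, depth + 1L)
    nodes[[id]] <<- list(size = length(idx), feat = sp, cut = cut,
                         left = l, right = rr)
    id
  }
  build(seq_len(nrow(X)), 0L)
  nodes
}

.itree_path <- function(nodes, X) {
  n <- nrow(X)
  depth <- numeric(n)
  node <- rep(1L, n)
  active <- rep(TRUE, n)
  while (any(active)) {
    for (u in unique(node[active])) {
      nd <- nodes[[u]]
      sel <- active & node == u
      if (is.null(nd$feat)) {
        depth[sel] <- depth[sel] + .iforest_c(nd$size)
        active[sel] <- FALSE
      } else {
        goleft <- X[sel, nd$feat] < nd$cut
        node[sel][goleft] <- nd$left
        node[sel][!goleft] <- nd$right
        depth[sel] <- depth[sel] + 1
      }
    }
  }
  depth
}

#' Isolation-forest anomaly scores
#'
#' @param X numeric matrix (rows = days).
#' @param n_estimators number of isolation trees.
#' @param sample_size subsample size per tree.
#' @param seed integer seed.
#' @return Numeric anomaly scores in `(0, 1)`; higher = more anomalous.
#' @export
iforest_score <- function(X, n_estimators = 100L, sample_size = 256L,
                          seed = 1L) {
  set.seed(seed)
  psi <- min(sample_size, nrow(X))
  depth_limit <- ceiling(log2(max(psi, 2)))
  paths <- matrix(0, nrow(X), n_estimators)
  for (t in seq_len(n_estimators)) {
    idx <- sample(nrow(X), psi)
    nodes <- .itree_grow(X[idx, , drop = FALSE], depth_limit)
    paths[, t] <- .itree_path(nodes, X)
  }
  2^(-rowMeans(paths) / .iforest_c(psi))
}

#' Unguided isolation-forest baseline
#'
#' Fits an isolation forest on all days with no label information, flags
#' the most anomalous days as pain at a contamination level equal to the
#' labeled pain prevalence, and scores the flags against the true labels.
#' Labels enter only the final accuracy computation.
#'
#' @param data a `feature_matrix`.
#' @param n_estimators number of isolation trees.
#' @param seed integer seed.
#' @return List with `baseline_accuracy`, `predictions`, `scores`,
#'   `contamination`.
#' @export
iforest_baseline <- function(data, n_estimators = 100L, seed = 1L) {
  stopifnot(inherits(data, "feature_matrix"))
  sc <- iforest_score(data$X, n_estimators = n_estimators, seed = seed)
  contamination <- mean(data$y == "pain")
  thr <- stats::quantile(sc, 1 - contamination, names = FALSE)
  pred_pos <- sc > thr
  # quantile ties can under-flag; top up from the ranked scores
  need <- round(contamination * length(sc)) - sum(pred_pos)
  if (need > 0) {
    at_thr <- which(!pred_pos & sc == thr)
    pred_pos[utils::head(at_thr, need)] <- TRUE
  }
  list(baseline_accuracy = mean(pred_pos == (data$y == "pain")),
       predictions = ifelse(pred_pos, "pain", "pain_free"),
       scores = sc,
       contamination = contamination,
       config = list(model = "isolation_forest",
                     n_estimators = n_estimators, seed = seed))
}

#' Rank markers by single-split information gain
#'
#' For each marker, the gain is the entropy of the class labels (bits)
#' minus the minimum, over all single thresholds on that marker, of the
#' size-weighted split entropy — the criterion a depth-one decision tree
#' greedily optimizes. Markers are ranked by decreasing gain, ties broken
#' lexicographically by name; the direction records the sign of the
#' pain-minus-control mean difference.
#'
#' @param data a `feature_matrix`.
#' @return data.frame (`marker`, `gain`, `direction`) sorted by
#'   decreasing gain, class `marker_ranking`.
#' @export
rank_markers_information_gain <- function(data) {
  stopifnot(inherits(data, "feature_matrix"))
  y <- data$y == "pain"
  n <- length(y)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h0 <- ent(c(mean(y), 1 - mean(y)))
  gains <- vapply(seq_len(ncol(data$X)), function(j) {
    x <- data$X[, j]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L]           # thresholds between distinct values
    if (!any(valid)) return(0)
    nl <- k[valid]; n1l <- cum1[k][valid]
    pl <- n1l / nl; pr <- (sum(ys) - n1l) / (n - nl)
    e <- function(p) ifelse(p <= 0 | p >= 1, 0,
                            -(p * log2(p) + (1 - p) * log2(1 - p)))
    split_ent <- (nl * e(pl) + (n - nl) * e(pr)) / n
    max(0, h0 - min(split_ent))
  }, 0)
  mu1 <- colMeans(data$X[y, , drop = FALSE])
  mu0 <- colMeans(data$X[!y, , drop = FALSE])
  out <- data.frame(marker = colnames(data$X), gain = gains,
                    direction = sign(mu1 - mu0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_ranking", "data.frame")
  out
}

#' Paired permutation test: guided vs unguided accuracy
#'
#' Compares two per-day prediction vectors against the truth with a
#' two-sided paired permutation test on the per-day correctness
#' indicators: under the null the guided/unguided assignment of each
#' day's pair of outcomes is exchangeable, so each pair's difference has
#' its sign flipped with probability 1/2.
#'
#' @param guided,baseline character prediction vectors (`"pain"` /
#'   `"pain_free"`).
#' @param y true labels, same length.
#' @param n_permutations number of sign-flip draws.
#' @param seed integer seed.
#' @return p-value in `[1/(n_permutations+1), 1]`.
#' @export
compare_guided_vs_unguided <- function(guided, baseline, y,
                                       n_permutations = 10000L,
                                       seed = 1L) {
  if (length(guided) != length(baseline) ||
      length(guided) != length(y))
    stop("length mismatch between prediction vectors")
  diffs <- as.numeric(guided == y) - as.numeric(baseline == y)
  d_obs <- mean(diffs)
  set.seed(seed)
  n <- length(diffs)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  d_perm <- as.vector(signs %*% diffs) / n
  (1 + sum(abs(d_perm) >= abs(d_obs) - 1e-12)) / (n_permutations + 1)
}
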