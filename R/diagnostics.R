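#' Feature-selection / classification configuration
#'
#' Mirrors the study protocol: a two-sample-t filter keeping the top 20%
#' of edges by |t|, linear SVM-RFE with a dimension-dependent step
#' schedule (remove 500 while > 10,000 features, 50 down to 1,000, 5 down
#' to 100, then 1), a nested stratified 5-fold search for the SVM cost C
#' over 2^beta, beta in -8..8, and a feature-fraction grid from 10% of the
#' filtered set upward in 5% steps.
#'
#' @param filter_keep_frac fraction of columns kept by the t filter.
#' @param fraction_grid fractions of the filtered set evaluated (by RFE
#'   rank) for the accuracy curve.
#' @param C_grid SVM cost candidates, ascending.
#' @param inner_folds folds of the nested C search.
#' @param seed RNG seed for fold assignment.
#' @param positive_label the class treated as positive (convertors).
#' @return a `selection_config` object.
#' @export
selection_config <- function(filter_keep_frac = 0.20,
                             fraction_grid = seq(0.10, 1.00, by = 0.05),
                             C_grid = 2^(-8:8),
                             inner_folds = 5L,
                             seed = 1L,
                             positive_label = "pMCI") {
  if (any(fraction_grid <= 0 | fraction_grid > 1)) stop("fractions must be in (0, 1]")
  if (filter_keep_frac <= 0 || filter_keep_frac > 1) stop("filter_keep_frac must be in (0, 1]")
  structure(list(filter_keep_frac = filter_keep_frac,
                 fraction_grid = fraction_grid,
                 C_grid = sort(C_grid), inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed), positive_label = positive_label),
            class = "selection_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Vectorize connectivity networks into an edge-feature table
#'
#' Concatenates each subject's asymmetric K x K weight matrix into a
#' K(K-1)-long row (target region k outer, regressor j inner, skipping
#' j = k), e.g. 246 regions give 60,270 edge features.
#'
#' @param networks list of `mmc_network` objects (or raw K x K matrices),
#'   one per subject, sharing K.
#' @param labels per-subject group labels.
#' @return an `edge_feature_table`: list with `features`
#'   (n x K(K-1) matrix), `edge_map` (data.frame target/regressor), and
#'   `labels`.
#' @export
vectorize_networks <- function(networks, labels) {
  mats <- lapply(networks, function(x) if (inherits(x, "mmc_network")) x$weights else x)
  K <- nrow(mats[[1L]])
  if (any(vapply(mats, nrow, 0L) != K)) stop("networks have mixed region counts")
  diag_idx <- (seq_len(K) - 1L) * K + seq_len(K)
  features <- do.call(rbind, lapply(mats, function(w) as.vector(t(w))[-diag_idx]))
  grid <- expand.grid(regressor = seq_len(K), target = seq_len(K))[, 2:1]
  edge_map <- grid[grid$target != grid$regressor, ]
  rownames(edge_map) <- NULL
  structure(list(features = features, edge_map = edge_map,
                 labels = labels, K = K),
            class = "edge_feature_table")
}

#' @rdname vectorize_networks
#' @param row one row of the feature matrix.
#' @param K region count.
#' @return `devectorize_network()`: the K x K matrix with zero diagonal.
#' @export
devectorize_network <- function(row, K) {
  full <- numeric(K * K)
  diag_idx <- (seq_len(K) - 1L) * K + seq_len(K)
  full[-diag_idx] <- row
  t(matrix(full, K, K))
}

# vectorized pooled-variance two-sample t over columns of X, class 1 vs 2
.col_pooled_t <- function(X, is1) {
  n1 <- sum(is1); n2 <- sum(!is1)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per class")
  m1 <- colMeans(X[is1, , drop = FALSE]); m2 <- colMeans(X[!is1, , drop = FALSE])
  v1 <- apply(X[is1, , drop = FALSE], 2L, var)
  v2 <- apply(X[!is1, , drop = FALSE], 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  list(t = t, df = n1 + n2 - 2, diff = d)
}

#' Two-sample-t feature filter
#'
#' Pooled-variance two-sample t per column; keeps the top
#' `round(keep_frac * ncol)` columns (half-up rounding) ranked by |t|
#' descending. Constant columns get t = 0 and rank last.
#'
#' @param X training feature matrix (rows = subjects).
#' @param labels training class labels (exactly two classes present).
#' @param keep_frac fraction of columns to keep.
#' @return integer vector of kept column indices, ranked by |t| descending.
#' @export
ttest_filter <- function(X, labels, keep_frac = 0.20) {
  cls <- unique(labels)
  if (length(cls) != 2L) stop("ttest_filter needs exactly two classes in the training rows")
  tt <- .col_pooled_t(X, labels == cls[1L])
  keep <- round_half_up(keep_frac * ncol(X))
  order(abs(tt$t), decreasing = TRUE)[seq_len(keep)]
}

#' RFE step schedule
#'
#' Step size as a function of the current surviving dimension d:
#' 500 while d > 10,000; 50 while d > 1,000; 5 while d > 100; otherwise 1.
#'
#' @param d current feature dimension.
#' @return integer step.
#' @export
rfe_step_size <- function(d) {
  if (d > 10000L) 500L else if (d > 1000L) 50L else if (d > 100L) 5L else 1L
}

#' @rdname rfe_step_size
#' @param n_start starting dimension.
#' @return `rfe_schedule_trace()`: the full sequence of surviving
#'   dimensions from `n_start` down to 1.
#' @export
rfe_schedule_trace <- function(n_start) {
  d <- as.integer(n_start); out <- d
  while (d > 1L) {
    d <- max(1L, d - min(rfe_step_size(d), d - 1L))
    out <- c(out, d)
  }
  out
}

# fit a linear SVM and return the model plus squared primal weights
.linear_svm <- function(X, y, C) {
  m <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(t(m$coefs) %*% m$SV)
  list(model = m, w2 = w^2)
}

# decision values oriented so positive => positive_label
.decision_values <- function(model, newdata, positive_label) {
  p <- predict(model, newdata, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  lab <- colnames(dv)[1L]
  flip <- !startsWith(lab, paste0(positive_label, "/"))
  list(pred = as.character(p), dv = if (flip) -dv[, 1L] else dv[, 1L])
}

#' Linear SVM recursive feature elimination
#'
#' Iteratively fits a linear SVM at fixed cost C, ranks the surviving
#' columns by squared primal weights w_j^2 (w = sum_k alpha_k y_k x_k) and
#' removes the lowest-ranked block per the step schedule, until one column
#' remains. Returns the complete ranking (elimination order reversed;
#' best-surviving first).
#'
#' @param X training matrix restricted to the filtered columns.
#' @param labels training labels (two classes).
#' @param C SVM cost (fixed throughout; typically the nested-search winner).
#' @param step_fn step schedule, by default [rfe_step_size()].
#' @return integer vector: column indices of `X` from best to worst.
#' @export
svm_rfe <- function(X, labels, C, step_fn = rfe_step_size) {
  if (ncol(X) < 2L) stop("svm_rfe needs at least 2 columns")
  y <- factor(labels)
  surviving <- seq_len(ncol(X))
  eliminated <- integer(0)
  while (length(surviving) > 1L) {
    fit <- tryCatch(.linear_svm(X[, surviving, drop = FALSE], y, C),
                    error = function(e)
                      stop(sprintf("SVM fit failed at dimension %d: %s",
                                   length(surviving), conditionMessage(e))))
    step <- min(step_fn(length(surviving)), length(surviving) - 1L)
    drop_local <- order(fit$w2)[seq_len(step)]
    eliminated <- c(eliminated, surviving[drop_local])
    surviving <- surviving[-drop_local]
  }
  c(surviving, rev(eliminated))
}

# balanced stratified fold assignment
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    fold[ix] <- rep(seq_len(k), length.out = length(ix))
  }
  fold
}

#' Nested cross-validated search for the SVM cost
#'
#' Stratified `folds`-fold cross-validation on the training rows over an
#' ascending C grid; returns the C with the highest mean held-in accuracy,
#' ties going to the smallest C.
#'
#' @param X training matrix.
#' @param labels training labels.
#' @param C_grid ascending cost candidates.
#' @param folds fold count.
#' @param seed RNG seed for the fold assignment (deterministic replay).
#' @return the selected C.
#' @export
nested_c_search <- function(X, labels, C_grid = 2^(-8:8), folds = 5L, seed = 1L) {
  y <- factor(labels)
  if (length(y) < folds) stop("fewer training rows than folds")
  fold <- .make_folds(y, folds, seed)
  ok <- function(f) all(vapply(seq_len(folds), function(i)
    length(unique(y[f != i])) == 2L && sum(f == i) > 0L, NA))
  if (!ok(fold)) {
    fold <- .make_folds(y, folds, seed + 1L)
    if (!ok(fold)) stop("could not stratify folds with both classes present")
  }
  acc <- vapply(C_grid, function(C) {
    mean(vapply(seq_len(folds), function(i) {
      m <- e1071::svm(X[fold != i, , drop = FALSE], y[fold != i],
                      kernel = "linear", cost = C, scale = FALSE)
      mean(predict(m, X[fold == i, , drop = FALSE]) == y[fold == i])
    }, 0))
  }, 0)
  C_grid[which.max(acc)]   # which.max takes the first (smallest C) on ties
}

#' Classification metrics
#'
#' Accuracy, sensitivity (TP/(TP+FN), positive = convertors), specificity
#' (TN/(TN+FP)) and AUC (rank statistic on the pooled decision values,
#' tie-corrected, via pROC).
#'
#' @param predictions predicted class labels.
#' @param decision_values real-valued scores, larger = more positive-like.
#' @param labels true labels.
#' @param positive_label positive class (default `"pMCI"`).
#' @return named list: `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   and the confusion counts.
#' @export
compute_metrics <- function(predictions, decision_values, labels,
                            positive_label = "pMCI") {
  stopifnot(length(predictions) == length(labels),
            length(decision_values) == length(labels))
  pos <- labels == positive_label
  if (!any(pos) || all(pos)) stop("both classes must be present to compute sensitivity/specificity")
  tp <- sum(predictions == positive_label & pos)
  fn <- sum(predictions != positive_label & pos)
  tn <- sum(predictions != positive_label & !pos)
  fp <- sum(predictions == positive_label & !pos)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = factor(pos, levels = c(FALSE, TRUE)),
    predictor = as.numeric(decision_values),
    direction = "<", quiet = TRUE)))
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       auc = auc, tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Leave-one-out cross-validated classification with nested selection
#'
#' For each held-out subject, the remaining n-1 rows alone drive: the
#' two-sample-t filter (top `filter_keep_frac`), the nested C search on
#' the filtered set, and SVM-RFE ranking at that C. The classifier is then
#' trained on the top f-fraction of the filtered set (by RFE rank) for
#' every f on the fraction grid, and the held-out subject is predicted.
#' Metrics are aggregated per grid point; the peak-accuracy point is
#' reported and flagged as optimistically biased (the fraction is selected
#' on the evaluation metric itself). An honest variant selecting the
#' fraction inside each training fold is available via
#' `honest_fraction = TRUE`.
#'
#' @param table an `edge_feature_table` (or any list with `features` and
#'   `labels`).
#' @param config a [selection_config()].
#' @param honest_fraction also pick the feature fraction by inner
#'   cross-validation within each training fold (slower).
#' @param audit_folds in the first `audit_folds` folds, re-run the whole
#'   selection with the held-out row poisoned (set to huge values) and
#'   stop if any selection changes — a leakage self-check.
#' @return a `cv_report`: per-grid-point metric table, peak point,
#'   per-fold chosen C and selected edges, pooled decision values.
#' @export
loocv_classify <- function(table, config = selection_config(),
                           honest_fraction = FALSE, audit_folds = 0L) {
  X <- table$features
  labels <- as.character(table$labels)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects")
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("need exactly two classes")
  pos <- config$positive_label
  fracs <- config$fraction_grid
  preds <- matrix(NA_character_, n, length(fracs))
  dvals <- matrix(NA_real_, n, length(fracs))
  chosen_C <- numeric(n)
  selected <- vector("list", n)
  honest_pred <- character(n); honest_dv <- numeric(n)

  run_selection <- function(Xtr, ytr, fold_seed) {
    filt <- ttest_filter(Xtr, ytr, config$filter_keep_frac)
    C <- nested_c_search(Xtr[, filt, drop = FALSE], ytr, config$C_grid,
                         config$inner_folds, fold_seed)
    rank_local <- svm_rfe(Xtr[, filt, drop = FALSE], ytr, C)
    list(filt = filt, C = C, ranking = filt[rank_local])
  }

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fold_seed <- stage_seed(config$seed, paste0("fold", i))
    sel <- run_selection(X[tr, , drop = FALSE], labels[tr], fold_seed)
    if (i <= audit_folds) {
      Xp <- X; Xp[i, ] <- 1e9   # poison the held-out row; selections must not move
      sel2 <- run_selection(Xp[tr, , drop = FALSE], labels[tr], fold_seed)
      if (!identical(sel, sel2))
        stop("leakage self-check failed: selection depends on the held-out row")
    }
    chosen_C[i] <- sel$C
    selected[[i]] <- sel$ranking
    yf <- factor(labels[tr])
    for (fi in seq_along(fracs)) {
      keep <- sel$ranking[seq_len(max(1L, round_half_up(fracs[fi] * length(sel$filt))))]
      m <- e1071::svm(X[tr, keep, drop = FALSE], yf, kernel = "linear",
                      cost = sel$C, scale = FALSE)
      out <- .decision_values(m, X[i, keep, drop = FALSE], pos)
      preds[i, fi] <- out$pred
      dvals[i, fi] <- out$dv
    }
    if (honest_fraction) {
      fold <- .make_folds(factor(labels[tr]), config$inner_folds, fold_seed)
      inner_acc <- vapply(seq_along(fracs), function(fi) {
        keep <- sel$ranking[seq_len(max(1L, round_half_up(fracs[fi] * length(sel$filt))))]
        mean(vapply(seq_len(config$inner_folds), function(f) {
          itr <- tr[fold != f]; ite <- tr[fold == f]
          m <- e1071::svm(X[itr, keep, drop = FALSE], factor(labels[itr], levels = cls),
                          kernel = "linear", cost = sel$C, scale = FALSE)
          mean(predict(m, X[ite, keep, drop = FALSE]) == labels[ite])
        }, 0))
      }, 0)
      fi <- which.max(inner_acc)
      honest_pred[i] <- preds[i, fi]
      honest_dv[i] <- dvals[i, fi]
    }
  }

  grid <- do.call(rbind, lapply(seq_along(fracs), function(fi) {
    m <- compute_metrics(preds[, fi], dvals[, fi], labels, pos)
    data.frame(fraction = fracs[fi], accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               auc = m$auc)
  }))
  peak_i <- which.max(grid$accuracy)
  report <- list(grid = grid,
                 peak = grid[peak_i, ],
                 peak_is_optimistic = TRUE,
                 folds = list(chosen_C = chosen_C, selected = selected,
                              predictions = preds, decision_values = dvals),
                 labels = labels, positive_label = pos)
  if (honest_fraction)
    report$honest <- compute_metrics(honest_pred, honest_dv, labels, pos)
  structure(report, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  p <- x$peak
  cat(sprintf("cv_report: peak accuracy %.2f%% at fraction %.2f (sens %.2f%%, spec %.2f%%, AUC %.4f)\n",
              100 * p$accuracy, p$fraction, 100 * p$sensitivity,
              100 * p$specificity, p$auc))
  if (x$peak_is_optimistic)
    cat("  note: the peak point is selected on the evaluation metric (optimistic)\n")
  if (!is.null(x$honest))
    cat(sprintf("  honest (inner-loop fraction): accuracy %.2f%%\n",
                100 * x$honest$accuracy))
  invisible(x)
}

#' Edge-wise group difference with FDR control
#'
#' Pooled-variance two-sample t and two-sided p per edge, Benjamini-
#' Hochberg adjusted q, and a significance flag at `q < q_threshold`.
#' Sign is the group-2 minus group-1 mean difference. Edges constant in
#' both groups get p = 1.
#'
#' @param X1,X2 feature matrices of the two groups (same columns).
#' @param q_threshold FDR level (default 0.05).
#' @param edge_map optional data.frame (target, regressor) labeling columns.
#' @return data.frame with columns t, p, q, significant, sign (+ edge ids).
#' @export
edge_group_difference <- function(X1, X2, q_threshold = 0.05, edge_map = NULL) {
  stopifnot(ncol(X1) == ncol(X2))
  X <- rbind(X1, X2)
  is1 <- rep(c(TRUE, FALSE), c(nrow(X1), nrow(X2)))
  tt <- .col_pooled_t(X, is1)
  t_stat <- tt$t
  p <- ifelse(is.finite(t_stat), 2 * pt(abs(t_stat), tt$df, lower.tail = FALSE),
              0)
  p[t_stat == 0 & tt$diff == 0] <- 1
  q <- p.adjust(p, method = "BH")
  out <- data.frame(t = t_stat, p = p, q = q,
                    significant = q < q_threshold,
                    sign = sign(-tt$diff))
  if (!is.null(edge_map)) out <- cbind(edge_map, out)
  out
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param counts 2x2 nonnegative count matrix with positive margins.
#' @return list with `statistic` (1 df) and `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2x2 table")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Pooled two-sample t from summary statistics
#'
#' @param mean1,sd1,n1 group-1 summaries.
#' @param mean2,sd2,n2 group-2 summaries.
#' @return list with `t`, `df` (= n1 + n2 - 2) and two-sided `p`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Regional-mean feature table (baseline features)
#'
#' Per subject, modality and region, the mean voxel value — the simple
#' volumetric/metabolic feature set the connectivity features are compared
#' against.
#'
#' @param cohort a `regional_cohort`.
#' @return a list shaped like an `edge_feature_table` (`features`,
#'   `labels`), usable by [loocv_classify()].
#' @export
regional_mean_features <- function(cohort) {
  feats <- do.call(cbind, lapply(cohort$modalities, function(m)
    do.call(cbind, lapply(cohort$data[[m]], rowMeans))))
  structure(list(features = unname(feats), labels = cohort$metadata$group,
                 K = length(cohort$region_ids)),
            class = "edge_feature_table")
}
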