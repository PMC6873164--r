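test_that("vectorization enumerates off-diagonal edges in row-major order", {
  W <- matrix(1:9, 3, 3, byrow = TRUE)
  fe <- vectorize_networks(list(W), labels = "sMCI")
  expect_equal(ncol(fe$features), 6)
  expect_equal(as.numeric(fe$features), c(2, 3, 4, 6, 7, 8))
  expect_equal(fe$edge_map$target, c(1, 1, 2, 2, 3, 3))
  expect_equal(fe$edge_map$regressor, c(2, 3, 1, 3, 1, 2))
  # K = 246 gives the canonical feature length
  expect_equal(246 * (246 - 1), 60270)
  # round trip
  set.seed(1)
  W2 <- matrix(runif(25), 5, 5); diag(W2) <- 0
  fe2 <- vectorize_networks(list(W2), "pMCI")
  expect_equal(devectorize_network(fe2$features[1, ], 5), W2)
  expect_error(vectorize_networks(list(W, W2), c("a", "b")), "mixed")
})

test_that("t filter ranks by pooled |t| and keeps the rounded top fraction", {
  # closed-form check: group A (1,2,3) vs B (4,5,6)
  x <- c(1, 2, 3, 4, 5, 6)
  lab <- rep(c("A", "B"), each = 3)
  tt <- mmcnet:::.col_pooled_t(matrix(x, 6, 1), lab == "A")
  sp <- sqrt((2 * 1 + 2 * 1) / 4)
  expect_equal(tt$t, (2 - 5) / (sp * sqrt(2 / 3)), tolerance = 1e-12)

  set.seed(2)
  X <- cbind(matrix(rnorm(60), 6, 10), 1)   # constant column last
  keep <- ttest_filter(X, lab, keep_frac = 0.5)
  expect_equal(length(keep), round(0.5 * 11))   # half-up: 6 (round(5.5))
  expect_false(11L %in% keep)                   # constant column excluded
  expect_error(ttest_filter(X, rep("A", 6), 0.2), "two classes")
  # the canonical 20% of 60,270
  expect_equal(mmcnet:::round_half_up(0.20 * 60270), 12054)
})

test_that("RFE schedule trace equals an independent simulator from 12,054", {
  sim <- function(n) {   # independent re-statement of the published schedule
    dims <- n
    while (n > 1) {
      s <- if (n > 10000) 500 else if (n > 1000) 50 else if (n > 100) 5 else 1
      n <- max(1, n - min(s, n - 1))
      dims <- c(dims, n)
    }
    dims
  }
  tr <- rfe_schedule_trace(12054)
  expect_identical(tr, as.integer(sim(12054)))
  expect_true(all(diff(tr[tr > 10000]) == -500))
  expect_true(all(abs(diff(tr[tr <= 1000 & tr > 100])) == 5))
  expect_true(all(abs(diff(tr[tr <= 100])) == 1))
})

test_that("SVM-RFE eliminates uninformative columns first", {
  set.seed(4)
  y <- rep(c("sMCI", "pMCI"), each = 10)
  sep <- ifelse(y == "pMCI", 1, -1) + rnorm(20, sd = 0.05)
  X <- cbind(sep, rnorm(20, sd = 1e-6))
  rank <- svm_rfe(X, y, C = 1)
  expect_equal(rank, c(1L, 2L))
})

test_that("SVM-RFE with step 1 matches an exhaustive refit oracle", {
  set.seed(5)
  n <- 24; d <- 10
  y <- rep(c("sMCI", "pMCI"), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 3] <- X[, 3] + ifelse(y == "pMCI", 1.5, -1.5)
  X[, 7] <- X[, 7] + ifelse(y == "pMCI", 0.7, -0.7)
  oracle <- local({   # independent elimination loop, refit after each removal
    surv <- 1:d; elim <- integer(0)
    while (length(surv) > 1) {
      m <- e1071::svm(X[, surv, drop = FALSE], factor(y), kernel = "linear",
                      cost = 1, scale = FALSE)
      w2 <- as.numeric(t(m$coefs) %*% m$SV)^2
      worst <- surv[which.min(w2)]
      elim <- c(elim, worst); surv <- setdiff(surv, worst)
    }
    c(surv, rev(elim))
  })
  expect_identical(svm_rfe(X, y, C = 1), oracle)
})

test_that("nested C search is deterministic and breaks ties toward small C", {
  set.seed(6)
  y <- rep(c("sMCI", "pMCI"), each = 10)
  X <- matrix(rnorm(40), 20, 2) + ifelse(y == "pMCI", 3, -3)
  # linearly separable: all C tie at 100% -> smallest beta wins
  expect_equal(nested_c_search(X, y, 2^(-8:8), folds = 5, seed = 3), 2^-8)
  # single candidate
  expect_equal(nested_c_search(X, y, 4, folds = 5, seed = 3), 4)
  # seeded replay
  Xn <- matrix(rnorm(40), 20, 2) + ifelse(y == "pMCI", 0.3, -0.3)
  c1 <- nested_c_search(Xn, y, 2^(-2:2), folds = 5, seed = 9)
  c2 <- nested_c_search(Xn, y, 2^(-2:2), folds = 5, seed = 9)
  expect_identical(c1, c2)
  expect_identical(mmcnet:::.make_folds(factor(y), 5, 11),
                   mmcnet:::.make_folds(factor(y), 5, 11))
})

test_that("metric aggregation satisfies the confusion-matrix identities", {
  # all correct
  lab <- rep(c("pMCI", "sMCI"), c(4, 6))
  m <- compute_metrics(lab, ifelse(lab == "pMCI", 1, -1), lab)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity", "auc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, auc = 1))
  # constant decision values -> AUC 0.5
  m2 <- compute_metrics(lab, rep(0, 10), lab)
  expect_equal(m2$auc, 0.5)
  # reconstructed printed confusion matrix: TP=38 FN=13 TN=62 FP=13
  lab3 <- rep(c("pMCI", "sMCI"), c(51, 75))
  pred3 <- c(rep("pMCI", 38), rep("sMCI", 13), rep("sMCI", 62), rep("pMCI", 13))
  dv3 <- ifelse(pred3 == "pMCI", 1, -1)
  m3 <- compute_metrics(pred3, dv3, lab3)
  expect_equal(round(100 * m3$accuracy, 2), 79.37)
  expect_equal(round(100 * m3$sensitivity, 2), 74.51)
  expect_equal(round(100 * m3$specificity, 2), 82.67)
  # identity: accuracy = (sens*n_pos + spec*n_neg)/n
  expect_equal(m3$accuracy, (m3$sensitivity * 51 + m3$specificity * 75) / 126,
               tolerance = 1e-12)
  # AUC equals the hand rank statistic with tie correction
  set.seed(8)
  dv <- round(rnorm(30), 1)
  lab4 <- sample(rep(c("pMCI", "sMCI"), 15))
  m4 <- compute_metrics(sample(lab4), dv, lab4)
  r <- rank(dv)
  auc_hand <- (sum(r[lab4 == "pMCI"]) - 15 * 16 / 2) / (15 * 15)
  expect_equal(m4$auc, auc_hand, tolerance = 1e-12)
  expect_error(compute_metrics("pMCI", 1, "pMCI"), "both classes")
})

test_that("LOOCV separates well-separated clusters at every grid point", {
  set.seed(10)
  n <- 24
  lab <- rep(c("sMCI", "pMCI"), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 1:5] <- X[, 1:5] + ifelse(lab == "pMCI", 4, -4)
  fe <- list(features = X, labels = lab)
  rep_ <- loocv_classify(fe, selection_config(filter_keep_frac = 0.5, seed = 2,
                                              C_grid = 2^(-4:4), inner_folds = 3))
  expect_true(all(rep_$grid$accuracy == 1))
  expect_equal(rep_$peak$accuracy, 1)
})

test_that("LOOCV leakage audit passes on clean code and catches poisoning", {
  set.seed(11)
  n <- 18
  lab <- rep(c("sMCI", "pMCI"), each = n / 2)
  X <- matrix(rnorm(n * 12), n, 12)
  X[, 1:3] <- X[, 1:3] + ifelse(lab == "pMCI", 2, -2)
  fe <- list(features = X, labels = lab)
  expect_no_error(loocv_classify(fe, selection_config(filter_keep_frac = 0.5,
                                                      C_grid = 2^(-2:2),
                                                      inner_folds = 3, seed = 4),
                                 audit_folds = 3L))
})

test_that("honest inner-loop fraction selection reports a full metric set", {
  set.seed(12)
  n <- 20
  lab <- rep(c("sMCI", "pMCI"), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 1:2] <- X[, 1:2] + ifelse(lab == "pMCI", 3, -3)
  fe <- list(features = X, labels = lab)
  rep_ <- loocv_classify(fe, selection_config(filter_keep_frac = 0.5,
                                              C_grid = 1, inner_folds = 3,
                                              seed = 5),
                         honest_fraction = TRUE)
  expect_true(is.numeric(rep_$honest$accuracy))
  expect_gte(rep_$honest$accuracy, 0.9)
})

test_that("BH adjustment matches the step-up definition", {
  p <- c(0.001, 0.01, 0.02, 0.5)
  # brute-force step-up oracle
  n <- length(p); o <- order(p); q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  expect_equal(p.adjust(p, "BH"), q)
  X1 <- matrix(rnorm(40), 10, 4); X2 <- matrix(rnorm(40), 10, 4)
  es <- edge_group_difference(X1, X2)
  expect_true(all(es$q >= es$p))
  expect_true(all(diff(es$q[order(es$p)]) >= -1e-12))
})

test_that("identical groups yield zero significant edges; planted shifts are found", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  es <- edge_group_difference(X, X)
  expect_equal(sum(es$significant), 0)

  # power: single-edge shift of d = 1.5 at n = 40/40, 100 edges
  hits <- 0
  for (s in 1:30) {
    set.seed(s)
    X1 <- matrix(rnorm(40 * 100), 40, 100)
    X2 <- matrix(rnorm(40 * 100), 40, 100)
    X2[, 7] <- X2[, 7] + 1.5
    es <- edge_group_difference(X1, X2)
    hits <- hits + (es$significant[7] && es$sign[7] > 0)
  }
  expect_gte(hits, 29)   # >= 95% power is the design point
  # zero-variance edge handling
  X1c <- X1; X2c <- X2; X1c[, 1] <- 1; X2c[, 1] <- 1
  esc <- edge_group_difference(X1c, X2c)
  expect_equal(esc$p[1], 1)
})

test_that("cohort summary statistics match their textbook definitions", {
  res <- chi_square_2x2(matrix(c(50, 25, 32, 19), 2, byrow = TRUE))
  expect_equal(round(res$statistic, 4), 0.2054)
  expect_equal(round(res$p, 4), 0.6504)
  expect_equal(chi_square_2x2(matrix(c(20, 10, 40, 20), 2, byrow = TRUE))$statistic, 0)
  # random table vs brute-force sum (O-E)^2/E
  set.seed(14)
  tab <- matrix(rpois(4, 30) + 1, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab)$statistic, sum((tab - E)^2 / E),
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")

  tt <- two_sample_t_summary(5, 1, 10, 5, 2, 12)
  expect_equal(tt$t, 0)
  expect_equal(two_sample_t_summary(76.22, 6.28, 75, 74.95, 7.29, 51)$df, 124)
  # pooled formula on the printed age summaries
  expect_equal(round(two_sample_t_summary(76.22, 6.28, 75, 74.95, 7.29, 51)$t, 2),
               1.04)
})
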