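#' Solver configuration for the multi-task sparse regressions
#'
#' @param lambda_ratio penalty level as a fraction of the problem's
#'   `lambda_max` (the smallest penalty that zeroes all coefficients), in
#'   (0, 1]. The study grid is `{1,...,10} x 1e-3`.
#' @param tol relative objective-change stopping threshold.
#' @param max_iter iteration cap.
#' @param kkt_tol KKT-residual threshold that also terminates the solve.
#' @param penalty_mode `"l21_multitask"` (row-wise l2 norm across
#'   modalities, the multi-modal coupling penalty) or `"l1_single_task"`
#'   (plain lasso penalty; with M = 1 this is the single-modality variant).
#' @return a `solver_config` object.
#' @export
solver_config <- function(lambda_ratio = 6e-3, tol = 1e-8, max_iter = 5000L,
                          penalty_mode = c("l21_multitask", "l1_single_task"),
                          kkt_tol = 1e-6) {
  if (lambda_ratio <= 0 || lambda_ratio > 1) stop("lambda_ratio must be in (0, 1]")
  if (tol <= 0 || kkt_tol <= 0) stop("tolerances must be > 0")
  structure(list(lambda_ratio = lambda_ratio, tol = tol,
                 max_iter = as.integer(max_iter),
                 penalty_mode = match.arg(penalty_mode), kkt_tol = kkt_tol),
            class = "solver_config")
}

#' Smallest penalty that zeroes all coefficients
#'
#' For the l2,1 penalty this is the maximum over regressor columns j of the
#' l2 norm across tasks of the column-target inner products; solving at any
#' lambda at or above it returns an all-zero coefficient matrix. The
#' target region's own (zeroed) column is excluded.
#'
#' @param designs list of per-task `T x K` design matrices (column of the
#'   target region set to zero).
#' @param targets list of per-task length-T response vectors.
#' @param exclude optional column index to exclude (the target region).
#' @return scalar `lambda_max`.
#' @export
lambda_max <- function(designs, targets, exclude = NULL) {
  corr2 <- Reduce(`+`, Map(function(X, y) as.numeric(crossprod(X, y))^2,
                           designs, targets))
  if (!is.null(exclude)) corr2[exclude] <- 0
  lm <- sqrt(max(corr2))
  if (lm == 0 && all(vapply(designs, function(X) all(X == 0), NA)))
    warning("all-zero designs: lambda_max = 0")
  lm
}

# row-wise group soft-threshold: shrink each row's l2 norm by thr
.prox_l21 <- function(W, thr) {
  nrm <- sqrt(rowSums(W^2))
  scale <- pmax(0, 1 - thr / pmax(nrm, .Machine$double.eps))
  scale[nrm == 0] <- 0
  W * scale
}

.prox_l1 <- function(W, thr) sign(W) * pmax(abs(W) - thr, 0)

.penalty <- function(W, mode) {
  if (mode == "l21_multitask") sum(sqrt(rowSums(W^2))) else sum(abs(W))
}

# KKT residual for the group-lasso stationarity conditions; G is the
# smooth-part gradient at W. Active rows must satisfy G_j = -lambda *
# W_j/||W_j||; inactive rows ||G_j|| <= lambda.
.kkt_residual <- function(W, G, lambda, mode) {
  if (mode == "l21_multitask") {
    nrm <- sqrt(rowSums(W^2))
    act <- nrm > 0
    r_in <- if (any(!act)) max(0, max(sqrt(rowSums(G[!act, , drop = FALSE]^2))) - lambda) else 0
    r_ac <- if (any(act)) {
      D <- G[act, , drop = FALSE] + lambda * W[act, , drop = FALSE] / nrm[act]
      max(sqrt(rowSums(D^2)))
    } else 0
  } else {
    act <- W != 0
    r_in <- if (any(!act)) max(0, max(abs(G[!act])) - lambda) else 0
    r_ac <- if (any(act)) max(abs(G[act] + lambda * sign(W[act]))) else 0
  }
  max(r_in, r_ac)
}

#' Multi-task l2,1-penalized (or lasso) regression solver
#'
#' Minimizes `0.5 * sum_m ||y^m - X^m w^m||^2 + lambda * P(W)` where `P` is
#' the row-wise l2,1 norm (joint region selection across modalities) or the
#' elementwise l1 norm, by accelerated proximal gradient (FISTA) with a
#' function-value monotonicity safeguard. The group soft-threshold prox
#' yields exact zero rows, so the support can be read off without
#' thresholding. Convergence is certified by the KKT residual dropping
#' below `kkt_tol`; a stalled objective (relative change below `tol` on
#' many consecutive iterations) restarts the momentum, and the iteration
#' cap returns the best iterate with a warning.
#'
#' @param designs list of per-task `T x K` design matrices.
#' @param targets list of per-task length-T response vectors.
#' @param config a [solver_config()].
#' @param lambda absolute penalty; by default
#'   `config$lambda_ratio * lambda_max(designs, targets)`.
#' @return `K x M` coefficient matrix with attributes `lambda`,
#'   `converged`, `iterations`, `kkt_residual`, `objective`.
#' @export
solve_multitask_l21 <- function(designs, targets, config = solver_config(),
                                lambda = NULL) {
  M <- length(designs)
  K <- ncol(designs[[1L]])
  stopifnot(length(targets) == M,
            all(vapply(designs, ncol, 0L) == K))
  mode <- config$penalty_mode
  if (is.null(lambda))
    lambda <- config$lambda_ratio * lambda_max(designs, targets)

  obj <- function(W) {
    fit <- 0
    for (m in seq_len(M))
      fit <- fit + 0.5 * sum((targets[[m]] - designs[[m]] %*% W[, m])^2)
    fit + lambda * .penalty(W, mode)
  }
  grad <- function(W) {
    G <- matrix(0, K, M)
    for (m in seq_len(M))
      G[, m] <- crossprod(designs[[m]], designs[[m]] %*% W[, m] - targets[[m]])
    G
  }
  prox <- if (mode == "l21_multitask") .prox_l21 else .prox_l1
  L <- max(vapply(designs, function(X) {
    s <- svd(X, nu = 0, nv = 0)$d
    if (length(s)) s[1L]^2 else 0
  }, 0))
  if (L == 0) L <- 1

  W <- matrix(0, K, M)
  # exact boundary: if lambda is at or above the zero-solution threshold,
  # W = 0 is the certified minimizer (avoids one-ulp support leakage)
  G0 <- grad(W)
  thr0 <- if (mode == "l21_multitask") max(sqrt(rowSums(G0^2))) else max(abs(G0))
  if (lambda >= thr0 * (1 - 1e-12))
    return(structure(W, lambda = lambda, converged = TRUE, iterations = 0L,
                     kkt_residual = max(0, thr0 - lambda), objective = obj(W)))
  Z <- W
  th <- 1
  f_prev <- obj(W)
  stall <- 0L
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    W_new <- prox(Z - grad(Z) / L, lambda / L)
    f_new <- obj(W_new)
    if (f_new > f_prev) {          # monotone safeguard: restart momentum
      W_new <- prox(W - grad(W) / L, lambda / L)
      f_new <- obj(W_new)
      th <- 1
    }
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    Z <- W_new + ((th - 1) / th_new) * (W_new - W)
    th <- th_new
    rel <- abs(f_prev - f_new) / max(1, abs(f_prev))
    stall <- if (rel < config$tol) stall + 1L else 0L
    W <- W_new
    f_prev <- f_new
    kkt <- .kkt_residual(W, grad(W), lambda, mode)
    if (kkt < (config$kkt_tol %||% 1e-6)) { converged <- TRUE; break }
    if (stall >= 5L) { th <- 1; Z <- W; stall <- 0L }  # restart momentum
  }
  if (!converged)
    warning(sprintf("solver reached max_iter = %d (KKT residual %.2e); returning best iterate",
                    config$max_iter, .kkt_residual(W, grad(W), lambda, mode)))
  structure(W, lambda = lambda, converged = converged, iterations = it,
            kkt_residual = .kkt_residual(W, grad(W), lambda, mode),
            objective = f_prev)
}

#' Row support of a multi-task coefficient matrix
#'
#' @param W `K x M` coefficient matrix from [solve_multitask_l21()] (the
#'   prox produces exact zeros, so no epsilon threshold is applied).
#' @return integer 0/1 vector of length K; entry j is 1 iff row j has any
#'   nonzero coefficient.
#' @export
extract_support <- function(W) as.integer(rowSums(abs(W)) > 0)

#' Binary-to-decimal edge weight
#'
#' Reads the length-S support pattern of a region pair across PCs as a
#' binary number with PC 1 as the most significant bit, normalized by the
#' all-ones value: `bin2dec(v) / (2^S - 1)`. Top-ranking PCs therefore
#' dominate the weight.
#'
#' @param v binary vector of length S (entries 0/1), ordered PC1 first.
#' @return weight in `[0, 1]`.
#' @export
encode_weight <- function(v) {
  S <- length(v)
  if (S < 1L) stop("empty support vector")
  if (!all(v %in% c(0, 1))) stop("support vector must be binary")
  sum(v * 2^(S - seq_len(S))) / (2^S - 1)
}

#' Build one subject's multi-modal connectivity network
#'
#' For each target region k and PC index i: the PC-i projected matrices of
#' all regions (one `T x K` design per modality) are column-standardized
#' (z-score over replicates, then unit l2-norm), the target's own column is
#' fixed at zero, the target's centered projected vector serves as the
#' response of every task, and the multi-task regression is solved at
#' `lambda = lambda_ratio * lambda_max` for that problem. The S per-PC
#' supports of each regressor are encoded to a weight by [encode_weight()],
#' giving an asymmetric `K x K` matrix with zero diagonal and values on the
#' grid `{0, 1, ..., 2^S - 1} / (2^S - 1)`.
#'
#' @param projected a `projected_subject`.
#' @param config a [solver_config()].
#' @param S encoding length (number of PCs used; defaults to all
#'   projected PCs).
#' @return an `mmc_network`: list with `weights` (K x K), `support`
#'   (K x K x S binary array), `S`, and the solver config.
#' @export
build_network <- function(projected, config = solver_config(), S = projected$S) {
  stopifnot(inherits(projected, "projected_subject"))
  if (S > projected$S) stop("S exceeds the projected tensor depth")
  K <- length(projected$region_ids)
  M <- length(projected$tensors)
  single <- config$penalty_mode == "l1_single_task"
  mods <- seq_len(if (single && M > 1L) 1L else M)

  raw <- lapply(mods, function(m) projected$tensors[[m]])
  support <- array(0L, dim = c(K, K, S))
  for (i in seq_len(S)) {
    Xs <- lapply(raw, function(a) standardize_columns(a[, , i]))
    Yc <- lapply(raw, function(a) scale(a[, , i], center = TRUE, scale = FALSE))
    for (k in seq_len(K)) {
      designs <- lapply(Xs, function(X) { X[, k] <- 0; X })
      targets <- lapply(Yc, function(Y) as.numeric(Y[, k]))
      lm <- lambda_max(designs, targets, exclude = k)
      if (lm == 0) next
      W <- suppressWarnings(
        solve_multitask_l21(designs, targets, config,
                            lambda = config$lambda_ratio * lm))
      support[k, , i] <- extract_support(W)
      support[k, k, i] <- 0L
    }
  }
  weights <- matrix(0, K, K,
                    dimnames = list(projected$region_ids, projected$region_ids))
  denom <- 2^S - 1
  pow <- 2^(S - seq_len(S))
  for (k in seq_len(K)) {
    w <- as.numeric(matrix(support[k, , ], K, S) %*% pow) / denom
    w[k] <- 0
    weights[k, ] <- w
  }
  structure(list(weights = weights, support = support, S = S,
                 config = config, region_ids = projected$region_ids),
            class = "mmc_network")
}

#' @export
print.mmc_network <- function(x, ...) {
  cat(sprintf("mmc_network: %d regions, S = %d, %.1f%% nonzero edges\n",
              nrow(x$weights), x$S,
              100 * mean(x$weights[row(x$weights) != col(x$weights)] > 0)))
  invisible(x)
}
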