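#' Projection configuration
#'
#' @param T_boot number of stratified bootstrap replicates (default 200).
#' @param S number of principal components retained per region.
#' @param seed integer RNG seed for the resampling.
#' @return a `projection_config` object.
#' @export
projection_config <- function(T_boot = 200L, S = 12L, seed = 1L) {
  if (T_boot < 1L) stop("T_boot must be >= 1")
  if (S < 1L) stop("S must be >= 1")
  structure(list(T_boot = as.integer(T_boot), S = as.integer(S),
                 seed = as.integer(seed)),
            class = "projection_config")
}

# deterministic orthonormal completion of a partial basis (n x r) to n x S:
# Gram-Schmidt on identity columns, used when a resample is rank-deficient.
.complete_basis <- function(V, S) {
  n <- nrow(V)
  j <- 1L
  while (ncol(V) < S && j <= n) {
    e <- numeric(n); e[j] <- 1
    r <- e - V %*% crossprod(V, e)
    nr <- sqrt(sum(r^2))
    if (nr > 1e-8) V <- cbind(V, r / nr)
    j <- j + 1L
  }
  V
}

# sign-align columns of V to reference R: flip so diag(crossprod) >= 0;
# exact-zero dot ties broken by forcing the largest-|loading| entry positive.
.sign_align <- function(V, R) {
  d <- colSums(V * R)
  for (i in seq_along(d)) {
    if (d[i] < 0) V[, i] <- -V[, i]
    else if (d[i] == 0) {
      im <- which.max(abs(V[, i]))
      if (V[im, i] < 0) V[, i] <- -V[, i]
    }
  }
  V
}

# top-S PCA eigenvectors (voxel space) of an n x p data matrix via SVD of
# the centered matrix; returns unit-norm columns ordered by descending
# eigenvalue, completing rank-deficient cases deterministically.
.pca_vectors <- function(X, S) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sv <- svd(Xc, nu = 0, nv = min(S, ncol(Xc)))
  keep <- sv$d[seq_len(ncol(sv$v))] > 1e-10
  V <- sv$v[, keep, drop = FALSE]
  low_rank <- ncol(V) < S
  if (low_rank) V <- .complete_basis(V, S)
  list(center = mu, vectors = V[, seq_len(S), drop = FALSE], low_rank = low_rank)
}

#' Fit a bagged per-region PCA basis on the auxiliary AD/NC cohort
#'
#' Draws `T_boot` stratified bootstrap resamples (n_AD subjects from AD and
#' n_NC from NC, with replacement; one resample shared by every region and
#' modality at replicate t) and computes, per (replicate, region, modality),
#' the bootstrap-sample mean and the top-S PCA eigenvectors of the voxel
#' covariance. Eigenvector signs are aligned to the full-sample reference
#' PCA so projections are comparable across replicates.
#'
#' @param aux a `regional_cohort` containing exactly groups AD and NC.
#' @param config a [projection_config()].
#' @return a `bagged_basis` object: `resample_idx` (`T_boot x n` subject
#'   indices), and per modality/region the `T_boot x n_k` centering matrix
#'   and `n_k x S x T_boot` eigenvector array.
#' @export
fit_bagged_basis <- function(aux, config) {
  stopifnot(inherits(aux, "regional_cohort"), inherits(config, "projection_config"))
  grp <- aux$metadata$group
  if (!setequal(unique(grp), c("AD", "NC")))
    stop("auxiliary cohort must contain exactly groups AD and NC")
  S <- config$S; T_boot <- config$T_boot
  nv <- vapply(aux$data[[1L]], ncol, 0L)
  s_max <- min(min(nv), n_subjects(aux))
  if (S > s_max)
    stop(sprintf("S = %d infeasible; the smallest region supports at most S = %d", S, s_max))

  idx_ad <- which(grp == "AD"); idx_nc <- which(grp == "NC")
  set.seed(config$seed)
  resample_idx <- t(vapply(seq_len(T_boot), function(t)
    c(sample(idx_ad, length(idx_ad), replace = TRUE),
      sample(idx_nc, length(idx_nc), replace = TRUE)),
    integer(length(grp))))

  low_rank_events <- 0L
  basis <- lapply(aux$modalities, function(m) {
    per_region <- lapply(aux$region_ids, function(k) {
      X <- aux$data[[m]][[k]]
      ref <- .pca_vectors(X, S)$vectors
      center <- matrix(0, T_boot, ncol(X))
      vectors <- array(0, dim = c(ncol(X), S, T_boot))
      for (t in seq_len(T_boot)) {
        p <- .pca_vectors(X[resample_idx[t, ], , drop = FALSE], S)
        if (p$low_rank) low_rank_events <<- low_rank_events + 1L
        center[t, ] <- p$center
        vectors[, , t] <- .sign_align(p$vectors, ref)
      }
      list(center = center, vectors = vectors, reference = ref)
    })
    names(per_region) <- aux$region_ids
    per_region
  })
  names(basis) <- aux$modalities
  if (low_rank_events > 0L)
    warning(sprintf("%d rank-deficient resamples completed with a deterministic orthonormal basis",
                    low_rank_events))
  structure(list(basis = basis, resample_idx = resample_idx,
                 T_boot = T_boot, S = S, seed = config$seed,
                 modalities = aux$modalities, region_ids = aux$region_ids,
                 voxels_per_region = nv),
            class = "bagged_basis")
}

#' @export
print.bagged_basis <- function(x, ...) {
  cat(sprintf("bagged_basis: T = %d replicates, S = %d PCs, %d regions, modalities [%s]\n",
              x$T_boot, x$S, length(x$region_ids),
              paste(x$modalities, collapse = ", ")))
  invisible(x)
}

#' Project one target-domain subject onto a bagged basis
#'
#' For each modality m, region k, replicate t and PC index i, computes
#' `dot(eigenvector(t,k,m,i), x_k - centering(t,k,m))`, yielding a
#' `T_boot x K x S` tensor per modality. Slice `[, , i]` is the design
#' matrix for the PC-i region-wise regressions.
#'
#' @param cohort a `regional_cohort` (target domain).
#' @param subject index of the subject row to project.
#' @param basis a `bagged_basis` fit on the auxiliary cohort.
#' @param S number of PCs to use (defaults to the basis S; must not exceed it).
#' @return a `projected_subject`: named list per modality of
#'   `T_boot x K x S` arrays.
#' @export
project_subject <- function(cohort, subject, basis, S = basis$S) {
  stopifnot(inherits(basis, "bagged_basis"))
  if (S > basis$S) stop("S exceeds the stored basis S")
  K <- length(basis$region_ids)
  out <- lapply(basis$modalities, function(m) {
    tensor <- array(0, dim = c(basis$T_boot, K, S))
    for (ki in seq_len(K)) {
      k <- basis$region_ids[ki]
      x <- as.numeric(cohort$data[[m]][[k]][subject, ])
      b <- basis$basis[[m]][[k]]
      if (length(x) != nrow(b$vectors))
        stop(sprintf("voxel-count mismatch in region %s: subject has %d, basis expects %d",
                     k, length(x), nrow(b$vectors)))
      diffs <- matrix(x, basis$T_boot, length(x), byrow = TRUE) - b$center
      for (t in seq_len(basis$T_boot))
        tensor[t, ki, ] <- crossprod(matrix(b$vectors[, seq_len(S), t], ncol = S),
                                     diffs[t, ])
    }
    tensor
  })
  names(out) <- basis$modalities
  structure(list(tensors = out, S = S, T_boot = basis$T_boot,
                 region_ids = basis$region_ids),
            class = "projected_subject")
}
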