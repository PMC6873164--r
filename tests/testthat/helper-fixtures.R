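# Shared fixture builders. Everything is generated in code at test time.

# a tiny hand-rolled cohort: K regions, n subjects per group label vector
tiny_cohort <- function(K = 3L, n_vox = c(4L, 5L, 6L),
                        groups = c("AD", "AD", "NC", "NC"), seed = 1L) {
  set.seed(seed)
  n <- length(groups)
  data <- lapply(c(structural = "structural", metabolic = "metabolic"),
                 function(m) {
    out <- lapply(seq_len(K), function(k)
      matrix(rnorm(n * n_vox[k]), n, n_vox[k]))
    names(out) <- as.character(seq_len(K))
    out
  })
  regional_cohort(data, data.frame(
    subject_id = sprintf("s%02d", seq_len(n)), group = groups,
    age = 70 + seq_len(n), sex = rep(c("M", "F"), length.out = n)))
}

# small simulated study reused across tests (memoised per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_study(simulation_config(
        K = 10L, voxels_per_region = c(10L, 15L),
        group_sizes = c(20L, 20L, 12L, 12L),
        couplings = data.frame(region_a = c(1L, 3L), region_b = c(2L, 4L),
                               loading_structural = 1.5,
                               loading_metabolic = 1.5),
        seed = 77L))
    cache
  }
})

# random standardized design/target pair for solver tests: unit-norm,
# mean-centered columns so the closed-form BCD oracle applies
random_instance <- function(T_n = 30L, K = 6L, M = 2L, seed = 1L) {
  set.seed(seed)
  designs <- lapply(seq_len(M), function(m)
    apply(matrix(rnorm(T_n * K), T_n, K), 2L, function(v) {
      v <- v - mean(v); v / sqrt(sum(v^2))
    }))
  targets <- lapply(seq_len(M), function(m) rnorm(T_n))
  list(designs = designs, targets = targets)
}

# independent block-coordinate-descent group-lasso oracle (closed-form row
# updates; valid for unit-l2-norm columns), run to machine convergence
bcd_group_lasso <- function(designs, targets, lambda, max_sweeps = 50000L) {
  K <- ncol(designs[[1L]]); M <- length(designs)
  W <- matrix(0, K, M)
  r <- Map(function(X, m) targets[[m]] - X %*% W[, m], designs, seq_len(M))
  for (sweep in seq_len(max_sweeps)) {
    max_change <- 0
    for (j in seq_len(K)) {
      cn <- vapply(seq_len(M), function(m) sum(designs[[m]][, j]^2), 0)
      if (all(cn == 0)) next
      rho <- vapply(seq_len(M), function(m)
        sum(designs[[m]][, j] * r[[m]]) + W[j, m] * cn[m], 0)
      nrm <- sqrt(sum(rho^2))
      new_row <- if (nrm <= lambda) rep(0, M) else (1 - lambda / nrm) * rho
      max_change <- max(max_change, max(abs(new_row - W[j, ])))
      for (m in seq_len(M)) {
        r[[m]] <- r[[m]] - designs[[m]][, j] * (new_row[m] - W[j, m])
        W[j, m] <- new_row[m]
      }
    }
    if (max_change < 1e-15) break
  }
  W
}

l21_objective <- function(W, designs, targets, lambda) {
  fit <- sum(vapply(seq_along(designs), function(m)
    0.5 * sum((targets[[m]] - designs[[m]] %*% W[, m])^2), 0))
  fit + lambda * sum(sqrt(rowSums(W^2)))
}

# an arbitrary fixed unit pattern unrelated to any planted map
.unit_pattern_for_test <- function(n, seed) {
  set.seed(seed + 1000L)
  v <- rnorm(n); v <- v - mean(v)
  v / sqrt(sum(v^2))
}
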