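#' Simulation configuration for a synthetic two-domain study
#'
#' Defines a desk-scale emulation of a multi-modal MCI-conversion study: an
#' auxiliary AD/NC cohort and a target sMCI/pMCI cohort with (i) planted
#' AD-vs-NC mean shifts along per-region spatial effect patterns, attenuated
#' into the MCI subtypes, and (ii) cross-regional latent couplings shared by
#' both modalities, which are the connectivity ground truth the network
#' stage should recover.
#'
#' Effect maps are zero-mean unit-norm voxel patterns: disease effects are
#' modeled as sub-regional spatial redistribution rather than a uniform
#' regional shift, so regional mean values alone carry little group signal.
#'
#' @param K region count.
#' @param voxels_per_region length-2 integer range; each region's voxel
#'   count is drawn uniformly from it.
#' @param group_sizes named or positional integer vector
#'   `(n_AD, n_NC, n_sMCI, n_pMCI)`.
#' @param effect_size AD-vs-NC shift magnitude along each region's effect
#'   map, in units of `noise_sd`; scalar, or a `K x 2` matrix
#'   (columns structural, metabolic).
#' @param mci_attenuation pair `(a_sMCI, a_pMCI)` in `[0,1]`, scaling the
#'   AD-side shift for the MCI subtypes; must satisfy
#'   `0 <= a_sMCI <= a_pMCI <= 1`.
#' @param couplings data.frame with columns `region_a`, `region_b`,
#'   `loading_structural`, `loading_metabolic`: latent factors shared by a
#'   region pair across both modalities. `NULL` selects the frozen default
#'   (6 disjoint pairs, loadings 1.5).
#' @param noise_sd independent Gaussian voxel noise SD (> 0).
#' @param coupling_disease_delta disease modulation of connectivity: a
#'   subject with disease score a (1 = AD, 0 = NC, the attenuations for
#'   the MCI subtypes) expresses each coupling at
#'   `loading * (1 - delta * a)` — couplings weaken along the AD
#'   continuum, emulating the disconnection that makes connectivity
#'   features diagnostic. 0 disables the modulation.
#' @param modality_specific_couplings if `TRUE`, each coupling uses an
#'   independent latent per modality (ablation switch; breaks the
#'   cross-modal sharing the multi-task penalty exploits).
#' @param seed integer RNG seed.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(K = 30L,
                              voxels_per_region = c(20L, 40L),
                              group_sizes = c(AD = 60L, NC = 60L,
                                              sMCI = 40L, pMCI = 40L),
                              effect_size = 3,
                              mci_attenuation = c(0.2, 0.8),
                              couplings = NULL,
                              noise_sd = 0.3,
                              coupling_disease_delta = 0.9,
                              modality_specific_couplings = FALSE,
                              seed = 20191115L) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (length(group_sizes) != 4L || any(group_sizes < 2L))
    stop("group_sizes must be 4 counts, all >= 2")
  names(group_sizes) <- c("AD", "NC", "sMCI", "pMCI")
  a <- as.numeric(mci_attenuation)
  if (length(a) != 2L || a[1] < 0 || a[2] > 1 || a[1] > a[2])
    stop("mci_attenuation must satisfy 0 <= a_sMCI <= a_pMCI <= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(couplings)) {
    np <- min(6L, K %/% 2L)
    couplings <- data.frame(region_a = seq(1L, by = 2L, length.out = np),
                            region_b = seq(2L, by = 2L, length.out = np),
                            loading_structural = 1.5,
                            loading_metabolic = 1.5)
  }
  couplings <- as.data.frame(couplings)
  if (nrow(couplings) &&
      any(c(couplings$region_a, couplings$region_b) > K |
          c(couplings$region_a, couplings$region_b) < 1L))
    stop("coupling names a region outside 1..K")
  if (is.matrix(effect_size)) {
    if (!all(dim(effect_size) == c(K, 2L)))
      stop("matrix effect_size must be K x 2")
  } else {
    effect_size <- matrix(as.numeric(effect_size), K, 2L)
  }
  colnames(effect_size) <- c("structural", "metabolic")
  structure(list(K = K, voxels_per_region = as.integer(voxels_per_region),
                 group_sizes = group_sizes, effect_size = effect_size,
                 mci_attenuation = c(a_sMCI = a[1], a_pMCI = a[2]),
                 couplings = couplings, noise_sd = noise_sd,
                 coupling_disease_delta = coupling_disease_delta,
                 modality_specific_couplings = modality_specific_couplings,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# zero-mean unit-l2-norm random voxel pattern
.unit_pattern <- function(n) {
  v <- rnorm(n)
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic auxiliary + target study
#'
#' Voxel model for subject s, region k, modality m:
#' `baseline_{k,m} + g_s * effect_size_{k,m} * noise_sd * effect_map_{k,m}
#'  + sum over couplings through k of
#'  z_{s,c} * loading_{c,m} * (1 - delta * g_s) * coupling_map
#'  + N(0, noise_sd^2)`,
#' where `g_s` is 1 for AD, 0 for NC, `a_sMCI`/`a_pMCI` for the MCI
#' subtypes, `z_{s,c}` is a per-subject standard-normal latent shared by
#' the coupled pair in both modalities (the connectivity ground truth),
#' and `delta` is the disease modulation of coupling strength.
#'
#' @param config a [simulation_config()].
#' @return list with `aux` (AD+NC `regional_cohort`), `target`
#'   (sMCI+pMCI), and `truth` (list: `adjacency` K x K binary symmetric,
#'   `effect_maps`, `coupling_maps`, per-subject latents).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  K <- config$K
  vox_range <- seq.int(config$voxels_per_region[1], config$voxels_per_region[2])
  nv <- vox_range[sample.int(length(vox_range), K, replace = TRUE)]
  modalities <- c("structural", "metabolic")
  base_range <- list(structural = c(0.4, 0.8), metabolic = c(0.9, 1.5))

  baselines <- effect_maps <- list()
  for (m in modalities) {
    baselines[[m]] <- lapply(nv, function(n)
      stats::runif(1, base_range[[m]][1], base_range[[m]][2]) + 0.05 * rnorm(n))
    effect_maps[[m]] <- lapply(nv, .unit_pattern)
  }
  cpl <- config$couplings
  coupling_maps <- list()
  if (nrow(cpl)) for (c_i in seq_len(nrow(cpl))) {
    for (m in modalities) {
      coupling_maps[[paste(c_i, m, "a", sep = ".")]] <- .unit_pattern(nv[cpl$region_a[c_i]])
      coupling_maps[[paste(c_i, m, "b", sep = ".")]] <- .unit_pattern(nv[cpl$region_b[c_i]])
    }
  }

  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  n_all <- sum(gs)
  g_shift <- c(AD = 1, NC = 0,
               sMCI = unname(config$mci_attenuation["a_sMCI"]),
               pMCI = unname(config$mci_attenuation["a_pMCI"]))[groups]
  # latents: one per (subject, coupling) shared across modalities, or one
  # per modality in the ablation mode
  nz <- if (config$modality_specific_couplings) 2L else 1L
  z <- array(rnorm(n_all * max(1L, nrow(cpl)) * nz),
             dim = c(n_all, max(1L, nrow(cpl)), nz))

  data <- lapply(modalities, function(m) {
    mi <- match(m, modalities)
    out <- vector("list", K)
    for (k in seq_len(K)) {
      mat <- matrix(rep(baselines[[m]][[k]], each = n_all), n_all, nv[k])
      mat <- mat + outer(g_shift * config$effect_size[k, m] * config$noise_sd,
                         effect_maps[[m]][[k]])
      if (nrow(cpl)) for (c_i in seq_len(nrow(cpl))) {
        side <- if (cpl$region_a[c_i] == k) "a" else if (cpl$region_b[c_i] == k) "b" else next
        loading <- cpl[[paste0("loading_", m)]][c_i] *
          (1 - config$coupling_disease_delta * g_shift)
        zc <- z[, c_i, if (config$modality_specific_couplings) mi else 1L]
        mat <- mat + outer(zc * loading,
                           coupling_maps[[paste(c_i, m, side, sep = ".")]])
      }
      mat <- mat + matrix(rnorm(n_all * nv[k], sd = config$noise_sd), n_all, nv[k])
      out[[k]] <- mat
    }
    names(out) <- as.character(seq_len(K))
    out
  })
  names(data) <- modalities

  metadata <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_all)),
    group = groups,
    age = round(stats::rnorm(n_all, 75, 6), 1),
    sex = sample(c("M", "F"), n_all, replace = TRUE),
    stringsAsFactors = FALSE)

  cohort <- regional_cohort(data, metadata)
  adjacency <- matrix(0L, K, K)
  if (nrow(cpl)) {
    adjacency[cbind(cpl$region_a, cpl$region_b)] <- 1L
    adjacency[cbind(cpl$region_b, cpl$region_a)] <- 1L
  }
  list(aux = subset_cohort(cohort, c("AD", "NC")),
       target = subset_cohort(cohort, c("sMCI", "pMCI")),
       truth = list(adjacency = adjacency, effect_maps = effect_maps,
                    coupling_maps = coupling_maps, latents = z,
                    voxels_per_region = nv))
}
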