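#' Atlas specification
#'
#' Describes a parcellation: the ordered set of positive integer region
#' labels and optional region names. Label 0 is reserved for background.
#'
#' @param region_ids integer vector of unique, strictly positive labels.
#'   Labels need not be contiguous.
#' @param region_names optional character vector, same length.
#' @return An `atlas_spec` object with fields `region_ids`, `region_names`
#'   and `K` (region count).
#' @export
atlas_spec <- function(region_ids, region_names = NULL) {
  region_ids <- as.integer(region_ids)
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  if (any(region_ids <= 0L)) stop("region_ids must be strictly positive (0 is background)")
  if (length(region_ids) < 2L) stop("an atlas needs at least 2 regions")
  if (!is.null(region_names) && length(region_names) != length(region_ids))
    stop("region_names must match region_ids in length")
  structure(list(region_ids = region_ids,
                 region_names = region_names %||% paste0("R", region_ids),
                 K = length(region_ids)),
            class = "atlas_spec")
}

#' Construct a regional cohort container
#'
#' The universal input type: per (modality, region) a subjects x voxels
#' matrix of values (gray-matter volume density or normalized FDG uptake),
#' aligned to one metadata table. Subject row order is identical across all
#' modalities and regions; voxel columns follow a fixed ascending
#' linear-index order declared at extraction time.
#'
#' @param data named list, one entry per modality (default order
#'   `structural`, `metabolic`); each entry a named list of numeric
#'   matrices keyed by region id, each `n_subjects x n_voxels`.
#' @param metadata data.frame with columns `subject_id`, `group`
#'   (AD/NC/sMCI/pMCI), `age`, `sex` (M/F).
#' @param axis_order character scalar recorded for provenance; linear
#'   voxel indices are taken in this axis order (default column-major
#'   "xyz", R's native array order).
#' @return A `regional_cohort` object.
#' @export
regional_cohort <- function(data, metadata, axis_order = "xyz") {
  stopifnot(is.list(data), length(data) >= 1L)
  modalities <- names(data)
  if (is.null(modalities) || any(!nzchar(modalities)))
    stop("modalities must be named")
  region_ids <- names(data[[1L]])
  n <- nrow(metadata)
  for (m in modalities) {
    if (!identical(names(data[[m]]), region_ids))
      stop("all modalities must share the same region set and order")
    for (k in region_ids) {
      x <- data[[m]][[k]]
      if (!is.matrix(x) || nrow(x) != n)
        stop(sprintf("region %s / modality %s: expected a matrix with %d rows", k, m, n))
      if (ncol(x) < 1L) stop(sprintf("region %s has zero voxels", k))
      if (!all(is.finite(x))) stop(sprintf("non-finite values in region %s / %s", k, m))
    }
  }
  md <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "sex")
  if (!all(req %in% names(md))) stop("metadata needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(md$subject_id)) stop("subject_ids must be unique")
  bad <- setdiff(unique(md$group), c("AD", "NC", "sMCI", "pMCI"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  structure(list(data = data,
                 metadata = md,
                 modalities = modalities,
                 region_ids = region_ids,
                 axis_order = axis_order),
            class = "regional_cohort")
}

#' @export
print.regional_cohort <- function(x, ...) {
  nv <- vapply(x$data[[1L]], ncol, 0L)
  cat(sprintf("regional_cohort: %d subjects, %d regions, modalities [%s]\n",
              nrow(x$metadata), length(x$region_ids),
              paste(x$modalities, collapse = ", ")))
  cat(sprintf("  voxels/region: %d-%d; groups: %s\n", min(nv), max(nv),
              paste(sprintf("%s=%d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = " ")))
  invisible(x)
}

#' Number of subjects / regions in a cohort
#' @param cohort a `regional_cohort`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$metadata)

#' @rdname n_subjects
#' @export
n_regions <- function(cohort) length(cohort$region_ids)

#' Subset a cohort by subject
#'
#' @param cohort a `regional_cohort`.
#' @param idx integer or logical subject index, or a character vector of
#'   group labels to keep.
#' @return a `regional_cohort` with the selected subject rows, orderings
#'   preserved.
#' @export
subset_cohort <- function(cohort, idx) {
  if (is.character(idx)) idx <- cohort$metadata$group %in% idx
  data <- lapply(cohort$data, function(mod)
    lapply(mod, function(x) x[idx, , drop = FALSE]))
  regional_cohort(data, cohort$metadata[idx, , drop = FALSE],
                  axis_order = cohort$axis_order)
}

#' Extract regional voxel matrices from volumes using an atlas
#'
#' Masks each subject's 3-D volume with an integer label volume on the same
#' grid. Region k's columns are the voxel values where `atlas == k`, in
#' ascending linear index (column-major) order, identically for every
#' subject and modality.
#'
#' @param volumes named list per modality; each entry a list of per-subject
#'   3-D arrays (or file paths to NIfTI volumes, read via RNifti).
#' @param atlas integer 3-D label array (or NIfTI path) on the same grid;
#'   0 = background.
#' @param spec an [atlas_spec()]; every nonzero atlas label must be one of
#'   its `region_ids`.
#' @param metadata cohort metadata data.frame (see [regional_cohort()]).
#' @return a `regional_cohort`.
#' @export
extract_regional_data <- function(volumes, atlas, spec, metadata) {
  if (is.character(atlas)) atlas <- as.array(RNifti::readNifti(atlas))
  atlas <- as.array(atlas)
  labs <- sort(unique(as.vector(atlas)))
  extra <- setdiff(labs, c(0L, spec$region_ids))
  if (length(extra)) stop("atlas contains labels outside the spec: ",
                          paste(extra, collapse = ", "))
  masks <- lapply(spec$region_ids, function(k) which(atlas == k))
  names(masks) <- as.character(spec$region_ids)
  empty <- names(masks)[lengths(masks) == 0L]
  if (length(empty)) stop("region(s) with zero voxels in the atlas: ",
                          paste(empty, collapse = ", "))
  data <- lapply(volumes, function(vols) {
    rows <- lapply(vols, function(v) {
      if (is.character(v)) v <- as.array(RNifti::readNifti(v))
      v <- as.array(v)
      if (!identical(dim(v), dim(atlas)))
        stop(sprintf("volume grid %s does not match atlas grid %s",
                     paste(dim(v), collapse = "x"),
                     paste(dim(atlas), collapse = "x")))
      lapply(masks, function(ix) as.numeric(v[ix]))
    })
    lapply(names(masks), function(k)
      do.call(rbind, lapply(rows, `[[`, k))) |> stats::setNames(names(masks))
  })
  regional_cohort(data, metadata)
}

# ---- cohort container I/O ------------------------------------------------
# Directory container: header.json (modalities, region ids, voxel counts,
# axis order), metadata.tsv, and <modality>.tsv holding the subjects x
# total-voxels matrix with regions as contiguous column blocks. Values are
# written as %.17g so the round trip is exact for doubles.

#' Write / read a regional cohort container
#'
#' `write_cohort()` serializes a cohort to a directory with a JSON header,
#' a tab-separated metadata table and one full-precision TSV value matrix
#' per modality. `read_cohort()` inverts it losslessly (bit-for-bit in
#' values, orderings and metadata).
#'
#' @param cohort a `regional_cohort`.
#' @param path directory to create (write) or read.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` a
#'   `regional_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "regional_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nv <- vapply(cohort$data[[1L]], ncol, 0L)
  header <- list(format = "mmcnet-cohort", version = 1L,
                 modalities = cohort$modalities,
                 region_ids = cohort$region_ids,
                 voxels_per_region = as.integer(nv),
                 axis_order = cohort$axis_order,
                 n_subjects = n_subjects(cohort))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(cohort$metadata, file.path(path, "metadata.tsv"),
                     sep = "\t")
  for (m in cohort$modalities) {
    flat <- do.call(cbind, cohort$data[[m]])
    con <- file(file.path(path, paste0(m, ".tsv")), "w")
    writeLines(apply(flat, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a cohort container (missing header.json): ", path)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  for (fld in c("modalities", "region_ids", "voxels_per_region"))
    if (is.null(header[[fld]])) stop("malformed header: missing field ", fld)
  md <- as.data.frame(data.table::fread(
    file.path(path, "metadata.tsv"),
    sep = "\t", colClasses = list(character = c("subject_id", "group", "sex"),
                                  double = "age")))
  nv <- as.integer(header$voxels_per_region)
  ends <- cumsum(nv); starts <- ends - nv + 1L
  data <- lapply(header$modalities, function(m) {
    f <- file.path(path, paste0(m, ".tsv"))
    if (!file.exists(f)) stop("malformed container: missing modality group '", m, "'")
    flat <- as.matrix(data.table::fread(f, sep = "\t", header = FALSE))
    dimnames(flat) <- NULL
    out <- lapply(seq_along(nv), function(i)
      flat[, starts[i]:ends[i], drop = FALSE])
    names(out) <- as.character(header$region_ids)
    out
  })
  names(data) <- header$modalities
  regional_cohort(data, md, axis_order = header$axis_order %||% "xyz")
}

#' Export a connectivity matrix as TSV with region-id headers
#'
#' @param mat K x K numeric matrix with region ids as dimnames.
#' @param path output file.
#' @export
write_network_tsv <- function(mat, path) {
  dt <- data.table::as.data.table(mat, keep.rownames = "region")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
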