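#' Construct a label volume
#'
#' A `label_volume` couples a 3D array of non-negative integer labels with
#' its physical voxel geometry. Label 0 is background; every positive label
#' marks node tissue. All downstream measurements are taken in physical
#' millimetres using `spacing`, on the two in-plane axes orthogonal to
#' `axial_axis` (measurements are in-plane, mirroring axial DWI reading).
#'
#' @param voxels 3D array of non-negative integers (logical accepted and
#'   coerced to 0/1).
#' @param spacing numeric length-3, physical voxel size in mm per array
#'   axis; all components must be positive.
#' @param axial_axis which array axis is the slice (inferior-superior)
#'   axis; default 3.
#' @param source_id free-text provenance tag (patient, timepoint, reader).
#' @return An object of class `label_volume` with elements `voxels`,
#'   `spacing`, `axial_axis`, `source_id`.
#' @examples
#' arr <- array(0L, c(8, 8, 4)); arr[3:5, 3:5, 2] <- 1L
#' vol <- label_volume(arr, spacing = c(1.75, 1.75, 4))
#' @export
label_volume <- function(voxels, spacing, axial_axis = 3L, source_id = "") {
  if (is.logical(voxels)) storage.mode(voxels) <- "integer"
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (is.double(voxels)) {
    if (max(abs(voxels - round(voxels)), 0) > 1e-6)
      stop("non-integer label values in volume", call. = FALSE)
    voxels <- round(voxels)
    storage.mode(voxels) <- "integer"
  }
  if (any(voxels < 0L)) stop("labels must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) stop("`axial_axis` must be 1, 2 or 3", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, axial_axis = axial_axis,
         source_id = as.character(source_id)[1]),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(x$voxels[x$voxels > 0L]))
  cat(sprintf(
    "label_volume [%s] %s, spacing %s mm, axial axis %d, %d label(s)\n",
    x$source_id, paste(dim(x$voxels), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    x$axial_axis, length(labs)))
  invisible(x)
}

in_plane_axes <- function(volume) setdiff(1:3, volume$axial_axis)

voxel_volume_mm3 <- function(volume) prod(volume$spacing)

#' Read a 3D label volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` image, validates that it is 3D with
#' integer-valued voxels (floating-point storage is accepted when every
#' value is a whole number within 1e-6), and takes voxel spacing from the
#' header `pixdim`.
#'
#' @param path file path to a NIfTI image.
#' @param axial_axis array axis treated as the slice axis (default 3).
#' @param source_id provenance tag; defaults to the file name.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, axial_axis = 3L, source_id = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("cannot read label volume '%s': file not found", path),
         call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read label volume '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  dims <- dim(img)
  if (length(dims) != 3L)
    stop(sprintf("label volume '%s' is %dD, expected 3D", path, length(dims)),
         call. = FALSE)
  vox <- as.array(img)
  vox <- array(as.vector(vox), dim(vox))   # drop NIfTI attributes
  if (is.double(vox) && max(abs(vox - round(vox)), 0) > 1e-6)
    stop(sprintf("label volume '%s' contains non-integer label values", path),
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("label volume '%s' has missing/zero voxel spacing", path),
         call. = FALSE)
  label_volume(vox, spacing = sp, axial_axis = axial_axis,
               source_id = source_id)
}

#' Write a label volume to a NIfTI file
#'
#' Integer voxel data and header spacing round-trip bit-exactly through
#' [read_label_volume()].
#'
#' @param volume a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

## 26- or 6-neighbourhood linear offsets in an array padded by one voxel on
## every side, so frontier expansion never walks off the grid.
neighbour_offsets <- function(pdim, connectivity) {
  steps <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  steps <- steps[!(steps$di == 0 & steps$dj == 0 & steps$dk == 0), ]
  if (connectivity == 6L)
    steps <- steps[abs(steps$di) + abs(steps$dj) + abs(steps$dk) == 1L, ]
  as.integer(steps$di + steps$dj * pdim[1] + steps$dk * pdim[1] * pdim[2])
}

## Connected-component labelling of a logical 3D array by vectorised
## frontier flood fill. Returns an integer array of component ids (0 =
## background), ids in discovery order (first seed = smallest linear index).
flood_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  pdim <- d + 2L
  padded <- array(FALSE, pdim)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  labels <- array(0L, pdim)
  offs <- neighbour_offsets(pdim, connectivity)
  todo <- which(padded)
  comp <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    comp <- comp + 1L
    labels[seed] <- comp
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[padded[nb] & labels[nb] == 0L]
      labels[nb] <- comp
      frontier <- nb
    }
  }
  labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

node_object <- function(node_id, idx, volume) {
  centre <- (colMeans(idx) - 0.5) * volume$spacing
  structure(
    list(node_id = as.integer(node_id),
         voxel_idx = idx,
         n_voxels = nrow(idx),
         volume_mm3 = nrow(idx) * voxel_volume_mm3(volume),
         centroid_mm = as.numeric(centre)),
    class = "node_object")
}

#' @export
print.node_object <- function(x, ...) {
  cat(sprintf("node %d: %d voxels, %.1f mm3, centroid (%s) mm\n",
              x$node_id, x$n_voxels, x$volume_mm3,
              paste(sprintf("%.1f", x$centroid_mm), collapse = ", ")))
  invisible(x)
}

#' Extract discrete node objects from a label volume
#'
#' With `relabel = FALSE` each distinct positive label is one node —
#' upstream instance labels are trusted, and a label split into several
#' disconnected blobs stays one object. With `relabel = TRUE` connected
#' components over all foreground define the objects (26-connectivity by
#' default: nodes are compact blobs and face-edge-corner adjacency avoids
#' spurious splits across thick slices), with ids reassigned in descending
#' volume order, ties broken by the lexicographically smallest voxel index.
#'
#' @param volume a [label_volume()].
#' @param connectivity 26 (default) or 6; only used when relabelling.
#' @param relabel logical; run connected-component labelling over all
#'   foreground instead of trusting the stored labels.
#' @param min_voxels discard objects smaller than this many voxels
#'   (default 2: single-voxel specks are segmentation noise and not
#'   measurable in-plane). Set to 1 to keep everything.
#' @return List of `node_object`s sorted by `node_id`; empty foreground
#'   gives an empty list. Each node carries its voxel index matrix
#'   (`voxel_idx`, rows of (i,j,k)), voxel count, physical volume in mm3
#'   and physical centroid in mm.
#' @export
extract_nodes <- function(volume, connectivity = 26L, relabel = FALSE,
                          min_voxels = 2L) {
  stopifnot(inherits(volume, "label_volume"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  vox <- volume$voxels
  if (relabel) {
    comp <- flood_components(vox > 0L, connectivity)
    vox <- comp
  }
  labs <- sort(unique(vox[vox > 0L]))
  if (!length(labs)) return(list())
  nodes <- lapply(labs, function(l) {
    idx <- which(vox == l, arr.ind = TRUE)
    ## lexicographic (i, j, k) order; which() returns ascending linear
    ## index, i.e. k-major — reorder for a stable, axis-wise ordering
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
    node_object(l, idx, volume)
  })
  nodes <- Filter(function(n) n$n_voxels >= min_voxels, nodes)
  if (!length(nodes)) return(list())
  if (relabel) {
    ## descending volume; ties by smallest first voxel index (lexicographic)
    key <- vapply(nodes, function(n)
      paste(sprintf("%012.3f", 1e9 - n$volume_mm3),
            paste(sprintf("%05d", n$voxel_idx[1, ]), collapse = ""),
            sep = "|"), character(1))
    nodes <- nodes[order(key)]
    for (i in seq_along(nodes)) nodes[[i]]$node_id <- i
  }
  nodes[order(vapply(nodes, `[[`, integer(1), "node_id"))]
}
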