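#' Synthetic ellipsoid brain mask
#'
#' Axis-aligned ellipsoid filling 80\% of each grid dimension, for testing
#' the voxel mapping without a real MRI segmentation.
#'
#' @param dim integer grid dimensions (length 3).
#' @return Logical 3-D array.
#' @export
ellipsoid_mask <- function(dim = c(40L, 40L, 40L)) {
  ctr <- (dim + 1) / 2
  semi <- 0.4 * dim
  i <- slice.index(array(0, dim), 1L)
  j <- slice.index(array(0, dim), 2L)
  k <- slice.index(array(0, dim), 3L)
  ((i - ctr[1])^2 / semi[1]^2 + (j - ctr[2])^2 / semi[2]^2 +
      (k - ctr[3])^2 / semi[3]^2) <= 1
}

#' Interpolate contact SOZ probabilities onto a voxel grid
#'
#' Brain-boundary voxels (in-mask voxels touching the outside) are set to
#' the lowest predicted probability; voxels within `radius_vox` voxels of a
#' contact take that contact's probability (the nearest contact wins on
#' overlap); every other in-mask voxel is a Gaussian-kernel weighted convex
#' combination of the contact probabilities and the boundary value, so the
#' whole map lies within `[min(probabilities), max(probabilities)]`.
#' Out-of-mask voxels carry the boundary value.
#'
#' @param coords numeric matrix `n x 3` of contact positions, mm.
#' @param probabilities SOZ probabilities in `[0, 1]`, one per contact.
#' @param mask logical 3-D array brain mask.
#' @param voxel_mm voxel edge length, mm.
#' @param kernel_sigma Gaussian kernel width, mm.
#' @param radius_vox contact neighbourhood radius, voxels.
#' @param boundary_subsample keep every k-th boundary voxel as a kernel
#'   anchor (the boundary contributes one pooled anchor distance).
#' @return An object of class `soz_voxelmap`: `values` (3-D array),
#'   `voxel_mm`, `mask`.
#' @export
scores_to_voxelmap <- function(coords, probabilities, mask, voxel_mm = 1,
                               kernel_sigma = 5, radius_vox = 2,
                               boundary_subsample = 7L) {
  coords <- as.matrix(coords)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  dims <- dim(mask)
  vox <- round(coords / voxel_mm)   # 1-based voxel indices
  inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  inside[inside] <- mask[vox[inside, , drop = FALSE]]
  if (!all(inside))
    stop("contact(s) outside the brain mask: ",
         paste(which(!inside), collapse = ", "))
  p_min <- min(probabilities)

  # boundary = in-mask voxels with an out-of-mask 6-neighbour
  shift <- function(a, d, by) {
    out <- array(FALSE, dims)
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[d]] <- (1 + by):dims[d]; idx_src[[d]] <- 1:(dims[d] - by) }
    else { idx_dst[[d]] <- 1:(dims[d] + by); idx_src[[d]] <- (1 - by):dims[d] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  outside_any <- array(FALSE, dims)
  for (d in 1:3) for (by in c(-1, 1))
    outside_any <- outside_any | !shift(mask, d, by)
  boundary <- mask & outside_any

  grid_idx <- which(mask, arr.ind = TRUE)
  gx <- grid_idx * voxel_mm
  # squared distances voxels x contacts
  d2 <- outer(rowSums(gx^2), rep(1, nrow(coords))) -
    2 * gx %*% t(coords) + outer(rep(1, nrow(gx)), rowSums(coords^2))
  d2[d2 < 0] <- 0

  bidx <- which(boundary, arr.ind = TRUE)
  bsub <- bidx[seq(1L, nrow(bidx), by = max(1L, boundary_subsample)), ,
               drop = FALSE] * voxel_mm
  # distance of every in-mask voxel to the nearest (subsampled) boundary voxel
  db2 <- rep(Inf, nrow(gx))
  block <- 200L
  for (b0 in seq(1L, nrow(bsub), by = block)) {
    bb <- bsub[b0:min(b0 + block - 1L, nrow(bsub)), , drop = FALSE]
    dd <- outer(rowSums(gx^2), rep(1, nrow(bb))) - 2 * gx %*% t(bb) +
      outer(rep(1, nrow(gx)), rowSums(bb^2))
    db2 <- pmin(db2, apply(dd, 1L, min))
  }

  w <- exp(-cbind(d2, db2) / (2 * kernel_sigma^2))
  vals_anchor <- c(probabilities, p_min)
  values_in <- as.numeric(w %*% vals_anchor / rowSums(w))

  # contact neighbourhoods: nearest contact wins
  near <- sqrt(apply(d2, 1L, min)) <= radius_vox * voxel_mm
  nearest <- apply(d2, 1L, which.min)
  values_in[near] <- probabilities[nearest[near]]
  # boundary voxels pinned to the minimum
  bflag <- boundary[mask]
  values_in[bflag] <- p_min

  values <- array(p_min, dims)
  values[mask] <- values_in
  structure(list(values = values, voxel_mm = voxel_mm, mask = mask),
            class = "soz_voxelmap")
}

#' Write a voxel map as NIfTI
#'
#' @param voxelmap a [scores_to_voxelmap()] result.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(voxelmap, path) {
  img <- RNifti::asNifti(voxelmap$values)
  RNifti::pixdim(img) <- rep(voxelmap$voxel_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       voxel_mm = RNifti::pixdim(img)[1L])
}
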