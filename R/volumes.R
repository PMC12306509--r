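#' Construct a cohort volume collection
#'
#' Holds one 3D gray-matter volume per subject on a common grid, stored as a
#' subjects-by-voxels matrix in column-major (Fortran) voxel order, together
#' with the grid dimensions and the isotropic voxel size in millimetres.
#'
#' @param data numeric matrix, subjects in rows, `prod(dims)` voxels in columns.
#' @param dims integer triple of grid dimensions.
#' @param voxel_mm positive scalar, isotropic voxel edge length in mm.
#' @param subject_ids character vector of subject identifiers (rownames).
#' @return An object of class `cohort_volumes`.
#' @export
cohort_volumes <- function(data, dims, voxel_mm, subject_ids = rownames(data)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims > 0L), is.matrix(data),
            ncol(data) == prod(dims), voxel_mm > 0)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(nrow(data)))
  rownames(data) <- subject_ids
  structure(list(data = data, dims = dims, voxel_mm = as.numeric(voxel_mm)),
            class = "cohort_volumes")
}

#' @export
print.cohort_volumes <- function(x, ...) {
  cat(sprintf("<cohort_volumes> %d subjects on a %s grid (%.2f mm voxels)\n",
              nrow(x$data), paste(x$dims, collapse = "x"), x$voxel_mm))
  invisible(x)
}

#' @export
dim.cohort_volumes <- function(x) c(nrow(x$data), x$dims)

#' Number of subjects in a cohort volume collection
#' @param x a `cohort_volumes` object.
#' @return integer count of subjects.
#' @export
n_subjects <- function(x) nrow(x$data)

#' Subset subjects of a cohort volume collection
#' @param x a `cohort_volumes` object.
#' @param i subject index (integer, logical, or character ids).
#' @param ... ignored.
#' @return A `cohort_volumes` with the selected subjects.
#' @export
`[.cohort_volumes` <- function(x, i, ...) {
  cohort_volumes(x$data[i, , drop = FALSE], x$dims, x$voxel_mm)
}

#' Extract one subject's volume as a 3D array
#' @param x a `cohort_volumes` object.
#' @param subject subject row index or id.
#' @return 3D numeric array of grid dimensions.
#' @export
subject_volume <- function(x, subject) {
  array(x$data[subject, ], dim = x$dims)
}

#' The RAS affine implied by an isotropic voxel grid
#'
#' Voxel indices are 0-based; the affine maps index (i,j,k,1) to mm
#' coordinates with the grid corner at the origin.
#'
#' @param voxel_mm isotropic voxel size in mm.
#' @return 4x4 numeric affine matrix.
#' @export
grid_affine <- function(voxel_mm) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a
}

#' Voxel index to mm coordinates
#' @param ijk matrix (or vector) of 0-based voxel indices, one row per voxel.
#' @param voxel_mm isotropic voxel size in mm.
#' @return matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, voxel_mm) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  ijk * voxel_mm
}

# 0-based (i,j,k) coordinates of linear voxel indices on a grid
voxel_coords <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i = i, j = j, k = k)
}

# linear index from 0-based coordinates; NA outside the grid
coords_to_index <- function(ijk, dims) {
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
        ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
        ijk[, 3] >= 0 & ijk[, 3] < dims[3]
  out <- rep(NA_integer_, nrow(ijk))
  out[ok] <- 1L + ijk[ok, 1] + dims[1] * (ijk[ok, 2] + dims[2] * ijk[ok, 3])
  out
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths with an isotropic Gaussian kernel parameterised in mm full width at
#' half maximum, applied as three 1D convolutions with zero padding at the
#' boundary (kernel renormalised inside the grid).
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm; 0 returns the input unchanged.
#' @param voxel_mm voxel size in mm.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(vol)
  conv_axis <- function(x, axis) {
    # fold the target axis to columns, convolve, fold back
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (o in -half:half) {
      w <- k[o + half + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + w * m[src[ok], , drop = FALSE]
      wt[ok] <- wt[ok] + w
    }
    out <- out / wt
    xp <- array(out, dim = dp)
    aperm(xp, order(perm))
  }
  for (axis in 1:3) vol <- conv_axis(vol, axis)
  vol
}
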