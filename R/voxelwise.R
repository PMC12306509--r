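#' Build a group brain mask from the mean gray-matter map
#'
#' The mask contains every voxel whose mean value across subjects exceeds the
#' threshold, mirroring the standard VBM practice of thresholding the group
#' mean gray-matter map.
#'
#' @param volumes a `cohort_volumes` object.
#' @param threshold mean-GMV threshold (default 0.2).
#' @return An object of class `brain_mask`: list with logical array `mask`,
#'   `voxel_mm`, and `provenance` (threshold and number of subjects).
#' @export
build_mask <- function(volumes, threshold = 0.2) {
  stopifnot(inherits(volumes, "cohort_volumes"))
  mn <- colMeans(volumes$data)
  m <- mn > threshold
  if (!any(m)) stop("empty mask: no voxel with mean GMV > ", threshold)
  structure(list(mask = array(m, dim = volumes$dims),
                 voxel_mm = volumes$voxel_mm,
                 provenance = list(threshold = threshold,
                                   n_subjects = nrow(volumes$data))),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d/%d voxels (mean GMV > %g over %d subjects)\n",
              sum(x$mask), length(x$mask), x$provenance$threshold,
              x$provenance$n_subjects))
  invisible(x)
}

# design matrix for group + covariates; group coded exposed(DD)=1, ODD=0
group_design <- function(groups, covariates = NULL) {
  g <- as.integer(groups == "DD")
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    C <- as.matrix(as.data.frame(covariates))
    X <- cbind(X, C)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Covariate-adjusted voxel-wise two-group t-map
#'
#' Per in-mask voxel, fits the linear model GMV ~ group + covariates and
#' reports the t statistic of the group indicator (exposed minus control),
#' with two-sided p-values on n - rank(design) degrees of freedom. Covariate
#' adjustment happens inside the per-voxel model, not by pre-residualization.
#'
#' @param volumes `cohort_volumes`, or a subjects-x-voxels matrix of values
#'   already restricted to in-mask voxels.
#' @param groups character vector of group labels (`"DD"` exposed, `"ODD"`).
#' @param covariates optional data.frame of nuisance covariates (age, gender,
#'   education, total intracranial volume, ...), same row order as subjects.
#' @param mask optional `brain_mask`; required when `volumes` is a
#'   `cohort_volumes` (restricts the test to in-mask voxels).
#' @return An object of class `stat_map`: list with `t`, `p`, `q` (BH),
#'   `df`, `voxel_idx` (linear indices of tested voxels in the grid, or NULL
#'   for matrix input), `dims`, `covariates` (names used).
#' @export
group_tmap <- function(volumes, groups, covariates = NULL, mask = NULL) {
  if (inherits(volumes, "cohort_volumes")) {
    if (is.null(mask)) stop("a brain_mask is required with cohort_volumes input")
    voxel_idx <- which(as.vector(mask$mask))
    Y <- volumes$data[, voxel_idx, drop = FALSE]
    dims <- volumes$dims
  } else {
    Y <- as.matrix(volumes); voxel_idx <- NULL; dims <- NULL
  }
  n <- nrow(Y)
  X <- group_design(groups, covariates)
  p_rank <- ncol(X)
  if (min(table(groups)) < p_rank + 1L)
    stop("each group needs at least rank(design)+1 subjects")

  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)              # coefficients, p x V
  res <- Y - X %*% B
  df <- n - p_rank
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- B[2, ] / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(t = tval, p = pval, q = stats::p.adjust(pval, "BH"),
                 df = df, voxel_idx = voxel_idx, dims = dims,
                 covariates = colnames(X)[-(1:2)]),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, df = %d; %d with q <= 0.05\n",
              length(x$t), x$df, sum(x$q <= 0.05)))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values with the significance mask at the requested level.
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @param level FDR level (default 0.05).
#' @return list with `q` (adjusted p-values) and `significant` (logical).
#' @export
fdr_correct <- function(p, level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= level)
}

#' Extract connected significant clusters
#'
#' Labels face-connected (6-connectivity) components of a significance mask,
#' discards clusters smaller than `min_extent`, and reports per cluster the
#' size, the peak |t| voxel with its t value, 0-based voxel coordinate and mm
#' coordinate, and (optionally) the atlas label at the peak.
#'
#' @param stat_map a `stat_map` from [group_tmap()] computed on
#'   `cohort_volumes` input (so voxel geometry is known).
#' @param significant logical vector over the tested voxels (e.g. from
#'   [fdr_correct()]); defaults to `stat_map$q <= 0.05`.
#' @param min_extent minimum cluster size in voxels (default 10).
#' @param atlas optional integer label array on the same grid.
#' @param voxel_mm voxel size for mm coordinates (default 1.5).
#' @return data.frame with one row per cluster, ordered by decreasing size.
#' @export
extract_clusters <- function(stat_map, significant = NULL, min_extent = 10L,
                             atlas = NULL, voxel_mm = 1.5) {
  stopifnot(inherits(stat_map, "stat_map"), !is.null(stat_map$voxel_idx))
  if (is.null(significant)) significant <- stat_map$q <= 0.05
  dims <- stat_map$dims
  sig_idx <- stat_map$voxel_idx[significant]
  empty <- data.frame(cluster = integer(0), size = integer(0),
                      peak_t = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0), atlas_label = integer(0))
  if (!length(sig_idx)) return(empty)

  labels <- label_components(sig_idx, dims)
  tvals <- stats::setNames(stat_map$t[significant], sig_idx)
  rows <- list()
  for (cl in unique(labels)) {
    members <- sig_idx[labels == cl]
    if (length(members) < min_extent) next
    tv <- tvals[as.character(members)]
    peak <- members[which.max(abs(tv))]
    co <- voxel_coords(peak, dims)
    mm <- voxel_to_mm(co, voxel_mm)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = NA_integer_, size = length(members),
      peak_t = tv[which.max(abs(tv))],
      peak_i = co[1], peak_j = co[2], peak_k = co[3],
      peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
      atlas_label = if (is.null(atlas)) NA_integer_ else as.vector(atlas)[peak])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# connected components (6-connectivity) of a voxel index set; returns integer
# component label per input voxel
label_components <- function(idx, dims) {
  inset <- integer(prod(dims))
  inset[idx] <- seq_along(idx)
  labels <- integer(length(idx))
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  nextlab <- 0L
  for (s in seq_along(idx)) {
    if (labels[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    labels[s] <- nextlab
    while (length(queue)) {
      cur <- idx[queue]
      co <- voxel_coords(cur, dims)
      queue <- integer(0)
      for (o in seq_len(6)) {
        nb <- coords_to_index(sweep(co, 2, offs[o, ], "+"), dims)
        nb <- nb[!is.na(nb)]
        pos <- inset[nb]
        pos <- pos[pos != 0L]
        pos <- pos[labels[pos] == 0L]
        if (length(pos)) {
          labels[pos] <- nextlab
          queue <- c(queue, pos)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Cohen's d standardized mean difference
#'
#' @param x,y numeric samples (each n >= 2).
#' @return (mean(x) - mean(y)) / pooled SD.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
             (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}
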