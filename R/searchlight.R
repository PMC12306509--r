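#' Searchlight analysis settings
#'
#' @param radius_mm sphere radius in mm on voxel centers (default 2; with
#'   1.5 mm voxels this gives 7-voxel neighborhoods: the center plus its six
#'   face neighbors).
#' @param variance_retained fraction of variance the PCA features must retain
#'   (default 0.8).
#' @param folds cross-validation folds (default 10, stratified by group).
#' @param cost linear-SVM soft-margin regularization parameter (default 1).
#' @param accuracy_threshold map threshold for constrained regions
#'   (default 0.6; must exceed chance, i.e. lie in (0.5, 1]).
#' @param pca_per_fold if TRUE (default) PCA is fit on each training fold and
#'   applied to its test fold; FALSE fits PCA once on all subjects before
#'   cross-validation (the literal pipeline-figure order, which leaks test
#'   information into the features).
#' @param seed integer seed for the fold shuffle.
#' @return A `searchlight_spec` list.
#' @export
searchlight_spec <- function(radius_mm = 2, variance_retained = 0.8,
                             folds = 10L, cost = 1, accuracy_threshold = 0.6,
                             pca_per_fold = TRUE, seed = 1L) {
  stopifnot(radius_mm >= 0, variance_retained > 0, variance_retained <= 1,
            folds >= 2L, cost > 0,
            accuracy_threshold > 0.5, accuracy_threshold <= 1)
  structure(list(radius_mm = radius_mm, variance_retained = variance_retained,
                 folds = as.integer(folds), cost = cost,
                 accuracy_threshold = accuracy_threshold,
                 pca_per_fold = pca_per_fold, seed = as.integer(seed)),
            class = "searchlight_spec")
}

#' Spherical neighborhood index for every in-mask voxel
#'
#' For each in-mask voxel, lists the in-mask voxels whose center-to-center
#' Euclidean distance in mm is at most `radius_mm` (the center itself
#' included). Neighborhoods at the mask boundary are clipped.
#'
#' @param mask a `brain_mask`.
#' @param radius_mm sphere radius in mm.
#' @return list with `neighbors` (list of integer vectors indexing into the
#'   in-mask voxel ordering), `voxel_idx` (linear grid indices of in-mask
#'   voxels), and `offsets` (the within-radius voxel offset matrix).
#' @export
neighborhood_index <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "brain_mask"))
  dims <- dim(mask$mask); vmm <- mask$voxel_mm
  if (radius_mm < vmm && radius_mm > 0)
    warning("radius ", radius_mm, " mm is below the voxel size (", vmm,
            " mm); neighborhoods reduce to single voxels")
  voxel_idx <- which(as.vector(mask$mask))
  # lookup: grid index -> position in the in-mask ordering (0 outside mask)
  pos <- integer(prod(dims)); pos[voxel_idx] <- seq_along(voxel_idx)

  r_vox <- floor(radius_mm / vmm)
  grid <- expand.grid(di = -r_vox:r_vox, dj = -r_vox:r_vox, dk = -r_vox:r_vox)
  keep <- (grid$di^2 + grid$dj^2 + grid$dk^2) * vmm^2 <= radius_mm^2
  offsets <- as.matrix(grid[keep, , drop = FALSE])

  co <- voxel_coords(voxel_idx, dims)
  neighbors <- vector("list", length(voxel_idx))
  for (v in seq_along(voxel_idx)) {
    nb <- coords_to_index(sweep(offsets, 2, co[v, ], "+"), dims)
    nb <- nb[!is.na(nb)]
    p <- pos[nb]
    neighbors[[v]] <- p[p != 0L]
  }
  list(neighbors = neighbors, voxel_idx = voxel_idx, offsets = offsets)
}

#' PCA features of a searchlight neighborhood
#'
#' Centers the subjects-by-voxels neighborhood matrix (no scaling) and keeps
#' the smallest number of principal components whose cumulative explained
#' variance reaches `variance_retained`.
#'
#' @param X numeric matrix, subjects x neighborhood voxels.
#' @param variance_retained fraction in (0, 1].
#' @return Matrix of component scores (subjects x retained components); a
#'   single zero column, flagged with attribute `zero_variance`, if the
#'   neighborhood has no variance.
#' @export
searchlight_features <- function(X, variance_retained = 0.8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2
  if (sum(ev) < 1e-30) {
    out <- matrix(0, nrow(X), 1)
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_retained - 1e-12)[1]
  out <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  attr(out, "rotation") <- sv$v[, seq_len(k), drop = FALSE]
  attr(out, "center") <- colMeans(X)
  out
}

# stratified fold assignment: within each class, shuffled then dealt round-robin
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  if (min(table(labels)) < folds)
    stop("stratification error: a class has fewer members (",
         min(table(labels)), ") than folds (", folds, ")")
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated linear-SVM classification accuracy
#'
#' Pooled accuracy of a linear soft-margin SVM over stratified k-fold
#' cross-validation: each subject is classified exactly once while held out,
#' and accuracy is the overall fraction classified correctly.
#'
#' @param features subjects x features numeric matrix (or the raw
#'   neighborhood matrix when `variance_retained` is given).
#' @param labels two-class factor/character vector.
#' @param folds number of stratified folds.
#' @param cost SVM regularization parameter.
#' @param seed fold-shuffle seed.
#' @param fold_assign optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @param variance_retained if non-NULL, PCA with this retention is fit inside
#'   each training fold and applied to the held-out fold.
#' @return Scalar accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(features, labels, folds = 10L, cost = 1, seed = 1L,
                        fold_assign = NULL, variance_retained = NULL) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  stopifnot(nlevels(y) == 2L)
  if (is.null(fold_assign)) fold_assign <- stratified_folds(y, folds, seed)
  correct <- 0L
  for (f in sort(unique(fold_assign))) {
    test <- fold_assign == f
    Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    if (nlevels(droplevels(y[!test])) < 2L)
      stop("stratification error: a training fold lost a class")
    if (!is.null(variance_retained)) {
      feats <- searchlight_features(Xtr, variance_retained)
      if (isTRUE(attr(feats, "zero_variance"))) {
        Xtr <- matrix(0, nrow(Xtr), 1); Xte <- matrix(0, nrow(Xte), 1)
      } else {
        rot <- attr(feats, "rotation"); ctr <- attr(feats, "center")
        Xtr <- feats
        Xte <- sweep(Xte, 2, ctr) %*% rot
      }
    }
    if (all(abs(Xtr) < 1e-30)) {
      # degenerate features: majority-class prediction
      maj <- names(which.max(table(y[!test])))
      correct <- correct + sum(y[test] == maj)
      next
    }
    fit <- e1071::svm(Xtr, y[!test], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte)
    correct <- correct + sum(pred == y[test])
  }
  correct / length(y)
}

#' Per-voxel searchlight accuracy map
#'
#' Slides the spherical window over every requested in-mask voxel, extracts
#' PCA features from the neighborhood, and records the cross-validated
#' linear-SVM accuracy at the center voxel. The fold assignment is drawn once
#' from the spec seed and shared across voxels, so the map is deterministic
#' under a fixed seed.
#'
#' @param volumes `cohort_volumes` aligned to the mask.
#' @param mask a `brain_mask`.
#' @param labels group labels per subject.
#' @param spec a [searchlight_spec()].
#' @param voxels optional subset of in-mask voxel positions (indices into the
#'   in-mask ordering) at which to compute accuracy; default all.
#' @param nbhd optional precomputed [neighborhood_index()].
#' @return An `accuracy_map`: list with `accuracy` (named by in-mask voxel
#'   position; NA where not computed), `neighborhood_size`, `voxel_idx`
#'   (grid indices), `dims`, `spec`.
#' @export
accuracy_map <- function(volumes, mask, labels, spec = searchlight_spec(),
                         voxels = NULL, nbhd = NULL) {
  stopifnot(inherits(volumes, "cohort_volumes"), inherits(mask, "brain_mask"))
  if (is.null(nbhd)) nbhd <- neighborhood_index(mask, spec$radius_mm)
  Y <- volumes$data[, nbhd$voxel_idx, drop = FALSE]
  nv <- length(nbhd$voxel_idx)
  if (is.null(voxels)) voxels <- seq_len(nv)
  y <- as.factor(labels)
  fold_assign <- stratified_folds(y, spec$folds, spec$seed)

  acc <- rep(NA_real_, nv)
  nsize <- rep(NA_integer_, nv)
  for (v in voxels) {
    nb <- nbhd$neighbors[[v]]
    nsize[v] <- length(nb)
    Xv <- Y[, nb, drop = FALSE]
    acc[v] <- tryCatch({
      if (spec$pca_per_fold) {
        cv_accuracy(Xv, y, cost = spec$cost, fold_assign = fold_assign,
                    variance_retained = spec$variance_retained)
      } else {
        feats <- searchlight_features(Xv, spec$variance_retained)
        cv_accuracy(feats, y, cost = spec$cost, fold_assign = fold_assign)
      }
    }, error = function(e) NA_real_)
  }
  structure(list(accuracy = acc, neighborhood_size = nsize,
                 voxel_idx = nbhd$voxel_idx, dims = volumes$dims,
                 spec = spec),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  done <- !is.na(x$accuracy)
  cat(sprintf("<accuracy_map> %d/%d voxels computed; mean accuracy %.3f; %d above %.2f\n",
              sum(done), length(x$accuracy), mean(x$accuracy[done]),
              sum(x$accuracy[done] > x$spec$accuracy_threshold),
              x$spec$accuracy_threshold))
  invisible(x)
}

#' Partition significant voxels into constrained and excluded regions
#'
#' Constrained regions are the voxels that both differ between groups
#' (significant in the t-map) and classify group membership with accuracy
#' strictly above the threshold; the remaining significant voxels are
#' excluded. The two sets partition the significant mask exactly.
#'
#' @param acc_map an `accuracy_map`.
#' @param significant logical vector over the same in-mask voxel ordering
#'   (e.g. `fdr_correct(stat_map$p)$significant`).
#' @param threshold accuracy threshold (default from the map's spec).
#' @return A `region_partition`: list with logical vectors `constrained` and
#'   `excluded` over the in-mask ordering, plus provenance.
#' @export
constrain_regions <- function(acc_map, significant, threshold = NULL) {
  stopifnot(inherits(acc_map, "accuracy_map"),
            length(significant) == length(acc_map$accuracy))
  if (is.null(threshold)) threshold <- acc_map$spec$accuracy_threshold
  acc <- acc_map$accuracy
  constrained <- significant & !is.na(acc) & acc > threshold
  excluded <- significant & !constrained
  if (!any(constrained))
    warning("constrained set is empty; representation mapping would be skipped")
  structure(list(constrained = constrained, excluded = excluded,
                 threshold = threshold, voxel_idx = acc_map$voxel_idx,
                 dims = acc_map$dims),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %d constrained, %d excluded (accuracy > %g)\n",
              sum(x$constrained), sum(x$excluded), x$threshold))
  invisible(x)
}
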