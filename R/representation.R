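#' Linear-model prediction of cognitive scores from searchlight features
#'
#' Predicts each subject's composite score from the feature matrix with an
#' ordinary least-squares linear model. By default predictions are
#' cross-validated (out-of-fold): the model is fit with the subject's fold
#' held out, so every prediction is made for unseen data. In-sample fitted
#' values are available with `insample = TRUE` (optimistically biased).
#'
#' @param features subjects x features numeric matrix.
#' @param observed numeric vector of observed scores.
#' @param folds number of CV folds (ignored when `insample = TRUE`).
#' @param seed fold-shuffle seed.
#' @param insample if TRUE, return in-sample fitted values.
#' @return Numeric vector of predicted scores, one per subject.
#' @export
predict_scores <- function(features, observed, folds = 10L, seed = 1L,
                           insample = FALSE) {
  X <- as.matrix(features)
  y <- as.numeric(observed)
  stopifnot(nrow(X) == length(y))
  ols_predict <- function(Xtr, ytr, Xte) {
    Xtr1 <- cbind(1, Xtr)
    qrx <- qr(Xtr1)
    if (qrx$rank < ncol(Xtr1)) {
      keep <- qrx$pivot[seq_len(qrx$rank)]
      warning("rank-deficient feature matrix; dropping redundant components")
      Xtr1 <- Xtr1[, keep, drop = FALSE]
      Xte1 <- cbind(1, Xte)[, keep, drop = FALSE]
      qrx <- qr(Xtr1)
    } else Xte1 <- cbind(1, Xte)
    beta <- qr.coef(qrx, ytr)
    as.vector(Xte1 %*% beta)
  }
  if (insample) return(ols_predict(X, y, X))
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("need n > number of features + 1")
  fold_assign <- with_seed(seed, rep_len(seq_len(folds), n)[sample(n)])
  pred <- numeric(n)
  for (f in sort(unique(fold_assign))) {
    test <- fold_assign == f
    pred[test] <- ols_predict(X[!test, , drop = FALSE], y[!test],
                              X[test, , drop = FALSE])
  }
  pred
}

#' Permutation p-value for a predicted-vs-observed correlation
#'
#' Two-sided permutation test of the Pearson correlation between predicted
#' and observed scores: the predicted vector is shuffled `n_perm` times, the
#' correlation recomputed each time, and the add-one p-value is
#' `(1 + #permuted |r| >= observed |r|) / (n_perm + 1)`.
#'
#' With `exhaustive = TRUE` (only sensible for very small n) every one of the
#' n! permutations is evaluated instead and the p-value is the exact fraction
#' of permutations (identity included) with `|r| >= |r_obs|`.
#'
#' @param predicted,observed numeric vectors (n >= 4; >= 5 recommended).
#' @param n_perm number of permutations (default 10000).
#' @param seed permutation seed.
#' @param exhaustive enumerate all permutations (n <= 8).
#' @return list with `r` (observed correlation), `p` (permutation p-value),
#'   and `degenerate` (TRUE when either vector is constant; then p = 1).
#' @export
permutation_null <- function(predicted, observed, n_perm = 10000L, seed = 1L,
                             exhaustive = FALSE) {
  n <- length(observed)
  stopifnot(length(predicted) == n, n >= 4)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(list(r = NA_real_, p = 1, degenerate = TRUE))
  zp <- as.vector(scale(predicted)); zo <- as.vector(scale(observed))
  r_obs <- sum(zp * zo) / (n - 1)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(ix) sum(zp[ix] * zo) / (n - 1))
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    return(list(r = r_obs, p = p, degenerate = FALSE))
  }
  with_seed(seed, {
    perm <- replicate(n_perm, sum(zp[sample.int(n)] * zo) / (n - 1))
  })
  p <- (1 + sum(abs(perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p = p, degenerate = FALSE)
}

# all n! permutations of 1..n, one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Per-voxel cognitive representation map over the constrained regions
#'
#' At every constrained voxel, extracts the searchlight PCA features, predicts
#' each composite score with the (by default cross-validated) linear model,
#' computes the predicted-vs-observed Pearson correlation, assesses it against
#' a permutation null, and applies per-domain Benjamini-Hochberg correction at
#' the configured level.
#'
#' @param volumes `cohort_volumes`.
#' @param mask the `brain_mask` the partition was computed on.
#' @param partition a `region_partition` from [constrain_regions()].
#' @param composites subjects x domains matrix from [composite_scores()].
#' @param spec a [searchlight_spec()] (radius and variance retention reused).
#' @param n_perm permutations per voxel (default 10000).
#' @param fdr_level per-domain FDR level (default 0.001).
#' @param folds prediction CV folds (default 10).
#' @param insample use in-sample rather than out-of-fold predictions.
#' @param seed base seed; per-voxel permutation streams are derived from it.
#' @param nbhd optional precomputed [neighborhood_index()].
#' @return A `representation_map`: list of per-domain data.frames (`voxel`
#'   position in the in-mask ordering, `r`, `p`, `q`, `significant`), plus
#'   settings and the dropped-subject count.
#' @export
representation_map <- function(volumes, mask, partition, composites,
                               spec = searchlight_spec(), n_perm = 10000L,
                               fdr_level = 0.001, folds = 10L,
                               insample = FALSE, seed = 1L, nbhd = NULL) {
  stopifnot(inherits(partition, "region_partition"))
  voxels <- which(partition$constrained)
  if (!length(voxels)) stop("empty constrained set; nothing to map")
  if (is.null(nbhd)) nbhd <- neighborhood_index(mask, spec$radius_mm)
  composites <- as.matrix(composites)

  complete <- stats::complete.cases(composites)
  n_dropped <- sum(!complete)
  if (n_dropped) message(n_dropped, " subject(s) dropped for missing composites")
  Y <- volumes$data[complete, nbhd$voxel_idx, drop = FALSE]
  comp <- composites[complete, , drop = FALSE]

  out <- list()
  for (dom in colnames(comp)) {
    r <- p <- rep(NA_real_, length(voxels))
    for (i in seq_along(voxels)) {
      v <- voxels[i]
      feats <- searchlight_features(Y[, nbhd$neighbors[[v]], drop = FALSE],
                                    spec$variance_retained)
      pred <- predict_scores(feats, comp[, dom], folds = folds,
                             seed = seed, insample = insample)
      pn <- permutation_null(pred, comp[, dom], n_perm = n_perm,
                             seed = seed + v)
      r[i] <- pn$r; p[i] <- pn$p
    }
    fdr <- fdr_correct(p, fdr_level)
    out[[dom]] <- data.frame(voxel = voxels, r = r, p = p, q = fdr$q,
                             significant = fdr$significant)
  }
  structure(list(domains = out, fdr_level = fdr_level, n_perm = n_perm,
                 seed = seed, insample = insample, n_dropped = n_dropped,
                 voxel_idx = nbhd$voxel_idx, dims = volumes$dims),
            class = "representation_map")
}

#' @export
print.representation_map <- function(x, ...) {
  cat(sprintf("<representation_map> %d constrained voxels, %d domains (FDR %g)\n",
              nrow(x$domains[[1]]), length(x$domains), x$fdr_level))
  cov <- domain_coverage(x)
  for (d in names(cov)) cat(sprintf("  %-20s %5.1f%% significant\n", d, 100 * cov[d]))
  invisible(x)
}

#' Fraction of constrained voxels significant per domain
#'
#' @param map a `representation_map`.
#' @return Named numeric vector: per domain, significant count divided by the
#'   constrained voxel count.
#' @export
domain_coverage <- function(map) {
  stopifnot(inherits(map, "representation_map"))
  vapply(map$domains, function(d) mean(d$significant), numeric(1))
}

#' Voxels significant for one domain but not another
#'
#' @param map a `representation_map`.
#' @param domain_a,domain_b domain names present in the map.
#' @param atlas optional integer label array on the map's grid; adds the atlas
#'   label of each surviving voxel.
#' @return data.frame of voxels significant for `domain_a` and not `domain_b`,
#'   with grid indices and optional atlas labels.
#' @export
contrast_domains <- function(map, domain_a, domain_b, atlas = NULL) {
  stopifnot(inherits(map, "representation_map"),
            domain_a %in% names(map$domains), domain_b %in% names(map$domains))
  a <- map$domains[[domain_a]]; b <- map$domains[[domain_b]]
  keep <- a$significant & !b$significant
  vox <- a$voxel[keep]
  out <- data.frame(voxel = vox, grid_idx = map$voxel_idx[vox],
                    r = a$r[keep])
  if (!is.null(atlas)) out$atlas_label <- as.vector(atlas)[out$grid_idx]
  out
}
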