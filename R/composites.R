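#' Assign exposure group from the ICT-use frequency item
#'
#' The single leisure-activity item ("How often do you use a computer and
#' mobile devices?") is scored 0 (never), 1 (at least once per year),
#' 2 (at least once per month), 3 (several times per month), 4 (at least once
#' per week), 5 (every day). Scores 0-2 map to the digital-divide group
#' (`"DD"`), 4-5 to the overcoming group (`"ODD"`), and 3 is left unassigned
#' (`NA`): the classification rule covers only the two poles of use.
#'
#' @param ict_frequency integer vector with values in 0..5.
#' @return Character vector: `"DD"`, `"ODD"`, or `NA` (excluded).
#' @export
assign_group <- function(ict_frequency) {
  if (any(!ict_frequency %in% 0:5))
    stop("ict_frequency scores must lie in 0..5; got: ",
         paste(unique(ict_frequency[!ict_frequency %in% 0:5]), collapse = ", "))
  out <- rep(NA_character_, length(ict_frequency))
  out[ict_frequency %in% 0:2] <- "DD"
  out[ict_frequency %in% 4:5] <- "ODD"
  out
}

#' Estimate per-test loadings for each cognitive domain
#'
#' Fits an independent one-factor model per domain on the standardized test
#' scores (maximum likelihood via [stats::factanal()]; if the ML fit fails,
#' e.g. with exactly two tests, the first principal component's loadings are
#' used). Loadings are sign-fixed so that the majority are positive. A domain
#' with a single test gets weight 1, i.e. the composite is that test's
#' z-score.
#'
#' @param tests data.frame or matrix of raw test scores (subjects x tests).
#' @param domain_map named character vector mapping test column name -> domain.
#' @return Named list of numeric weight vectors, one per domain.
#' @export
estimate_loadings <- function(tests, domain_map) {
  tests <- as.data.frame(tests)
  stopifnot(all(names(domain_map) %in% names(tests)))
  out <- list()
  for (dom in unique(domain_map)) {
    cols <- names(domain_map)[domain_map == dom]
    X <- scale(as.matrix(tests[, cols, drop = FALSE]))
    if (length(cols) == 1L) {
      out[[dom]] <- stats::setNames(1, cols)
      next
    }
    if (nrow(X) <= length(cols))
      stop("domain ", dom, ": need more subjects than tests")
    S <- stats::cov(X)
    if (abs(det(S)) < 1e-12) stop("domain ", dom, ": singular test covariance")
    load <- tryCatch(
      as.vector(stats::factanal(covmat = S, factors = 1,
                                n.obs = nrow(X))$loadings),
      error = function(e) {
        e1 <- eigen(S, symmetric = TRUE)
        e1$vectors[, 1] * sqrt(e1$values[1])
      })
    if (sum(load > 0) < sum(load < 0)) load <- -load
    out[[dom]] <- stats::setNames(load, cols)
  }
  out
}

#' Synthesize per-domain cognitive composite scores
#'
#' Each domain composite is the weighted sum of the standardized test scores
#' (weights from [estimate_loadings()] or supplied externally), re-scaled to
#' mean 0 and SD 1 across subjects. Tests where higher raw scores mean worse
#' performance (timing-based tests) should be sign-flipped before entry, or
#' given negative weights. A subject missing any test of a domain gets `NA`
#' for that domain's composite.
#'
#' @param tests data.frame or matrix of raw test scores (subjects x tests).
#' @param weights named list of per-domain weight vectors (names = test
#'   columns), as returned by [estimate_loadings()].
#' @return Matrix of z-scaled composites, subjects x domains.
#' @export
composite_scores <- function(tests, weights) {
  tests <- as.data.frame(tests)
  out <- matrix(NA_real_, nrow(tests), length(weights),
                dimnames = list(rownames(tests), names(weights)))
  zscore <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  for (dom in names(weights)) {
    w <- weights[[dom]]
    X <- apply(as.matrix(tests[, names(w), drop = FALSE]), 2, zscore)
    raw <- as.vector(X %*% w)   # NA propagates: missing test -> missing composite
    out[, dom] <- zscore(raw)
  }
  out
}
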