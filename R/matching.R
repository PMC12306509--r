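#' Fit a logistic propensity model for exposure
#'
#' Models the probability of belonging to the exposed group (`DD`) given the
#' supplied covariates with logistic regression. Perfect or quasi-perfect
#' separation is detected (fitted probabilities indistinguishable from 0/1)
#' and handled by refitting with a small ridge penalty on the coefficients,
#' flagged in the result.
#'
#' @param phenotypes data.frame with a `group` column (`"DD"` = exposed,
#'   `"ODD"` = control) and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return An object of class `propensity_result` with elements
#'   `coefficients`, `score` (per-subject P(exposed)), `logit`, `separation`
#'   (logical), `phenotypes`, `covariates`; `pairs` is `NULL` until
#'   [match_pairs()] is run.
#' @export
fit_propensity <- function(phenotypes, covariates) {
  stopifnot(is.data.frame(phenotypes), "group" %in% names(phenotypes))
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov))
    stop("covariates absent from phenotype table: ",
         paste(missing_cov, collapse = ", "))
  y <- as.integer(phenotypes$group == "DD")
  if (length(unique(y)) < 2L) stop("both exposure groups must be present")
  X <- as.matrix(phenotypes[, covariates, drop = FALSE])
  if (any(apply(X, 2, function(col) stats::sd(col) == 0)))
    stop("constant covariate(s): ",
         paste(covariates[apply(X, 2, function(col) stats::sd(col) == 0)],
               collapse = ", "))

  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  p <- fit$fitted.values
  separation <- any(p < 1e-8 | p > 1 - 1e-8) || !fit$converged
  coefs <- fit$coefficients
  if (separation) {
    warning("separation detected in the propensity model; using a ridge-penalized fit")
    coefs <- ridge_logistic(cbind(1, X), y, lambda = 1e-2)
    p <- stats::plogis(as.vector(cbind(1, X) %*% coefs))
  }
  names(coefs) <- c("(Intercept)", covariates)
  structure(list(coefficients = coefs, score = p,
                 logit = stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)),
                 separation = separation, phenotypes = phenotypes,
                 covariates = covariates, pairs = NULL),
            class = "propensity_result")
}

# ridge-penalized logistic regression by IRLS (intercept penalized too; the
# penalty only exists to cap coefficients under separation)
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

#' @export
print.propensity_result <- function(x, ...) {
  cat("<propensity_result>\n  covariates:",
      paste(x$covariates, collapse = ", "), "\n")
  cat(sprintf("  scores in [%.3f, %.3f]%s\n", min(x$score), max(x$score),
              if (x$separation) " (ridge fallback: separation)" else ""))
  if (!is.null(x$pairs))
    cat(sprintf("  %d matched pairs (caliper %.3g SD of the logit)\n",
                nrow(x$pairs), attr(x$pairs, "caliper_sd")))
  invisible(x)
}

#' Greedy 1:1 propensity matching within a caliper
#'
#' Pairs each exposed subject with the nearest unmatched control on the logit
#' of the propensity score (greedy nearest neighbor without replacement),
#' discarding candidate pairs farther apart than `caliper_sd` pooled standard
#' deviations of the logit. Exposed subjects are processed in a fixed shuffled
#' order derived from `seed` so that ties resolve deterministically.
#'
#' @param result a `propensity_result` from [fit_propensity()].
#' @param caliper_sd caliper width in SD units of the logit score (default 0.2).
#' @param seed integer seed for the processing-order shuffle.
#' @return The `propensity_result` with `pairs` filled (data.frame of
#'   `exposed_id`, `control_id`, `distance`).
#' @export
match_pairs <- function(result, caliper_sd = 0.2, seed = 1L) {
  stopifnot(inherits(result, "propensity_result"))
  phen <- result$phenotypes
  lg <- result$logit
  exposed_idx <- which(phen$group == "DD")
  control_idx <- which(phen$group == "ODD")
  caliper <- caliper_sd * stats::sd(lg)

  order_exposed <- with_seed(seed, sample(exposed_idx))
  available <- control_idx
  pairs <- vector("list", length(order_exposed))
  for (i in seq_along(order_exposed)) {
    e <- order_exposed[i]
    if (!length(available)) break
    dists <- abs(lg[available] - lg[e])
    j <- which.min(dists)
    if (dists[j] <= caliper) {
      pairs[[i]] <- data.frame(exposed_id = phen$id[e],
                               control_id = phen$id[available[j]],
                               distance = dists[j],
                               stringsAsFactors = FALSE)
      available <- available[-j]
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no pairs found within the caliper (caliper = ", signif(caliper, 3),
         " on the logit scale); inspect the score overlap")
  attr(pairs, "caliper_sd") <- caliper_sd
  result$pairs <- pairs
  result
}

#' Standardized mean differences before and after matching
#'
#' For each covariate, the standardized mean difference
#' SMD = (mean_exposed - mean_control) / pooled SD, computed on the full
#' sample (before) and on the matched sample (after).
#'
#' @param result a matched `propensity_result`.
#' @return data.frame with columns `covariate`, `smd_before`, `smd_after`.
#' @export
balance_table <- function(result) {
  stopifnot(inherits(result, "propensity_result"))
  if (is.null(result$pairs)) stop("run match_pairs() first")
  phen <- result$phenotypes
  matched_ids <- c(result$pairs$exposed_id, result$pairs$control_id)
  matched <- phen[phen$id %in% matched_ids, ]
  smd <- function(df, cov) {
    x <- df[[cov]][df$group == "DD"]; y <- df[[cov]][df$group == "ODD"]
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
    if (!is.finite(sp) || sp == 0) {
      warning("zero pooled SD for ", cov, "; SMD reported as 0")
      return(0)
    }
    (mean(x) - mean(y)) / sp
  }
  data.frame(
    covariate = result$covariates,
    smd_before = vapply(result$covariates, function(cv) smd(phen, cv), numeric(1)),
    smd_after = vapply(result$covariates, function(cv) smd(matched, cv),
                       numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Matched subset of a phenotype table
#' @param result a matched `propensity_result`.
#' @return The phenotype rows of matched subjects only.
#' @export
matched_phenotypes <- function(result) {
  stopifnot(inherits(result, "propensity_result"), !is.null(result$pairs))
  phen <- result$phenotypes
  phen[phen$id %in% c(result$pairs$exposed_id, result$pairs$control_id), ]
}
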