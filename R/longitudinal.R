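#' Per-subject annual gray-matter decline-rate maps
#'
#' Default mode is the fractional rate `(V_t2 - V_t1) / (V_t1 * interval)`:
#' the signed change per year as a fraction of the baseline value (negative =
#' atrophy). `mode = "absolute"` gives `(V_t2 - V_t1) / interval` instead.
#' Voxels with zero baseline are undefined in fractional mode: they are set
#' to `NA` and counted.
#'
#' @param baseline,followup `cohort_volumes` on the same grid, same subjects.
#' @param interval_years per-subject inter-scan interval in years (> 0).
#' @param mode `"fractional"` (default) or `"absolute"`.
#' @return A `decline_rate_map`: list with `rates` (subjects x voxels matrix),
#'   `interval_years`, `mode`, `n_undefined`, `dims`, `voxel_mm`.
#' @export
annual_decline_rate <- function(baseline, followup, interval_years,
                                mode = c("fractional", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "cohort_volumes"),
            inherits(followup, "cohort_volumes"),
            identical(baseline$dims, followup$dims),
            nrow(baseline$data) == nrow(followup$data),
            length(interval_years) == nrow(baseline$data),
            all(interval_years > 0))
  diff <- followup$data - baseline$data
  rates <- diff / interval_years
  n_undefined <- 0L
  if (mode == "fractional") {
    zero <- baseline$data == 0
    n_undefined <- sum(zero)
    rates <- rates / baseline$data
    rates[zero] <- NA_real_
  }
  structure(list(rates = rates, interval_years = interval_years, mode = mode,
                 n_undefined = n_undefined, dims = baseline$dims,
                 voxel_mm = baseline$voxel_mm),
            class = "decline_rate_map")
}

#' @export
print.decline_rate_map <- function(x, ...) {
  cat(sprintf("<decline_rate_map> %d subjects, %s mode; mean rate %.4f/yr\n",
              nrow(x$rates), x$mode, mean(x$rates, na.rm = TRUE)))
  invisible(x)
}

#' Region-level decline rates from an atlas
#'
#' @param rate_map a `decline_rate_map`.
#' @param atlas integer label array on the same grid (0 = outside).
#' @param mask optional `brain_mask` restricting the averaging.
#' @return Matrix, subjects x regions, of mean in-region rates.
#' @export
region_rates <- function(rate_map, atlas, mask = NULL) {
  stopifnot(inherits(rate_map, "decline_rate_map"))
  lab <- as.vector(atlas)
  if (!is.null(mask)) lab[!as.vector(mask$mask)] <- 0L
  regions <- sort(unique(lab[lab > 0L]))
  out <- sapply(regions, function(rg)
    rowMeans(rate_map$rates[, lab == rg, drop = FALSE], na.rm = TRUE))
  colnames(out) <- paste0("region_", regions)
  rownames(out) <- rownames(rate_map$rates)
  out
}

#' Voxel-wise group contrast of decline rates
#'
#' Applies the covariate-adjusted two-group t-map to the rate maps: per voxel,
#' rate ~ group + covariates, with BH FDR over in-mask voxels.
#'
#' @param rate_map a `decline_rate_map`.
#' @param groups group labels per subject.
#' @param covariates optional nuisance covariate data.frame (baseline
#'   demographics and total intracranial volume).
#' @param mask a `brain_mask`.
#' @return A `stat_map` (see [group_tmap()]).
#' @export
rate_group_diff <- function(rate_map, groups, covariates = NULL, mask) {
  stopifnot(inherits(rate_map, "decline_rate_map"), inherits(mask, "brain_mask"))
  voxel_idx <- which(as.vector(mask$mask))
  R <- rate_map$rates[, voxel_idx, drop = FALSE]
  ok <- colSums(is.na(R)) == 0L
  sm <- group_tmap(R[, ok, drop = FALSE], groups, covariates)
  # reattach geometry for cluster extraction
  sm$voxel_idx <- voxel_idx[ok]
  sm$dims <- rate_map$dims
  sm
}

#' Pearson correlation of region rates with cognitive change
#'
#' @param region_rate_tab subjects x regions matrix from [region_rates()].
#' @param cognitive_change subjects x domains matrix (e.g. annualized
#'   composite change).
#' @return data.frame with one row per region x domain: `r`, `p`, `n`.
#' @export
rate_cognition_correlation <- function(region_rate_tab, cognitive_change) {
  region_rate_tab <- as.matrix(region_rate_tab)
  cognitive_change <- as.matrix(cognitive_change)
  rows <- list()
  for (rg in colnames(region_rate_tab)) for (dom in colnames(cognitive_change)) {
    x <- region_rate_tab[, rg]; y <- cognitive_change[, dom]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 5) stop("fewer than 5 complete pairs for ", rg, " x ", dom)
    ct <- stats::cor.test(x[ok], y[ok])
    rows[[length(rows) + 1L]] <- data.frame(region = rg, domain = dom,
                                            r = unname(ct$estimate),
                                            p = ct$p.value, n = sum(ok))
  }
  do.call(rbind, rows)
}

#' Percent of outcome variance explained by a correlation
#'
#' The coefficient of determination implied by a Pearson correlation,
#' expressed in percent: `100 * r^2`.
#'
#' @param r Pearson correlation coefficient.
#' @return Percent variance explained.
#' @export
variance_explained_pct <- function(r) 100 * r^2

#' Product-of-coefficients mediation with percentile bootstrap
#'
#' Estimates how much of the group effect on cognitive change runs through a
#' regional decline rate: path `a` from the exposure group to the mediator
#' (rate ~ group + covariates), path `b` from mediator to outcome adjusting
#' for group (change ~ rate + group + covariates), total effect `c`
#' (change ~ group + covariates) and direct effect `c'`. The proportion
#' mediated is `a*b / c`, reported with percentile bootstrap confidence
#' intervals over subjects. The proportion is flagged unreliable when the
#' indirect and total effects disagree in sign or `|c|` is near zero.
#'
#' @param group binary exposure (character `"DD"`/`"ODD"`, factor, or 0/1).
#' @param mediator numeric mediator (regional decline rate).
#' @param outcome numeric outcome (annualized cognitive change).
#' @param covariates optional data.frame of adjustment covariates.
#' @param n_boot bootstrap draws (default 5000).
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return A `mediation_result` with paths `a`, `b`, `c`, `c_prime`,
#'   indirect effect `ab`, `proportion_mediated` (NA when undefined),
#'   bootstrap CIs, and settings.
#' @export
mediate <- function(group, mediator, outcome, covariates = NULL,
                    n_boot = 5000L, seed = 1L, conf = 0.95) {
  g <- if (is.numeric(group)) as.numeric(group) else as.numeric(group == "DD")
  C <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(g, mediator, outcome,
                              if (is.null(C)) rep(TRUE, length(g)) else C)
  g <- g[ok]; m <- mediator[ok]; y <- outcome[ok]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]
  n <- length(g)

  paths <- function(idx) {
    gi <- g[idx]; mi <- m[idx]; yi <- y[idx]
    Ci <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
    Xa <- cbind(1, gi, Ci)
    a <- stats::lm.fit(Xa, mi)$coefficients[2]
    Xb <- cbind(1, mi, gi, Ci)
    cb <- stats::lm.fit(Xb, yi)$coefficients
    b <- cb[2]; c_prime <- cb[3]
    cc <- stats::lm.fit(Xa, yi)$coefficients[2]
    c(a = unname(a), b = unname(b), c = unname(cc), c_prime = unname(c_prime))
  }
  est <- paths(seq_len(n))
  ab <- est["a"] * est["b"]
  prop <- if (abs(est["c"]) < 1e-10 || sign(ab) != sign(est["c"]))
    NA_real_ else unname(ab / est["c"])

  boot <- with_seed(seed, {
    t(replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      p <- paths(idx)
      c(ab = unname(p["a"] * p["b"]),
        prop = if (abs(p["c"]) < 1e-10) NA_real_
               else unname(p["a"] * p["b"] / p["c"]))
    }))
  })
  alpha <- (1 - conf) / 2
  ci_ab <- stats::quantile(boot[, "ab"], c(alpha, 1 - alpha), na.rm = TRUE)
  ci_prop <- stats::quantile(boot[, "prop"], c(alpha, 1 - alpha), na.rm = TRUE)
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 c = unname(est["c"]), c_prime = unname(est["c_prime"]),
                 ab = unname(ab), proportion_mediated = prop,
                 ci_ab = ci_ab, ci_proportion = ci_prop,
                 n = n, n_boot = n_boot, seed = seed, conf = conf),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result>\n")
  cat(sprintf("  a (group -> mediator)  = %+.4f\n", x$a))
  cat(sprintf("  b (mediator -> outcome | group) = %+.4f\n", x$b))
  cat(sprintf("  c (total), c' (direct) = %+.4f, %+.4f\n", x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %+.4f  [%.4f, %.4f]\n",
              x$ab, x$ci_ab[1], x$ci_ab[2]))
  if (is.na(x$proportion_mediated)) {
    cat("  proportion mediated: undefined (inconsistent signs or |c| ~ 0)\n")
  } else {
    cat(sprintf("  proportion mediated = %.1f%%  [%.1f%%, %.1f%%] (%d bootstrap draws)\n",
                100 * x$proportion_mediated, 100 * x$ci_proportion[1],
                100 * x$ci_proportion[2], x$n_boot))
  }
  invisible(x)
}

#' Intercept-only two-level null model and ICC
#'
#' Fits `score ~ 1 + (1 | id)` by maximum likelihood and reports the
#' intraclass correlation: between-subject variance over total variance.
#'
#' @param data long-format data.frame with columns `id`, `score`.
#' @return list with `icc`, `var_between`, `var_within`, and the `lme4` fit.
#' @export
fit_null_model <- function(data) {
  stopifnot(all(c("id", "score") %in% names(data)))
  fit <- lme4::lmer(score ~ 1 + (1 | id), data = data, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "id"]
  vw <- vc$vcov[vc$grp == "Residual"]
  list(icc = vb / (vb + vw), var_between = vb, var_within = vw, fit = fit)
}

#' Two-level growth model of cognitive aging
#'
#' Fits the combined mixed model implied by a level-1 individual trajectory
#' `score = pi0 + pi1 * time + e` with level-2 models for the intercept,
#' `pi0 = b00 + b01*age + b02*gender + b03*edu + b04*group + r0`, and the
#' slope, `pi1 = b10 + b11*age + b12*gender + b13*edu + b14*group + r1`:
#' fixed effects for the four baseline predictors, time, and their
#' interactions with time, plus correlated random intercepts and slopes.
#' Fitted by maximum likelihood via `lme4::lmer`.
#'
#' @param data long-format data.frame with columns `id`, `score`, `time`
#'   (years since baseline), `age_baseline`, `gender`, `education`, `group`
#'   (`"DD"`/`"ODD"` or 0/1; coded so 1 = exposed/DD).
#' @return A `growth_model` object: fixed effects named `beta00..beta04`
#'   (intercept model) and `beta10..beta14` (slope model), their SEs,
#'   random-effect variances and covariance, residual variance,
#'   log-likelihood, convergence flag, and the underlying fit.
#' @export
fit_growth_model <- function(data) {
  need <- c("id", "score", "time", "age_baseline", "gender", "education", "group")
  stopifnot(all(need %in% names(data)))
  d <- data
  d$group_num <- if (is.numeric(d$group)) as.numeric(d$group)
                 else as.numeric(d$group == "DD")
  fit <- lme4::lmer(
    score ~ age_baseline + gender + education + group_num +
      time + time:age_baseline + time:gender + time:education + time:group_num +
      (1 + time | id),
    data = d, REML = FALSE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit, tol = 1e-4)
  converged <- is.null(msgs)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  name_map <- c("(Intercept)" = "beta00", "age_baseline" = "beta01",
                "gender" = "beta02", "education" = "beta03",
                "group_num" = "beta04", "time" = "beta10",
                "age_baseline:time" = "beta11", "gender:time" = "beta12",
                "education:time" = "beta13", "group_num:time" = "beta14")
  ord <- match(names(name_map), names(fe))
  beta <- stats::setNames(fe[ord], name_map)
  beta_se <- stats::setNames(se[ord], name_map)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r0 <- vc$vcov[vc$grp == "id" & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  var_r1 <- vc$vcov[vc$grp == "id" & vc$var1 == "time" & is.na(vc$var2)]
  cov_r01 <- vc$vcov[vc$grp == "id" & !is.na(vc$var2)]
  var_e <- vc$vcov[vc$grp == "Residual"]
  structure(list(beta = beta, se = beta_se,
                 var_r0 = var_r0, var_r1 = var_r1, cov_r01 = cov_r01,
                 var_e = var_e, logLik = as.numeric(stats::logLik(fit)),
                 converged = converged, singular = singular,
                 messages = msgs, fit = fit),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> two-level growth model (ML)\n")
  tab <- data.frame(estimate = x$beta, se = x$se,
                    z = x$beta / x$se)
  print(round(tab, 4))
  cat(sprintf("  var(r0)=%.4f var(r1)=%.4f cov=%.4f var(e)=%.4f\n",
              x$var_r0, x$var_r1, x$cov_r01, x$var_e))
  if (!x$converged) cat("  WARNING: optimizer reported convergence issues\n")
  if (x$singular) cat("  NOTE: singular fit (a variance component at the boundary)\n")
  invisible(x)
}

#' @export
summary.growth_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.growth_model <- function(object, ...) object$beta

#' Wald confidence intervals for growth-model fixed effects
#' @param object a `growth_model`.
#' @param parm parameter names (default all).
#' @param level confidence level.
#' @param ... ignored.
#' @return Matrix of lower/upper bounds.
#' @export
confint.growth_model <- function(object, parm = names(object$beta),
                                 level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$beta[parm] - z * object$se[parm]
  hi <- object$beta[parm] + z * object$se[parm]
  cbind(lower = lo, upper = hi)
}
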