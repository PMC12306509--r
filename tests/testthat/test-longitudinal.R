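test_that("annual decline rates follow the defining arithmetic", {
  v1 <- cohort_volumes(matrix(1.0, 2, 8), c(2, 2, 2), 1.5)
  v2 <- cohort_volumes(matrix(0.98, 2, 8), c(2, 2, 2), 1.5)
  rm <- annual_decline_rate(v1, v2, c(2, 2))
  expect_equal(unique(as.vector(rm$rates)), -0.01, tolerance = 1e-14)
  # identical volumes: zero rates
  rm0 <- annual_decline_rate(v1, v1, c(2, 2))
  expect_true(all(rm0$rates == 0))
  # absolute mode
  rma <- annual_decline_rate(v1, v2, c(2, 2), mode = "absolute")
  expect_equal(unique(as.vector(rma$rates)), -0.01, tolerance = 1e-14)
  # zero baseline voxels are undefined and counted
  v1z <- cohort_volumes(matrix(c(0, rep(1, 15)), 2, 8, byrow = FALSE),
                        c(2, 2, 2), 1.5)
  rmz <- annual_decline_rate(v1z, v2, c(2, 2))
  expect_equal(rmz$n_undefined, sum(v1z$data == 0))
  expect_true(anyNA(rmz$rates))
})

test_that("rates round-trip the generator's planted rates to machine precision", {
  cfg <- tiny_config(d = 0, n = 10, seed = 13, followup_jitter_sd = 0,
                     decline_rate_base = -0.008, decline_rate_delta = -0.012)
  coh <- generate_cohort(cfg)
  fu <- generate_followup(coh, cfg)
  expect_equal(fu$n_clipped, 0)
  rm <- annual_decline_rate(coh$volumes, fu$volumes_t2,
                            fu$phenotypes$interval_years)
  nonzero <- coh$volumes$data > 0
  expect_lt(max(abs(rm$rates[nonzero] - fu$true_rate[nonzero])), 1e-12)
})

test_that("region rates aggregate correctly on a hand-checked toy", {
  rates <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                    8, 7, 6, 5, 4, 3, 2, 1), 2, 8, byrow = TRUE)
  rm <- structure(list(rates = rates, interval_years = c(1, 1),
                       mode = "fractional", n_undefined = 0L,
                       dims = c(2, 2, 2), voxel_mm = 1.5),
                  class = "decline_rate_map")
  atlas <- array(c(1, 1, 1, 1, 2, 2, 2, 2), dim = c(2, 2, 2))
  rr <- region_rates(rm, atlas)
  expect_equal(unname(rr[1, ]), c(mean(1:4), mean(5:8)))
  expect_equal(unname(rr[2, ]), c(mean(8:5), mean(4:1)))
  # constant map: every region equals the constant; one-region atlas = global mean
  rmc <- rm; rmc$rates[] <- -0.02
  expect_true(all(abs(region_rates(rmc, atlas) + 0.02) < 1e-14))
  a1 <- array(1L, dim = c(2, 2, 2))
  expect_equal(unname(region_rates(rm, a1)[, 1]), rowMeans(rates))
})

test_that("rate group contrasts localize the planted decline region", {
  cfg <- synth_config(grid_dims = c(12, 12, 12), n_per_group = 30,
                      effect_regions = list(list(center = c(6, 6, 6),
                                                 radius_mm = 5, d = 0)),
                      decline_rate_base = -0.005, decline_rate_delta = -0.03,
                      followup_jitter_sd = 0.2, seed = 17)
  coh <- generate_cohort(cfg)
  fu <- generate_followup(coh, cfg)
  mask <- build_mask(coh$volumes)
  rm <- annual_decline_rate(coh$volumes, fu$volumes_t2,
                            fu$phenotypes$interval_years)
  sm <- rate_group_diff(rm, coh$phenotypes$group,
                        coh$phenotypes[, c("age", "gender", "education", "tiv")],
                        mask)
  cl <- extract_clusters(sm, fdr_correct(sm$p)$significant, min_extent = 5)
  expect_gt(nrow(cl), 0)
  peak_lin <- 1L + cl$peak_i[1] + 12L * (cl$peak_j[1] + 12L * cl$peak_k[1])
  expect_true(as.vector(coh$truth$planted_voxel_masks[[1]])[peak_lin])
  # antisymmetry under label swap
  sm2 <- rate_group_diff(rm, ifelse(coh$phenotypes$group == "DD", "ODD", "DD"),
                         coh$phenotypes[, c("age", "gender", "education", "tiv")],
                         mask)
  expect_equal(sm$t, -sm2$t, tolerance = 1e-10)
})

test_that("rate-cognition correlation matches the textbook formula", {
  # printed 6-pair toy
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  y <- c(1.2, 0.9, 1.1, 0.7, 0.6, 0.2)
  out <- rate_cognition_correlation(matrix(x, dimnames = list(NULL, "region_1")),
                                    matrix(y, dimnames = list(NULL, "memory")))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$p, cor.test(x, y)$p.value)
  # exact dependence: r = 1
  out1 <- rate_cognition_correlation(matrix(x, dimnames = list(NULL, "region_1")),
                                     matrix(x, dimnames = list(NULL, "memory")))
  expect_equal(out1$r, 1)
  expect_error(rate_cognition_correlation(matrix(x[1:4], dimnames = list(NULL, "r")),
                                          matrix(y[1:4], dimnames = list(NULL, "m"))),
               "fewer than 5")
})

test_that("variance explained converts a correlation to percent R^2", {
  expect_equal(variance_explained_pct(0.5), 25)
  expect_equal(variance_explained_pct(-0.3), 9, tolerance = 1e-12)
})

test_that("mediation with b = 0 reports no mediation; full mediation reports ~1", {
  set.seed(24)
  n <- 300
  g <- rep(c(1, 0), each = n / 2)
  m <- 0.8 * g + rnorm(n, sd = 0.5)
  y_direct <- 1.0 * g + rnorm(n, sd = 0.5)        # no path through m
  med0 <- mediate(g, m, y_direct, n_boot = 400, seed = 1)
  expect_lt(abs(med0$b), 0.15)
  expect_true(med0$ci_ab[1] <= 0 & med0$ci_ab[2] >= 0)
  # full mediation: group affects outcome only through the mediator, so the
  # indirect effect approaches the total effect and the proportion sits near 1
  y_med <- 1.2 * m + rnorm(n, sd = 0.4)
  med1 <- mediate(g, m, y_med, n_boot = 400, seed = 2)
  expect_false(is.na(med1$proportion_mediated))
  expect_true(med1$ci_ab[1] <= 0.8 * 1.2 & 0.8 * 1.2 <= med1$ci_ab[2])
  expect_gt(med1$proportion_mediated, 0.7)
  expect_lt(med1$proportion_mediated, 1.4)
})

test_that("mediation paths are recovered and the proportion is scale-invariant", {
  set.seed(22)
  abs_err <- replicate(10, {
    n <- 500
    g <- rep(c(1, 0), each = n / 2)
    m <- 0.6 * g + rnorm(n, sd = 0.6)
    y <- 0.5 * m + 0.4 * g + rnorm(n, sd = 0.6)
    med <- mediate(g, m, y, n_boot = 200, seed = sample.int(1e6, 1))
    med$ab - 0.6 * 0.5
  })
  expect_lt(abs(mean(abs_err)), 0.1 * 0.3 + 0.02)
  # affine rescaling of the outcome leaves the proportion mediated unchanged
  n <- 400
  g <- rep(c(1, 0), each = n / 2)
  m <- 0.6 * g + rnorm(n, sd = 0.6)
  y <- 0.5 * m + 0.4 * g + rnorm(n, sd = 0.6)
  p1 <- mediate(g, m, y, n_boot = 100, seed = 3)$proportion_mediated
  p2 <- mediate(g, m, 5 * y, n_boot = 100, seed = 3)$proportion_mediated
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("the null model separates between- and within-subject variance", {
  set.seed(23)
  n <- 200; visits <- 3
  id <- rep(sprintf("S%03d", 1:n), each = visits)
  u <- rep(rnorm(n, sd = 2), each = visits)
  d_all <- data.frame(id = id, score = u + rnorm(n * visits, sd = 1))
  nm <- fit_null_model(d_all)
  expect_lt(abs(nm$var_between - 4), 0.8)
  expect_lt(abs(nm$var_within - 1), 0.2)
  expect_lt(abs(nm$icc - 4 / 5), 0.05)
  # replicated identical scores within subject: ICC ~ 1
  d_same <- data.frame(id = id, score = u + rnorm(n * visits, sd = 1e-3))
  expect_gt(fit_null_model(d_same)$icc, 0.99)
  # no subject effect: ICC ~ 0
  d_noise <- data.frame(id = id, score = rnorm(n * visits))
  expect_lt(fit_null_model(d_noise)$icc, 0.05)
})

test_that("the growth model recovers a planted exposure effect on the slope", {
  d_all <- simulate_growth(n = 250, beta14 = -0.3, seed = 31)
  fit <- fit_growth_model(d_all)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta["beta14"] + 0.3), 2.5 * fit$se["beta14"])
  expect_gt(fit$var_r0, 0)
  ci <- confint(fit, "beta14")
  expect_lt(ci[1], fit$beta["beta14"])
  # fixed effects invariant to gender recoding {0,1} -> {1,2} except intercepts
  d2 <- d_all; d2$gender <- d2$gender + 1
  fit2 <- fit_growth_model(d2)
  keep <- c("beta01", "beta03", "beta04", "beta11", "beta13", "beta14")
  expect_equal(fit$beta[keep], fit2$beta[keep], tolerance = 1e-3)
})

test_that("a zero random-slope variance generator is flagged near the boundary", {
  d_all <- simulate_growth(n = 120, beta14 = 0, seed = 32, sd_r1 = 0)
  fit <- suppressMessages(fit_growth_model(d_all))
  expect_lt(fit$var_r1, 0.01)
  expect_true(fit$singular || fit$var_r1 < 0.01)
})
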