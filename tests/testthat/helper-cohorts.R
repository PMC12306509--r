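# small cohort configurations shared across test files

tiny_config <- function(d = 0, n = 12, seed = 1, grid = c(10, 10, 10),
                        radius_mm = 4, ...) {
  synth_config(grid_dims = grid, n_per_group = n,
               effect_regions = list(list(center = round(grid / 2),
                                          radius_mm = radius_mm, d = d)),
               seed = seed, ...)
}

# planted-region logical vector over the in-mask ordering of `voxel_idx`
planted_inmask <- function(cohort, voxel_idx, region = 1) {
  as.vector(cohort$truth$planted_voxel_masks[[region]])[voxel_idx]
}

# independent step-up BH oracle (kept deliberately naive)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# two-level growth trajectories with a known exposure effect on the slope
simulate_growth <- function(n = 200, visits = 3, beta14 = -0.3, seed = 1,
                            sd_r0 = 1, sd_r1 = 0.15, sd_e = 0.5) {
  set.seed(seed)
  age <- rnorm(n, 72, 5); gender <- rbinom(n, 1, 0.5)
  edu <- round(rnorm(n, 11, 3)); grp <- rep(c(1, 0), each = n / 2)
  r0 <- rnorm(n, sd = sd_r0); r1 <- rnorm(n, sd = sd_r1)
  pi0 <- 2 + 0.02 * age + 0.1 * gender + 0.05 * edu - 0.2 * grp + r0
  pi1 <- -0.1 - 0.01 * age + 0.02 * gender + 0.01 * edu + beta14 * grp + r1
  do.call(rbind, lapply(1:n, function(i) {
    time <- (0:(visits - 1)) * 1.6
    data.frame(id = sprintf("S%03d", i),
               score = pi0[i] + pi1[i] * time + rnorm(visits, sd = sd_e),
               time = time, age_baseline = age[i], gender = gender[i],
               education = edu[i], group = grp[i])
  }))
}

# explicit per-voxel OLS oracle for the group t statistic
ols_t_oracle <- function(y, design) {
  fit <- lm.fit(design, y)
  res <- fit$residuals
  df <- length(y) - ncol(design)
  sigma2 <- sum(res^2) / df
  XtXi <- solve(crossprod(design))
  fit$coefficients[2] / sqrt(sigma2 * XtXi[2, 2])
}
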