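make_phen <- function(n = 40, seed = 1, age_shift = 0) {
  set.seed(seed)
  data.frame(id = sprintf("P%03d", 1:n),
             group = rep(c("DD", "ODD"), each = n / 2),
             age = rnorm(n, 70, 5) + rep(c(age_shift, 0), each = n / 2),
             gender = rbinom(n, 1, 0.5),
             education = round(rnorm(n, 11, 3)),
             tiv = rnorm(n, 1450, 100),
             stringsAsFactors = FALSE)
}

test_that("a covariate independent of group gives near-prevalence scores", {
  phen <- make_phen(200, seed = 2)
  res <- fit_propensity(phen, c("age", "gender", "education"))
  expect_true(all(res$score > 0 & res$score < 1))
  expect_lt(max(abs(res$score - 0.5)), 0.35)
  expect_lt(abs(mean(res$score) - 0.5), 0.05)
})

test_that("logistic scores match an independent IRLS oracle", {
  phen <- make_phen(80, seed = 3, age_shift = 4)
  res <- fit_propensity(phen, c("age", "gender"))
  # independent unpenalized IRLS solver
  X <- cbind(1, phen$age, phen$gender)
  y <- as.integer(phen$group == "DD")
  beta <- numeric(3)
  for (i in 1:60) {
    mu <- plogis(as.vector(X %*% beta))
    w <- mu * (1 - mu)
    beta <- beta + solve(crossprod(X, X * w), crossprod(X, y - mu))
  }
  oracle <- plogis(as.vector(X %*% beta))
  expect_lt(max(abs(res$score - oracle)), 1e-8)
})

test_that("a fully separating covariate triggers the penalized fallback", {
  phen <- make_phen(40, seed = 4)
  phen$flag <- as.integer(phen$group == "DD")
  expect_warning(res <- fit_propensity(phen, c("age", "flag")), "separation")
  expect_true(res$separation)
  expect_true(all(res$score > 0 & res$score < 1))
})

test_that("constant covariates and one-group tables are rejected", {
  phen <- make_phen(20)
  phen$constant <- 1
  expect_error(fit_propensity(phen, c("age", "constant")), "constant")
  phen2 <- make_phen(20); phen2$group <- "DD"
  expect_error(fit_propensity(phen2, "age"), "both exposure groups")
})

test_that("identical score distributions match everyone; caliper 0 matches ties only", {
  phen <- make_phen(40, seed = 5)
  res <- fit_propensity(phen, c("age", "gender"))
  # force identical logits across groups: every exposed finds a partner
  res$logit <- rep(seq(-1, 1, length.out = 20), 2)
  res$score <- plogis(res$logit)
  m <- match_pairs(res, caliper_sd = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 20)
  expect_equal(anyDuplicated(c(m$pairs$exposed_id, m$pairs$control_id)), 0L)
  # caliper 0 with no exact cross-group ties: no pairs at all
  res$logit <- c(seq(0, 1, length.out = 20), seq(0.001, 1.001, length.out = 20))
  expect_error(match_pairs(res, caliper_sd = 0, seed = 1), "no pairs")
})

test_that("greedy pairing equals exhaustive optimal pairing on a 6-subject toy", {
  # scores chosen so greedy and global-optimal coincide
  phen <- data.frame(id = sprintf("T%d", 1:6),
                     group = c("DD", "DD", "DD", "ODD", "ODD", "ODD"),
                     stringsAsFactors = FALSE)
  logit <- c(-1.0, 0.0, 1.0, -0.95, 0.1, 2.5)
  res <- structure(list(phenotypes = phen, logit = logit,
                        score = plogis(logit), covariates = character(0),
                        pairs = NULL, separation = FALSE),
                   class = "propensity_result")
  caliper_sd <- 0.3
  caliper <- caliper_sd * sd(logit)
  m <- match_pairs(res, caliper_sd = caliper_sd, seed = 1)

  # oracle: enumerate all one-to-one assignments, maximize pairs then
  # minimize total distance within the caliper
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- NULL
  for (pm in perms) {
    d <- abs(logit[1:3] - logit[3 + pm])
    ok <- d <= caliper
    cand <- list(n = sum(ok), total = sum(d[ok]),
                 pairs = cbind(which(ok), pm[ok]))
    if (is.null(best) || cand$n > best$n ||
        (cand$n == best$n && cand$total < best$total)) best <- cand
  }
  expect_equal(nrow(m$pairs), best$n)
  got <- sort(paste(m$pairs$exposed_id, m$pairs$control_id))
  want <- sort(paste(phen$id[best$pairs[, 1]], phen$id[3 + best$pairs[, 2]]))
  expect_equal(got, want)
})

test_that("matching improves covariate balance on imbalanced cohorts", {
  improved <- logical(0)
  for (s in 1:20) {
    phen <- make_phen(60, seed = s, age_shift = 4)
    res <- fit_propensity(phen, c("age", "gender", "education"))
    res <- tryCatch(match_pairs(res, caliper_sd = 0.25, seed = s),
                    error = function(e) NULL)
    if (is.null(res)) next
    bal <- balance_table(res)
    improved <- c(improved,
                  abs(bal$smd_after[bal$covariate == "age"]) <=
                    abs(bal$smd_before[bal$covariate == "age"]) + 1e-9)
    # matched n is even and equals twice the pair count
    expect_equal(nrow(matched_phenotypes(res)), 2 * nrow(res$pairs))
    # matching never widens the mean logit gap
    mp <- matched_phenotypes(res)
    lg <- res$logit[match(mp$id, phen$id)]
    gap_after <- abs(mean(lg[mp$group == "DD"]) - mean(lg[mp$group == "ODD"]))
    gap_before <- abs(mean(res$logit[phen$group == "DD"]) -
                      mean(res$logit[phen$group == "ODD"]))
    expect_lte(gap_after, gap_before + 1e-9)
  }
  expect_gt(mean(improved), 0.85)
})

test_that("SMD definitions hold on constructed examples", {
  # identical groups: every SMD is 0
  half <- data.frame(id = sprintf("A%d", 1:10), group = "DD",
                     age = 1:10, gender = rep(0:1, 5),
                     stringsAsFactors = FALSE)
  other <- half; other$id <- sprintf("B%d", 1:10); other$group <- "ODD"
  phen <- rbind(half, other)
  res <- structure(list(phenotypes = phen, logit = rep(0, 20),
                        score = rep(0.5, 20), covariates = c("age", "gender"),
                        pairs = data.frame(exposed_id = half$id,
                                           control_id = other$id,
                                           distance = 0),
                        separation = FALSE),
                   class = "propensity_result")
  bal <- balance_table(res)
  expect_true(all(bal$smd_before == 0))
  expect_true(all(bal$smd_after == 0))
  # mean difference equal to the pooled SD gives SMD exactly 1
  x <- c(1, 2, 3, 4, 5)   # per-group variance 2.5, pooled SD sqrt(2.5)
  phen2 <- data.frame(id = sprintf("C%d", 1:10),
                      group = rep(c("DD", "ODD"), each = 5),
                      age = c(x + sqrt(2.5), x), stringsAsFactors = FALSE)
  res2 <- structure(list(phenotypes = phen2, logit = rep(0, 10),
                         score = rep(0.5, 10), covariates = "age",
                         pairs = data.frame(exposed_id = phen2$id[1:5],
                                            control_id = phen2$id[6:10],
                                            distance = 0),
                         separation = FALSE),
                    class = "propensity_result")
  bal2 <- balance_table(res2)
  expect_equal(bal2$smd_before, 1.0, tolerance = 1e-12)
})
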