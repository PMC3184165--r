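make_design <- function(values, groups, runs = NULL, bin = 712.38) {
  if (is.null(runs)) runs <- rep(1L, length(values))
  data.frame(animal = sprintf("A%02d", seq_along(values)),
             group = groups, run = runs, bin = bin, value = values)
}

test_that("the per-bin linear model handles degenerate and planted cases", {
  # all observations equal -> zero effect, p = 1
  d <- make_design(rep(0.5, 9), rep(c("LC", "LD", "HD"), each = 3))
  r <- fit_linear_model(d, 712.38, contrast = "HD")
  expect_equal(r$effect, 0)
  expect_equal(r$p, 1)

  # balanced run offset leaves the treatment effect untouched
  set.seed(2)
  vals <- c(rnorm(4, 0, 0.2), rnorm(5, 0.8, 0.2))
  g <- rep(c("LC", "HD"), c(4, 5))
  d0 <- make_design(c(vals, vals), rep(g, 2), runs = rep(1:2, each = 9))
  d1 <- d0
  d1$value <- d1$value + ifelse(d1$run == 2, 0.7, 0)  # pure batch shift
  r0 <- fit_linear_model(d0, 712.38)
  r1 <- fit_linear_model(d1, 712.38)
  expect_equal(r1$effect, r0$effect, tolerance = 1e-10)
})

test_that("with two groups and no covariate the model reproduces the t-test", {
  set.seed(4)
  a <- rnorm(5); b <- rnorm(6, 0.5)
  d <- make_design(c(a, b), rep(c("LC", "HD"), c(5, 6)))
  r <- fit_linear_model(d, 712.38)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r$effect, mean(b) - mean(a), tolerance = 1e-12)
  expect_equal(r$t^2, unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the confounded column named", {
  # run perfectly confounded with group
  d <- make_design(rnorm(8), rep(c("LC", "HD"), each = 4),
                   runs = rep(1:2, each = 4))
  expect_error(fit_linear_model(d, 712.38), "confounded")
  expect_error(fit_linear_model(make_design(1:3, rep("LC", 3)), 712.38),
               "2 treatment groups")
})

test_that("the planted HD effect is recovered across seeds at study noise", {
  # per-observation noise matching 30% spot CV averaged over 12-spot ROIs
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    g <- rep(c("LC", "LD", "HD"), c(4, 5, 5))
    eff <- ifelse(g == "HD", log2(1.75), 0)
    vals <- c(eff + rnorm(14, 0, 0.18), eff + rnorm(14, 0, 0.18))
    d <- make_design(vals, rep(g, 2), runs = rep(1:2, each = 14))
    d$animal <- rep(sprintf("A%02d", 1:14), 2)
    r <- fit_linear_model(d, 712.38)
    hits <- hits + (abs(r$effect - log2(1.75)) <= 0.25)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)

  set.seed(14)
  for (k in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone, permutation-equivariant and order-preserving", {
  set.seed(15)
  p <- runif(30)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(30)
  expect_equal(adjust_bh(p[perm]), adj[perm])
  # adjusted values preserve the ranking of the raw p-values
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("under a uniform null BH rejects in about alpha of experiments", {
  set.seed(16)
  any_rej <- vapply(1:400, function(i) {
    any(adjust_bh(runif(200)) < 0.05)
  }, logical(1))
  expect_lte(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("behavior correlation returns exact values on constructed data", {
  x <- c(1, 2, 3, 4)
  r <- correlate_with_behavior(x, 2 * x)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)

  r2 <- correlate_with_behavior(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r2$r, 0.5)

  expect_error(correlate_with_behavior(rep(1, 5), 1:5), "undefined")
  expect_error(correlate_with_behavior(1:2, 2:3), "3 animals")
})

test_that("correlation is invariant to sign-preserving affine transforms", {
  set.seed(18)
  x <- rnorm(10); y <- 0.8 * x + rnorm(10, 0, 0.5)
  r0 <- correlate_with_behavior(x, y)$r
  expect_equal(correlate_with_behavior(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(correlate_with_behavior(x, 0.1 * y - 2)$r, r0,
               tolerance = 1e-12)
})

test_that("a planted bivariate correlation of 0.8 is recovered in expectation", {
  set.seed(19)
  rs <- vapply(1:500, function(i) {
    z <- rnorm(10)
    correlate_with_behavior(z, 0.8 * z + sqrt(1 - 0.64) * rnorm(10))$r
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.1)
})

test_that("one-way ANOVA with Tukey matches the sum-of-squares oracle", {
  # groups identical to each other (with internal spread): F = 0, p = 1
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anova_tukey(g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  # two groups: F equals the squared pooled t statistic
  set.seed(22)
  a <- rnorm(6); b <- rnorm(7, 1)
  r2 <- anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # fixture: F from explicit between/within sums of squares
  g3 <- list(x = c(3.1, 2.8, 3.5), y = c(4.0, 4.4, 3.9), z = c(2.0, 2.3, 2.6))
  r3 <- anova_tukey(g3)
  all_v <- unlist(g3)
  grand <- mean(all_v)
  ssb <- sum(vapply(g3, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  F_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(r3$F, F_oracle, tolerance = 1e-10)
  expect_equal(nrow(r3$tukey), 3L)

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("repeated-measures ANOVA separates time, group and interaction", {
  # identical trajectories in both groups -> no group effect
  traj <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6)
  r <- repeated_measures_anova(traj, rep(c("LD", "HD"), each = 3))
  expect_equal(r$p_group, 1)

  # constant offset, tiny within-group jitter: group effect, no interaction
  set.seed(23)
  base <- matrix(rep(seq(2, 16, by = 2), each = 8), nrow = 8)
  base[5:8, ] <- base[5:8, ] + 30
  base <- base + matrix(rnorm(64, 0, 0.1), nrow = 8)
  r2 <- repeated_measures_anova(base, rep(c("LD", "HD"), each = 4))
  expect_lt(r2$p_group, 0.001)
  expect_lt(r2$p_time, 0.001)
  expect_gt(r2$p_interaction, 0.05)
  expect_equal(nrow(r2$posthoc), 8L)
  expect_true(all(r2$posthoc$p_bonf >= r2$posthoc$p))

  base[1, 1] <- NA
  expect_error(repeated_measures_anova(base, rep(c("LD", "HD"), each = 4)),
               "missing cells")
})

test_that("generator-default trajectories yield time and group effects", {
  cfg <- cohort_config()
  ok <- 0
  for (seed in 1:100) {
    scores <- rbind(
      t(vapply(1:5, function(i) {
        beh <- generate_behavior(cfg, "LD", seed * 100 + i)
        vapply(beh$sessions, session_score, integer(1))
      }, integer(8))),
      t(vapply(1:5, function(i) {
        beh <- generate_behavior(cfg, "HD", seed * 100 + 50 + i)
        vapply(beh$sessions, session_score, integer(1))
      }, integer(8))))
    r <- repeated_measures_anova(scores, rep(c("LD", "HD"), each = 5))
    ok <- ok + (r$p_time < 0.05 && r$p_group < 0.05 &&
                  r$p_interaction > 0.05)
  }
  expect_gte(ok / 100, 0.9)
})
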