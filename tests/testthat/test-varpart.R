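test_that("marginal R2 matches the variance-ratio definition", {
  expect_equal(marginal_r2(0, 1, 1), 0)
  expect_equal(marginal_r2(1, 1, 2), 0.25)
  expect_error(marginal_r2(0, 0, 0), class = "fwtrace_domain_error")
  expect_error(marginal_r2(-1, 0, 1), class = "fwtrace_domain_error")
})

test_that("without grouping structure marginal R2 matches OLS R-squared", {
  set.seed(51)
  n <- 300
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  fit <- lm(y ~ x)
  r2_ols <- summary(fit)$r.squared
  expect_equal(r2_from_fit(fit), r2_ols, tolerance = 2 / n)
})

test_that("mixed-model marginal R2 uses the random-slope extension", {
  st <- generate_study(one_cohort(200, visits = 3), no_batch_truth(),
                       seed = 52, atlas = tiny_atlas(), metrics = "FW")
  fit <- suppressMessages(lme4::lmer(
    memory ~ baseline_age + interval + (1 + interval | participant_id),
    data = st))
  r2 <- r2_from_fit(fit)
  expect_gt(r2, 0)
  expect_lt(r2, 1)
  # decomposition consistency against hand-assembled components
  X <- lme4::getME(fit, "X")
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)$participant_id
  t_ <- st$interval
  var_r <- mean(vc[1, 1] + 2 * vc[1, 2] * t_ + vc[2, 2] * t_^2)
  expect_equal(r2, marginal_r2(var_f, var_r, stats::sigma(fit)^2),
               tolerance = 1e-10)
})

test_that("the identity resample reproduces the point estimate exactly", {
  st <- generate_study(one_cohort(150, visits = 3), no_batch_truth(),
                       seed = 53, atlas = tiny_atlas(), metrics = "FW")
  b <- bootstrap_delta_r2(st, "fornix.FW", n_boot = 2, seed = 1,
                          identity_resample = TRUE)
  expect_equal(b$replicates, rep(b$point_delta, 2))
})

test_that("bootstrap replicates are seed-deterministic", {
  st <- generate_study(one_cohort(80, visits = 3), no_batch_truth(),
                       seed = 54, atlas = tiny_atlas(), metrics = "FW")
  b1 <- bootstrap_delta_r2(st, "fornix.FW", n_boot = 5, seed = 9)
  b2 <- bootstrap_delta_r2(st, "fornix.FW", n_boot = 5, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_delta_r2(st, "fornix.FW", n_boot = 5, seed = 10)
  expect_false(identical(b1$replicates, b3$replicates))
  # nested in-sample fits: added variance cannot be meaningfully negative
  expect_gt(mean(b1$replicates), -0.1)
})

test_that("head-to-head handles ties, shifts and the full pair count", {
  mk <- function(tract, metric, reps) {
    structure(list(tract = tract, metric = metric, domain = "memory",
                   replicates = reps, n_boot = length(reps),
                   mean = mean(reps),
                   ci95 = range(reps), base_r2_mean = 30,
                   base_r2_ci = c(28, 32)), class = "boot_r2")
  }
  # identical replicate vectors: F = 0, q = 1
  r <- rnorm(50, 1, 1)
  h <- head_to_head(list(mk("fornix", "FW", r), mk("fornix", "FAt", r)),
                    grouping = "metric")
  expect_equal(h$anova_F, 0, tolerance = 1e-12)
  expect_equal(h$pairs$q, 1)

  # one group shifted by +5 with SD 1 dominates the ranking
  set.seed(55)
  groups <- list(mk("fornix", "FW", rnorm(100, 5, 1)),
                 mk("fornix", "FAt", rnorm(100, 0, 1)),
                 mk("fornix", "MDt", rnorm(100, 0.5, 1)))
  h2 <- head_to_head(groups, grouping = "metric")
  expect_equal(h2$ranking$group[1], "FW")
  fw_pairs <- h2$pairs$group1 == "FW" | h2$pairs$group2 == "FW"
  expect_true(all(h2$pairs$q[fw_pairs] < 0.05))

  # 7 tract types -> C(7,2) = 21 post-hoc pairs
  at <- atlas_registry()
  one_per_type <- at[!duplicated(at$tract_type), ]
  dl <- lapply(seq_len(7), function(i) {
    mk(one_per_type$tract[i], "FW", rnorm(10, i, 1))
  })
  h3 <- head_to_head(dl, grouping = "tract_type")
  expect_equal(nrow(h3$pairs), 21L)

  expect_error(head_to_head(groups[1], grouping = "metric"),
               class = "fwtrace_config_error")
})

test_that("delta R2 converges across sample sizes for a fixed effect", {
  tr <- no_batch_truth(theta_wm_slope = -0.15)
  st1 <- generate_study(one_cohort(150, visits = 3), tr, seed = 56,
                        atlas = tiny_atlas(), metrics = "FW")
  st2 <- generate_study(one_cohort(600, visits = 3), tr, seed = 57,
                        atlas = tiny_atlas(), metrics = "FW")
  b1 <- bootstrap_delta_r2(st1, "fornix.FW", n_boot = 30, seed = 11)
  b2 <- bootstrap_delta_r2(st2, "fornix.FW", n_boot = 30, seed = 11)
  wider <- max(diff(b1$ci95), diff(b2$ci95))
  expect_lt(abs(b1$mean - b2$mean), wider / 2 + 1e-9)
})
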