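test_that("demographic comparison routes through the decision tree", {
  set.seed(101)
  n <- 200
  demo <- data.frame(
    cohort = rep(c("X", "Y"), each = n),
    gauss_eq = rnorm(2 * n, 10, 1),                       # ANOVA
    gauss_uneq = c(rnorm(n, 10, 1), rnorm(n, 10, 4)),     # Welch
    heavy = c(rt(n, 2), rt(n, 2) + 1),                    # Kruskal-Wallis
    bigcat = sample(c("a", "b"), 2 * n, replace = TRUE),  # chi-square
    rarecat = c(rep("a", n - 2), rep("b", 2),
                rep("a", n - 1), rep("b", 1)),            # Fisher (exp < 5)
    flat = 1                                              # untestable
  )
  res <- compare_demographics(demo,
                              variables = c("gauss_eq", "gauss_uneq", "heavy",
                                            "bigcat", "rarecat", "flat"),
                              group = "cohort", baseline_only = FALSE)
  routes <- stats::setNames(res$test, res$variable)
  expect_equal(routes[["gauss_eq"]], "ANOVA")
  expect_equal(routes[["gauss_uneq"]], "Welch ANOVA")
  expect_equal(routes[["heavy"]], "Kruskal-Wallis")
  expect_equal(routes[["bigcat"]], "chi-square")
  expect_equal(routes[["rarecat"]], "Fisher exact")
  expect_equal(routes[["flat"]], "none")
  expect_error(compare_demographics(demo[demo$cohort == "X", ],
                                    variables = "gauss_eq",
                                    baseline_only = FALSE),
               class = "fwtrace_config_error")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  # order preservation and monotonicity in m
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- fdr_adjust(p)
  expect_equal(order(q), order(p))
  expect_true(all(q >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "fwtrace_domain_error")
  expect_error(fdr_adjust(c(0.5, NA)), class = "fwtrace_domain_error")
})

test_that("a noiseless outcome identical to the predictor returns beta = 1", {
  st <- generate_study(one_cohort(100), no_batch_truth(), seed = 31,
                       atlas = tiny_atlas(), metrics = "FW")
  st$memory <- st$fornix.FW
  res <- suppressWarnings(   # summary.lm warns on an exact fit
    cross_sectional_scan(st, features = "fornix.FW",
                         spec = model_spec("memory", covariates = NULL)))
  expect_equal(res$beta[1], 1, tolerance = 1e-8)
  expect_lt(res$p[1], 1e-12)
})

test_that("cross-sectional scan recovers the generating effect and nulls stay null", {
  tr <- no_batch_truth(beta_wm_cross = -0.5, theta_wm_slope = 0,
                       domain_weights = c(memory = 1, executive = 0,
                                          language = 0))
  st <- generate_study(one_cohort(1000, visits = 1), tr, seed = 32,
                       atlas = tiny_atlas(), metrics = "FW")
  res <- cross_sectional_scan(st, spec = model_spec("memory",
                                                    scale_outcome = FALSE))
  r <- res[res$tract == "fornix" & res$metric == "FW", ]
  se <- r$beta / r$z
  expect_lt(abs(r$beta - (-0.5)), 1.96 * se)
  # domains with no effect: uncorrelated tracts stay null
  res2 <- cross_sectional_scan(st, spec = model_spec("language"))
  null_feats <- res2$tract %in% c("corticospinal_tract", "TC_SPL", "TC_V1")
  expect_true(all(res2$q[null_feats] > 0.05))
})

test_that("permuted outcomes give uniform raw p-values", {
  st <- generate_study(one_cohort(400, visits = 1), no_batch_truth(),
                       seed = 33, atlas = atlas_registry(), metrics = "FW")
  set.seed(1)
  base <- !duplicated(st$participant_id)
  st$memory[base] <- sample(st$memory[base])
  res <- cross_sectional_scan(st, spec = model_spec("memory"))
  frac <- mean(res$p < 0.05)
  # binomial 99% bounds around 0.05 at 48 tests (features correlated, so
  # generous bound)
  expect_lt(frac, 0.2)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("longitudinal scan recovers the slope coefficient and flags degenerate designs", {
  tr <- no_batch_truth(theta_wm_slope = -0.15)
  st <- generate_study(one_cohort(800, visits = 3), tr, seed = 34,
                       atlas = tiny_atlas(), metrics = "FW")
  res <- longitudinal_scan(st, features = "fornix.FW",
                           spec = model_spec("memory", scale_outcome = FALSE))
  expect_true(res$converged[1])
  se <- res$beta[1] / res$z[1]
  expect_lt(abs(res$beta[1] - (-0.15)), 1.96 * se)

  st1 <- generate_study(one_cohort(100, visits = 1), tr, seed = 35,
                        atlas = tiny_atlas(), metrics = "FW")
  st1 <- st1[st1$visit_index == 1, ]
  expect_error(longitudinal_scan(st1), class = "fwtrace_degenerate_design")
})

test_that("null slope effects are non-significant after FDR", {
  tr <- no_batch_truth(theta_wm_slope = 0, beta_wm_cross = 0)
  st <- generate_study(one_cohort(300, visits = 3), tr, seed = 36,
                       atlas = tiny_atlas(), metrics = c("FW", "FAt"))
  res <- longitudinal_scan(st, spec = model_spec("memory"))
  expect_gte(mean(res$q >= 0.05), 0.95)
})

test_that("standardized beta is invariant to covariate rescaling", {
  st <- generate_study(one_cohort(300), no_batch_truth(), seed = 37,
                       atlas = tiny_atlas(), metrics = "FW")
  r1 <- cross_sectional_scan(st, features = "fornix.FW")
  st2 <- st
  st2$education <- st2$education * 100
  r2 <- cross_sectional_scan(st2, features = "fornix.FW")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("interaction scan recovers a generating interaction and keeps hierarchy", {
  tr <- no_batch_truth(phi_endo_cross = c(hippocampal_volume = 0.3,
                                          spare_ad = 0, amyloid_positive = 0,
                                          tau_positive = 0))
  st <- generate_study(one_cohort(800, visits = 1), tr, seed = 38,
                       atlas = tiny_atlas(), metrics = "FW")
  res <- interaction_scan(st, features = "fornix.FW",
                          endophenotype = "hippocampal_volume",
                          mode = "cross-sectional",
                          spec = model_spec("memory", scale_outcome = FALSE))
  expect_true(res$converged[1])
  se <- res$beta[1] / res$z[1]
  expect_lt(abs(res$beta[1] - 0.3), 2.5 * abs(se))
  expect_lt(res$p[1], 0.05)
})

test_that("null interactions stay null and degenerate endophenotypes are flagged", {
  tr <- no_batch_truth()
  st <- generate_study(one_cohort(300, visits = 2), tr, seed = 39,
                       atlas = tiny_atlas(), metrics = c("FW", "FAt"))
  res <- interaction_scan(st, endophenotype = "tau_positive",
                          mode = "cross-sectional")
  expect_gte(mean(res$q >= 0.05, na.rm = TRUE), 0.9)

  st$const_endo <- 1
  res2 <- interaction_scan(st, features = "fornix.FW",
                           endophenotype = "const_endo",
                           mode = "cross-sectional")
  expect_false(res2$converged[1])

  st$bad <- factor(rep("x", nrow(st)), levels = c("x", "y"))
  expect_error(interaction_scan(st, features = "fornix.FW",
                                endophenotype = "bad",
                                mode = "cross-sectional"),
               class = "fwtrace_config_error")
})

test_that("longitudinal interaction models contain all lower-order terms", {
  tr <- no_batch_truth(phi_endo = c(hippocampal_volume = 0.1, spare_ad = 0,
                                    amyloid_positive = 0, tau_positive = 0))
  st <- generate_study(one_cohort(300, visits = 3), tr, seed = 40,
                       atlas = tiny_atlas(), metrics = "FW")
  res <- interaction_scan(st, features = "fornix.FW",
                          endophenotype = "hippocampal_volume",
                          mode = "longitudinal",
                          spec = model_spec("memory", scale_outcome = FALSE))
  expect_true(res$converged[1])
  expect_equal(res$term[1], "wm:hippocampal_volume:interval")
})
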