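test_that("default 7-cohort configuration reproduces the study composition", {
  st <- generate_study(seed = 1, atlas = tiny_atlas(), metrics = "FW")
  counts <- table(st$cohort[!duplicated(st$participant_id)])
  expect_equal(sum(counts), 4467L)
  expect_equal(as.integer(counts[c("ADNI", "BLSA", "BIOCARD", "NACC",
                                   "ROSMAPMARS", "VMAP", "WRAP")]),
               c(830L, 757L, 127L, 974L, 1160L, 326L, 293L))
  # interval bookkeeping
  expect_equal(st$interval, st$age_at_visit - st$baseline_age)
  expect_true(all(st$interval >= 0))
  expect_true(all(st$interval[st$visit_index == 1] == 0))
  # one batch per participant
  expect_true(all(tapply(st$batch, st$participant_id,
                         function(b) length(unique(b))) == 1))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_study(one_cohort(50), no_batch_truth(), seed = 3,
                      atlas = tiny_atlas(), metrics = "FW")
  b <- generate_study(one_cohort(50), no_batch_truth(), seed = 3,
                      atlas = tiny_atlas(), metrics = "FW")
  expect_identical(a, b)
  c_ <- generate_study(one_cohort(50), no_batch_truth(), seed = 4,
                       atlas = tiny_atlas(), metrics = "FW")
  expect_false(identical(a$memory, c_$memory))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config("X", 0, 70, 5, 2, 1),
               class = "fwtrace_config_error")
  expect_error(cohort_config("X", 10, 70, 5, 2, 1,
                             diagnosis_mix = c(0.5, 0.4, 0.2)),
               class = "fwtrace_config_error")
  expect_error(cohort_config("X", 10, 70, 5, 2, 0),
               class = "fwtrace_config_error")
  expect_error(truth_params(delta_batch = c(b = -1)),
               class = "fwtrace_config_error")
  expect_error(truth_params(sigma_resid = -0.1),
               class = "fwtrace_config_error")
  expect_error(generate_study(list(), seed = 1),
               class = "fwtrace_config_error")
  expect_error(generate_study(one_cohort(20),
                              truth_params(wm_feature = "nope.FW"),
                              seed = 1, atlas = tiny_atlas(), metrics = "FW"),
               class = "fwtrace_config_error")
})

test_that("marginal structure matches the configured cohort parameters", {
  cfg <- list(cohort_config("A", 600, 74, 7, 2.5, 1.5),
              cohort_config("B", 400, 68, 9, 1.8, 2.0,
                            batch_ids = "B_b1"))
  st <- generate_study(cfg, truth_params(), seed = 5, atlas = tiny_atlas(),
                       metrics = "FW")
  base <- st[!duplicated(st$participant_id), ]
  for (cf in cfg) {
    b <- base[base$cohort == cf$name, ]
    se_age <- cf$age_sd / sqrt(nrow(b))
    expect_lt(abs(mean(b$age) - cf$age_mean) / se_age, 3.5)
    nv <- table(st$participant_id[st$cohort == cf$name])
    se_v <- sqrt(max(cf$visit_count_mean - 1, 0)) / sqrt(length(nv))
    expect_lt(abs(mean(nv) - cf$visit_count_mean) / max(se_v, 1e-9), 3.5)
  }
})

test_that("null slope effect leaves per-participant slopes uncorrelated with baseline WM", {
  tr <- no_batch_truth(theta_wm_slope = 0)
  st <- generate_study(one_cohort(400, visits = 3), tr, seed = 6,
                       atlas = tiny_atlas(), metrics = "FW")
  nv <- table(st$participant_id)
  keep <- names(nv)[nv >= 2]
  slopes <- vapply(keep, function(p) {
    d <- st[st$participant_id == p, ]
    stats::coef(stats::lm(d$memory ~ d$interval))[2]
  }, numeric(1))
  W <- attr(st, "truth")$W[keep]
  r <- stats::cor(slopes, W)
  # 95% null bound for a correlation at this n
  expect_lt(abs(r), 1.96 / sqrt(length(keep) - 3))
})

test_that("injected batch shifts appear in pre-harmonization feature means", {
  cfg <- list(cohort_config("A", 300, 74, 7, 2, 1.5, batch_ids = "b1"),
              cohort_config("B", 300, 74, 7, 2, 1.5, batch_ids = "b2"))
  tr <- truth_params(gamma_batch = c(b1 = 0, b2 = 2), delta_batch = c(b1 = 1, b2 = 1))
  st <- generate_study(cfg, tr, seed = 7, atlas = tiny_atlas(), metrics = "FW")
  # gamma is in feature-SD units: expect a 2 * 0.04 shift on FW features
  gap <- diff(tapply(st$fornix.FW, st$batch, mean))
  sdW <- stats::sd(st$fornix.FW)
  se <- sdW * sqrt(2 / 300)
  expect_lt(abs(gap - 2 * 0.04), 3 * se)
})

test_that("monotone dropout shortens follow-up", {
  tr_off <- no_batch_truth()
  tr_on <- no_batch_truth(dropout_hazard = 0.5)
  st0 <- generate_study(one_cohort(200, visits = 4), tr_off, seed = 8,
                        atlas = tiny_atlas(), metrics = "FW")
  st1 <- generate_study(one_cohort(200, visits = 4), tr_on, seed = 8,
                        atlas = tiny_atlas(), metrics = "FW")
  expect_lt(nrow(st1), nrow(st0))
  expect_true(all(st1$interval[st1$visit_index == 1] == 0))
})
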