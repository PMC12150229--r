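three_batch_config <- function(n = 120, visits = 2.5) {
  list(cohort_config("A", n, 74, 7, visits, 1.5, batch_ids = "b1"),
       cohort_config("B", n, 74, 7, visits, 1.5, batch_ids = "b2"),
       cohort_config("C", n, 74, 7, visits, 1.5, batch_ids = "b3"))
}

test_that("null batch effects give near-zero gamma and unit delta", {
  tr <- truth_params(gamma_batch = c(b1 = 0, b2 = 0, b3 = 0),
                     delta_batch = c(b1 = 1, b2 = 1, b3 = 1))
  st <- generate_study(three_batch_config(150), tr, seed = 21,
                       atlas = tiny_atlas(), metrics = "FW")
  cm <- fit_longcombat(st)
  be <- batch_effects(cm)
  # raw-scale gamma reflects between-subject sampling of batch composition:
  # SE ~ sd(feature) / sqrt(subjects per batch); 4 SE guards the max over
  # 6 features x 3 batches
  nsub <- tapply(st$participant_id, st$batch, function(p) length(unique(p)))
  for (i in seq_len(nrow(be))) {
    se <- stats::sd(st[[be$feature[i]]]) / sqrt(nsub[[be$batch[i]]])
    expect_lt(abs(be$gamma_star_raw[i]), 4 * se)
  }
  expect_true(all(be$delta_star > 0.9 & be$delta_star < 1.1))
})

test_that("an injected additive batch shift is recovered within 0.02", {
  tr <- truth_params(gamma_batch = c(b1 = 0, b2 = 2.5, b3 = 0),
                     delta_batch = c(b1 = 1, b2 = 1, b3 = 1))
  st <- generate_study(three_batch_config(200), tr, seed = 22,
                       atlas = tiny_atlas(), metrics = "FW")
  cm <- fit_longcombat(st)
  be <- subset(batch_effects(cm), feature == "fornix.FW")
  # injected raw shift = 2.5 gamma units x 0.04 SD = 0.1
  gap <- be$gamma_star_raw[be$batch == "b2"] -
    mean(be$gamma_star_raw[be$batch != "b2"])
  expect_lt(abs(gap - 0.1), 0.02)
})

test_that("harmonization removes injected location and scale effects", {
  tr <- truth_params(gamma_batch = c(b1 = 0, b2 = 2.5, b3 = 0),
                     delta_batch = c(b1 = 1, b2 = 1, b3 = 2))
  st <- generate_study(three_batch_config(150), tr, seed = 23,
                       atlas = tiny_atlas(), metrics = "FW")
  cm <- fit_longcombat(st)
  h <- apply_longcombat(st, cm)
  gap <- function(d, col) diff(range(tapply(d[[col]], d$batch, mean)))
  expect_lt(gap(h, "fornix.FW"), 0.1 * gap(st, "fornix.FW"))

  # per-batch refit residual variances equalize
  resvar <- function(d, col) {
    vapply(split(seq_len(nrow(d)), d$batch), function(ix) {
      di <- d[ix, ]
      m <- suppressMessages(suppressWarnings(
        lme4::lmer(di[[col]] ~ age_at_visit + (1 | participant_id),
                   data = di)))
      stats::sigma(m)^2
    }, numeric(1))
  }
  pre <- resvar(st, "SLF.FW"); post <- resvar(h, "SLF.FW")
  expect_gt(max(pre) / min(pre), 2)
  expect_lt(max(post) / min(post), 1.25)
  expect_gt(max(post) / min(post), 0.8)
})

test_that("two equal batches with a pure mean shift decompose exactly", {
  # no covariates, one feature, no noise beyond the shift: gamma (raw)
  # equals each batch's deviation from the grand mean
  set.seed(1)
  n <- 30
  base <- rnorm(n)
  df <- data.frame(
    participant_id = c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n)),
    batch = rep(c("A", "B"), each = n),
    y.FW = c(base, base + 0.5)
  )
  df <- rbind(df, df)  # two visits per subject, identical values
  cm <- fit_longcombat(df, feature_cols = "y.FW", design = ~1, eb = FALSE)
  be <- batch_effects(cm)
  # optimizer-level precision on a degenerate zero-residual problem
  expect_lt(abs(be$gamma_star_raw[be$batch == "A"] + 0.25), 1e-5)
  expect_lt(abs(be$gamma_star_raw[be$batch == "B"] - 0.25), 1e-5)
  h <- apply_longcombat(df, cm)
  expect_lt(abs(diff(tapply(h$y.FW, df$batch, mean))), 1e-5)
})

test_that("harmonization is an identity when batches are clones", {
  st <- generate_study(one_cohort(40), no_batch_truth(), seed = 24,
                       atlas = tiny_atlas(), metrics = "FW")
  st2 <- st
  st2$batch <- "clone"
  st2$participant_id <- paste0(st2$participant_id, "_c")
  both <- rbind(as.data.frame(st), as.data.frame(st2))
  fc <- attr(st, "truth")$feature_names
  cm <- fit_longcombat(both, feature_cols = fc)
  h <- apply_longcombat(both, cm)
  for (f in fc) {
    expect_lt(max(abs(h[[f]] - both[[f]])) / stats::sd(both[[f]]), 1e-6)
  }
})

test_that("harmonizing twice changes values by less than 1% RMS", {
  tr <- truth_params(gamma_batch = c(b1 = -1, b2 = 0, b3 = 1),
                     delta_batch = c(b1 = 0.8, b2 = 1, b3 = 1.3))
  st <- generate_study(three_batch_config(120), tr, seed = 25,
                       atlas = tiny_atlas(), metrics = "FW")
  h1 <- apply_longcombat(st, fit_longcombat(st))
  h2 <- apply_longcombat(h1, fit_longcombat(h1))
  for (f in attr(st, "truth")$feature_names) {
    expect_lt(sqrt(mean((h2[[f]] - h1[[f]])^2)) / stats::sd(h1[[f]]), 0.01)
  }
})

test_that("feature-column permutation permutes outputs identically", {
  tr <- truth_params(gamma_batch = c(b1 = 0, b2 = 1.5, b3 = 0),
                     delta_batch = c(b1 = 1, b2 = 1, b3 = 1))
  st <- generate_study(three_batch_config(60, visits = 2), tr, seed = 26,
                       atlas = tiny_atlas(), metrics = "FW")
  fc <- attr(st, "truth")$feature_names
  h1 <- apply_longcombat(st, fit_longcombat(st, feature_cols = fc))
  h2 <- apply_longcombat(st, fit_longcombat(st, feature_cols = rev(fc)))
  for (f in fc) expect_equal(h1[[f]], h2[[f]], tolerance = 1e-10)
})

test_that("degenerate inputs are refused with informative errors", {
  st <- generate_study(one_cohort(30), no_batch_truth(), seed = 27,
                       atlas = tiny_atlas(), metrics = "FW")
  expect_error(fit_longcombat(st), "2 batches")
  st$batch[st$participant_id == st$participant_id[1]] <- "lonely"
  expect_error(fit_longcombat(st), "lonely")
  # rank-deficient preserve design names the collinear term
  st2 <- generate_study(three_batch_config(20, visits = 2),
                        truth_params(gamma_batch = c(b1 = 0, b2 = 0, b3 = 0),
                                     delta_batch = c(b1 = 1, b2 = 1, b3 = 1)),
                        seed = 28, atlas = tiny_atlas(), metrics = "FW")
  st2$dup_age <- st2$age_at_visit
  expect_error(fit_longcombat(st2, design = ~ age_at_visit + dup_age),
               "dup_age")
  # unseen batch at apply time
  cm <- fit_longcombat(st2)
  st3 <- st2; st3$batch[1] <- "new_batch"
  expect_error(apply_longcombat(st3, cm), class = "fwtrace_apply_error")
})
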