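# Multi-cohort longitudinal study simulator.
#
# Generates participant-visit tables with the statistical structure the
# downstream analyses assume: unequal cohorts, subject-specific cognitive
# trajectories, tract features with injected batch effects, and cognition
# whose baseline level and annual slope depend on a designated white-matter
# feature and its interactions with AD endophenotypes. The generating
# mixed model for each cognitive domain d of participant i at visit j is
#
#   y_dij = alpha_d + x_i' beta + w_d * beta_wm_cross * W_i + b0_di
#           + (s0 + s_age (age_i0 - 74) + b1_di
#              + w_d * (theta + sum_e phi_e E_ie) * W_i) * t_ij + eps_dij
#
# with W_i the standardized noise-free baseline value of the driving
# feature, t_ij the interval in years, and (b0, b1) subject random effects.

#' Cohort configuration for the study simulator
#'
#' @param name cohort label.
#' @param n_participants number of participants (>= 1).
#' @param age_mean,age_sd baseline age distribution (years).
#' @param visit_count_mean mean total visits per participant (visits beyond
#'   baseline are Poisson with mean `visit_count_mean - 1`).
#' @param visit_interval_mean mean gap between consecutive visits (years,
#'   > 0); gaps are gamma-jittered around this mean.
#' @param diagnosis_mix named proportions over `c(CU, MCI, AD)`, summing to 1.
#' @param apoe4_rate APOE e4 carrier proportion.
#' @param batch_ids imaging batch labels available to this cohort; each
#'   participant's sessions are assigned one batch.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(name, n_participants, age_mean, age_sd,
                          visit_count_mean, visit_interval_mean,
                          diagnosis_mix = c(CU = 0.7, MCI = 0.22, AD = 0.08),
                          apoe4_rate = 0.3,
                          batch_ids = paste0(name, "_b1")) {
  check_number(n_participants, "n_participants", lower = 1)
  check_number(visit_interval_mean, "visit_interval_mean", lower = 1e-9)
  check_number(visit_count_mean, "visit_count_mean", lower = 1)
  if (length(diagnosis_mix) != 3L || abs(sum(diagnosis_mix) - 1) > 1e-6 ||
      any(diagnosis_mix < 0)) {
    fw_stop("diagnosis_mix must be 3 non-negative proportions summing to 1",
            "fwtrace_config_error")
  }
  names(diagnosis_mix) <- c("CU", "MCI", "AD")
  structure(list(name = name, n_participants = as.integer(n_participants),
                 age_mean = age_mean, age_sd = age_sd,
                 visit_count_mean = visit_count_mean,
                 visit_interval_mean = visit_interval_mean,
                 diagnosis_mix = diagnosis_mix, apoe4_rate = apoe4_rate,
                 batch_ids = batch_ids),
            class = "cohort_config")
}

#' Default 7-cohort configuration
#'
#' Mirrors the participant counts, baseline-age distributions, mean visit
#' counts and baseline clinical mix of the seven contributing cohorts
#' (ADNI, BLSA, BIOCARD, NACC, ROS/MAP/MARS, VMAP, WRAP). Visit-interval
#' means are back-computed from mean follow-up time over mean extra visits
#' and clipped to a plausible 1-3 year window.
#'
#' @param scale optional multiplier on every cohort's `n_participants`
#'   (e.g. `scale = 0.1` for a desk-scale run); resulting counts are
#'   rounded up to at least 2.
#' @return List of 7 [cohort_config()] objects.
#' @export
default_cohort_configs <- function(scale = 1) {
  mk <- function(name, n, am, asd, vc, fu, dx_n, apoe4) {
    iv <- if (vc > 1.1) min(max(fu / (vc - 1), 1), 3) else 2
    cohort_config(name, max(2L, ceiling(n * scale)), am, asd, vc, iv,
                  diagnosis_mix = dx_n / sum(dx_n), apoe4_rate = apoe4)
  }
  list(
    mk("ADNI",   830, 74.75,  7.50, 2.17, 2.68, c(393, 325, 112), 0.357),
    mk("BLSA",   757, 70.45, 10.28, 2.56, 3.98, c(749,   6,   2), 0.255),
    mk("BIOCARD",127, 71.81,  7.40, 1.17, 1.96, c(102,  22,   3), 0.370),
    mk("NACC",   974, 74.95,  8.11, 1.34, 1.65, c(550, 276, 148), 0.395),
    mk("ROSMAPMARS", 1160, 79.48, 7.32, 2.21, 4.28, c(936, 209, 15), 0.190),
    mk("VMAP",   326, 73.32,  7.23, 3.16, 2.98, c(194, 131,   1), 0.353),
    mk("WRAP",   293, 62.01,  6.20, 1.46, 3.47, c(289,   3,   1), 0.307)
  )
}

#' Ground-truth generating parameters
#'
#' @param beta_wm_cross standardized effect of the baseline driving feature
#'   on cognition level (memory scale; other domains are down-weighted by
#'   `domain_weights`).
#' @param theta_wm_slope effect of the standardized baseline driving feature
#'   on the annual cognitive slope (z-score units per year per SD) — the
#'   generating analogue of the white-matter-at-baseline x interval term.
#' @param wm_feature driving feature column, `"<tract>.<metric>"`.
#' @param gamma_batch named per-batch additive shifts in feature-SD units,
#'   or `NULL` to auto-assign an even spread over `gamma_range`.
#' @param delta_batch named per-batch scale factors (> 0), or `NULL` to
#'   auto-assign an even spread over `delta_range`.
#' @param gamma_range,delta_range ranges used for auto-assignment.
#' @param sigma_subject_intercept,sigma_subject_slope random-effect SDs
#'   (z-score, z-score/year).
#' @param sigma_resid residual SD of the visit-level cognitive score.
#' @param phi_endo named interaction effects of the driving feature with
#'   standardized endophenotypes on the annual slope.
#' @param phi_endo_cross named interaction effects on the cross-sectional
#'   level.
#' @param domain_weights multipliers applied to all white-matter effects for
#'   `c(memory, executive, language)`.
#' @param feature_noise_frac visit-level measurement noise of each feature,
#'   as a fraction of its between-subject SD.
#' @param dropout_hazard annual hazard of monotone dropout (0 disables).
#' @return A `truth_params` list.
#' @export
truth_params <- function(beta_wm_cross = -0.3, theta_wm_slope = -0.15,
                         wm_feature = "fornix.FW",
                         gamma_batch = NULL, delta_batch = NULL,
                         gamma_range = c(-0.25, 0.25),
                         delta_range = c(0.85, 1.15),
                         sigma_subject_intercept = 0.5,
                         sigma_subject_slope = 0.05,
                         sigma_resid = 0.25,
                         phi_endo = c(hippocampal_volume = 0.05,
                                      spare_ad = -0.05,
                                      amyloid_positive = -0.04,
                                      tau_positive = 0),
                         phi_endo_cross = c(hippocampal_volume = 0.1,
                                            spare_ad = -0.1,
                                            amyloid_positive = 0,
                                            tau_positive = 0),
                         domain_weights = c(memory = 1, executive = 0.7,
                                            language = 0.7),
                         feature_noise_frac = 0.1,
                         dropout_hazard = 0) {
  if (!is.null(delta_batch) && any(delta_batch <= 0)) {
    fw_stop("delta_batch must be positive", "fwtrace_config_error")
  }
  if (sigma_subject_intercept < 0 || sigma_subject_slope < 0 || sigma_resid < 0) {
    fw_stop("random-effect and residual SDs must be >= 0", "fwtrace_config_error")
  }
  structure(list(beta_wm_cross = beta_wm_cross, theta_wm_slope = theta_wm_slope,
                 wm_feature = wm_feature, gamma_batch = gamma_batch,
                 delta_batch = delta_batch, gamma_range = gamma_range,
                 delta_range = delta_range,
                 sigma_subject_intercept = sigma_subject_intercept,
                 sigma_subject_slope = sigma_subject_slope,
                 sigma_resid = sigma_resid, phi_endo = phi_endo,
                 phi_endo_cross = phi_endo_cross,
                 domain_weights = domain_weights,
                 feature_noise_frac = feature_noise_frac,
                 dropout_hazard = dropout_hazard),
            class = "truth_params")
}

# natural-unit scales for the five metrics (diffusivities in 1e-3 mm^2/s)
metric_scales <- function() {
  list(mu = c(FW = 0.15, FAt = 0.45, MDt = 0.75, AxDt = 1.20, RDt = 0.55),
       sigma = c(FW = 0.04, FAt = 0.06, MDt = 0.05, AxDt = 0.08, RDt = 0.05),
       # annual age trend in natural units (FW and diffusivities rise,
       # corrected FA falls with age)
       age = c(FW = 0.0012, FAt = -0.0012, MDt = 0.0012, AxDt = 0.0012,
               RDt = 0.0012),
       # baseline-diagnosis shifts in SD units, worse microstructure in
       # MCI/AD (sign flipped for FAt)
       dx = c(CU = 0, MCI = 0.3, AD = 0.6))
}

#' Generate a synthetic multi-cohort longitudinal study
#'
#' Produces a long-format participant-visit table ("study table") with
#' demographics, covariates, AD endophenotypes, three cognitive composites
#' and one column per tract x metric feature, generated under the mixed
#' model described above with known ground truth retrievable via
#' `attr(x, "truth")`.
#'
#' Features share variance through per-subject tract-type and tract latent
#' factors, so tracts of the same type are correlated; imaging batch
#' effects enter each observed feature as `gamma_b + delta_b * signal`
#' on the feature's SD scale.
#'
#' @param configs list of [cohort_config()]s.
#' @param truth a [truth_params()].
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param atlas a `tract_atlas` (or subset) naming the tracts to simulate.
#' @param metrics metrics to simulate, default all five.
#' @return A `data.frame` of class `study_table`, one row per visit, with
#'   attribute `truth`: the realized generating parameters plus per-batch
#'   gamma/delta, per-participant driving-feature values `W`, and the
#'   feature latent loadings.
#' @examples
#' cfg <- default_cohort_configs(scale = 0.01)
#' st <- generate_study(cfg, truth_params(), seed = 1)
#' nrow(st); length(unique(st$participant_id))
#' @export
generate_study <- function(configs = default_cohort_configs(),
                           truth = truth_params(), seed = 1L,
                           atlas = atlas_registry(), metrics = fw_metrics()) {
  if (!length(configs)) fw_stop("configs must be non-empty", "fwtrace_config_error")
  configs <- lapply(configs, function(cf) {
    if (!inherits(cf, "cohort_config")) fw_stop("configs must be cohort_config objects",
                                                "fwtrace_config_error")
    cf
  })
  set.seed(as.integer(seed))
  tracts <- if (is.data.frame(atlas)) atlas$tract else as.character(atlas)
  ttype <- if (is.data.frame(atlas)) atlas$tract_type else rep("unknown", length(tracts))
  feats <- feature_names(tracts, metrics)
  sc <- metric_scales()

  # ---- participants -----------------------------------------------------
  part <- do.call(rbind, lapply(configs, function(cf) {
    n <- cf$n_participants
    data.frame(
      participant_id = sprintf("%s_%04d", cf$name, seq_len(n)),
      cohort = cf$name,
      batch = sample(cf$batch_ids, n, replace = TRUE),
      baseline_age = pmin(pmax(stats::rnorm(n, cf$age_mean, cf$age_sd), 50), 95),
      sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4)),
      education = pmin(pmax(round(stats::rnorm(n, 16, 3)), 8), 22),
      race_ethnicity = sample(c("NHW", "NHB", "HISP", "OTH"), n, replace = TRUE,
                              prob = c(0.75, 0.15, 0.06, 0.04)),
      apoe4 = stats::rbinom(n, 1, cf$apoe4_rate),
      apoe2 = stats::rbinom(n, 1, 0.10),
      baseline_diagnosis = sample(names(cf$diagnosis_mix), n, replace = TRUE,
                                  prob = cf$diagnosis_mix),
      n_visits = 1L + stats::rpois(n, max(cf$visit_count_mean - 1, 0)),
      visit_interval_mean = cf$visit_interval_mean,
      stringsAsFactors = FALSE
    )
  }))
  rownames(part) <- NULL
  np <- nrow(part)
  part$converter <- ifelse(part$baseline_diagnosis != "CU", 1L,
                           stats::rbinom(np, 1, 0.15))

  # ---- latent feature structure ----------------------------------------
  types <- unique(ttype)
  u_type <- matrix(stats::rnorm(np * length(types)), np,
                   dimnames = list(NULL, types))
  v_tract <- matrix(stats::rnorm(np * length(tracts)), np,
                    dimnames = list(NULL, tracts))
  l_ty <- 0.5; l_tr <- 0.55; l_un <- sqrt(1 - l_ty^2 - l_tr^2)
  a_latent <- matrix(NA_real_, np, length(feats), dimnames = list(NULL, feats))
  for (k in seq_along(tracts)) {
    for (m in metrics) {
      a_latent[, paste(tracts[k], m, sep = ".")] <-
        l_ty * u_type[, ttype[k]] + l_tr * v_tract[, tracts[k]] +
        l_un * stats::rnorm(np)
    }
  }

  # ---- endophenotypes ---------------------------------------------------
  lim <- if ("limbic" %in% types) u_type[, "limbic"] else u_type[, 1]
  dx_i <- part$baseline_diagnosis
  hv <- -0.4 * lim + sqrt(1 - 0.16) * stats::rnorm(np) +
    c(CU = 0, MCI = -0.5, AD = -1.0)[dx_i]
  spare <- 0.45 * lim + sqrt(1 - 0.45^2) * stats::rnorm(np) +
    c(CU = 0, MCI = 0.5, AD = 1.0)[dx_i]
  amy_lat <- 0.5 * spare + sqrt(0.75) * stats::rnorm(np)
  tau_lat <- 0.5 * spare + sqrt(0.75) * stats::rnorm(np)
  part$hippocampal_volume <- round(hv, 6)
  part$spare_ad <- round(spare, 6)
  part$amyloid_positive <- as.integer(amy_lat > stats::quantile(amy_lat, 1 - 0.35))
  part$tau_positive <- as.integer(tau_lat > stats::quantile(tau_lat, 1 - 0.25))

  # ---- driving feature and random effects -------------------------------
  if (!truth$wm_feature %in% feats) {
    fw_stop(sprintf("wm_feature '%s' is not among the simulated features",
                    truth$wm_feature), "fwtrace_config_error")
  }
  b0 <- matrix(stats::rnorm(np * 3, 0, truth$sigma_subject_intercept), np)
  b1 <- matrix(stats::rnorm(np * 3, 0, truth$sigma_subject_slope), np)

  # ---- batches ----------------------------------------------------------
  batches <- sort(unique(part$batch))
  gb <- truth$gamma_batch
  db <- truth$delta_batch
  if (is.null(gb)) {
    gb <- stats::setNames(if (length(batches) == 1) 0 else
      seq(truth$gamma_range[1], truth$gamma_range[2], length.out = length(batches)),
      batches)
  }
  if (is.null(db)) {
    db <- stats::setNames(if (length(batches) == 1) 1 else
      seq(truth$delta_range[1], truth$delta_range[2], length.out = length(batches)),
      batches)
  }
  if (!all(batches %in% names(gb)) || !all(batches %in% names(db))) {
    fw_stop("gamma_batch/delta_batch must name every batch", "fwtrace_config_error")
  }

  # ---- visit schedule ---------------------------------------------------
  gaps <- lapply(seq_len(np), function(i) {
    nv <- part$n_visits[i]
    if (nv == 1L) return(numeric(0))
    stats::rgamma(nv - 1L, shape = 4, scale = part$visit_interval_mean[i] / 4)
  })
  if (truth$dropout_hazard > 0) {
    gaps <- lapply(gaps, function(g) {
      if (!length(g)) return(g)
      t <- cumsum(g)
      keep <- stats::rexp(1, truth$dropout_hazard)
      g[seq_len(sum(t <= keep))]
    })
  }
  nv <- lengths(gaps) + 1L
  row_part <- rep(seq_len(np), nv)
  interval <- unlist(lapply(gaps, function(g) c(0, cumsum(g))), use.names = FALSE)
  visit_index <- unlist(lapply(nv, seq_len), use.names = FALSE)
  nrow_all <- length(row_part)

  # ---- feature values per visit ----------------------------------------
  age0 <- part$baseline_age[row_part]
  age_v <- age0 + interval
  dx_v <- part$baseline_diagnosis[row_part]
  feat_obs <- matrix(NA_real_, nrow_all, length(feats),
                     dimnames = list(NULL, feats))
  dxshift <- sc$dx[dx_v]
  W <- NULL
  for (k in seq_along(tracts)) {
    for (m in metrics) {
      fn <- paste(tracts[k], m, sep = ".")
      sgn <- if (m == "FAt") -1 else 1     # corrected FA falls when others rise
      z_true <- a_latent[row_part, fn] + sgn * dxshift
      nat_true <- sc$mu[m] + sc$sigma[m] * z_true + sc$age[m] * (age_v - 74)
      if (fn == truth$wm_feature) {
        # driving value: standardized noise-free baseline feature
        base_rows <- visit_index == 1L
        wvals <- nat_true[base_rows]
        W <- stats::setNames(as.numeric(scale(wvals)), part$participant_id)
      }
      g <- gb[part$batch[row_part]]
      d <- db[part$batch[row_part]]
      # batch gain d scales signal and measurement noise alike
      feat_obs[, fn] <- sc$mu[m] +
        sc$sigma[m] * (g + d * ((nat_true - sc$mu[m]) / sc$sigma[m] +
                                truth$feature_noise_frac * stats::rnorm(nrow_all)))
    }
  }

  # ---- cognition --------------------------------------------------------
  dx_int <- c(CU = 0, MCI = -0.8, AD = -1.8)
  endo_std <- cbind(
    hippocampal_volume = as.numeric(scale(part$hippocampal_volume)),
    spare_ad = as.numeric(scale(part$spare_ad)),
    amyloid_positive = as.numeric(scale(part$amyloid_positive)),
    tau_positive = as.numeric(scale(part$tau_positive)))
  phi_l <- truth$phi_endo
  phi_c <- truth$phi_endo_cross
  endo_slope <- as.numeric(endo_std[, names(phi_l), drop = FALSE] %*% phi_l)
  endo_cross <- as.numeric(endo_std[, names(phi_c), drop = FALSE] %*% phi_c)

  Wv <- W[part$participant_id[row_part]]
  cog <- matrix(NA_real_, nrow_all, 3,
                dimnames = list(NULL, c("memory", "executive", "language")))
  for (d in 1:3) {
    wd <- truth$domain_weights[[d]]
    level <- 0.45 - 0.02 * (age0 - 74) + 0.03 * (part$education[row_part] - 16) -
      0.10 * (part$sex[row_part] == "male") +
      dx_int[dx_v] - 0.05 * part$apoe4[row_part] +
      wd * (truth$beta_wm_cross + endo_cross[row_part]) * Wv +
      b0[row_part, d]
    slope <- -0.03 - 0.003 * (age0 - 74) + b1[row_part, d] +
      wd * (truth$theta_wm_slope + endo_slope[row_part]) * Wv
    cog[, d] <- level + slope * interval +
      stats::rnorm(nrow_all, 0, truth$sigma_resid)
  }

  out <- data.frame(
    participant_id = part$participant_id[row_part],
    cohort = part$cohort[row_part],
    batch = part$batch[row_part],
    visit_index = visit_index,
    baseline_age = age0,
    age_at_visit = age_v,
    interval = interval,
    sex = part$sex[row_part],
    education = part$education[row_part],
    race_ethnicity = part$race_ethnicity[row_part],
    apoe4 = part$apoe4[row_part],
    apoe2 = part$apoe2[row_part],
    baseline_diagnosis = dx_v,
    converter = part$converter[row_part],
    hippocampal_volume = part$hippocampal_volume[row_part],
    spare_ad = part$spare_ad[row_part],
    amyloid_positive = part$amyloid_positive[row_part],
    tau_positive = part$tau_positive[row_part],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(cog), as.data.frame(feat_obs))
  attr(out, "truth") <- list(
    params = truth, gamma_batch = gb, delta_batch = db, W = W,
    seed = as.integer(seed), tracts = tracts, tract_type = ttype,
    metrics = metrics, feature_names = feats, scales = sc,
    loadings = c(type = l_ty, tract = l_tr, unique = l_un))
  class(out) <- c("study_table", "data.frame")
  out
}

#' @export
print.study_table <- function(x, ...) {
  cat("<study_table> ", length(unique(x$participant_id)), " participants, ",
      nrow(x), " visits, ", length(unique(x$cohort)), " cohorts, ",
      length(attr(x, "truth")$feature_names %||% character(0)),
      " feature columns\n", sep = "")
  invisible(x)
}
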