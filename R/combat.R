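# Longitudinal ComBat harmonization.
#
# Location-scale model per feature v, observation j of subject i in batch b:
#   y_ivj = alpha_v + x_ivj' beta_v + gamma_bv + eta_iv + e_ivj,
#   eta_iv ~ N(0, sigma2_subject), e_ivj ~ N(0, delta2_bv sigma2_v),
# estimated feature-by-feature by REML (lme4) with batch as a fixed effect
# recentred so that sum_b n_b gamma_b = 0. Residuals standardized by
# sigma_v retain the batch signal; per-batch location (gamma) and scale
# (delta) are then shrunk across features by parametric empirical Bayes
# (normal prior on gamma, inverse-gamma on delta^2, method-of-moments
# hyperparameters) and removed:
#   y_adj = sigma_v (z - gamma*_bv) / delta*_bv + alpha_v + x'beta_v + eta_iv.

#' Covariate design preserved by harmonization
#'
#' The default preserves age, age^2, sex, baseline diagnosis, and age x
#' converter / age^2 x converter interactions — the biological structure
#' whose variance must survive batch correction.
#'
#' @param formula right-hand-side formula over study-table columns.
#' @return A `preserve_design` (a formula with a class attribute).
#' @export
preserve_design <- function(formula = ~ age_at_visit + I(age_at_visit^2) +
                              sex + baseline_diagnosis +
                              age_at_visit:converter +
                              I(age_at_visit^2):converter) {
  structure(formula, class = c("preserve_design", "formula"))
}

design_matrix <- function(design, data) {
  X <- stats::model.matrix(design, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    fw_stop(paste0("preserve design is rank-deficient; collinear terms: ",
                   paste(drop, collapse = ", ")), "fwtrace_config_error")
  }
  X
}

#' Fit the longitudinal ComBat model
#'
#' @param data a `study_table` or long-format data.frame.
#' @param feature_cols feature columns to harmonize; defaults to the
#'   simulator's feature names or all `<tract>.<metric>` columns.
#' @param design a [preserve_design()] (or plain RHS formula) of covariates
#'   whose variance is preserved.
#' @param batch_col,subject_col key columns.
#' @param eb empirical-Bayes shrinkage of batch parameters across features;
#'   automatically disabled below 5 features (unshrunken estimates used).
#' @return A `combat_model`: per-feature fixed effects, residual SD, subject
#'   BLUPs, and per-batch shrunken `gamma_star` / `delta_star` on the
#'   standardized scale (multiply `gamma_star` by `sigma` for feature units),
#'   plus the EB hyperparameters.
#' @export
fit_longcombat <- function(data, feature_cols = NULL,
                           design = preserve_design(),
                           batch_col = "batch",
                           subject_col = "participant_id", eb = TRUE) {
  feature_cols <- feature_cols %||% attr(data, "truth")$feature_names %||%
    grep("^[A-Za-z0-9_]+\\.(FW|FAt|MDt|AxDt|RDt)$", names(data), value = TRUE)
  if (!length(feature_cols)) fw_stop("no feature columns found", "fwtrace_config_error")
  batch <- factor(data[[batch_col]])
  subject <- factor(data[[subject_col]])
  if (nlevels(batch) < 2L) {
    fw_stop("need >= 2 batches to estimate batch effects", "fwtrace_config_error")
  }
  nsub_b <- tapply(as.character(subject), batch, function(s) length(unique(s)))
  if (any(nsub_b < 2)) {
    fw_stop(paste0("every batch needs >= 2 subjects; offending batch(es): ",
                   paste(names(nsub_b)[nsub_b < 2], collapse = ", ")),
            "fwtrace_config_error")
  }
  X <- design_matrix(design, data)     # includes intercept
  nb <- table(batch)                   # observations per batch
  levs <- levels(batch)

  per_feature <- vector("list", length(feature_cols))
  names(per_feature) <- feature_cols
  gamma_hat <- delta2_hat <- matrix(
    NA_real_, length(feature_cols), length(levs),
    dimnames = list(feature_cols, levs))
  zres <- vector("list", length(feature_cols))
  names(zres) <- feature_cols

  for (fc in feature_cols) {
    y <- data[[fc]]
    dfit <- data.frame(y = y, X[, -1, drop = FALSE], batch = batch,
                       subject = subject, check.names = FALSE)
    fml <- stats::reformulate(
      c(sprintf("`%s`", colnames(X)[-1]), "batch", "(1 | subject)"),
      response = "y")
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = dfit, REML = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fe <- lme4::fixef(fit)
      names(fe) <- gsub("`", "", names(fe), fixed = TRUE)
      sigma_v <- stats::sigma(fit)
      re <- lme4::ranef(fit)$subject
      eta <- stats::setNames(re[[1]], rownames(re))
      sig_sub <- sqrt(lme4::VarCorr(fit)$subject[1])
    } else {
      # degenerate fallback (e.g. noiseless toy data): plain OLS, eta = 0
      lmf <- stats::lm(y ~ 0 + X + batch, data = dfit)
      cf <- stats::coef(lmf)
      names(cf) <- sub("^X", "", names(cf))
      fe <- cf[c(colnames(X), paste0("batch", levs[-1]))]
      names(fe)[1] <- "(Intercept)"
      fe[is.na(fe)] <- 0
      sigma_v <- stats::sigma(lmf)
      eta <- stats::setNames(numeric(0), character(0))
      sig_sub <- 0
    }
    sigma_v <- max(sigma_v, 1e-12)
    g_raw <- stats::setNames(numeric(length(levs)), levs)
    g_raw[-1] <- fe[paste0("batch", levs[-1])]
    gbar <- sum(nb * g_raw) / sum(nb)
    alpha <- unname(fe["(Intercept)"]) + gbar
    beta <- fe[colnames(X)[-1]]
    eta_row <- if (length(eta)) unname(eta[as.character(subject)]) else 0
    eta_row[is.na(eta_row)] <- 0
    fitted_bio <- alpha + as.numeric(X[, -1, drop = FALSE] %*% beta) + eta_row
    z <- (y - fitted_bio) / sigma_v
    gamma_hat[fc, ] <- tapply(z, batch, mean)
    delta2_hat[fc, ] <- tapply(z, batch, function(v) {
      max(sum((v - mean(v))^2) / length(v), 1e-12)
    })
    zres[[fc]] <- z
    per_feature[[fc]] <- list(alpha = alpha, beta = beta, sigma = sigma_v,
                              eta = eta, sigma_subject = sig_sub)
  }

  # scale preservation: constrain each feature's batch scales to
  # observation-weighted mean 1 (the multiplicative analogue of the
  # sum_b n_b gamma_b = 0 location constraint), so harmonization never
  # changes the overall residual scale and is an identity when batches
  # do not differ
  w <- as.numeric(nb) / sum(nb)
  delta2_hat <- delta2_hat / as.numeric(delta2_hat %*% w)

  # ---- empirical Bayes shrinkage across features ------------------------
  use_eb <- isTRUE(eb) && length(feature_cols) >= 5L
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  hyper <- list()
  if (use_eb) {
    for (b in levs) {
      g <- gamma_hat[, b]; d2 <- delta2_hat[, b]
      g_bar <- mean(g); t2 <- stats::var(g)
      m <- mean(d2); s2 <- stats::var(d2)
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      hyper[[b]] <- list(gamma_bar = g_bar, tau2 = t2, a = a_pr, b = b_pr)
      if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) next
      n_b <- nb[[b]]
      for (fc in feature_cols) {
        # sufficient statistics on the normalized scale:
        # sum (z - g)^2 = n delta2_hat + n (gamma_hat - g)^2
        g_new <- g[fc]; d_new <- d2[fc]
        for (it in 1:100) {
          g_old <- g_new; d_old <- d_new
          g_new <- (n_b * t2 * g[fc] + d_old * g_bar) / (n_b * t2 + d_old)
          ss <- n_b * d2[fc] + n_b * (g[fc] - g_new)^2
          d_new <- (b_pr + 0.5 * ss) / (n_b / 2 + a_pr - 1)
          if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-8) break
        }
        gamma_star[fc, b] <- g_new
        delta2_star[fc, b] <- d_new
      }
    }
  }

  delta2_star <- delta2_star / as.numeric(delta2_star %*% w)

  structure(list(feature_cols = feature_cols, design = design,
                 batch_col = batch_col, subject_col = subject_col,
                 batch_levels = levs, per_feature = per_feature,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta_star = sqrt(delta2_star),
                 eb = use_eb, hyper = hyper),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", length(x$feature_cols), " features, ",
      length(x$batch_levels), " batches",
      if (x$eb) ", EB-shrunken" else ", unshrunken", "\n", sep = "")
  invisible(x)
}

#' Per-batch harmonization parameters
#'
#' @param model a `combat_model`.
#' @return data.frame with one row per feature x batch: `gamma_star`
#'   (standardized), `gamma_star_raw` (feature units), `delta_star`.
#' @export
batch_effects <- function(model) {
  stopifnot(inherits(model, "combat_model"))
  sig <- vapply(model$per_feature, `[[`, numeric(1), "sigma")
  out <- expand.grid(feature = model$feature_cols, batch = model$batch_levels,
                     stringsAsFactors = FALSE)
  out$gamma_star <- mapply(function(f, b) model$gamma_star[f, b],
                           out$feature, out$batch)
  out$gamma_star_raw <- out$gamma_star * sig[out$feature]
  out$delta_star <- mapply(function(f, b) model$delta_star[f, b],
                           out$feature, out$batch)
  out
}

#' Apply a fitted longitudinal ComBat model
#'
#' @param data data with the same feature columns and batches the model was
#'   fitted on (typically the same table).
#' @param model a `combat_model` from [fit_longcombat()].
#' @return `data` with harmonized feature columns (schema unchanged).
#' @export
apply_longcombat <- function(data, model) {
  stopifnot(inherits(model, "combat_model"))
  batch <- factor(data[[model$batch_col]])
  unseen <- setdiff(levels(batch), model$batch_levels)
  if (length(unseen)) {
    fw_stop(paste0("batch(es) not seen at fit time: ",
                   paste(unseen, collapse = ", ")), "fwtrace_apply_error")
  }
  subject <- as.character(data[[model$subject_col]])
  X <- stats::model.matrix(model$design, data = data)
  out <- data
  for (fc in model$feature_cols) {
    pf <- model$per_feature[[fc]]
    eta_row <- if (length(pf$eta)) unname(pf$eta[subject]) else 0
    eta_row[is.na(eta_row)] <- 0
    fitted_bio <- pf$alpha + as.numeric(X[, -1, drop = FALSE] %*% pf$beta) + eta_row
    z <- (data[[fc]] - fitted_bio) / pf$sigma
    g <- model$gamma_star[fc, as.character(batch)]
    d <- model$delta_star[fc, as.character(batch)]
    out[[fc]] <- pf$sigma * (z - g) / d + fitted_bio
  }
  attr(out, "truth") <- attr(data, "truth")
  out
}
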