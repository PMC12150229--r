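# Association scans: demographic comparisons, per-tract cross-sectional
# regressions, longitudinal mixed-effects models of cognitive decline, and
# endophenotype interaction models, with BH-FDR control per scan family.

#' Model specification for association scans
#'
#' @param outcome cognitive domain column (`memory`, `executive`, `language`).
#' @param covariates covariate columns; age means baseline age, scaled and
#'   centered. Categorical covariates are dummy-coded against the reference
#'   levels CU (diagnosis), female (sex) and non-carrier (APOE).
#' @param scale_outcome z-score the outcome on the analysis subset (default
#'   TRUE). Continuous predictors are always z-scored, so the white-matter
#'   term is a standardized beta.
#' @param satterthwaite use Satterthwaite degrees of freedom (via lmerTest)
#'   instead of large-sample Wald z for mixed-model inference.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = "memory",
                       covariates = c("age", "education", "sex",
                                      "race_ethnicity", "baseline_diagnosis",
                                      "apoe4", "apoe2"),
                       scale_outcome = TRUE, satterthwaite = FALSE) {
  structure(list(outcome = outcome, covariates = covariates,
                 scale_outcome = scale_outcome,
                 satterthwaite = satterthwaite),
            class = "model_spec")
}

# reference-coded covariate data for model fitting
covariate_frame <- function(data, spec) {
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (cv in spec$covariates) {
    df[[cv]] <- switch(cv,
      age = zscore(data$baseline_age),
      education = zscore(data$education),
      sex = factor(data$sex, levels = c("female", "male")),
      race_ethnicity = factor(data$race_ethnicity),
      baseline_diagnosis = factor(data$baseline_diagnosis,
                                  levels = c("CU", "MCI", "AD")),
      data[[cv]]
    )
  }
  df
}

split_feature <- function(feature) {
  m <- regmatches(feature, regexpr("\\.[^.]+$", feature))
  c(tract = sub("\\.[^.]+$", "", feature), metric = sub("^\\.", "", m))
}

scan_row <- function(feature, domain, term, est = NA_real_, z = NA_real_,
                     p = NA_real_, n_obs = NA_integer_, n_part = NA_integer_,
                     converged = FALSE) {
  sp <- split_feature(feature)
  data.frame(tract = sp[["tract"]], metric = sp[["metric"]], domain = domain,
             term = term, beta = est, z = z, p = p, q = NA_real_,
             n_obs = n_obs, n_participants = n_part, converged = converged,
             stringsAsFactors = FALSE)
}

finish_scan <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$converged & is.finite(out$p)
  out$q[ok] <- fdr_adjust(out$p[ok])
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", nrow(x), " models (", sum(!x$converged),
      " non-converged), term '", x$term[1], "', domain '", x$domain[1],
      "'\n", sep = "")
  sig <- sum(x$q < 0.05, na.rm = TRUE)
  cat("  q < 0.05: ", sig, " of ", sum(x$converged), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values, order-preserving with the input vector.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    fw_stop("p-values must be finite numbers in [0, 1]", "fwtrace_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cohort demographic comparisons
#'
#' Routes each variable through the standard decision tree: Shapiro-Wilk
#' normality per group, then Levene homogeneity for normal variables,
#' choosing ANOVA (equal variances), Welch ANOVA (unequal) or
#' Kruskal-Wallis (non-normal); categorical variables get a chi-square
#' test, or Fisher's exact test when any expected cell count is below 5.
#'
#' @param data a `study_table` (or any data.frame); one row per
#'   participant is selected by `participant_id` unless `baseline_only`
#'   is FALSE.
#' @param variables columns to compare.
#' @param group grouping column (default `cohort`).
#' @param alpha significance level used inside the routing tests.
#' @param baseline_only use each participant's first row.
#' @return data.frame: variable, type, test, statistic, p (untestable
#'   variables are reported with test = "none").
#' @export
compare_demographics <- function(data,
                                 variables = c("baseline_age", "education",
                                               "sex", "baseline_diagnosis",
                                               "apoe4"),
                                 group = "cohort", alpha = 0.05,
                                 baseline_only = TRUE) {
  if (baseline_only && "participant_id" %in% names(data)) {
    data <- data[!duplicated(data$participant_id), , drop = FALSE]
  }
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) fw_stop("need >= 2 groups", "fwtrace_config_error")
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      return(data.frame(variable = v, type = "constant", test = "none",
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (is.numeric(x) && length(unique(x)) > 6L) {
      normal <- all(tapply(x, g, function(xx) {
        xx <- xx[is.finite(xx)]
        if (length(xx) < 3) return(TRUE)
        if (length(xx) > 5000) xx <- xx[seq(1, length(xx), length.out = 5000)]
        stats::shapiro.test(xx)$p.value > alpha
      }))
      if (!normal) {
        kw <- stats::kruskal.test(x, g)
        return(data.frame(variable = v, type = "continuous",
                          test = "Kruskal-Wallis",
                          statistic = unname(kw$statistic), p = kw$p.value,
                          stringsAsFactors = FALSE))
      }
      lev <- car::leveneTest(x ~ g, center = "mean")
      if (lev[["Pr(>F)"]][1] > alpha) {
        a <- stats::oneway.test(x ~ g, var.equal = TRUE)
        data.frame(variable = v, type = "continuous", test = "ANOVA",
                   statistic = unname(a$statistic), p = a$p.value,
                   stringsAsFactors = FALSE)
      } else {
        w <- stats::oneway.test(x ~ g, var.equal = FALSE)
        data.frame(variable = v, type = "continuous", test = "Welch ANOVA",
                   statistic = unname(w$statistic), p = w$p.value,
                   stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(factor(x), g)
      expected <- suppressWarnings(stats::chisq.test(tab)$expected)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 4,
                                 B = 10000)
        data.frame(variable = v, type = "categorical", test = "Fisher exact",
                   statistic = NA_real_, p = ft$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ct <- stats::chisq.test(tab)
        data.frame(variable = v, type = "categorical", test = "chi-square",
                   statistic = unname(ct$statistic), p = ct$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-sectional white-matter association scan
#'
#' One OLS model per feature: scaled cognition on the scaled baseline
#' feature plus covariates; reports the feature term's standardized beta,
#' z, p, and BH-FDR q over the scanned family.
#'
#' @param data a `study_table`; baseline rows (first visit per participant)
#'   are used.
#' @param features feature columns to scan; defaults to the table's
#'   simulated/extracted feature set.
#' @param spec a [model_spec()].
#' @return A `scan_result` data.frame, one row per feature.
#' @export
cross_sectional_scan <- function(data, features = NULL, spec = model_spec()) {
  features <- features %||% attr(data, "truth")$feature_names %||%
    grep("^[A-Za-z0-9_]+\\.(FW|FAt|MDt|AxDt|RDt)$", names(data), value = TRUE)
  base <- data[!duplicated(data$participant_id), , drop = FALSE]
  y <- base[[spec$outcome]]
  if (spec$scale_outcome) y <- zscore(y)
  cf <- covariate_frame(base, spec)
  rows <- lapply(features, function(fc) {
    df <- cbind(data.frame(.y = y, .wm = zscore(base[[fc]])), cf)
    fit <- tryCatch(stats::lm(.y ~ ., data = df), error = function(e) NULL)
    if (is.null(fit)) return(scan_row(fc, spec$outcome, "wm"))
    sm <- summary(fit)$coefficients
    if (!".wm" %in% rownames(sm) || !is.finite(sm[".wm", 2]) ||
        sm[".wm", 2] == 0) {
      return(scan_row(fc, spec$outcome, "wm", n_obs = nrow(df),
                      n_part = nrow(df)))
    }
    scan_row(fc, spec$outcome, "wm", est = sm[".wm", 1],
             z = sm[".wm", 3], p = sm[".wm", 4],
             n_obs = stats::nobs(fit), n_part = stats::nobs(fit),
             converged = TRUE)
  })
  finish_scan(rows)
}

# shared mixed-model fitter with the diagonal-covariance retry
fit_lmm <- function(formula, data, retry_formula = NULL, satterthwaite = FALSE) {
  engine <- if (satterthwaite && requireNamespace("lmerTest", quietly = TRUE)) {
    lmerTest::lmer
  } else {
    lme4::lmer
  }
  quiet_fit <- function(fm) {
    tryCatch({
      fit <- suppressMessages(suppressWarnings(
        engine(fm, data = data, REML = TRUE)))
      conv <- length(fit@optinfo$conv$lme4$messages) == 0L
      list(fit = fit, clean = conv)
    }, error = function(e) NULL)
  }
  res <- quiet_fit(formula)
  if ((is.null(res) || !res$clean) && !is.null(retry_formula)) {
    res2 <- quiet_fit(retry_formula)
    if (!is.null(res2)) res <- res2
  }
  res
}

lmm_term <- function(res, term, satterthwaite = FALSE) {
  sm <- stats::coef(summary(res$fit))
  rn <- gsub("`", "", rownames(sm), fixed = TRUE)
  i <- match(term, rn)
  if (is.na(i) || !is.finite(sm[i, 2]) || sm[i, 2] == 0) return(NULL)
  est <- sm[i, 1]; se <- sm[i, 2]
  zval <- est / se
  p <- if (satterthwaite && "Pr(>|t|)" %in% colnames(sm)) {
    sm[i, "Pr(>|t|)"]
  } else {
    2 * stats::pnorm(-abs(zval))
  }
  list(est = est, se = se, z = zval, p = p)
}

# attach a standardized baseline feature column to all visits
baseline_feature <- function(data, fc) {
  base <- data[!duplicated(data$participant_id), c("participant_id", fc)]
  w <- stats::setNames(zscore(base[[fc]]), base$participant_id)
  unname(w[as.character(data$participant_id)])
}

#' Longitudinal white-matter association scan
#'
#' One linear mixed-effects model per feature: cognition over all visits on
#' covariates, the standardized baseline feature, interval, baseline age x
#' interval and feature x interval, with a per-participant random intercept
#' and interval slope. Inference on the feature x interval term (Wald z by
#' default). Models flagged by lme4 are retried with a diagonal
#' random-effect covariance before being marked non-converged.
#'
#' @inheritParams cross_sectional_scan
#' @param report which term to report: `"wm:interval"` (default) or
#'   `"wm"`.
#' @return A `scan_result` data.frame.
#' @export
longitudinal_scan <- function(data, features = NULL, spec = model_spec(),
                              report = "wm:interval") {
  features <- features %||% attr(data, "truth")$feature_names %||%
    grep("^[A-Za-z0-9_]+\\.(FW|FAt|MDt|AxDt|RDt)$", names(data), value = TRUE)
  nvis <- table(data$participant_id)
  if (max(nvis) < 2L) {
    fw_stop("all participants have a single visit; interval effects are inestimable",
            "fwtrace_degenerate_design")
  }
  y <- data[[spec$outcome]]
  if (spec$scale_outcome) y <- zscore(y)
  cf <- covariate_frame(data, spec)
  has_age <- "age" %in% spec$covariates
  rows <- lapply(features, function(fc) {
    df <- cbind(data.frame(.y = y, .wm = baseline_feature(data, fc),
                           interval = data$interval,
                           .pid = data$participant_id), cf)
    fixed <- c(names(cf), ".wm", "interval",
               if (has_age) "age:interval", ".wm:interval")
    fml <- stats::reformulate(c(fixed, "(1 + interval | .pid)"),
                              response = ".y")
    fml2 <- stats::reformulate(c(fixed, "(1 + interval || .pid)"),
                               response = ".y")
    res <- fit_lmm(fml, df, fml2, spec$satterthwaite)
    np <- length(unique(df$.pid))
    if (is.null(res)) return(scan_row(fc, spec$outcome, report))
    tm <- lmm_term(res, if (report == "wm") ".wm" else ".wm:interval",
                   spec$satterthwaite)
    if (is.null(tm)) return(scan_row(fc, spec$outcome, report,
                                     n_obs = nrow(df), n_part = np))
    scan_row(fc, spec$outcome, report, est = tm$est, z = tm$z, p = tm$p,
             n_obs = nrow(df), n_part = np, converged = TRUE)
  })
  finish_scan(rows)
}

#' White-matter x endophenotype interaction scan
#'
#' Cross-sectional mode adds the endophenotype and its two-way interaction
#' with the feature to the cross-sectional model and reports the feature x
#' endophenotype term. Longitudinal mode adds endophenotype x interval and
#' feature x endophenotype x interval (with all lower-order terms) to the
#' longitudinal model and reports the three-way term.
#'
#' @inheritParams cross_sectional_scan
#' @param endophenotype column name (e.g. `hippocampal_volume`, `spare_ad`,
#'   `amyloid_positive`, `baseline_diagnosis`, `apoe4`).
#' @param mode `"cross-sectional"` or `"longitudinal"`.
#' @return A `scan_result` data.frame reporting the interaction term.
#' @export
interaction_scan <- function(data, features = NULL, endophenotype,
                             mode = c("cross-sectional", "longitudinal"),
                             spec = model_spec()) {
  mode <- match.arg(mode)
  features <- features %||% attr(data, "truth")$feature_names %||%
    grep("^[A-Za-z0-9_]+\\.(FW|FAt|MDt|AxDt|RDt)$", names(data), value = TRUE)
  ev <- data[[endophenotype]]
  if (is.null(ev)) fw_stop(sprintf("endophenotype column '%s' not found",
                                   endophenotype), "fwtrace_config_error")
  if (is.factor(ev) && any(table(ev) == 0)) {
    fw_stop(sprintf("endophenotype '%s' has an empty level", endophenotype),
            "fwtrace_config_error")
  }
  term_lab <- paste0("wm:", endophenotype, if (mode == "longitudinal") ":interval")
  inest <- length(unique(ev[!is.na(ev)])) < 2L

  # drop the endophenotype from the covariate list if present (it enters
  # explicitly with its interactions)
  spec2 <- spec
  spec2$covariates <- setdiff(spec$covariates, endophenotype)
  use_base <- mode == "cross-sectional"
  dat <- if (use_base) data[!duplicated(data$participant_id), , drop = FALSE] else data
  y <- dat[[spec$outcome]]
  if (spec$scale_outcome) y <- zscore(y)
  cf <- covariate_frame(dat, spec2)
  e <- dat[[endophenotype]]
  if (is.numeric(e) && length(unique(e)) > 2L) e <- zscore(e)
  has_age <- "age" %in% spec2$covariates

  rows <- lapply(features, function(fc) {
    if (inest) return(scan_row(fc, spec$outcome, term_lab))
    wm <- if (use_base) zscore(dat[[fc]]) else baseline_feature(dat, fc)
    df <- cbind(data.frame(.y = y, .wm = wm, .endo = e), cf)
    if (mode == "cross-sectional") {
      fit <- tryCatch(stats::lm(.y ~ . + .wm:.endo, data = df),
                      error = function(e) NULL)
      if (is.null(fit)) return(scan_row(fc, spec$outcome, term_lab))
      sm <- summary(fit)$coefficients
      tn <- grep("^\\.wm:", rownames(sm), value = TRUE)[1]
      if (is.na(tn) || !is.finite(sm[tn, 2]) || sm[tn, 2] == 0) {
        return(scan_row(fc, spec$outcome, term_lab, n_obs = nrow(df),
                        n_part = nrow(df)))
      }
      scan_row(fc, spec$outcome, term_lab, est = sm[tn, 1], z = sm[tn, 3],
               p = sm[tn, 4], n_obs = stats::nobs(fit),
               n_part = stats::nobs(fit), converged = TRUE)
    } else {
      df$interval <- dat$interval
      df$.pid <- dat$participant_id
      fixed <- c(names(cf), ".wm", ".endo", ".wm:.endo", "interval",
                 if (has_age) "age:interval",
                 ".wm:interval", ".endo:interval", ".wm:.endo:interval")
      fml <- stats::reformulate(c(fixed, "(1 + interval | .pid)"),
                                response = ".y")
      fml2 <- stats::reformulate(c(fixed, "(1 + interval || .pid)"),
                                 response = ".y")
      res <- fit_lmm(fml, df, fml2, spec$satterthwaite)
      np <- length(unique(df$.pid))
      if (is.null(res)) return(scan_row(fc, spec$outcome, term_lab))
      sm <- stats::coef(summary(res$fit))
      tn <- grep("^\\.wm:.*:interval$|^\\.wm:interval:", rownames(sm),
                 value = TRUE)
      tn <- setdiff(tn, ".wm:interval")[1]
      if (is.na(tn) || !is.finite(sm[tn, 2]) || sm[tn, 2] == 0) {
        return(scan_row(fc, spec$outcome, term_lab, n_obs = nrow(df),
                        n_part = np))
      }
      zv <- sm[tn, 1] / sm[tn, 2]
      scan_row(fc, spec$outcome, term_lab, est = sm[tn, 1], z = zv,
               p = 2 * stats::pnorm(-abs(zv)), n_obs = nrow(df),
               n_part = np, converged = TRUE)
    }
  })
  finish_scan(rows)
}
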