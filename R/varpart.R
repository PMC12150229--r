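# Bootstrapped head-to-head variance partitioning.
#
# Marginal R^2 follows the Nakagawa-Schielzeth definition with the
# random-slope extension: the variance of the fixed-effect predictions over
# the total (fixed + average random-effect + residual) variance. Delta R^2
# is the marginal variance a white-matter feature adds beyond a
# covariate-only longitudinal model, bootstrapped over participants
# (cluster bootstrap, stratified by cohort).

#' Marginal R-squared from variance components
#'
#' @param fixed_var variance of the fixed-effect predictions.
#' @param random_vars summed (average) random-effect variances.
#' @param resid_var residual variance.
#' @return Proportion sigma2_f / (sigma2_f + sigma2_random + sigma2_eps).
#' @examples
#' marginal_r2(1, 1, 2)   # 0.25
#' @export
marginal_r2 <- function(fixed_var, random_vars, resid_var) {
  if (any(c(fixed_var, random_vars, resid_var) < 0)) {
    fw_stop("variance components must be >= 0", "fwtrace_domain_error")
  }
  tot <- fixed_var + random_vars + resid_var
  if (tot == 0) fw_stop("all variance components are zero; R^2 undefined",
                        "fwtrace_domain_error")
  fixed_var / tot
}

#' Marginal R-squared of a fitted mixed model
#'
#' Fixed-effect prediction variance over total variance, with the
#' random-effect contribution averaged over observations (this handles
#' random slopes, whose variance varies with the time covariate).
#'
#' @param fit a fitted `lmerMod` (or an `lm`, for which the usual R^2 of
#'   the fitted values is returned).
#' @return Proportion in \[0, 1\].
#' @export
r2_from_fit <- function(fit) {
  if (inherits(fit, "lm")) {
    mu <- stats::fitted(fit)
    return(marginal_r2(stats::var(mu), 0, stats::sigma(fit)^2))
  }
  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  var_f <- stats::var(as.numeric(X %*% beta))
  vc <- lme4::VarCorr(fit)
  mml <- lme4::getME(fit, "mmList")
  var_r <- 0
  for (k in seq_along(mml)) {
    M <- mml[[k]]
    Sg <- vc[[k]]
    var_r <- var_r + mean(rowSums((M %*% Sg) * M))
  }
  marginal_r2(var_f, var_r, stats::sigma(fit)^2)
}

# fit the covariate-only and covariate+WM longitudinal models on one dataset;
# returns marginal R^2 pair or NULL on failure
delta_r2_once <- function(df, fixed_base, fixed_full, re, re2) {
  fb <- fit_lmm(stats::reformulate(c(fixed_base, re), response = ".y"), df,
                stats::reformulate(c(fixed_base, re2), response = ".y"))
  ff <- fit_lmm(stats::reformulate(c(fixed_full, re), response = ".y"), df,
                stats::reformulate(c(fixed_full, re2), response = ".y"))
  if (is.null(fb) || is.null(ff)) return(NULL)
  c(base = r2_from_fit(fb$fit), full = r2_from_fit(ff$fit))
}

#' Bootstrapped added variance of a white-matter feature
#'
#' For each replicate, participants are resampled with replacement within
#' cohort (all visits of a drawn participant move together), the
#' covariate-only and covariate + white-matter longitudinal mixed models
#' are refitted, and the difference in marginal R^2 is recorded in
#' percentage points. Non-converged replicates are dropped and counted.
#'
#' @param data a `study_table`.
#' @param feature feature column (`"<tract>.<metric>"`).
#' @param spec a [model_spec()] naming the outcome domain and covariates.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param identity_resample if TRUE, every replicate is the original sample
#'   (degenerate bootstrap for testing; Delta R^2 then equals the point
#'   estimate).
#' @param strata column for stratified resampling (default `cohort`).
#' @param strict escalate a > 20% non-convergence rate from warning to error.
#' @return A `boot_r2` object: replicate vector (percent scale), `mean`,
#'   percentile `ci95`, covariate-only `base_r2` summaries, point
#'   estimates, and counts.
#' @export
bootstrap_delta_r2 <- function(data, feature, spec = model_spec(),
                               n_boot = 1000, seed = 1L,
                               identity_resample = FALSE, strata = "cohort",
                               strict = FALSE) {
  y <- data[[spec$outcome]]
  if (spec$scale_outcome) y <- zscore(y)
  cf <- covariate_frame(data, spec)
  has_age <- "age" %in% spec$covariates
  df0 <- cbind(data.frame(.y = y, .wm = baseline_feature(data, feature),
                          interval = data$interval,
                          .pid = as.character(data$participant_id),
                          .stratum = data[[strata]]), cf)
  fixed_base <- c(names(cf), "interval", if (has_age) "age:interval")
  fixed_full <- c(fixed_base, ".wm", ".wm:interval")
  re <- "(1 + interval | .pid)"
  re2 <- "(1 + interval || .pid)"

  point <- delta_r2_once(df0, fixed_base, fixed_full, re, re2)
  if (is.null(point)) fw_stop("point-estimate models failed to fit",
                              "fwtrace_fit_error")

  pid_by_stratum <- split(unique(df0$.pid),
                          df0$.stratum[!duplicated(df0$.pid)])
  rows_by_pid <- split(seq_len(nrow(df0)), df0$.pid)

  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("base", "full")))
  for (bidx in seq_len(n_boot)) {
    if (identity_resample) {
      dfb <- df0
    } else {
      draw <- unlist(lapply(pid_by_stratum, function(p) {
        sample(p, length(p), replace = TRUE)
      }), use.names = FALSE)
      idx <- unlist(rows_by_pid[draw], use.names = FALSE)
      dfb <- df0[idx, , drop = FALSE]
      # resampled copies of a participant become distinct clusters
      dfb$.pid <- rep(seq_along(draw),
                      vapply(rows_by_pid[draw], length, integer(1)))
    }
    r2 <- tryCatch(delta_r2_once(dfb, fixed_base, fixed_full, re, re2),
                   error = function(e) NULL)
    if (!is.null(r2)) reps[bidx, ] <- r2
  }
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * n_boot) {
    msg <- sprintf("%d of %d bootstrap replicates failed to converge",
                   n_dropped, n_boot)
    if (strict) fw_stop(msg, "fwtrace_fit_error") else warning(msg)
  }
  delta <- unname(100 * (reps[ok, "full"] - reps[ok, "base"]))
  base_pct <- unname(100 * reps[ok, "base"])
  sp <- split_feature(feature)
  structure(list(
    tract = sp[["tract"]], metric = sp[["metric"]], domain = spec$outcome,
    replicates = delta, n_boot = length(delta), n_dropped = n_dropped,
    mean = mean(delta),
    ci95 = unname(stats::quantile(delta, c(0.025, 0.975))),
    base_r2_mean = mean(base_pct),
    base_r2_ci = unname(stats::quantile(base_pct, c(0.025, 0.975))),
    point_delta = 100 * (point[["full"]] - point[["base"]]),
    point_base = 100 * point[["base"]], seed = as.integer(seed)),
    class = "boot_r2")
}

#' @export
print.boot_r2 <- function(x, ...) {
  cat(sprintf(
    "<boot_r2> %s.%s ~ %s: dR2 = %.2f%% (95%% CI %.2f-%.2f), base R2 = %.2f%%, n_boot = %d (%d dropped)\n",
    x$tract, x$metric, x$domain, x$mean, x$ci95[1], x$ci95[2],
    x$base_r2_mean, x$n_boot, x$n_dropped))
  invisible(x)
}

#' Head-to-head comparison of bootstrap distributions
#'
#' Pools replicate Delta R^2 values, runs a one-way ANOVA across groups
#' (metric, tract type, or tract), follows up with pairwise Welch t tests
#' under BH-FDR, and ranks groups by mean added variance. Treating
#' bootstrap replicates as independent observations makes these tests
#' anticonservative; the report carries that caveat and the ranking is the
#' primary output.
#'
#' @param distributions list of `boot_r2` objects.
#' @param grouping `"metric"`, `"tract_type"`, or `"tract"`.
#' @param atlas atlas used to map tracts to types (for
#'   `grouping = "tract_type"`).
#' @return A `head_to_head` report: ANOVA F/p, pairwise table with q-values,
#'   and the ranking by mean.
#' @export
head_to_head <- function(distributions,
                         grouping = c("metric", "tract_type", "tract"),
                         atlas = atlas_registry()) {
  grouping <- match.arg(grouping)
  stopifnot(all(vapply(distributions, inherits, logical(1), "boot_r2")))
  grp <- vapply(distributions, function(d) {
    switch(grouping,
           metric = d$metric,
           tract = d$tract,
           tract_type = atlas$tract_type[match(d$tract, atlas$tract)])
  }, character(1))
  if (anyNA(grp)) fw_stop("some tracts are missing from the atlas",
                          "fwtrace_config_error")
  vals <- lapply(distributions, `[[`, "replicates")
  df <- data.frame(value = unlist(vals), group = rep(grp, lengths(vals)))
  if (length(unique(df$group)) < 2L) {
    fw_stop("need >= 2 groups for a head-to-head comparison",
            "fwtrace_config_error")
  }
  if (any(table(df$group) < 2L)) {
    fw_stop("every group needs >= 2 replicate values", "fwtrace_config_error")
  }
  av <- stats::anova(stats::aov(value ~ group, data = df))
  pairs <- utils::combn(sort(unique(df$group)), 2)
  pt <- apply(pairs, 2, function(pr) {
    a <- df$value[df$group == pr[1]]
    b <- df$value[df$group == pr[2]]
    if (stats::var(a) + stats::var(b) == 0) {
      return(c(t = 0, p = if (mean(a) == mean(b)) 1 else 0))
    }
    tt <- stats::t.test(a, b)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  pair_tab <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         t = pt["t", ], p = pt["p", ])
  pair_tab$q <- fdr_adjust(pair_tab$p)
  means <- sort(tapply(df$value, df$group, mean), decreasing = TRUE)
  ranking <- data.frame(group = names(means), mean_delta_r2 = as.numeric(means),
                        rank = seq_along(means))
  structure(list(grouping = grouping,
                 anova_F = av[["F value"]][1], anova_p = av[["Pr(>F)"]][1],
                 pairs = pair_tab, ranking = ranking,
                 caveat = paste("bootstrap replicates treated as independent",
                                "observations; tests are anticonservative")),
            class = "head_to_head")
}

#' @export
print.head_to_head <- function(x, ...) {
  cat("<head_to_head> by ", x$grouping, ": F = ",
      format(x$anova_F, digits = 4), ", p = ",
      format.pval(x$anova_p, digits = 3), "\n", sep = "")
  print(x$ranking, row.names = FALSE)
  cat("note:", x$caveat, "\n")
  invisible(x)
}
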