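# Tract-mean feature extraction and age-regressed outlier QC.

#' Extract tract-mean features from scalar maps
#'
#' Computes the (weight-normalized) mean of each metric map over every tract
#' mask of an atlas, giving one feature row per imaging session. With a full
#' 48-tract atlas and all five metrics this yields the standard 240-column
#' feature block. Probabilistic masks are used as weights; binary masks are
#' the weight-1 special case. NaN voxels (outside the fitted brain mask) are
#' dropped before averaging; a tract whose mask is empty after NaN removal
#' yields `NA` with a warning.
#'
#' @param maps named list of 3-D arrays (names from [fw_metrics()], or any
#'   subset).
#' @param atlas a `tract_atlas` with masks attached ([attach_atlas_masks()]).
#' @param session_key list or 1-row data.frame with identifying columns
#'   (e.g. `participant_id`, `session`).
#' @return 1-row data.frame: session-key columns then one column per
#'   tract x metric.
#' @export
extract_features <- function(maps, atlas, session_key = list(session = "s1")) {
  stopifnot(inherits(atlas, "tract_atlas"))
  masks <- attr(atlas, "masks")
  if (is.null(masks)) fw_stop("atlas has no masks; use attach_atlas_masks()",
                              "fwtrace_config_error")
  grid <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), grid)) fw_stop("metric maps share no common grid",
                                          "fwtrace_shape_error")
  }
  vals <- list()
  for (tr in atlas$tract) {
    w <- masks[[tr]]
    if (!identical(dim(w), grid)) {
      fw_stop(sprintf("mask grid mismatch for tract '%s'", tr),
              "fwtrace_shape_error")
    }
    for (met in names(maps)) {
      x <- as.vector(maps[[met]])
      wt <- as.vector(w)
      ok <- is.finite(x) & wt > 0
      nm <- paste(tr, met, sep = ".")
      if (!any(ok)) {
        warning(sprintf("empty mask after NaN removal for %s; feature set NA", nm))
        vals[[nm]] <- NA_real_
      } else {
        vals[[nm]] <- sum(x[ok] * wt[ok]) / sum(wt[ok])
      }
    }
  }
  cbind(as.data.frame(session_key, stringsAsFactors = FALSE),
        as.data.frame(vals, check.names = FALSE))
}

#' Age-regressed outlier exclusion
#'
#' For each feature column, regresses the participant-level baseline value on
#' baseline age and standardizes the residuals by the residual SD of that
#' regression. A participant is excluded — all of their sessions — when ANY
#' feature's standardized residual exceeds `threshold` in absolute value.
#' Residual SDs are frozen from this first pass, so re-running the filter on
#' its own output excludes nobody further (idempotence by construction).
#'
#' @param features a `study_table` or data.frame with `participant_id`,
#'   `baseline_age` and feature columns.
#' @param feature_cols character vector of feature columns; defaults to the
#'   simulated feature names when present, else to all `<tract>.<metric>`
#'   style columns.
#' @param threshold exclusion threshold in residual-SD units (default 5).
#' @param frozen regression parameters from a previous run (the `frozen`
#'   element of its result); when supplied, residuals are standardized
#'   against those first-pass fits, making repeated filtering idempotent
#'   by construction.
#' @return List with `data` (filtered table), `excluded` (participant ids),
#'   `report` (data.frame of participant, feature, residual_sd triples for
#'   every flagged value), and `frozen` (per-feature intercept, slope and
#'   residual SD for reuse).
#' @examples
#' st <- generate_study(list(cohort_config("A", 50, 74, 7, 2, 2)), seed = 1)
#' qc <- exclude_age_outliers(st)
#' nrow(qc$report)
#' @export
exclude_age_outliers <- function(features, feature_cols = NULL, threshold = 5,
                                 frozen = NULL) {
  if (!is.numeric(threshold) || threshold <= 0) {
    fw_stop("threshold must be a positive number of SD units",
            "fwtrace_config_error")
  }
  feature_cols <- feature_cols %||% attr(features, "truth")$feature_names %||%
    grep("^[A-Za-z0-9_]+\\.(FW|FAt|MDt|AxDt|RDt)$", names(features), value = TRUE)
  if (!length(feature_cols)) fw_stop("no feature columns found", "fwtrace_config_error")

  base <- features[!duplicated(features$participant_id), , drop = FALSE]
  if (nrow(base) < 10L) {
    fw_stop("need >= 10 participants for a stable residual SD",
            "fwtrace_input_error")
  }
  age <- base$baseline_age
  flagged <- list()
  frozen_out <- list()
  for (fc in feature_cols) {
    y <- base[[fc]]
    ok <- is.finite(y)
    if (is.null(frozen)) {
      fit <- stats::lm.fit(cbind(1, age[ok]), y[ok])
      pars <- c(fit$coefficients, sqrt(sum(fit$residuals^2) /
                                         max(1, sum(ok) - 2)))
    } else {
      pars <- frozen[[fc]]
      if (is.null(pars)) next
    }
    frozen_out[[fc]] <- pars
    rsd <- pars[3]
    if (!is.finite(rsd) || rsd == 0) next
    z <- (y[ok] - pars[1] - pars[2] * age[ok]) / rsd
    bad <- which(abs(z) > threshold)
    if (length(bad)) {
      flagged[[fc]] <- data.frame(
        participant_id = base$participant_id[ok][bad],
        feature = fc, residual_sd = z[bad], stringsAsFactors = FALSE)
    }
  }
  report <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(participant_id = character(0), feature = character(0),
               residual_sd = numeric(0))
  rownames(report) <- NULL
  excluded <- unique(report$participant_id)
  out <- features[!features$participant_id %in% excluded, , drop = FALSE]
  attr(out, "truth") <- attr(features, "truth")
  class(out) <- class(features)
  list(data = out, excluded = excluded, report = report, frozen = frozen_out)
}
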