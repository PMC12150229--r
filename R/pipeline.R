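# Configuration-driven orchestration of the synthetic study: simulate ->
# QC -> harmonize -> association scans -> variance partitioning ->
# interactions, with every table written to a run directory under a
# manifest. All stages are deterministic given the configured seed.

STUDY_REQUIRED_COLS <- c("participant_id", "cohort", "batch", "visit_index",
                         "baseline_age", "age_at_visit", "sex", "education",
                         "race_ethnicity", "apoe4", "apoe2",
                         "baseline_diagnosis", "converter",
                         "memory", "executive", "language")

#' Read / write a study table as CSV
#'
#' `write_study` writes one row per participant-visit with a header row
#' (UTF-8, full numeric precision); `read_study` validates the schema,
#' derives `interval` from the two age columns when absent, and rejects
#' malformed rows by number.
#'
#' @param path CSV file path.
#' @return `read_study`: a `study_table` data.frame.
#' @export
read_study <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STUDY_REQUIRED_COLS, names(x))
  if (length(missing_cols)) {
    fw_stop(paste0("study file lacks required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "fwtrace_schema_error")
  }
  num_cols <- c("baseline_age", "age_at_visit", "memory", "executive",
                "language")
  for (nc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x[[nc]]))))
    if (length(bad)) {
      fw_stop(sprintf("malformed value in column '%s' at row(s) %s", nc,
                      paste(utils::head(bad, 5), collapse = ", ")),
              "fwtrace_schema_error")
    }
    x[[nc]] <- as.numeric(x[[nc]])
  }
  if (!"interval" %in% names(x)) {
    x$interval <- x$age_at_visit - x$baseline_age
    message("derived `interval` as age_at_visit - baseline_age")
  }
  if (any(x$interval < -1e-9)) {
    fw_stop("negative interval(s); ages are inconsistent", "fwtrace_schema_error")
  }
  class(x) <- c("study_table", "data.frame")
  x
}

#' @rdname read_study
#' @param x a `study_table`.
#' @export
write_study <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read generating truth as a YAML sidecar
#'
#' @param truth the `truth` attribute of a generated study table.
#' @param path YAML path.
#' @export
write_truth <- function(truth, path) {
  keep <- truth[c("gamma_batch", "delta_batch", "seed")]
  keep$params <- unclass(truth$params)
  yaml::write_yaml(lapply(keep, function(v) if (is.list(v)) v else as.list(v)),
                   path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) yaml::read_yaml(path)

PIPELINE_STAGES <- c("simulate", "fit-fw", "extract", "qc", "harmonize",
                     "scan-cross", "scan-long", "varpart", "interactions")

#' Pipeline configuration
#'
#' @param out_dir run directory (created if needed).
#' @param seed integer seed propagated to every stochastic stage.
#' @param stages stages to run, in dependency order; a subset of
#'   `r paste(PIPELINE_STAGES, collapse = ", ")`.
#' @param cohort_scale multiplier on the default cohort sizes.
#' @param truth a [truth_params()].
#' @param domains cognitive domains to scan.
#' @param n_boot bootstrap replicates for the varpart stage.
#' @param varpart_tracts tracts (one per type by default, chosen
#'   alphabetically) whose FW feature enters the bootstrap comparison.
#' @param atlas tract atlas (subset allowed for desk-scale runs).
#' @param metrics metrics to simulate and scan.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 7L, stages = PIPELINE_STAGES,
                            cohort_scale = 0.05, truth = truth_params(),
                            domains = c("memory", "executive", "language"),
                            n_boot = 100, varpart_tracts = NULL,
                            atlas = atlas_registry(), metrics = fw_metrics()) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) {
    fw_stop(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                   "; valid stages: ", paste(PIPELINE_STAGES, collapse = ", ")),
            "fwtrace_config_error")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 cohort_scale = cohort_scale, truth = truth, domains = domains,
                 n_boot = n_boot, varpart_tracts = varpart_tracts,
                 atlas = atlas, metrics = metrics),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the synthetic-study pipeline
#'
#' Executes the enabled stages in dependency order, writing each table as
#' CSV into the run directory together with a `manifest.csv` (stage, file,
#' seed, rows). Rerunning with the same configuration reproduces the
#' deterministic outputs byte for byte.
#'
#' @param config a [pipeline_config()], or a path to a YAML file with its
#'   scalar fields (`out_dir`, `seed`, `stages`, `cohort_scale`, `n_boot`).
#' @return Invisibly, the run directory; the manifest is also returned as
#'   the `manifest` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- pipeline_config(
      out_dir = cfg$out_dir %||% dirname(config),
      seed = cfg$seed %||% 7L,
      stages = unlist(cfg$stages) %||% PIPELINE_STAGES,
      cohort_scale = cfg$cohort_scale %||% 0.05,
      n_boot = cfg$n_boot %||% 100)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         seed = integer(0), rows = integer(0))
  emit <- function(stage, name, obj) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    manifest <<- rbind(manifest, data.frame(stage = stage, file = name,
                                            seed = config$seed,
                                            rows = nrow(obj)))
    path
  }
  on_stage <- function(s) s %in% config$stages
  need <- function(obj, stage_needed) {
    if (is.null(obj)) {
      fw_stop(paste0("missing upstream artifact; run stage '", stage_needed,
                     "' first"), "fwtrace_pipeline_error")
    }
    obj
  }
  study <- NULL; harmonized <- NULL

  if (on_stage("simulate")) {
    study <- generate_study(default_cohort_configs(config$cohort_scale),
                            config$truth, seed = config$seed,
                            atlas = config$atlas, metrics = config$metrics)
    emit("simulate", "study.csv", study)
    write_truth(attr(study, "truth"), file.path(config$out_dir, "truth.yaml"))
    stage_log("simulate", length(unique(study$participant_id)),
              " participants, ", nrow(study), " visits")
  }

  if (on_stage("fit-fw")) {
    ph <- generate_dwi_phantom(27, f_values = seq(0.05, 0.6, length.out = 27),
                               seed = sub_seed(config$seed, "phantom"))
    dwi <- array(t(ph$signals), dim = c(length(ph$gtab$bvals), 3, 3, 3))
    dwi <- aperm(dwi, c(2, 3, 4, 1))
    maps <- map_volume(dwi, ph$gtab)
    sc <- data.frame(voxel = seq_len(27),
                     lapply(maps, function(m) as.vector(m)))
    emit("fit-fw", "phantom_scalars.csv", sc)
    stage_log("fit-fw", "fitted ", nrow(sc), " phantom voxels")
    if (on_stage("extract")) {
      at3 <- config$atlas[seq_len(min(3, nrow(config$atlas))), ]
      masks <- lapply(seq_len(nrow(at3)), function(i) {
        m <- array(0, dim(maps$FW)); m[i, , ] <- 1; m
      })
      names(masks) <- at3$tract
      at3 <- attach_atlas_masks(at3, masks)
      fx <- extract_features(maps, at3, session_key = list(
        participant_id = "phantom", session = 1))
      emit("extract", "phantom_features.csv", fx)
      stage_log("extract", ncol(fx) - 2, " tract features")
    }
  }

  if (on_stage("qc")) {
    study <- need(study, "simulate")
    qc <- exclude_age_outliers(study)
    study <- qc$data
    emit("qc", "study_qc.csv", study)
    emit("qc", "qc_exclusions.csv", qc$report)
    stage_log("qc", length(qc$excluded), " participants excluded, ",
              length(unique(study$participant_id)), " retained")
  }

  if (on_stage("harmonize")) {
    study <- need(study, "simulate")
    cm <- fit_longcombat(study)
    harmonized <- apply_longcombat(study, cm)
    emit("harmonize", "study_harmonized.csv", harmonized)
    emit("harmonize", "batch_effects.csv", batch_effects(cm))
    stage_log("harmonize", length(cm$feature_cols), " features over ",
              length(cm$batch_levels), " batches")
  }

  analysis <- harmonized %||% study

  if (on_stage("scan-cross")) {
    analysis <- need(analysis, "simulate")
    res <- do.call(rbind, lapply(config$domains, function(d) {
      cross_sectional_scan(analysis, spec = model_spec(outcome = d))
    }))
    emit("scan-cross", "scan_cross.csv", res)
    stage_log("scan-cross", nrow(res), " models, ",
              sum(!res$converged), " non-converged")
  }

  if (on_stage("scan-long")) {
    analysis <- need(analysis, "simulate")
    res <- do.call(rbind, lapply(config$domains, function(d) {
      longitudinal_scan(analysis, spec = model_spec(outcome = d))
    }))
    emit("scan-long", "scan_long.csv", res)
    stage_log("scan-long", nrow(res), " models, ",
              sum(!res$converged), " non-converged")
  }

  boots <- NULL
  if (on_stage("varpart")) {
    analysis <- need(analysis, "simulate")
    tracts <- config$varpart_tracts %||% vapply(
      split(config$atlas$tract, config$atlas$tract_type),
      function(v) sort(v)[1], character(1))
    feats <- paste0(intersect(tracts, attr(analysis, "truth")$tracts), ".FW")
    boots <- lapply(feats, function(fc) {
      bootstrap_delta_r2(analysis, fc, model_spec(outcome = config$domains[1]),
                         n_boot = config$n_boot,
                         seed = sub_seed(config$seed, fc))
    })
    reps <- do.call(rbind, lapply(boots, function(b) {
      data.frame(tract = b$tract, metric = b$metric, domain = b$domain,
                 replicate = seq_along(b$replicates), delta_r2 = b$replicates)
    }))
    emit("varpart", "bootstrap_delta_r2.csv", reps)
    h2h <- head_to_head(boots, "tract_type", atlas = config$atlas)
    emit("varpart", "head_to_head_ranking.csv", h2h$ranking)
    dropped <- sum(vapply(boots, `[[`, numeric(1), "n_dropped"))
    stage_log("varpart", length(boots), " features x ", config$n_boot,
              " replicates, ", dropped, " dropped")
  }

  if (on_stage("interactions")) {
    analysis <- need(analysis, "simulate")
    fx <- attr(analysis, "truth")$params$wm_feature
    res <- do.call(rbind, lapply(c("hippocampal_volume", "spare_ad"),
                                 function(e) {
      rbind(interaction_scan(analysis, features = fx, endophenotype = e,
                             mode = "cross-sectional"),
            interaction_scan(analysis, features = fx, endophenotype = e,
                             mode = "longitudinal"))
    }))
    emit("interactions", "scan_interactions.csv", res)
    stage_log("interactions", nrow(res), " interaction models")
  }

  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  structure(invisible(config$out_dir), manifest = manifest)
}
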