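# End-to-end orchestration: simulate (or read) a cohort, compute
# volumetrics, parcellation, the shape atlas with z-scores, calliper
# morphometry with mode associations, and the staged risk models plus
# PRVI surrogate analysis, writing every stage's outputs and a
# deterministic manifest.

#' Default run configuration
#'
#' @param output_dir where stage outputs are written.
#' @param cohort overrides passed to \code{cohort_spec} (list).
#' @param seed top-level seed; stage sub-seeds derive from it.
#' @param retention atlas mode-retention threshold.
#' @param gpa_tol,gpa_max_iter Procrustes controls.
#' @param max_k,folds risk-model controls.
#' @param density myocardial density (g/ml).
#' @param write_meshes write per-subject PLY + landmark JSON files.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(output_dir = "bivatlas_run",
                       cohort = list(), seed = 1L, retention = 0.01,
                       gpa_tol = 1e-6, gpa_max_iter = 100L,
                       max_k = 3L, folds = 4L, density = 1.05,
                       write_meshes = TRUE) {
  cfg <- list(output_dir = output_dir, cohort = cohort,
              seed = as.integer(seed), retention = retention,
              gpa_tol = gpa_tol, gpa_max_iter = as.integer(gpa_max_iter),
              max_k = as.integer(max_k), folds = as.integer(folds),
              density = density, write_meshes = isTRUE(write_meshes))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so that config typos cannot silently
#' change a study.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return run_config.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$cohort)) {
    bad_c <- setdiff(names(raw$cohort), names(formals(cohort_spec)))
    if (length(bad_c))
      stop("unknown cohort keys: ", paste(bad_c, collapse = ", "))
    raw$cohort <- as.list(raw$cohort)
  }
  do.call(run_config, raw)
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate -> volumetrics -> parcellation -> atlas ->
#' calipers -> risk -> report. Each stage writes its outputs under
#' \code{output_dir}; a manifest records the configuration, seed and
#' md5 checksums of every written file, so a rerun with identical
#' config and seed is bit-reproducible. Any stage error aborts with
#' the stage name and leaves a \code{FAILED} marker next to the
#' partial outputs.
#'
#' @param config run_config (or path to one).
#' @param models,records optional pre-loaded cohort (skips the
#'   simulate stage).
#' @return invisible list with all in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), models = NULL,
                         records = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(out, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on.exit(if (!done) writeLines("pipeline aborted", fail_marker))
  done <- FALSE

  truth <- NULL
  spec <- NULL
  if (is.null(models)) {
    spec <- do.call(cohort_spec, utils::modifyList(
      list(seed = config$seed), config$cohort))
    sim <- stage_run("simulate", generate_cohort(spec))
    models <- sim$models
    records <- sim$records
    truth <- sim$truth
    if (config$write_meshes) {
      mdir <- file.path(out, "meshes")
      dir.create(mdir, showWarnings = FALSE)
      for (m in models) {
        write_ply(m$ed, file.path(mdir, paste0(m$subject_id, "_ed.ply")))
        write_ply(m$es, file.path(mdir, paste0(m$subject_id, "_es.ply")))
        write_landmarks(m$landmarks_ed,
                        file.path(mdir, paste0(m$subject_id,
                                               "_landmarks_ed.json")))
        write_landmarks(m$landmarks_es,
                        file.path(mdir, paste0(m$subject_id,
                                               "_landmarks_es.json")))
      }
    }
    write_cohort(records, file.path(out, "cohort.csv"))
    utils::write.csv(truth, file.path(out, "ground_truth.csv"),
                     row.names = FALSE)
  }

  vol <- stage_run("volumetrics",
                   cohort_volumetrics(models, records, config$density))
  utils::write.csv(vol, file.path(out, "volumetrics.csv"),
                   row.names = FALSE)

  parc <- stage_run("parcellate", cohort_parcellation(models, records))
  utils::write.csv(parc, file.path(out, "parcellation.csv"),
                   row.names = FALSE)

  gpa <- stage_run("atlas", generalized_procrustes(
    models, tol = config$gpa_tol, max_iter = config$gpa_max_iter))
  atlas <- stage_run("atlas", fit_pca(gpa$models, config$retention))
  scores <- stage_run("atlas", cohort_scores(atlas, gpa$models))
  saveRDS(atlas, file.path(out, "atlas.rds"))
  jsonlite::write_json(
    list(n_train = atlas$n_train, n_retained = atlas$n_retained,
         retention = atlas$retention,
         eigenvalues = atlas$eigenvalues,
         explained_fraction = atlas$explained_fraction),
    file.path(out, "atlas.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(scores, file.path(out, "scores.csv"),
                   row.names = FALSE)

  cal <- stage_run("calipers", cohort_calipers(gpa$models))
  utils::write.csv(cal, file.path(out, "calipers.csv"),
                   row.names = FALSE)
  assoc <- stage_run("calipers", regress_calipers_on_modes(cal, scores))
  utils::write.csv(as.data.frame(assoc$coefficients),
                   file.path(out, "caliper_mode_association.csv"))

  ft <- stage_run("risk",
                  build_feature_table(vol, parc, scores, records))
  staged <- stage_run("risk", staged_analysis(
    ft, max_k = config$max_k, folds = config$folds,
    seed = config$seed))
  utils::write.csv(staged$summary, file.path(out, "risk_summary.csv"),
                   row.names = FALSE)
  comp <- staged$composite
  jsonlite::write_json(
    list(selected_features = comp$selected_features,
         weights = as.list(comp$lda_weights),
         cv_auc = comp$cv_auc, full_auc = comp$full_auc,
         cutoff = comp$cutoff, or_per_sd = comp$or_per_sd,
         or_ci = comp$or_ci),
    file.path(out, "risk_model.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(
    data.frame(subject_id = ft$subject_id[comp$subset_ids],
               score = comp$scores, outcome = comp$labels),
    file.path(out, "risk_scores.csv"), row.names = FALSE)

  prvi <- NULL
  if (sum(!is.na(ft$prvi)) >= 10L) {
    shape_dir <- rep(0, atlas$n_retained)
    sw <- staged$shape$lda_weights
    shape_dir[match(names(sw), paste0("z",
                                      seq_len(atlas$n_retained)))] <- sw
    prvi <- stage_run("risk", prvi_analysis(
      ft, comp, atlas = atlas, risk_direction = shape_dir,
      folds = config$folds, seed = config$seed))
    jsonlite::write_json(
      list(n_prvi = prvi$n_prvi,
           auc_without_prvi = prvi$auc_without_prvi,
           auc_with_prvi = prvi$auc_with_prvi,
           auc_prvi_alone = prvi$auc_prvi_alone,
           mode_regression = prvi$mode_regression[c("modes", "r2")]),
      file.path(out, "prvi_analysis.json"), digits = NA,
      auto_unbox = TRUE)
  }

  tables <- stage_run("report", list(
    demographics = group_comparison_table(
      ft, intersect(c("bsa", "qrs_ms", "sbp_mmHg", "dbp_mmHg"),
                    names(ft))),
    volumetric = group_comparison_table(
      ft, attr(ft, "pools")$conventional),
    regional = group_comparison_table(ft, attr(ft, "pools")$regional)))
  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(out, paste0("table_", nm, ".csv")),
                     row.names = FALSE)

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "bivatlas",
    version = tryCatch(as.character(utils::packageVersion("bivatlas")),
                       error = function(e) "dev"),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")],
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  done <- TRUE
  invisible(list(models = models, records = records, truth = truth,
                 volumetrics = vol, parcellation = parc, gpa = gpa,
                 atlas = atlas, scores = scores, calipers = cal,
                 association = assoc, feature_table = ft,
                 staged = staged, prvi = prvi, tables = tables,
                 config = config))
}
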