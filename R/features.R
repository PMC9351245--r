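#' Assemble the per-subject feature table for risk modelling
#'
#' Merges BSA-indexed global volumetrics, regional RV parcellation
#' measures, shape-mode z-scores and clinical covariates into one
#' table, with named feature pools attached: \code{conventional}
#' (total volumes indexed, EFs, LV mass index, QRS, blood pressure),
#' \code{regional} (partial volumes/SV indexed and regional EFs) and
#' \code{shape} (retained mode z-scores).
#'
#' @param volumetrics data.frame from \code{cohort_volumetrics}.
#' @param parcellation data.frame from \code{cohort_parcellation}.
#' @param scores data.frame from \code{cohort_scores}.
#' @param records cohort covariate data.frame.
#' @return data.frame with attribute \code{"pools"}; one row per
#'   subject, merged on \code{subject_id}.
#' @export
build_feature_table <- function(volumetrics, parcellation, scores,
                                records) {
  ft <- Reduce(function(a, b) merge(a, b, by = "subject_id",
                                    sort = FALSE),
               list(records, volumetrics, parcellation, scores))
  pools <- list(
    conventional = intersect(
      c("lvedv_i", "lvesv_i", "lv_sv_i", "lvef", "rvedv_i", "rvesv_i",
        "rv_sv_i", "rvef", "lvm_i", "qrs_ms", "sbp_mmHg", "dbp_mmHg"),
      names(ft)),
    regional = intersect(
      c("ipv_ed_i", "opv_ed_i", "apv_ed_i", "ipv_es_i", "opv_es_i",
        "apv_es_i", "ipsv_i", "opsv_i", "apsv_i", "ipef", "opef",
        "apef"),
      names(ft)),
    shape = grep("^z[0-9]+$", names(ft), value = TRUE))
  attr(ft, "pools") <- pools
  ft
}

#' Simulate a feature table directly from the latent outcome model
#'
#' Feature-level counterpart of the mesh generator, mirroring its
#' latent structure without building meshes: standard-normal latent
#' factors and an apical-contraction jitter drive the outcome through
#' the same logistic model, observed as noisy named features (an
#' apical-EF-like measure, mode-score-like measures, plus exchangeable
#' nuisance covariates). Used for statistically demanding validation
#' of the selection machinery at cohort sizes where full mesh
#' simulation would be wasteful.
#'
#' @param n subjects.
#' @param beta_apef,beta_mode logistic coefficients of the two true
#'   drivers (signs follow the mesh generator: higher risk with lower
#'   apical EF, higher basal-dilation score).
#' @param prevalence target outcome rate.
#' @param n_nuisance number of independent N(0,1) nuisance features.
#' @param feature_noise_sd observation noise added to the true
#'   drivers.
#' @param seed RNG seed.
#' @return data.frame with \code{adverse_outcome}, drivers
#'   \code{apef}, \code{z1}, and nuisance columns; pools attached as
#'   in \code{build_feature_table}.
#' @export
simulate_feature_table <- function(n = 400L, beta_apef = -1.0,
                                   beta_mode = 0.8,
                                   prevalence = 0.25,
                                   n_nuisance = 4L,
                                   feature_noise_sd = 0.3,
                                   seed = 1L) {
  set.seed(seed)
  apef_true <- stats::rnorm(n)
  mode_true <- stats::rnorm(n)
  b0 <- calibrate_intercept(c(beta_apef, beta_mode), prevalence)
  eta <- b0 + beta_apef * apef_true + beta_mode * mode_true
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  ft <- data.frame(
    adverse_outcome = y,
    apef = apef_true + stats::rnorm(n, 0, feature_noise_sd),
    z1 = mode_true + stats::rnorm(n, 0, feature_noise_sd))
  for (j in seq_len(n_nuisance))
    ft[[paste0("x", j)]] <- stats::rnorm(n)
  attr(ft, "pools") <- list(
    conventional = paste0("x", seq_len(n_nuisance)),
    regional = "apef", shape = "z1")
  ft
}
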