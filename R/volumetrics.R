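#' Body surface area by the Mosteller formula
#'
#' Fallback when the cohort table has no BSA column value:
#' \code{sqrt(height_cm * weight_kg / 3600)} (m^2).
#'
#' @param height_cm,weight_kg anthropometrics.
#' @return BSA in m^2.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  sqrt(height_cm * weight_kg / 3600)
}

#' Global chamber volumetrics for one subject
#'
#' Computes ED and ES cavity volumes for both ventricles from the
#' closed labelled surfaces, stroke volumes, ejection fractions,
#' LV myocardial mass (epicardial minus endocardial shell volume times
#' myocardial density) and mass-to-volume ratios, plus BSA-indexed
#' variants when BSA is available. The LV cavity is the closed
#' \code{lv_endo} surface; the RV cavity the closed
#' \code{rv_free_wall + rv_septum} surface. Trabeculae and papillary
#' muscles are not modelled separately: the cavity is everything
#' inside the endocardial surface.
#'
#' @param model biventricular_model.
#' @param bsa body surface area in m^2 (or NA to skip indexing).
#' @param density myocardial density in g/ml (default 1.05, the
#'   conventional CMR value).
#' @return one-row data.frame of class \code{volumetrics} with volumes
#'   in ml, EF as fractions, mass in g, indexed values per m^2.
#' @export
compute_volumetrics <- function(model, bsa = NA_real_, density = 1.05) {
  lvedv <- chamber_volume(model$ed, "lv_endo")
  lvesv <- chamber_volume(model$es, "lv_endo")
  rvedv <- chamber_volume(model$ed, "rv")
  rvesv <- chamber_volume(model$es, "rv")
  epi_ed <- chamber_volume(model$ed, "lv_epi")
  epi_es <- chamber_volume(model$es, "lv_epi")
  if (epi_ed <= lvedv || epi_es <= lvesv)
    stop("subject ", model$subject_id,
         ": epicardial volume <= endocardial volume (inverted surfaces)")
  lvm <- (epi_ed - lvedv) * density        # reported mass is the ED shell
  lvm_es <- (epi_es - lvesv) * density
  out <- data.frame(
    subject_id = model$subject_id,
    lvedv = lvedv, lvesv = lvesv, rvedv = rvedv, rvesv = rvesv,
    lv_sv = lvedv - lvesv, rv_sv = rvedv - rvesv,
    lvef = (lvedv - lvesv) / lvedv, rvef = (rvedv - rvesv) / rvedv,
    lvm = lvm,
    lv_ed_mvr = lvm / lvedv, lv_es_mvr = lvm_es / lvesv,
    stringsAsFactors = FALSE)
  if (is.finite(bsa) && bsa > 0) {
    for (nm in c("lvedv", "lvesv", "rvedv", "rvesv", "lv_sv", "rv_sv",
                 "lvm"))
      out[[paste0(nm, "_i")]] <- out[[nm]] / bsa
  }
  class(out) <- c("volumetrics", class(out))
  out
}

#' Volumetrics for a whole cohort
#'
#' @param models list of biventricular_model.
#' @param records cohort data.frame (matched on subject_id; supplies
#'   BSA for indexing).
#' @param density myocardial density (g/ml).
#' @return data.frame with one row per subject.
#' @export
cohort_volumetrics <- function(models, records = NULL, density = 1.05) {
  rows <- lapply(models, function(m) {
    bsa <- NA_real_
    if (!is.null(records)) {
      i <- match(m$subject_id, records$subject_id)
      if (!is.na(i)) bsa <- records$bsa[i]
    }
    compute_volumetrics(m, bsa = bsa, density = density)
  })
  do.call(rbind, rows)
}
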