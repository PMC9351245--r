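# Calliper morphometry: heights, level-wise widths, sphericity
# (width / height) and eccentricity (anterior-posterior width /
# septal-lateral width) for both ventricles at ED and ES, plus
# ED->ES displacements of apices and valve centroids and longitudinal
# shortening. Widths are extents of plane-mesh intersections
# projected on anatomical axes, the rotation-invariant reading of
# point-to-point calliper distances.

CALIPER_LEVELS <- c(apical = 0.25, mid = 0.5, basal = 0.75)

#' Anatomical reference frame for one phase
#'
#' Long axes run valve-to-apex (mitral centroid to LV apex; tricuspid
#' centroid to RV apex). The septal normal is the least-squares plane
#' normal through the \code{rv_septum}-labelled vertices, oriented
#' from LV to RV; the anterior-posterior axis is the unit vector
#' orthogonal to both the septal normal and the LV long axis.
#'
#' @param model biventricular_model.
#' @param phase \code{"ed"} or \code{"es"}.
#' @return list: unit vectors \code{long_axis_lv, long_axis_rv,
#'   septal_normal, ap_axis}, heights \code{h_lv, h_rv} (mm), and the
#'   apex/valve points used.
#' @export
anatomical_frame <- function(model, phase = c("ed", "es")) {
  phase <- match.arg(phase)
  mesh <- model[[phase]]
  lm <- model[[paste0("landmarks_", phase)]]
  unit <- function(v) v / sqrt(sum(v^2))

  la_lv <- unit(lm$lv_apex - lm$mv_centroid)
  la_rv <- unit(lm$rv_apex - lm$tv_centroid)
  h_lv <- sqrt(sum((lm$lv_apex - lm$mv_centroid)^2))
  h_rv <- sqrt(sum((lm$rv_apex - lm$tv_centroid)^2))

  sep <- mesh$vertices[mesh$labels == "rv_septum", , drop = FALSE]
  if (nrow(sep) < 3L) stop("no septal vertices labelled")
  cc <- sweep(sep, 2L, colMeans(sep))
  e <- eigen(crossprod(cc), symmetric = TRUE)
  if (e$values[2L] < 1e-6 * e$values[1L])
    stop("degenerate (collinear) septum; cannot fit a plane")
  nrm <- e$vectors[, 3L]
  lv_ctr <- colMeans(mesh$vertices[mesh$labels == "lv_endo", ,
                                   drop = FALSE])
  rv_ctr <- colMeans(mesh$vertices[mesh$labels %in% RV_LABELS, ,
                                   drop = FALSE])
  if (sum(nrm * (rv_ctr - lv_ctr)) < 0) nrm <- -nrm
  ap <- unit(pracma_cross(nrm, la_lv))
  list(long_axis_lv = la_lv, long_axis_rv = la_rv,
       septal_normal = nrm, ap_axis = ap, h_lv = h_lv, h_rv = h_rv,
       lv_apex = lm$lv_apex, rv_apex = lm$rv_apex,
       mv_centroid = lm$mv_centroid, tv_centroid = lm$tv_centroid)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Extent of the plane/mesh intersection projected on an axis. The
# plane passes through `point` with normal `normal`; faces are the
# chamber's triangles.
slice_extent <- function(verts, faces, point, normal, proj_axis) {
  d <- drop(sweep(verts, 2L, point) %*% normal)
  d1 <- d[faces[, 1L]]; d2 <- d[faces[, 2L]]; d3 <- d[faces[, 3L]]
  pts <- list()
  edge_cross <- function(ia, ib, da, db) {
    hit <- (da > 0 & db <= 0) | (da <= 0 & db > 0)
    if (!any(hit)) return(NULL)
    t <- da[hit] / (da[hit] - db[hit])
    verts[ia[hit], , drop = FALSE] * (1 - t) +
      verts[ib[hit], , drop = FALSE] * t
  }
  pts <- rbind(edge_cross(faces[, 1L], faces[, 2L], d1, d2),
               edge_cross(faces[, 2L], faces[, 3L], d2, d3),
               edge_cross(faces[, 3L], faces[, 1L], d3, d1))
  if (is.null(pts) || nrow(pts) == 0L)
    stop("empty slice: cutting plane misses the chamber")
  p <- drop(pts %*% proj_axis)
  max(p) - min(p)
}

#' Calliper measurements for one subject
#'
#' For each ventricle and phase, slices the chamber with planes
#' orthogonal to its long axis at 1/4 (apical), 1/2 (mid) and 3/4
#' (basal) of the height measured from the apex, and records the
#' septal-lateral width (slice extent along the septal normal) and
#' anterior-posterior width (extent along the AP axis).
#' Sphericity = septal-lateral width / height; eccentricity =
#' AP width / septal-lateral width. Displacements are the Euclidean
#' ED to ES motion of the apices and valve centroids in the frame the
#' model is expressed in (the atlas frame, for aligned cohorts);
#' longitudinal shortening is (h_ED - h_ES) / h_ED.
#'
#' @param model biventricular_model.
#' @return one-row data.frame of class \code{caliper_set}: columns
#'   like \code{h_lv_ed}, \code{w_lv_sl_mid_ed}, \code{w_rv_ap_basal_es},
#'   \code{spher_rv_apical_ed}, \code{ecc_lv_mid_es},
#'   \code{shortening_lv}, \code{disp_apex_rv}, \code{disp_mv}.
#' @export
compute_calipers <- function(model) {
  out <- list(subject_id = model$subject_id)
  frames <- list(ed = anatomical_frame(model, "ed"),
                 es = anatomical_frame(model, "es"))
  for (ph in c("ed", "es")) {
    fr <- frames[[ph]]
    mesh <- model[[ph]]
    out[[paste0("h_lv_", ph)]] <- fr$h_lv
    out[[paste0("h_rv_", ph)]] <- fr$h_rv
    for (vent in c("lv", "rv")) {
      faces <- chamber_faces(mesh,
                             if (vent == "lv") "lv_endo" else RV_LABELS)
      apex <- if (vent == "lv") fr$lv_apex else fr$rv_apex
      axis <- if (vent == "lv") fr$long_axis_lv else fr$long_axis_rv
      h <- if (vent == "lv") fr$h_lv else fr$h_rv
      for (lv_nm in names(CALIPER_LEVELS)) {
        r <- CALIPER_LEVELS[[lv_nm]]
        point <- apex - r * h * axis   # long axis points valve -> apex
        w_sl <- slice_extent(mesh$vertices, faces, point, axis,
                             fr$septal_normal)
        w_ap <- slice_extent(mesh$vertices, faces, point, axis,
                             fr$ap_axis)
        out[[sprintf("w_%s_sl_%s_%s", vent, lv_nm, ph)]] <- w_sl
        out[[sprintf("w_%s_ap_%s_%s", vent, lv_nm, ph)]] <- w_ap
        out[[sprintf("spher_%s_%s_%s", vent, lv_nm, ph)]] <- w_sl / h
        out[[sprintf("ecc_%s_%s_%s", vent, lv_nm, ph)]] <- w_ap / w_sl
      }
    }
  }
  dd <- function(a, b) sqrt(sum((a - b)^2))
  lm_ed <- model$landmarks_ed
  lm_es <- model$landmarks_es
  out$shortening_lv <- (frames$ed$h_lv - frames$es$h_lv) / frames$ed$h_lv
  out$shortening_rv <- (frames$ed$h_rv - frames$es$h_rv) / frames$ed$h_rv
  out$disp_apex_lv <- dd(lm_ed$lv_apex, lm_es$lv_apex)
  out$disp_apex_rv <- dd(lm_ed$rv_apex, lm_es$rv_apex)
  out$disp_mv <- dd(lm_ed$mv_centroid, lm_es$mv_centroid)
  out$disp_tv <- dd(lm_ed$tv_centroid, lm_es$tv_centroid)
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  class(res) <- c("caliper_set", class(res))
  res
}

#' Calipers for a whole cohort
#' @param models list of (aligned) biventricular_model.
#' @return data.frame, one row per subject.
#' @export
cohort_calipers <- function(models) {
  do.call(rbind, lapply(models, compute_calipers))
}

#' Regress calliper measures on shape-mode z-scores
#'
#' Ordinary least squares of each standardized calliper measure on
#' all retained mode z-scores; the coefficient magnitudes rank each
#' mode's contribution to each measure and give the shape modes their
#' morphometric interpretation.
#'
#' @param calipers data.frame from \code{cohort_calipers}.
#' @param scores data.frame from \code{cohort_scores} (or matrix of
#'   z-scores); matched on \code{subject_id} when present.
#' @return object of class \code{mode_caliper_association}:
#'   \code{coefficients} (modes x measures, standardized betas),
#'   \code{top_measures} (per mode, measures ranked by |beta|).
#' @export
regress_calipers_on_modes <- function(calipers, scores) {
  if (is.data.frame(scores) && "subject_id" %in% names(scores)) {
    m <- match(calipers$subject_id, scores$subject_id)
    z <- as.matrix(scores[m, grep("^z", names(scores)), drop = FALSE])
  } else z <- as.matrix(scores)
  if (nrow(calipers) < ncol(z) + 2L)
    stop("need at least n_modes + 2 subjects")
  y <- as.matrix(calipers[, !(names(calipers) %in% "subject_id"),
                          drop = FALSE])
  keep <- apply(y, 2L, stats::sd) > 0
  y <- scale(y[, keep, drop = FALSE])
  if (qr(cbind(1, z))$rank < ncol(z) + 1L)
    stop("rank-deficient design (collinear z-scores)")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, z), y)
  beta <- fit$coefficients
  if (is.null(dim(beta)))
    beta <- matrix(beta, ncol = 1L,
                   dimnames = list(names(beta), colnames(y)))
  beta <- beta[-1L, , drop = FALSE]
  top <- lapply(seq_len(nrow(beta)), function(k)
    colnames(beta)[order(-abs(beta[k, ]))])
  names(top) <- rownames(beta)
  structure(list(coefficients = beta, top_measures = top),
            class = "mode_caliper_association")
}

#' @export
print.mode_caliper_association <- function(x, ...) {
  cat("mode_caliper_association:", nrow(x$coefficients), "modes x",
      ncol(x$coefficients), "measures\n")
  for (k in seq_along(x$top_measures))
    cat(sprintf("  %s: %s\n", names(x$top_measures)[k],
                paste(utils::head(x$top_measures[[k]], 3L),
                      collapse = ", ")))
  invisible(x)
}
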