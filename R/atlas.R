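# Statistical shape atlas: rigid generalized Procrustes alignment of
# the ED shapes (each subject's transform propagated unchanged to its
# ES shape so that phase-to-phase motion is preserved), then PCA on
# the concatenated ED+ES coordinate vectors. Alignment is rigid only
# (rotation + translation, no scaling): size remains part of the
# shape modes.

#' Least-squares rigid alignment of corresponded point sets (Kabsch)
#'
#' Finds the proper rotation and translation minimising
#' \code{||R x + t - y||^2} over corresponded rows. Reflections are
#' never returned; the determinant sign is corrected, which is the
#' standard Procrustes treatment of degenerate configurations.
#'
#' @param x,y n x 3 matrices with row correspondence.
#' @return list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3), and \code{rmsd} after alignment.
#' @export
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- crossprod(sweep(x, 2L, cx), sweep(y, 2L, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - drop(rot %*% cx)
  aligned <- apply_rigid(x, rot, tr)
  list(rotation = rot, translation = tr,
       rmsd = sqrt(mean(rowSums((aligned - y)^2))))
}

#' Generalized Procrustes alignment of a cohort
#'
#' Iteratively aligns every subject's ED vertices to the evolving
#' population mean by least-squares rigid transforms, starting from
#' the first subject as reference, until the mean moves less than
#' \code{tol} mm RMS or \code{max_iter} iterations. Each subject's ED
#' transform is applied unchanged to its ES mesh and both landmark
#' sets.
#'
#' @param models list of biventricular_model (>= 2, corresponded).
#' @param tol convergence tolerance on the mean shape (mm RMS).
#' @param max_iter iteration cap.
#' @return list: \code{models} (aligned), \code{transforms} (per
#'   subject rotation/translation), \code{mean_ed} (aligned mean ED
#'   vertex matrix), \code{objective} (per-iteration mean squared
#'   distance to the mean; non-increasing), \code{iterations}.
#' @export
generalized_procrustes <- function(models, tol = 1e-6, max_iter = 100L) {
  if (length(models) < 2L) stop("need at least 2 models")
  eds <- lapply(models, function(m) m$ed$vertices)
  n <- length(eds)
  ref <- eds[[1L]]
  rots <- rep(list(diag(3)), n)
  trs <- rep(list(c(0, 0, 0)), n)
  objective <- numeric(0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aligned <- vector("list", n)
    for (i in seq_len(n)) {
      k <- kabsch(eds[[i]], ref)
      rots[[i]] <- k$rotation
      trs[[i]] <- k$translation
      aligned[[i]] <- apply_rigid(eds[[i]], k$rotation, k$translation)
    }
    new_ref <- Reduce(`+`, aligned) / n
    objective <- c(objective,
                   mean(vapply(aligned, function(a)
                     mean(rowSums((a - new_ref)^2)), 0)))
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol || iter >= max_iter) break
  }
  out_models <- vector("list", n)
  for (i in seq_len(n)) {
    out_models[[i]] <- transform_model(models[[i]], rots[[i]], trs[[i]])
  }
  list(models = out_models,
       transforms = Map(function(r, t) list(rotation = r, translation = t),
                        rots, trs),
       mean_ed = ref, objective = objective, iterations = iter)
}

# flatten a model into the concatenated ED+ES coordinate vector
# (x1,y1,z1,x2,... for ED then ES), length 6V
shape_vector <- function(model) {
  c(as.vector(t(model$ed$vertices)), as.vector(t(model$es$vertices)))
}

# split a shape vector back into ED/ES meshes on a template topology
shape_to_model <- function(shape, faces, labels, landmark_idx = NULL,
                           subject_id = "synthetic") {
  n <- length(shape) / 6L
  ed_v <- matrix(shape[seq_len(3L * n)], n, 3L, byrow = TRUE)
  es_v <- matrix(shape[3L * n + seq_len(3L * n)], n, 3L, byrow = TRUE)
  ed <- surface_mesh(ed_v, faces, labels, validate = FALSE)
  es <- surface_mesh(es_v, faces, labels, validate = FALSE)
  if (!is.null(landmark_idx)) {
    lm_ed <- do.call(landmark_set, lapply(LANDMARK_NAMES, function(nm)
      ed_v[landmark_idx[nm], ]))
    lm_es <- do.call(landmark_set, lapply(LANDMARK_NAMES, function(nm)
      es_v[landmark_idx[nm], ]))
  } else {
    z <- landmark_set(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      c(1, 1, 1))
    lm_ed <- lm_es <- z
  }
  biventricular_model(subject_id, ed, es, lm_ed, lm_es,
                      landmark_idx = landmark_idx)
}

#' Fit the PCA shape atlas on an aligned cohort
#'
#' Decomposes the mean-centred concatenated ED+ES shape vectors by
#' singular values; eigenvalue_k = sv_k^2 / (n - 1). Modes explaining
#' more than \code{retention} of total variance are retained. Mode
#' signs are fixed so each mode's largest-magnitude coordinate is
#' positive.
#'
#' @param aligned list of aligned biventricular_model (n >= 2), e.g.
#'   \code{generalized_procrustes(models)$models}.
#' @param retention explained-variance fraction threshold (default
#'   0.01, i.e. modes explaining > 1 per cent are kept).
#' @return object of class \code{shape_atlas}: \code{mean_shape},
#'   \code{modes} (6V x r orthonormal), \code{eigenvalues} (mm^2),
#'   \code{explained_fraction}, \code{n_retained}, training
#'   \code{scores} (z-scores, n x n_retained), plus template topology
#'   for synthesis.
#' @export
fit_pca <- function(aligned, retention = 0.01) {
  n <- length(aligned)
  if (n < 2L) stop("PCA needs at least 2 shapes")
  x <- t(vapply(aligned, shape_vector,
                numeric(6L * nrow(aligned[[1L]]$ed$vertices))))
  mean_shape <- colMeans(x)
  xc <- sweep(x, 2L, mean_shape)
  sv <- svd(xc)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|coordinate| of each mode positive
  for (k in seq_along(d)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  eig <- d^2 / (n - 1)
  frac <- eig / sum(eig)
  n_retained <- sum(frac > retention)
  scores <- u[, seq_len(n_retained), drop = FALSE] * sqrt(n - 1)
  colnames(scores) <- paste0("z", seq_len(n_retained))
  first <- aligned[[1L]]
  structure(list(mean_shape = mean_shape, modes = v, eigenvalues = eig,
                 explained_fraction = frac, n_retained = n_retained,
                 retention = retention, n_train = n, scores = scores,
                 faces = first$ed$faces, labels = first$ed$labels,
                 landmark_idx = first$landmark_idx),
            class = "shape_atlas")
}

#' @export
print.shape_atlas <- function(x, ...) {
  cat("shape_atlas:", x$n_train, "training shapes,",
      length(x$eigenvalues), "modes computed,", x$n_retained,
      sprintf("retained (> %g%% variance), covering %.1f%%\n",
              100 * x$retention,
              100 * sum(x$explained_fraction[seq_len(x$n_retained)])))
  invisible(x)
}

#' Project a model onto the atlas modes (z-scores)
#'
#' The subject's ED block is first rigidly aligned to the atlas mean
#' ED shape (the population frame) and the same transform applied to
#' its ES block; the centred shape vector is then projected on each
#' retained mode and normalised by the mode standard deviation:
#' \code{z_k = <shape - mean, mode_k> / sqrt(eigenvalue_k)}.
#'
#' @param atlas shape_atlas.
#' @param model biventricular_model on the atlas topology.
#' @param align rigidly align to the atlas frame first (default TRUE;
#'   set FALSE for shapes already expressed in the atlas frame).
#' @param n_modes how many modes (default all retained).
#' @return named numeric vector of z-scores.
#' @export
project_model <- function(atlas, model, align = TRUE,
                          n_modes = atlas$n_retained) {
  n <- length(atlas$mean_shape) / 6L
  if (nrow(model$ed$vertices) != n)
    stop("model topology does not match atlas")
  if (align) {
    mean_ed <- matrix(atlas$mean_shape[seq_len(3L * n)], n, 3L,
                      byrow = TRUE)
    k <- kabsch(model$ed$vertices, mean_ed)
    model <- transform_model(model, k$rotation, k$translation)
  }
  dif <- shape_vector(model) - atlas$mean_shape
  n_modes <- min(n_modes, sum(atlas$eigenvalues > 0))
  z <- drop(crossprod(atlas$modes[, seq_len(n_modes), drop = FALSE],
                      dif)) / sqrt(atlas$eigenvalues[seq_len(n_modes)])
  stats::setNames(z, paste0("z", seq_len(n_modes)))
}

#' Score a whole cohort of aligned models
#' @param atlas shape_atlas.
#' @param aligned list of aligned models.
#' @param align see \code{project_model}.
#' @return data.frame subject_id + z-scores.
#' @export
cohort_scores <- function(atlas, aligned, align = TRUE) {
  z <- t(vapply(aligned, function(m) project_model(atlas, m, align),
                numeric(atlas$n_retained)))
  data.frame(subject_id = vapply(aligned, `[[`, "", "subject_id"), z,
             stringsAsFactors = FALSE)
}

#' Synthesize a shape along a direction in z-space
#'
#' Reconstructs \code{mean + magnitude_sd * sum_k dir_k sqrt(eig_k)
#' mode_k} and splits it into ED/ES meshes on the template topology,
#' the construction behind "mean +/- 2 SD" mode visualisations.
#'
#' @param atlas shape_atlas.
#' @param direction either a mode index (scalar integer) or a numeric
#'   vector of length \code{n_retained} in z-space (normalised to
#'   unit length internally).
#' @param magnitude_sd offset in mode standard deviations.
#' @return biventricular_model.
#' @export
synthesize_shape <- function(atlas, direction, magnitude_sd = 2) {
  r <- atlas$n_retained
  if (length(direction) == 1L && direction == round(direction)) {
    dir <- rep(0, r)
    dir[as.integer(direction)] <- 1
  } else {
    dir <- as.numeric(direction)
    if (length(dir) != r) stop("direction must have length n_retained")
  }
  if (!all(is.finite(dir)) || sum(dir^2) == 0)
    stop("non-finite or zero direction")
  dir <- dir / sqrt(sum(dir^2))
  delta <- atlas$modes[, seq_len(r), drop = FALSE] %*%
    (magnitude_sd * dir * sqrt(atlas$eigenvalues[seq_len(r)]))
  shape_to_model(atlas$mean_shape + drop(delta), atlas$faces,
                 atlas$labels, atlas$landmark_idx,
                 subject_id = sprintf("synthesis_%+.1fsd", magnitude_sd))
}
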