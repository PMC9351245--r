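#' Anatomical region labels and integer codes used in mesh files
#'
#' Surfaces are labelled per vertex with one of four anatomical tags.
#' On disk (PLY/VTK) the tag is stored as an integer vertex attribute
#' named \code{"region"} with this mapping.
#'
#' @format Named integer vector.
#' @export
REGION_CODES <- c(lv_endo = 1L, lv_epi = 2L, rv_free_wall = 3L, rv_septum = 4L)

#' Labels whose union forms the closed RV endocardial surface
#' @export
RV_LABELS <- c("rv_free_wall", "rv_septum")

#' Construct a labelled triangular surface mesh
#'
#' A \code{surface_mesh} stores vertex coordinates in millimetres, a
#' triangle list with consistent outward orientation, and a per-vertex
#' anatomical label. Each chamber (LV endocardium, LV epicardium, RV
#' endocardium = free wall + septum) must form a closed, watertight
#' component: every edge shared by exactly two faces and total signed
#' volume positive.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices,
#'   consistently wound so that face normals point out of the cavity.
#' @param labels character vector of length n with values from
#'   \code{names(REGION_CODES)}.
#' @param validate check invariants (watertightness, orientation,
#'   degenerate faces). Set \code{FALSE} only for meshes known valid.
#' @return object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, labels, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(vertices))
    stop("labels must have one entry per vertex")
  bad <- setdiff(unique(labels), names(REGION_CODES))
  if (length(bad))
    stop("unknown vertex labels: ", paste(bad, collapse = ", "))
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         labels = labels),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

# Faces belonging to a label subset: all three vertices carry a label
# from the subset. Chambers are built so that no face straddles
# chamber boundaries (the RV septum/free-wall boundary stays inside
# the RV subset).
chamber_faces <- function(mesh, label_subset) {
  keep <- mesh$labels %in% label_subset
  idx <- matrix(keep[mesh$faces], ncol = 3L)
  mesh$faces[rowSums(idx) == 3L, , drop = FALSE]
}

# Edge multiplicity table for a face set. Returns data.frame of
# undirected edges with counts.
edge_counts <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  key <- (lo - 1) * 2^31 + hi  # exact for < 2^21 vertices
  tab <- table(key)
  list(key = as.numeric(names(tab)), count = as.integer(tab),
       lo = (as.numeric(names(tab)) - as.numeric(names(tab)) %% 2^31) / 2^31 + 1,
       hi = as.numeric(names(tab)) %% 2^31)
}

#' Check that a face set forms a closed surface
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param faces m x 3 integer matrix.
#' @return invisibly TRUE; otherwise an error naming offending edges.
#' @export
check_closed <- function(faces) {
  ec <- edge_counts(faces)
  bad <- ec$count != 2L
  if (any(bad)) {
    show <- utils::head(sprintf("(%d,%d)x%d", ec$lo[bad], ec$hi[bad],
                                ec$count[bad]), 5L)
    stop("surface not watertight; offending edges: ",
         paste(show, collapse = " "),
         if (sum(bad) > 5L) sprintf(" ... and %d more", sum(bad) - 5L))
  }
  invisible(TRUE)
}

# Doubled triangle areas (norm of cross product per face).
face_areas2 <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(cx^2 + cy^2 + cz^2)
}

# Signed volume (mm^3) of a face set via the divergence theorem:
# V = (1/6) * sum_f v1 . (v2 x v3), exact for closed polyhedra and
# independent of the origin when the surface is closed.
signed_volume_mm3 <- function(vertices, faces, origin = c(0, 0, 0)) {
  a <- sweep(vertices[faces[, 1L], , drop = FALSE], 2L, origin)
  b <- sweep(vertices[faces[, 2L], , drop = FALSE], 2L, origin)
  c_ <- sweep(vertices[faces[, 3L], , drop = FALSE], 2L, origin)
  det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
    a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
    a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det3) / 6
}

#' Validate surface-mesh invariants
#'
#' Checks per-chamber watertightness, absence of degenerate
#' (zero-area) triangles, and outward orientation (positive signed
#' volume) for each closed chamber present in the labels.
#'
#' @param mesh surface_mesh.
#' @param area_tol minimum doubled triangle area (mm^2).
#' @return invisibly TRUE or an error.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-9) {
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  a2 <- face_areas2(mesh$vertices, mesh$faces)
  if (any(a2 <= area_tol))
    stop(sum(a2 <= area_tol), " degenerate (zero-area) triangles")
  for (ch in chamber_label_sets(mesh)) {
    f <- chamber_faces(mesh, ch)
    if (!nrow(f)) next
    check_closed(f)
    v <- signed_volume_mm3(mesh$vertices, f)
    if (v <= 0)
      stop("chamber {", paste(ch, collapse = ","),
           "} has non-positive signed volume (inward orientation?)")
  }
  invisible(TRUE)
}

# Chambers present in a mesh, as label subsets.
chamber_label_sets <- function(mesh) {
  out <- list()
  if ("lv_endo" %in% mesh$labels) out <- c(out, list("lv_endo"))
  if ("lv_epi" %in% mesh$labels) out <- c(out, list("lv_epi"))
  if (any(RV_LABELS %in% mesh$labels)) out <- c(out, list(RV_LABELS))
  out
}

#' Cavity volume of one chamber in millilitres
#'
#' Integrates the signed tetrahedra of the chamber's closed surface
#' about the origin (divergence theorem), which is exact for
#' polyhedra, then converts mm^3 to ml.
#'
#' @param mesh surface_mesh.
#' @param chamber one of \code{"lv_endo"}, \code{"lv_epi"},
#'   \code{"rv"}, or an explicit character vector of vertex labels.
#' @return volume in ml (positive for outward-oriented surfaces).
#' @export
chamber_volume <- function(mesh, chamber = c("lv_endo", "lv_epi", "rv")) {
  if (length(chamber) == 1L && chamber %in% c("lv_endo", "lv_epi", "rv")) {
    labels <- if (chamber == "rv") RV_LABELS else chamber
  } else labels <- chamber
  f <- chamber_faces(mesh, labels)
  if (!nrow(f)) stop("no faces with labels ", paste(labels, collapse = ","))
  check_closed(f)
  signed_volume_mm3(mesh$vertices, f) / 1000
}

#' Apply a rigid transform to points
#'
#' @param x n x 3 matrix.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 vector (mm).
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(x %*% t(rotation), 2L, translation, "+")
}

#' Rotation matrix from Euler angles (radians, XYZ intrinsic)
#' @param ax,ay,az rotations about x, y, z in radians.
#' @export
rotation_matrix <- function(ax = 0, ay = 0, az = 0) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rigidly transform a whole model (both phases and landmarks)
#' @param model biventricular_model.
#' @param rotation,translation rigid transform parameters.
#' @return transformed model.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  tf_lm <- function(lm) {
    lm[] <- lapply(lm, function(p)
      drop(apply_rigid(matrix(p, 1L), rotation, translation)))
    lm
  }
  model$ed$vertices <- apply_rigid(model$ed$vertices, rotation, translation)
  model$es$vertices <- apply_rigid(model$es$vertices, rotation, translation)
  model$landmarks_ed <- tf_lm(model$landmarks_ed)
  model$landmarks_es <- tf_lm(model$landmarks_es)
  model
}
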