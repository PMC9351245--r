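# Parametric biventricular template: LV endocardium and epicardium as
# truncated prolate spheroids capped at the base, RV as a crescent
# lofted along the long axis (flattened on the septal side), closed at
# the apex by a pole and at the base by a ring-and-centre cap. All
# dimensions in mm; the long axis is z (apex down, base up) and the
# septal plane is near x = 0 with the RV on the +x side.

# default template dimensions, sized so that cavity volumes land near
# typical values for adolescents late after tetralogy-of-Fallot repair
# (LVEDV ~ 140 ml, RVEDV ~ 210 ml, LV mass ~ 108 g at BSA 1.59 m^2)
TEMPLATE_DEFAULTS <- list(
  lv_cx = -38,            # LV axis x-position (mm)
  lv_endo_a = 26.7,       # LV endo radial semi-axis
  lv_endo_c = 50,         # LV endo long semi-axis
  lv_epi_a = 33.7,
  lv_epi_c = 57,
  lv_center_z = 50,       # spheroid centre height; endo apex at z = 0
  lv_cap_z = 85,          # basal truncation plane
  rv_apex_z = 4, rv_base_z = 92,
  rv_r = 62,              # free-wall extent from the septal plane
  rv_w = 35.5,            # half anterior-posterior width
  rv_septal_bulge = 0.02  # septal flattening factor
)

# Closed lofted surface: apex pole, rings (apex to base), base cap.
# rings: list of n_seg x 3 matrices. The base cap gets an interior
# ring at scale 0.5 plus a centre vertex so that landmarks can sit
# inside the cap. Returns vertices/faces with outward orientation.
loft_closed_surface <- function(apex, rings, cap_inner = TRUE) {
  s <- nrow(rings[[1L]])
  k <- length(rings)
  verts <- rbind(matrix(apex, 1L), do.call(rbind, rings))
  ring_idx <- function(i) 1L + (i - 1L) * s + seq_len(s)
  nxt <- c(seq_len(s)[-1L], 1L)
  faces <- list()
  r1 <- ring_idx(1L)
  faces[[1L]] <- cbind(1L, r1[nxt], r1)               # apex fan
  for (i in seq_len(k - 1L)) {
    a <- ring_idx(i); b <- ring_idx(i + 1L)
    faces[[length(faces) + 1L]] <- cbind(a, a[nxt], b)
    faces[[length(faces) + 1L]] <- cbind(a[nxt], b[nxt], b)
  }
  rim <- ring_idx(k)
  centre <- colMeans(rings[[k]])
  if (cap_inner) {
    inner_pts <- sweep(sweep(rings[[k]], 2L, centre) * 0.5, 2L, centre, "+")
    inner <- nrow(verts) + seq_len(s)
    verts <- rbind(verts, inner_pts)
    cidx <- nrow(verts) + 1L
    verts <- rbind(verts, matrix(centre, 1L))
    faces[[length(faces) + 1L]] <- cbind(rim, rim[nxt], inner)
    faces[[length(faces) + 1L]] <- cbind(rim[nxt], inner[nxt], inner)
    faces[[length(faces) + 1L]] <- cbind(cidx, inner, inner[nxt])
  } else {
    cidx <- nrow(verts) + 1L
    verts <- rbind(verts, matrix(centre, 1L))
    faces[[length(faces) + 1L]] <- cbind(cidx, rim, rim[nxt])
  }
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"
  if (signed_volume_mm3(verts, faces) < 0) faces <- faces[, c(1L, 3L, 2L)]
  list(vertices = verts, faces = faces, apex_idx = 1L, cap_centre_idx = cidx,
       rim_idx = rim)
}

# Truncated prolate spheroid (closed): apex pole at w = -1, rings up
# to the truncation height, flat fan cap.
spheroid_surface <- function(a, c_, center, cap_z, n_rings, n_seg) {
  w_cap <- (cap_z - center[3L]) / c_
  psi <- seq(pi, acos(w_cap), length.out = n_rings + 1L)[-1L]
  th <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  rings <- lapply(psi, function(p) {
    r <- a * sin(p)
    cbind(center[1L] + r * cos(th), center[2L] + r * sin(th),
          center[3L] + c_ * cos(p))
  })
  apex <- center + c(0, 0, -c_)
  loft_closed_surface(apex, rings, cap_inner = FALSE)
}

# RV crescent section in the xy-plane: elliptic free wall on +x,
# flattened (bulge factor f) septal side on -x.
crescent_section <- function(R, W, f, th) {
  x <- ifelse(cos(th) >= 0, R * cos(th), f * R * cos(th))
  cbind(x, W * sin(th))
}

#' Build the biventricular surface template
#'
#' Constructs the parametric two-chamber template used by the
#' synthetic-cohort generator: LV endocardial and epicardial truncated
#' prolate spheroids and a lofted RV crescent, all closed and
#' consistently oriented, with designated landmark vertices (valve
#' centroids and apices).
#'
#' @param n_rings axial resolution per surface.
#' @param n_seg circumferential resolution.
#' @param dims named list overriding entries of the default template
#'   dimensions (see source).
#' @return list with elements \code{mesh} (surface_mesh),
#'   \code{landmark_idx} (named vertex indices), and \code{meta}
#'   (axis/frame bookkeeping used by the generator).
#' @export
build_template <- function(n_rings = 14L, n_seg = 28L, dims = list()) {
  d <- utils::modifyList(TEMPLATE_DEFAULTS, dims)
  lvc <- c(d$lv_cx, 0, d$lv_center_z)
  endo <- spheroid_surface(d$lv_endo_a, d$lv_endo_c, lvc, d$lv_cap_z,
                           n_rings, n_seg)
  epi <- spheroid_surface(d$lv_epi_a, d$lv_epi_c, lvc, d$lv_cap_z,
                          n_rings, n_seg)

  th <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  psi <- seq(0, pi / 2, length.out = n_rings + 1L)[-1L]
  L <- d$rv_base_z - d$rv_apex_z
  rings <- lapply(psi, function(p) {
    sec <- crescent_section(d$rv_r * sin(p), d$rv_w * sin(p),
                            d$rv_septal_bulge, th)
    cbind(sec[, 1L], sec[, 2L], d$rv_base_z - L * cos(p))
  })
  rv <- loft_closed_surface(c(0, 0, d$rv_apex_z), rings, cap_inner = TRUE)

  # assemble: endo, epi, rv with index offsets
  n1 <- nrow(endo$vertices); n2 <- nrow(epi$vertices)
  verts <- rbind(endo$vertices, epi$vertices, rv$vertices)
  faces <- rbind(endo$faces, epi$faces + n1, rv$faces + n1 + n2)
  # septal tag from the construction angles: lofted ring vertices on
  # the flattened side (cos theta < -0.25); apex and cap stay free wall
  septal <- rep(FALSE, nrow(rv$vertices))
  ring_block <- 1L + seq_len(n_rings * n_seg)
  j <- ((ring_block - 2L) %% n_seg) + 1L
  septal[ring_block] <- cos(th)[j] < -0.25
  labels <- c(rep("lv_endo", n1), rep("lv_epi", n2),
              ifelse(septal, "rv_septum", "rv_free_wall"))

  mesh <- surface_mesh(verts, faces, labels)

  rv_off <- n1 + n2
  near <- function(target, cand_idx) {
    dif <- sweep(verts[cand_idx, , drop = FALSE], 2L, target)
    cand_idx[which.min(rowSums(dif^2))]
  }
  cap_idx <- rv_off + c(rv$rim_idx,
                        (max(rv$rim_idx) + 1L):(rv$cap_centre_idx))
  landmark_idx <- c(
    mv_centroid = n1,                       # LV endo cap centre (last vertex)
    lv_apex = 1L,                           # LV endo apex pole
    rv_apex = rv_off + 1L,
    # tricuspid inflow posterior (-y), central; pulmonary outflow
    # anterior (+y), peripheral - sized so nearest-landmark regions
    # roughly match in-vivo inlet/outlet/apical volume shares
    tv_centroid = near(c(14, -12, d$rv_base_z), cap_idx),
    pv_centroid = near(c(2, 34, d$rv_base_z), cap_idx))

  meta <- list(dims = d, n_rings = n_rings, n_seg = n_seg,
               lv_axis_apex = verts[1L, ],
               lv_axis_base = verts[n1, ],
               rv_axis_apex = verts[rv_off + 1L, ],
               rv_axis_base = verts[rv$cap_centre_idx + rv_off, ])
  list(mesh = mesh, landmark_idx = landmark_idx, meta = meta)
}

#' Triangulated ellipsoid mesh (closed, outward-oriented)
#'
#' Latitude-longitude triangulation of an axis-aligned ellipsoid,
#' mainly used as an analytic oracle for the volume integrator and the
#' calliper slices.
#'
#' @param a,b,c semi-axes along x, y, z (mm).
#' @param center length-3 centre.
#' @param n_lat,n_lon grid resolution (faces ~ 2 * n_lat * n_lon).
#' @param label vertex label applied to the whole surface.
#' @return surface_mesh.
#' @export
make_ellipsoid_mesh <- function(a, b, c_, center = c(0, 0, 0),
                                n_lat = 40L, n_lon = 60L,
                                label = "lv_endo") {
  psi <- seq(pi, 0, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  th <- 2 * pi * (seq_len(n_lon) - 1L) / n_lon
  rings <- lapply(psi, function(p)
    cbind(center[1L] + a * sin(p) * cos(th),
          center[2L] + b * sin(p) * sin(th),
          center[3L] + c_ * cos(p)))
  s <- n_lon
  verts <- rbind(matrix(center + c(0, 0, -c_), 1L), do.call(rbind, rings),
                 matrix(center + c(0, 0, c_), 1L))
  k <- length(rings)
  ring_idx <- function(i) 1L + (i - 1L) * s + seq_len(s)
  nxt <- c(seq_len(s)[-1L], 1L)
  faces <- list(cbind(1L, ring_idx(1L)[nxt], ring_idx(1L)))
  for (i in seq_len(k - 1L)) {
    a_ <- ring_idx(i); b_ <- ring_idx(i + 1L)
    faces[[length(faces) + 1L]] <- cbind(a_, a_[nxt], b_)
    faces[[length(faces) + 1L]] <- cbind(a_[nxt], b_[nxt], b_)
  }
  top <- nrow(verts)
  rim <- ring_idx(k)
  faces[[length(faces) + 1L]] <- cbind(top, rim, rim[nxt])
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"
  if (signed_volume_mm3(verts, faces) < 0) faces <- faces[, c(1L, 3L, 2L)]
  surface_mesh(verts, faces, rep(label, nrow(verts)), validate = FALSE)
}
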