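# Shared fixtures, built in code and memoised for the test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

template_fixture <- function() fixture("template", build_template)

# default-condition cohort (192 subjects, expected 16 events)
default_cohort <- function() {
  fixture("default_cohort", function() generate_cohort(cohort_spec()))
}

# axis-aligned closed box mesh; vertices on the x0 facet are tagged
# rv_septum, on the x1 facet rv_free_wall
make_box_mesh <- function(x0, x1, y0, y1, z0, z1) {
  v <- as.matrix(expand.grid(x = c(x0, x1), y = c(y0, y1),
                             z = c(z0, z1)))
  colnames(v) <- NULL
  f <- matrix(c(1, 3, 2, 2, 3, 4, 5, 6, 7, 6, 8, 7,
                1, 2, 5, 2, 6, 5, 3, 7, 4, 4, 7, 8,
                1, 5, 3, 3, 5, 7, 2, 4, 6, 4, 8, 6),
              ncol = 3L, byrow = TRUE)
  storage.mode(f) <- "integer"
  if (bivatlas:::signed_volume_mm3(v, f) < 0) f <- f[, c(1L, 3L, 2L)]
  list(vertices = v, faces = f,
       labels = ifelse(v[, 1L] == x0, "rv_septum", "rv_free_wall"))
}

# Oracle model: axis-aligned ellipsoid LV (septal-lateral semi-axis
# along x, anterior-posterior along y, long axis z, apex at -c) plus
# a closed box standing in for the RV so the anatomical frame (septal
# plane in x = const) is defined. Landmarks put the mitral centroid
# at the +z pole and the LV apex at the -z pole.
oracle_ellipsoid_model <- function(a_sl = 15, b_ap = 20, c_long = 45,
                                   n_lat = 120L, n_lon = 160L) {
  el <- make_ellipsoid_mesh(a_sl, b_ap, c_long, n_lat = n_lat,
                            n_lon = n_lon)
  bx <- make_box_mesh(a_sl + 10, a_sl + 20, -10, 10,
                      c_long - 5, c_long + 15)
  verts <- rbind(el$vertices, bx$vertices)
  faces <- rbind(el$faces, bx$faces + nrow(el$vertices))
  mesh <- surface_mesh(verts, faces, c(el$labels, bx$labels),
                       validate = FALSE)
  lm <- landmark_set(mv_centroid = c(0, 0, c_long),
                     tv_centroid = c(a_sl + 15, 0, c_long + 15),
                     pv_centroid = c(a_sl + 15, 5, c_long + 15),
                     rv_apex = c(a_sl + 15, 0, c_long - 5),
                     lv_apex = c(0, 0, -c_long))
  biventricular_model("oracle", mesh, mesh, lm, lm)
}

# regular icosahedron with unit circumradius (closed-form volume
# oracle (5/12) (3 + sqrt 5) a^3 with a the edge length)
icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)  # unit circumradius
  f <- matrix(c(1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
                2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
                4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
                5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2),
              ncol = 3L, byrow = TRUE)
  storage.mode(f) <- "integer"
  if (bivatlas:::signed_volume_mm3(v, f) < 0) f <- f[, c(1L, 3L, 2L)]
  surface_mesh(v, f, rep("lv_endo", 12L), validate = FALSE)
}

# random proper rotation (uniform-ish via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# rotate a flattened displacement field into another frame
rotate_field <- function(f, rot) {
  n <- length(f) / 3L
  as.vector(t(matrix(f, n, 3L, byrow = TRUE) %*% t(rot)))
}

# angle (radians) between two rotation matrices
rotation_angle <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1))
}
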