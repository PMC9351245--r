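test_that("signed-volume integrator matches analytic volumes and
          converges under refinement", {
  # icosahedron, unit circumradius: closed-form volume
  ico <- icosahedron_mesh()
  a_edge <- sqrt(sum((ico$vertices[1L, ] - ico$vertices[12L, ])^2))
  v_exact <- 5 / 12 * (3 + sqrt(5)) * a_edge^3
  expect_equal(chamber_volume(ico, "lv_endo") * 1000, v_exact,
               tolerance = 1e-10)
  expect_equal(v_exact, 2.53615, tolerance = 1e-5)

  # sphere r = 10 mm at >= 20k faces: within 0.5% of 4/3 pi r^3
  sph <- make_ellipsoid_mesh(10, 10, 10, n_lat = 100L, n_lon = 110L)
  expect_gte(nrow(sph$faces), 20000L)
  v_true <- 4 / 3 * pi * 1000
  err1 <- abs(chamber_volume(sph, "lv_endo") * 1000 - v_true) / v_true
  expect_lt(err1, 0.005)

  # one refinement step at least halves the relative error
  sph2 <- make_ellipsoid_mesh(10, 10, 10, n_lat = 200L, n_lon = 220L)
  err2 <- abs(chamber_volume(sph2, "lv_endo") * 1000 - v_true) / v_true
  expect_lt(err2, err1 / 2)
})

test_that("volume is rigid-invariant and scales as s^3", {
  mesh <- template_fixture()$mesh
  v0 <- chamber_volume(mesh, "rv")
  set.seed(11)
  for (rep in 1:3) {
    rot <- random_rotation()
    tr <- stats::rnorm(3, 0, 50)
    moved <- surface_mesh(apply_rigid(mesh$vertices, rot, tr),
                          mesh$faces, mesh$labels, validate = FALSE)
    expect_equal(chamber_volume(moved, "rv"), v0, tolerance = 1e-9)
  }
  s <- 1.7
  scaled <- surface_mesh(mesh$vertices * s, mesh$faces, mesh$labels,
                         validate = FALSE)
  expect_equal(chamber_volume(scaled, "rv"), v0 * s^3,
               tolerance = 1e-12)
})

test_that("mesh invariants are enforced", {
  tpl <- template_fixture()$mesh
  # drop one face -> watertightness error naming edges
  broken <- tpl
  broken$faces <- broken$faces[-1L, ]
  expect_error(chamber_volume(broken, "lv_endo"), "offending edges")
  # degenerate triangle detected
  degen <- tpl
  degen$vertices[degen$faces[1L, 2L], ] <-
    degen$vertices[degen$faces[1L, 1L], ]
  expect_error(validate_mesh(degen), "degenerate")
  # inward orientation rejected
  flipped <- surface_mesh(tpl$vertices, tpl$faces[, c(1L, 3L, 2L)],
                          tpl$labels, validate = FALSE)
  expect_error(validate_mesh(flipped), "non-positive signed volume")
  # unknown labels rejected
  expect_error(surface_mesh(tpl$vertices, tpl$faces,
                            rep("ventricle", nrow(tpl$vertices))),
               "unknown vertex labels")
})

test_that("volumetrics match the analytic ellipsoid LV oracle", {
  # endo 80 ml, epi 140 ml -> LVM 63 g at density 1.05, MVR 0.7875
  a_en <- 24; c_en <- 80000 * 3 / (4 * pi * a_en^2)
  a_ep <- 28; c_ep <- 140000 * 3 / (4 * pi * a_ep^2)
  endo <- make_ellipsoid_mesh(a_en, a_en, c_en, n_lat = 100L,
                              n_lon = 120L, label = "lv_endo")
  epi <- make_ellipsoid_mesh(a_ep, a_ep, c_ep, n_lat = 100L,
                             n_lon = 120L, label = "lv_epi")
  bx <- make_box_mesh(40, 60, -10, 10, -10, 10)
  verts <- rbind(endo$vertices, epi$vertices, bx$vertices)
  faces <- rbind(endo$faces, epi$faces + nrow(endo$vertices),
                 bx$faces + nrow(endo$vertices) + nrow(epi$vertices))
  labels <- c(endo$labels, epi$labels, bx$labels)
  ed <- surface_mesh(verts, faces, labels, validate = FALSE)
  es <- surface_mesh(sweep(sweep(verts, 2L, colMeans(verts)) * 0.9,
                           2L, colMeans(verts), "+"),
                     faces, labels, validate = FALSE)
  lm <- landmark_set(c(0, 0, c_en), c(50, 0, 10), c(50, 5, 10),
                     c(50, 0, -10), c(0, 0, -c_en))
  mdl <- biventricular_model("ellipsoid", ed, es, lm, lm)
  vol <- compute_volumetrics(mdl, bsa = 2.0)
  expect_equal(vol$lvedv, 80, tolerance = 0.01)
  expect_equal(vol$lvm, 63, tolerance = 0.01)
  expect_equal(vol$lv_ed_mvr, 0.7875, tolerance = 0.01)
  # indexing and identities
  expect_equal(vol$lvedv_i, vol$lvedv / 2.0)
  expect_equal(vol$lv_sv, vol$lvedv - vol$lvesv)
  expect_equal(vol$lvef, vol$lv_sv / vol$lvedv)
  expect_equal(vol$rv_sv, vol$rvedv - vol$rvesv)
  # ES volume of the 0.9-scaled mesh is 0.9^3 of ED
  expect_equal(vol$lvesv, 80 * 0.9^3, tolerance = 0.01)

  # inverted surfaces rejected: swap endo/epi labels
  swapped <- labels
  swapped[labels == "lv_endo"] <- "lv_epi"
  swapped[labels == "lv_epi"] <- "lv_endo"
  ed2 <- surface_mesh(verts, faces, swapped, validate = FALSE)
  mdl2 <- biventricular_model("inv", ed2, ed2, lm, lm)
  expect_error(compute_volumetrics(mdl2), "inverted")
})

test_that("EDV 100 / ESV 60 gives SV 40 and EF 0.40", {
  # pure-definition check on spheres scaled to the target volumes
  r_ed <- (3 * 100000 / (4 * pi))^(1 / 3)
  r_es <- (3 * 60000 / (4 * pi))^(1 / 3)
  mk <- function(r, lab) make_ellipsoid_mesh(r, r, r, n_lat = 80L,
                                             n_lon = 100L, label = lab)
  build <- function(r) {
    en <- mk(r, "lv_endo"); ep <- mk(r * 1.3, "lv_epi")
    bx <- make_box_mesh(80, 100, -10, 10, -10, 10)
    surface_mesh(rbind(en$vertices, ep$vertices, bx$vertices),
                 rbind(en$faces, ep$faces + nrow(en$vertices),
                       bx$faces + nrow(en$vertices) + nrow(ep$vertices)),
                 c(en$labels, ep$labels, bx$labels), validate = FALSE)
  }
  lm <- landmark_set(c(0, 0, 60), c(90, 0, 10), c(90, 5, 10),
                     c(90, 0, -10), c(0, 0, -60))
  mdl <- biventricular_model("efdef", build(r_ed), build(r_es), lm, lm)
  vol <- compute_volumetrics(mdl)
  expect_equal(vol$lv_sv, 40, tolerance = 0.01)
  expect_equal(vol$lvef, 0.40, tolerance = 0.001)
})

test_that("Mosteller BSA fallback", {
  expect_equal(bsa_mosteller(180, 80), sqrt(180 * 80 / 3600))
})

test_that("PLY and VTK writers round-trip vertices, faces and labels", {
  mesh <- template_fixture()$mesh
  for (fmt in c("ply", "vtk")) {
    path <- tempfile(fileext = paste0(".", fmt))
    if (fmt == "ply") write_ply(mesh, path) else write_vtk(mesh, path)
    back <- if (fmt == "ply") read_ply(path) else read_vtk(path)
    expect_identical(back$faces, mesh$faces)
    expect_identical(back$labels, mesh$labels)
    expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
    unlink(path)
  }
})

test_that("read_model validates correspondence and label channels", {
  tpl <- template_fixture()
  dir <- tempfile(); dir.create(dir)
  ed_p <- file.path(dir, "ed.ply")
  es_p <- file.path(dir, "es.ply")
  lm_p <- file.path(dir, "lm.json")
  write_ply(tpl$mesh, ed_p)
  write_ply(tpl$mesh, es_p)
  lm <- do.call(landmark_set, lapply(bivatlas:::LANDMARK_NAMES,
                                     function(nm)
                                       tpl$mesh$vertices[tpl$landmark_idx[nm], ]))
  write_landmarks(lm, lm_p)
  mdl <- read_model(c(ed = ed_p, es = es_p), lm_p, "rt")
  expect_s3_class(mdl, "biventricular_model")
  expect_identical(mdl$ed$faces, tpl$mesh$faces)

  # ES with different vertex count -> correspondence error
  small <- build_template(n_rings = 10L, n_seg = 20L)$mesh
  es_bad <- file.path(dir, "es_bad.ply")
  write_ply(small, es_bad)
  expect_error(read_model(c(ed = ed_p, es = es_bad), lm_p, "rt"),
               "vertex counts differ")

  # landmark file lacking pv_centroid -> validation error
  bad_lm <- file.path(dir, "bad_lm.json")
  writeLines('{"mv_centroid":[0,0,0],"tv_centroid":[1,0,0],
    "rv_apex":[0,1,0],"lv_apex":[0,0,1]}', bad_lm)
  expect_error(read_landmarks(bad_lm), "pv_centroid")

  # PLY without a region channel -> reject
  noreg <- file.path(dir, "noregion.ply")
  lines <- readLines(ed_p)
  lines <- lines[!grepl("property int region", lines)]
  writeLines(lines, noreg)
  expect_error(read_ply(noreg), "region")
  unlink(dir, recursive = TRUE)
})

test_that("landmark_set enforces presence and distinctness", {
  expect_error(landmark_set(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                            c(1, 1, 1), c(5, 5, 5)),
               "coincides")
  expect_error(landmark_set(c(0, 0, NA), c(1, 1, 1), c(2, 2, 2),
                            c(3, 3, 3), c(5, 5, 5)),
               "finite")
})

test_that("cohort table round-trips and validates", {
  rec <- data.frame(subject_id = c("a", "b"), bsa = c(1.5, 2.0),
                    qrs_ms = c(140, NA), sbp_mmHg = c(120, 110),
                    dbp_mmHg = c(70, 65), adverse_outcome = c(0L, 1L),
                    prvi = c(NA, 30))
  path <- tempfile(fileext = ".csv")
  write_cohort(rec, path)
  back <- read_cohort(path)
  expect_equal(back$bsa, rec$bsa)
  expect_true(is.na(back$qrs_ms[2L]))
  expect_true(is.na(back$prvi[1L]))

  bad <- rec; bad$bsa[1L] <- -1
  write_cohort(bad, path)
  expect_error(read_cohort(path), "bsa")
  utils::write.csv(data.frame(subject_id = "a", bsa = 1), path,
                   row.names = FALSE)
  expect_error(read_cohort(path), "header")
  unlink(path)
})
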