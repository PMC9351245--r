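#' Construct a landmark set
#'
#' Five anatomical key points in mm: mitral, tricuspid and pulmonary
#' valve centroids and the two apices. Heights used downstream require
#' \code{rv_apex} to differ from both the tricuspid and pulmonary
#' centroids.
#'
#' @param mv_centroid,tv_centroid,pv_centroid,rv_apex,lv_apex
#'   length-3 numeric vectors (mm).
#' @return object of class \code{landmark_set}.
#' @export
landmark_set <- function(mv_centroid, tv_centroid, pv_centroid,
                         rv_apex, lv_apex) {
  lm <- list(mv_centroid = as.numeric(mv_centroid),
             tv_centroid = as.numeric(tv_centroid),
             pv_centroid = as.numeric(pv_centroid),
             rv_apex = as.numeric(rv_apex),
             lv_apex = as.numeric(lv_apex))
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || !all(is.finite(lm[[nm]])))
      stop("landmark ", nm, " must be a finite 3-vector")
  }
  if (sqrt(sum((lm$rv_apex - lm$tv_centroid)^2)) < 1e-9 ||
      sqrt(sum((lm$rv_apex - lm$pv_centroid)^2)) < 1e-9)
    stop("rv_apex coincides with a valve centroid (zero RV height)")
  structure(lm, class = "landmark_set")
}

LANDMARK_NAMES <- c("mv_centroid", "tv_centroid", "pv_centroid",
                    "rv_apex", "lv_apex")

#' Bundle corresponded ED and ES meshes with landmarks for one subject
#'
#' Both phases must share the same topology (identical face lists,
#' vertex counts and labels), giving vertex-level point correspondence
#' between end-diastole and end-systole.
#'
#' @param subject_id character scalar.
#' @param ed,es surface_mesh at end-diastole / end-systole.
#' @param landmarks_ed,landmarks_es landmark_set per phase.
#' @param landmark_idx optional named integer vector mapping landmark
#'   names to mesh vertex indices (set by the synthetic generator and
#'   propagated by the atlas so synthesized shapes carry landmarks).
#' @return object of class \code{biventricular_model}.
#' @export
biventricular_model <- function(subject_id, ed, es, landmarks_ed,
                                landmarks_es, landmark_idx = NULL) {
  stopifnot(inherits(ed, "surface_mesh"), inherits(es, "surface_mesh"),
            inherits(landmarks_ed, "landmark_set"),
            inherits(landmarks_es, "landmark_set"))
  if (nrow(ed$vertices) != nrow(es$vertices))
    stop("subject ", subject_id,
         ": ED/ES vertex counts differ (correspondence broken)")
  if (!identical(ed$faces, es$faces))
    stop("subject ", subject_id, ": ED/ES face lists differ")
  if (!identical(ed$labels, es$labels))
    stop("subject ", subject_id, ": ED/ES vertex labels differ")
  structure(list(subject_id = as.character(subject_id), ed = ed, es = es,
                 landmarks_ed = landmarks_ed, landmarks_es = landmarks_es,
                 landmark_idx = landmark_idx),
            class = "biventricular_model")
}

#' @export
print.biventricular_model <- function(x, ...) {
  cat("biventricular_model", x$subject_id, "-",
      nrow(x$ed$vertices), "corresponded vertices, 2 phases\n")
  invisible(x)
}

# ---------------------------------------------------------------- PLY

#' Write a labelled mesh as ASCII PLY
#'
#' Vertices carry \code{x y z} (float, mm) plus an integer
#' \code{region} property coded via \code{REGION_CODES}.
#'
#' @param mesh surface_mesh.
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           "comment bivatlas biventricular surface",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property int region",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices", "end_header")
  region <- REGION_CODES[mesh$labels]
  vl <- sprintf("%.6f %.6f %.6f %d", mesh$vertices[, 1L],
                mesh$vertices[, 2L], mesh$vertices[, 3L], region)
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY surface written by \code{write_ply}
#'
#' Requires the integer \code{region} vertex property; files without a
#' label channel are rejected.
#'
#' @param path PLY file.
#' @return surface_mesh.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1L], "ply")) stop(path, ": not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop(path, ": missing end_header")
  hdr <- lines[seq_len(end)]
  if (any(grepl("^format binary", hdr)))
    stop(path, ": binary PLY not supported; use ASCII")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", hdr, value = TRUE)))
  if (!length(nv) || !length(nf)) stop(path, ": malformed PLY header")
  vprops <- sub("^property \\S+ ", "",
                grep("^property (float|int|double|uchar) ", hdr,
                     value = TRUE))
  if (!"region" %in% vprops)
    stop(path, ": missing 'region' label channel")
  vcols <- match(c("x", "y", "z", "region"), vprops)
  vdat <- utils::read.table(text = lines[end + seq_len(nv)])
  verts <- as.matrix(vdat[, vcols[1:3]])
  region <- as.integer(vdat[[vcols[4L]]])
  labels <- names(REGION_CODES)[match(region, REGION_CODES)]
  if (anyNA(labels)) stop(path, ": unknown region codes")
  fdat <- utils::read.table(text = lines[end + nv + seq_len(nf)])
  if (any(fdat[[1L]] != 3L)) stop(path, ": non-triangular faces")
  faces <- as.matrix(fdat[, 2:4]) + 1L
  surface_mesh(verts, faces, labels)
}

# ---------------------------------------------------------------- VTK

#' Write a labelled mesh as legacy VTK polydata (ASCII)
#' @param mesh surface_mesh.
#' @param path output file.
#' @export
write_vtk <- function(mesh, path) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  out <- c("# vtk DataFile Version 3.0",
           "bivatlas biventricular surface", "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d float", n),
           sprintf("%.6f %.6f %.6f", mesh$vertices[, 1L],
                   mesh$vertices[, 2L], mesh$vertices[, 3L]),
           sprintf("POLYGONS %d %d", m, 4L * m),
           sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                   mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L),
           sprintf("POINT_DATA %d", n),
           "SCALARS region int 1", "LOOKUP_TABLE default",
           sprintf("%d", REGION_CODES[mesh$labels]))
  writeLines(out, path)
  invisible(path)
}

#' Read legacy VTK polydata written by \code{write_vtk}
#' @param path VTK file.
#' @return surface_mesh.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)
  if (!length(ip)) stop(path, ": no POINTS section")
  n <- as.integer(strsplit(lines[ip], " ")[[1L]][2L])
  verts <- as.matrix(utils::read.table(text = lines[ip + seq_len(n)]))
  ig <- grep("^POLYGONS ", lines)
  m <- as.integer(strsplit(lines[ig], " ")[[1L]][2L])
  fdat <- utils::read.table(text = lines[ig + seq_len(m)])
  if (any(fdat[[1L]] != 3L)) stop(path, ": non-triangular polygons")
  faces <- as.matrix(fdat[, 2:4]) + 1L
  is_ <- grep("^SCALARS region ", lines)
  if (!length(is_)) stop(path, ": missing 'region' label channel")
  region <- as.integer(unlist(strsplit(lines[is_ + 1L + seq_len(n)], " ")))
  region <- region[!is.na(region)][seq_len(n)]
  labels <- names(REGION_CODES)[match(region, REGION_CODES)]
  if (anyNA(labels)) stop(path, ": unknown region codes")
  surface_mesh(verts, faces, labels)
}

# ---------------------------------------------------------- landmarks

#' Write landmarks as key-point JSON
#'
#' Format: a JSON object \code{{"mv_centroid":[x,y,z], ...}} in mm.
#' @param landmarks landmark_set.
#' @param path output file.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a key-point JSON landmark file
#' @param path JSON file.
#' @return landmark_set; missing keys are a validation error.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(LANDMARK_NAMES, names(obj))
  if (length(missing))
    stop(path, ": landmark file lacking ", paste(missing, collapse = ", "))
  do.call(landmark_set, obj[LANDMARK_NAMES])
}

#' Read one subject's meshes and landmarks into a model
#'
#' @param mesh_paths named list/vector with entries \code{ed} and
#'   \code{es}; format picked by extension (.ply or .vtk).
#' @param landmark_path either one JSON file (used for both phases) or
#'   a named list with entries \code{ed} and \code{es}.
#' @param subject_id subject identifier for error messages.
#' @return biventricular_model.
#' @export
read_model <- function(mesh_paths, landmark_path,
                       subject_id = "subject") {
  read1 <- function(p) {
    if (grepl("\\.ply$", p, ignore.case = TRUE)) read_ply(p)
    else if (grepl("\\.vtk$", p, ignore.case = TRUE)) read_vtk(p)
    else stop("unsupported mesh format: ", p)
  }
  ed <- read1(mesh_paths[["ed"]])
  es <- read1(mesh_paths[["es"]])
  if (is.list(landmark_path) || length(landmark_path) == 2L) {
    lm_ed <- read_landmarks(landmark_path[["ed"]])
    lm_es <- read_landmarks(landmark_path[["es"]])
  } else {
    lm_ed <- lm_es <- read_landmarks(landmark_path)
  }
  biventricular_model(subject_id, ed, es, lm_ed, lm_es)
}

# ------------------------------------------------------- cohort table

COHORT_HEADER <- c("subject_id", "bsa", "qrs_ms", "sbp_mmHg",
                   "dbp_mmHg", "adverse_outcome", "prvi")

#' Read the cohort covariate table
#'
#' CSV with header exactly
#' \code{subject_id,bsa,qrs_ms,sbp_mmHg,dbp_mmHg,adverse_outcome,prvi};
#' empty cells are missing values. BSA is in m^2, PRVI in ml/m^2,
#' adverse_outcome is 0/1.
#'
#' @param path CSV file.
#' @return data.frame of subject records.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  if (!identical(names(df), COHORT_HEADER))
    stop(path, ": cohort header must be exactly ",
         paste(COHORT_HEADER, collapse = ","))
  if (any(!is.finite(df$bsa) | df$bsa <= 0))
    stop(path, ": bsa must be positive for all subjects")
  if (!all(df$adverse_outcome %in% c(0L, 1L)))
    stop(path, ": adverse_outcome must be 0/1")
  df
}

#' Write a cohort covariate table
#' @param records data.frame with the standard cohort columns.
#' @param path output CSV.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records[, COHORT_HEADER], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
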