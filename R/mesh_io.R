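# ASCII PLY IO for labeled meshes, with a JSON sidecar carrying landmarks,
# legend and identifiers. Faces carry an integer "tissue" scalar property.

#' Write a labeled mesh as ASCII PLY plus JSON sidecar
#'
#' @param mesh a `labeled_mesh`.
#' @param path output `.ply` path; the sidecar is written next to it as
#'   `<model_id>.landmarks.json`.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  validate_mesh(mesh)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "property int tissue",
              "end_header")
  vlines <- apply(format(mesh$vertices, digits = 17, scientific = FALSE,
                         trim = TRUE), 1, paste, collapse = " ")
  flines <- paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L, mesh$face_labels)
  writeLines(c(header, vlines, flines), path)
  sidecar <- file.path(dirname(path),
                       paste0(mesh$model_id, ".landmarks.json"))
  lm <- mesh_landmarks(mesh)
  jsonlite::write_json(
    list(model_id = mesh$model_id,
         landmarks = lapply(lm, unname),
         landmark_idx = as.list(mesh$landmark_idx),
         legend = as.list(mesh$legend)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a labeled mesh written by [write_mesh_ply()]
#'
#' @param path `.ply` path; the JSON sidecar is located via the header-free
#'   convention `<model_id>.landmarks.json` in the same directory, or can be
#'   given explicitly.
#' @param sidecar optional explicit sidecar path.
#' @return a `labeled_mesh`.
#' @export
read_mesh_ply <- function(path, sidecar = NULL) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  hend <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vtx <- matrix(scan(text = lines[hend + seq_len(nv)], quiet = TRUE),
                nrow = nv, byrow = TRUE)
  fm <- matrix(scan(text = lines[hend + nv + seq_len(nf)], quiet = TRUE),
               nrow = nf, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular face in ", path)
  if (is.null(sidecar)) {
    cand <- list.files(dirname(path), pattern = "\\.landmarks\\.json$",
                       full.names = TRUE)
    base <- sub("\\.ply$", "", basename(path))
    hit <- cand[basename(cand) == paste0(base, ".landmarks.json")]
    sidecar <- if (length(hit)) hit[1] else cand[1]
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mesh <- structure(list(
    vertices = vtx,
    faces = matrix(as.integer(fm[, 2:4] + 1L), ncol = 3),
    face_labels = as.integer(fm[, 5]),
    landmark_idx = unlist(meta$landmark_idx),
    legend = unlist(meta$legend),
    model_id = meta$model_id),
    class = "labeled_mesh")
  mesh$landmarks <- mesh_landmarks(mesh)
  validate_mesh(mesh)
}

#' Write a cohort of meshes to a directory
#' @param cohort list of `labeled_mesh`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_mesh_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort)
    write_mesh_ply(m, file.path(dir, paste0(m$model_id, ".ply")))
  invisible(dir)
}

#' Read all PLY meshes in a directory
#' @param dir directory of `.ply` + sidecar files.
#' @return list of `labeled_mesh`, sorted by filename.
#' @export
read_mesh_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.ply$", full.names = TRUE))
  if (!length(files)) stop("no .ply files in ", dir)
  lapply(files, read_mesh_ply)
}
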