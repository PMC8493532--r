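# Parametric heart phantoms: corresponded, tissue-labeled triangle meshes
# with analytic anatomical landmarks. Every phantom is built from the same
# template topology (identical vertex count and face arrays), so a cohort is
# corresponded by construction and can feed the PCA shape model directly.

#' Default phantom shape parameters
#'
#' All lengths in millimetres. The left ventricle (LV) is a truncated
#' half-ellipsoid blood pool capped by a flat mitral disk, wrapped in a
#' concentric myocardial shell; left atrium (LA), right ventricle (RV) and
#' right atrium (RA) are adjoining ellipsoidal pools; the aorta is a closed
#' tilted tube leaving the LV base; the mitral valve is a thin disk between
#' LV base and LA.
#'
#' @return named list of parameters.
#' @export
phantom_params <- function() {
  list(
    lv_length = 85,      # apex-to-mitral-plane long-axis length [70, 100]
    lv_radius = 26,      # LV endocardial short-axis radius [20, 32]
    wall = 10,           # myocardial wall thickness [6, 14]
    la_size = 20,        # LA semi-axis (x,y); z semi-axis = 1.1 * la_size
    rv_size = 16,        # RV semi-axis (x); y = 1.1x, z scales with lv_length
    ra_size = 14,        # RA semi-axis
    ao_radius = 9,       # aortic tube radius
    ao_length = 26,      # aortic tube length
    ao_tilt_deg = 25,    # aorta tilt from the long axis, toward the +x side
    bump_amplitude = 0.3 # smooth random surface displacement amplitude (mm)
  )
}

phantom_param_ranges <- function() {
  list(lv_length = c(70, 100), lv_radius = c(20, 32), wall = c(6, 14),
       la_size = c(12, 28), rv_size = c(10, 22), ra_size = c(8, 20),
       ao_radius = c(5, 13), ao_length = c(15, 40), ao_tilt_deg = c(0, 45),
       bump_amplitude = c(0, 2))
}

check_phantom_params <- function(params) {
  ranges <- phantom_param_ranges()
  for (nm in names(ranges)) {
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v))
      stop("phantom parameter '", nm, "' is missing or not finite")
    if (v < ranges[[nm]][1] || v > ranges[[nm]][2])
      stop("phantom parameter '", nm, "' = ", v, " outside plausible range [",
           ranges[[nm]][1], ", ", ranges[[nm]][2], "]")
  }
  invisible(params)
}

# Fixed template discretization (shared by every phantom => correspondence).
.PHANTOM_NTHETA <- 24L
.PHANTOM_NPHI <- 8L

# ---- sub-mesh topology builders --------------------------------------------
# Each returns vertices (n x 3) and 1-based faces (m x 3). Orientation is
# fixed afterwards so each closed compartment has positive signed volume.

ring_quads <- function(r1, r2, nt) {
  # two vertex-index rings of length nt -> 2*nt triangles
  j <- seq_len(nt)
  jn <- c(seq_len(nt)[-1], 1L)
  rbind(cbind(r1[j], r1[jn], r2[j]), cbind(r2[j], r1[jn], r2[jn]))
}

fan_faces <- function(center, ring, flip = FALSE) {
  j <- seq_along(ring)
  jn <- c(j[-1], 1L)
  if (flip) cbind(center, ring[jn], ring[j]) else cbind(center, ring[j], ring[jn])
}

# Capped half-ellipsoid: pole at base_center - (0,0,c), equator ring at the
# base plane, closed by a flat cap (fan around the base center vertex).
hemi_mesh <- function(a, b, c, base_center) {
  nt <- .PHANTOM_NTHETA; np <- .PHANTOM_NPHI
  th <- 2 * pi * (seq_len(nt) - 1) / nt
  phi <- (pi / 2) * seq_len(np) / np
  verts <- rbind(base_center + c(0, 0, -c))
  for (p in phi)
    verts <- rbind(verts, cbind(base_center[1] + a * sin(p) * cos(th),
                                base_center[2] + b * sin(p) * sin(th),
                                base_center[3] - c * cos(p)))
  verts <- rbind(verts, base_center)
  cap_center <- nrow(verts)
  ring <- function(i) 1L + (i - 1L) * nt + seq_len(nt)
  faces <- fan_faces(1L, ring(1), flip = TRUE)  # pole is the bottom of the shape
  for (i in seq_len(np - 1L)) faces <- rbind(faces, ring_quads(ring(i), ring(i + 1L), nt))
  faces <- rbind(faces, fan_faces(cap_center, ring(np)))  # flat cap on top
  list(verts = verts, faces = faces, pole = 1L, cap_center = cap_center)
}

# Full ellipsoid (UV sphere).
ellipsoid_mesh <- function(center, a, b, c) {
  nt <- .PHANTOM_NTHETA; np <- .PHANTOM_NPHI
  th <- 2 * pi * (seq_len(nt) - 1) / nt
  phi <- pi * seq_len(np - 1L) / np
  verts <- rbind(center + c(0, 0, c))
  for (p in phi)
    verts <- rbind(verts, cbind(center[1] + a * sin(p) * cos(th),
                                center[2] + b * sin(p) * sin(th),
                                center[3] + c * cos(p)))
  verts <- rbind(verts, center - c(0, 0, c))
  south <- nrow(verts)
  ring <- function(i) 1L + (i - 1L) * nt + seq_len(nt)
  faces <- fan_faces(1L, ring(1))
  for (i in seq_len(np - 2L)) faces <- rbind(faces, ring_quads(ring(i), ring(i + 1L), nt))
  faces <- rbind(faces, fan_faces(south, ring(np - 1L), flip = TRUE))
  list(verts = verts, faces = faces)
}

# Closed cylinder along `axis` from base_center, with cap-center vertices.
cylinder_mesh <- function(base_center, axis, radius, length) {
  nt <- .PHANTOM_NTHETA
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  th <- 2 * pi * (seq_len(nt) - 1) / nt
  circ <- outer(cos(th), e1) + outer(sin(th), e2)
  top_center <- base_center + length * axis
  verts <- rbind(base_center,
                 sweep(radius * circ, 2, base_center, `+`),
                 sweep(radius * circ, 2, top_center, `+`),
                 top_center)
  r1 <- 1L + seq_len(nt)
  r2 <- 1L + nt + seq_len(nt)
  faces <- rbind(fan_faces(1L, r1, flip = TRUE),
                 ring_quads(r1, r2, nt),
                 fan_faces(nrow(verts), r2))
  list(verts = verts, faces = faces, base_center = 1L)
}

compartment_volume <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

# Smooth pseudo-random displacement field: sum of low-frequency harmonics.
# Applied along fixed directions so the same topology deforms smoothly.
bump_field <- function(verts, amplitude, wavelength = 30) {
  if (amplitude <= 0) return(verts * 0)
  k <- 2 * pi / wavelength
  out <- matrix(0, nrow(verts), 3)
  for (d in 1:3) {
    ph <- stats::runif(3, 0, 2 * pi)
    w <- stats::rnorm(3)
    w <- w / sqrt(sum(w^2))
    out[, d] <- amplitude * sin(k * (verts %*% w) + ph[1]) *
      cos(0.7 * k * (verts %*% rev(w)) + ph[2])
  }
  out
}

#' Generate one labeled heart phantom
#'
#' Builds a corresponded, tissue-labeled triangle mesh with analytic
#' landmarks. The apex sits at the origin and the LV long axis runs along
#' +z to the mitral plane at `z = lv_length`. A seed-driven smooth surface
#' displacement (amplitude `bump_amplitude`) individualises the shape while
#' preserving template topology.
#'
#' @param seed integer RNG seed for the surface displacement field.
#' @param params parameter list as from [phantom_params()]; values outside
#'   the documented plausible ranges raise an error naming the parameter.
#' @param model_id identifier stored with the mesh.
#' @return a `labeled_mesh`: list with `vertices` (n x 3, mm), `faces`
#'   (m x 3, 1-based), `face_labels` (integer tissue codes, see
#'   [tissue_legend()]), `landmarks` (apex, mitral_valve_center,
#'   aortic_valve_center, lv_long_axis_direction), `landmark_idx`
#'   (vertex indices of the point landmarks), `legend`, `model_id`.
#' @export
#' @examples
#' m <- generate_phantom(seed = 0)
#' sort(unique(m$face_labels))
generate_phantom <- function(seed = 0L, params = phantom_params(),
                             model_id = sprintf("phantom_%03d", seed)) {
  params <- utils::modifyList(phantom_params(), params)
  check_phantom_params(params)
  set.seed(as.integer(seed))
  L <- params$lv_length; ae <- params$lv_radius; w <- params$wall
  aep <- ae + w
  lgd <- tissue_legend()

  parts <- list()
  # LV blood pool: half-ellipsoid, pole at z = w (apical wall), base at z = L
  parts$lv_pool <- hemi_mesh(ae, ae, L - w, c(0, 0, L))
  # epicardial shell boundary: pole at the apex (origin)
  parts$lv_myo <- hemi_mesh(aep, aep, L, c(0, 0, L))
  la_c <- 1.1 * params$la_size
  parts$la <- ellipsoid_mesh(c(-4, 0, L + 2 + la_c), params$la_size,
                             params$la_size, la_c)
  rv_c <- 0.42 * L
  parts$rv <- ellipsoid_mesh(c(-(0.95 * aep + params$rv_size), 0, 0.45 * L),
                             params$rv_size, 1.1 * params$rv_size, rv_c)
  parts$ra <- ellipsoid_mesh(c(-(0.95 * aep + params$ra_size), 0,
                               L + 2 + params$ra_size),
                             params$ra_size, params$ra_size, params$ra_size)
  tilt <- params$ao_tilt_deg * pi / 180
  parts$aorta <- cylinder_mesh(c(0.55 * aep, 0, L), c(sin(tilt), 0, cos(tilt)),
                               params$ao_radius, params$ao_length)
  parts$valve <- cylinder_mesh(c(0, 0, L + 0.3), c(0, 0, 1), 0.9 * ae, 1.5)

  verts <- NULL; faces <- NULL; face_labels <- integer(0)
  offsets <- integer(0)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    # outward orientation: positive signed volume per closed compartment
    if (compartment_volume(p$verts, p$faces) < 0)
      p$faces <- p$faces[, c(1, 3, 2)]
    off <- if (is.null(verts)) 0L else nrow(verts)
    offsets[nm] <- off
    verts <- rbind(verts, p$verts)
    faces <- rbind(faces, p$faces + off)
    face_labels <- c(face_labels, rep(lgd[[nm]], nrow(p$faces)))
  }
  verts <- verts + bump_field(verts, params$bump_amplitude)
  storage.mode(faces) <- "integer"

  landmark_idx <- c(
    apex = offsets[["lv_myo"]] + parts$lv_myo$pole,
    mitral_valve_center = offsets[["lv_pool"]] + parts$lv_pool$cap_center,
    aortic_valve_center = offsets[["aorta"]] + parts$aorta$base_center)
  mesh <- structure(list(
    vertices = unname(verts), faces = unname(faces),
    face_labels = unname(face_labels), landmark_idx = landmark_idx,
    legend = lgd, model_id = model_id, params = params),
    class = "labeled_mesh")
  mesh$landmarks <- mesh_landmarks(mesh)
  mesh
}

# Landmark positions and long-axis direction, derived from landmark vertices.
mesh_landmarks <- function(mesh) {
  lp <- lapply(mesh$landmark_idx, function(i) mesh$vertices[i, ])
  d <- lp$mitral_valve_center - lp$apex
  lp$lv_long_axis_direction <- d / sqrt(sum(d^2))
  lp
}

#' Generate a corresponded phantom cohort
#'
#' Draws `n` phantoms with shape parameters jittered independently and
#' uniformly within `vary` ranges (defaults: the main anatomical degrees of
#' freedom). All phantoms share the same template topology, so the cohort is
#' corresponded by construction and suitable for PCA.
#'
#' @param n cohort size (>= 2; a point-distribution model needs at least two
#'   shapes). Default 19, the size of a typical CT-derived model set.
#' @param seed master RNG seed; the cohort is bit-reproducible under it.
#' @param vary named list of `c(min, max)` ranges for the parameters to
#'   jitter; parameters not listed stay at their default.
#' @param params base parameters (see [phantom_params()]).
#' @return list of `labeled_mesh`.
#' @export
generate_phantom_cohort <- function(n = 19L, seed = 0L,
                                    vary = list(lv_length = c(75, 95),
                                                lv_radius = c(22, 30),
                                                wall = c(7, 13),
                                                la_size = c(15, 25),
                                                rv_size = c(12, 20),
                                                ra_size = c(10, 18),
                                                ao_radius = c(6, 12)),
                                    params = phantom_params()) {
  if (n < 2) stop("cohort size n must be >= 2 (PCA needs at least 2 shapes)")
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n), function(i) {
    p <- params
    for (nm in names(vary)) p[[nm]] <- stats::runif(1, vary[[nm]][1], vary[[nm]][2])
    list(p = p, s = sample.int(.Machine$integer.max - 1L, 1L))
  })
  lapply(seq_len(n), function(i)
    generate_phantom(seed = draws[[i]]$s, params = draws[[i]]$p,
                     model_id = sprintf("phantom_%03d", i)))
}

#' Signed volume of one tissue compartment
#'
#' @param mesh a `labeled_mesh`.
#' @param tissue tissue name (see [tissue_legend()]).
#' @return signed volume in mm^3 (positive for outward-oriented closed
#'   compartments). For `"lv_myo"` this is the shell boundary volume; the
#'   myocardial volume itself is `lv_myo - lv_pool - `the enclosed part of
#'   the valve plane, all positive by construction.
#' @export
mesh_compartment_volume <- function(mesh, tissue) {
  code <- mesh$legend[[tissue]]
  f <- mesh$faces[mesh$face_labels == code, , drop = FALSE]
  if (nrow(f) == 0) stop("no faces with tissue '", tissue, "'")
  compartment_volume(mesh$vertices, f)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh '", x$model_id, "': ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces, tissues {",
      paste(names(x$legend)[x$legend %in% unique(x$face_labels)],
            collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Validate structural invariants of a labeled mesh (used by IO and tests).
validate_mesh <- function(mesh) {
  stopifnot(all(mesh$faces >= 1), all(mesh$faces <= nrow(mesh$vertices)))
  if (!all(mesh$face_labels %in% mesh$legend))
    stop("face label outside legend")
  lm <- mesh_landmarks(mesh)
  stopifnot(all(is.finite(unlist(lm))))
  if (abs(sqrt(sum(lm$lv_long_axis_direction^2)) - 1) > 1e-9)
    stop("lv_long_axis_direction is not a unit vector")
  invisible(mesh)
}
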