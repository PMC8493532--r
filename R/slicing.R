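# Anatomical view planes and mesh cross-section rasterization.
#
# An apical four-chamber (A4C) plane is the plane through the apex, the
# mitral valve center and the aortic valve center; the two-chamber (A2C)
# plane is obtained by rotating it about the LV long axis. Slices are
# rasterized by a point-in-compartment test at every pixel center: for a
# point lying in the cut plane this reduces to 2D ray-crossing parity
# against the compartment's plane-intersection segments, evaluated with a
# vectorized scanline.

vnorm <- function(x) sqrt(sum(x^2))
unit <- function(x) x / vnorm(x)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Rodrigues rotation matrix about unit axis by angle (radians, right-handed).
rotation_about <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

new_slice_plane <- function(origin, u, v, view,
                            perturbation = c(rot_long = 0, rot_short = 0)) {
  normal <- cross3(u, v)
  G <- rbind(u, v, normal)
  if (max(abs(G %*% t(G) - diag(3))) > 1e-9)
    stop("plane axes are not orthonormal")
  structure(list(origin = origin, normal = normal, u = u, v = v,
                 view = view, perturbation = perturbation),
            class = "slice_plane")
}

#' Define the apical four-chamber plane of a mesh
#'
#' The A4C plane is the unique plane through the apex, the mitral valve
#' center and the aortic valve center. The in-plane `v` axis points from
#' apex to mitral valve (image "down" — the apex renders at the top of the
#' raster), `u` spans toward the aortic valve side, and
#' `normal = u x v`.
#'
#' @param mesh a `labeled_mesh` with landmarks.
#' @return a `slice_plane`.
#' @export
define_a4c_plane <- function(mesh) {
  lm <- mesh_landmarks(mesh)
  a <- lm$apex; mv <- lm$mitral_valve_center; av <- lm$aortic_valve_center
  v <- mv - a
  w <- av - a
  cr <- cross3(v, w)
  if (vnorm(cr) < 1e-8 * vnorm(v) * vnorm(w))
    stop("degenerate geometry: apex, mitral and aortic valve centers are collinear")
  v <- unit(v)
  u <- unit(w - sum(w * v) * v)
  new_slice_plane(origin = a, u = u, v = v, view = "A4C")
}

#' Define the apical two-chamber plane
#'
#' Rotates the A4C plane counter-clockwise (as seen from the apex looking
#' toward the base) about the LV long axis through the apex. The long axis
#' lies in both planes; the default rotation is 70 degrees.
#'
#' @param mesh a `labeled_mesh`.
#' @param rotation_deg rotation angle in degrees (default 70).
#' @return a `slice_plane`.
#' @export
define_a2c_plane <- function(mesh, rotation_deg = 70) {
  p <- define_a4c_plane(mesh)
  d <- mesh_landmarks(mesh)$lv_long_axis_direction
  # CCW for a viewer at the apex looking along +d is a negative right-handed
  # rotation about d.
  R <- rotation_about(d, -rotation_deg * pi / 180)
  apex <- mesh_landmarks(mesh)$apex
  new_slice_plane(origin = apex + as.vector(R %*% (p$origin - apex)),
                  u = as.vector(R %*% p$u), v = as.vector(R %*% p$v),
                  view = "A2C")
}

#' Randomly perturb a view plane (foreshortening)
#'
#' Applies random rotations about the LV long axis and about an in-plane
#' short axis, both through the LV centroid, emulating off-plane and
#' foreshortened acquisitions. Angles are drawn uniformly within
#' `+/- ranges`.
#'
#' @param plane a `slice_plane`.
#' @param mesh the `labeled_mesh` the plane belongs to (provides the long
#'   axis and LV centroid).
#' @param seed integer RNG seed.
#' @param ranges `c(long, short)` maximal absolute rotations in degrees
#'   (defaults 10 and 5).
#' @return a perturbed `slice_plane` with the drawn angles recorded in its
#'   `perturbation` field.
#' @export
perturb_plane <- function(plane, mesh, seed = 0L, ranges = c(long = 10, short = 5)) {
  if (any(ranges < 0)) stop("perturbation ranges must be non-negative")
  set.seed(as.integer(seed))
  a_long <- stats::runif(1, -ranges[1], ranges[1])
  a_short <- stats::runif(1, -ranges[2], ranges[2])
  lm <- mesh_landmarks(mesh)
  ctr <- colMeans(mesh$vertices[
    unique(as.vector(mesh$faces[mesh$face_labels == mesh$legend[["lv_myo"]], ])), ])
  R <- rotation_about(lm$lv_long_axis_direction, a_long * pi / 180)
  # short axis: the in-plane direction orthogonal to the long axis
  short_axis <- as.vector(R %*% plane$u)
  R <- rotation_about(short_axis, a_short * pi / 180) %*% R
  new_slice_plane(origin = ctr + as.vector(R %*% (plane$origin - ctr)),
                  u = as.vector(R %*% plane$u), v = as.vector(R %*% plane$v),
                  view = plane$view,
                  perturbation = c(rot_long = a_long, rot_short = a_short))
}

# Plane-intersection segments of one tissue compartment, in plane (u, v)
# coordinates (mm relative to plane origin). Returns a 4-column matrix
# (u1, v1, u2, v2), possibly empty.
compartment_plane_segments <- function(mesh, plane, code) {
  f <- mesh$faces[mesh$face_labels == code, , drop = FALSE]
  if (!nrow(f)) return(matrix(numeric(0), ncol = 4))
  sd <- matrix((mesh$vertices - matrix(plane$origin, nrow(mesh$vertices), 3,
                                       byrow = TRUE)) %*% plane$normal,
               ncol = 1)[, 1]
  sd[abs(sd) < 1e-12] <- 1e-12  # nudge on-plane vertices off the plane
  s <- matrix(sd[f], ncol = 3)
  keep <- (apply(s, 1, min) < 0) & (apply(s, 1, max) > 0)
  f <- f[keep, , drop = FALSE]
  s <- s[keep, , drop = FALSE]
  if (!nrow(f)) return(matrix(numeric(0), ncol = 4))
  e1 <- cbind(f[, 1], f[, 2], s[, 1], s[, 2])
  e2 <- cbind(f[, 2], f[, 3], s[, 2], s[, 3])
  e3 <- cbind(f[, 3], f[, 1], s[, 3], s[, 1])
  fid <- rep(seq_len(nrow(f)), 3)
  E <- rbind(e1, e2, e3)
  crossing <- E[, 3] * E[, 4] < 0
  E <- E[crossing, , drop = FALSE]
  fid <- fid[crossing]
  t <- E[, 3] / (E[, 3] - E[, 4])
  P <- mesh$vertices[E[, 1], , drop = FALSE] +
    t * (mesh$vertices[E[, 2], , drop = FALSE] -
           mesh$vertices[E[, 1], , drop = FALSE])
  rel <- P - matrix(plane$origin, nrow(P), 3, byrow = TRUE)
  pu <- rel %*% plane$u
  pv <- rel %*% plane$v
  ord <- order(fid)
  fid <- fid[ord]; pu <- pu[ord]; pv <- pv[ord]
  # generic position: exactly two crossing edges per cut triangle
  two <- fid %in% names(which(table(fid) == 2))
  fid <- fid[two]; pu <- pu[two]; pv <- pv[two]
  i1 <- seq(1, length(fid), by = 2)
  cbind(pu[i1], pv[i1], pu[i1 + 1], pv[i1 + 1])
}

# Scanline parity fill: which pixel centers lie inside the closed curve(s)
# given by segments (pixel-index coordinates). Returns an H x W logical.
scanline_fill <- function(segs, H, W) {
  inside <- matrix(FALSE, H, W)
  if (!nrow(segs)) return(inside)
  jgrid <- 0:(W - 1)
  for (i in 0:(H - 1)) {
    lo <- pmin(segs[, 2], segs[, 4])
    hi <- pmax(segs[, 2], segs[, 4])
    hit <- lo <= i & i < hi
    if (!any(hit)) next
    s <- segs[hit, , drop = FALSE]
    t <- (i - s[, 2]) / (s[, 4] - s[, 2])
    xc <- sort(s[, 1] + t * (s[, 3] - s[, 1]))
    inside[i + 1, ] <- findInterval(jgrid, xc) %% 2L == 1L
  }
  inside
}

#' Rasterize a mesh cross-section into a 2D label image
#'
#' Every pixel center is mapped into 3D via the plane frame and labeled by
#' the tissue compartment containing it; nested or touching compartments are
#' resolved by precedence (blood pools over myocardium over the valve disk),
#' so no pixel inside the LV blood pool is ever labeled myocardium. The apex
#' side of the view is at the top of the raster.
#'
#' @param mesh a `labeled_mesh`.
#' @param plane a `slice_plane`.
#' @param H,W raster dimensions in pixels (default 256 x 256).
#' @param pixel_spacing mm per pixel (default 0.6).
#' @param apex_margin_px rows above the plane origin (apex) at the top of
#'   the raster; defaults to `H / 10`.
#' @return a `label_slice`: `raster` (H x W integer tissue codes, 0 =
#'   background), `pixel_spacing`, `plane`, `model_id`, `apex_margin_px`.
#' @export
slice_mesh <- function(mesh, plane, H = 256L, W = 256L, pixel_spacing = 0.6,
                       apex_margin_px = round(H / 10)) {
  # pixel-index coords: column j at u = (j + 0.5 - W/2) * s, row i at
  # v = (i + 0.5 - margin) * s  (v axis points down-image, away from apex)
  to_px <- function(segs) {
    if (!nrow(segs)) return(segs)
    cbind(segs[, 1] / pixel_spacing + W / 2 - 0.5,
          segs[, 2] / pixel_spacing + apex_margin_px - 0.5,
          segs[, 3] / pixel_spacing + W / 2 - 0.5,
          segs[, 4] / pixel_spacing + apex_margin_px - 0.5)
  }
  lgd <- mesh$legend
  precedence <- c("valve", "lv_myo", "aorta", "ra", "rv", "la", "lv_pool")
  raster <- matrix(0L, H, W)
  any_cut <- FALSE
  for (nm in precedence) {
    if (!lgd[[nm]] %in% mesh$face_labels) next
    segs <- compartment_plane_segments(mesh, plane, lgd[[nm]])
    if (!nrow(segs)) next
    any_cut <- TRUE
    inside <- scanline_fill(to_px(segs), H, W)
    raster[inside] <- lgd[[nm]]
  }
  if (!any_cut)
    warning("plane does not intersect mesh: all-background slice")
  structure(list(raster = raster, pixel_spacing = pixel_spacing,
                 plane = plane, model_id = mesh$model_id,
                 apex_margin_px = apex_margin_px),
            class = "label_slice")
}

#' @export
print.label_slice <- function(x, ...) {
  tb <- table(x$raster)
  cat("label_slice ", nrow(x$raster), "x", ncol(x$raster), " @ ",
      x$pixel_spacing, " mm/px (", x$plane$view, ", model ", x$model_id,
      "): codes ", paste(names(tb), collapse = " "), "\n", sep = "")
  invisible(x)
}
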