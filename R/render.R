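# Pseudo-ultrasound rendering: task label derivation, cone masking, crops
# and affine augmentation, uniform noise + angular shadow sectors, Gaussian
# blur. Image and label rasters always pass through the identical geometric
# transform (image bilinear, labels nearest-neighbor), so every emitted pair
# is pixel-exactly aligned.

#' Ultrasound cone geometry
#'
#' The sector of valid pixels: apex at the top of the raster, opening
#' symmetric about the straight-down direction.
#'
#' @param H,W raster size the cone is defined on.
#' @param opening_angle full opening angle in degrees, in (0, 180).
#' @param radius sector radius in pixels (default `0.95 * H`).
#' @param apex `c(row, col)` apex position in 0-based pixel coordinates
#'   (default top-center).
#' @return a `cone_geometry`.
#' @export
cone_geometry <- function(H, W, opening_angle = 75, radius = 0.95 * H,
                          apex = c(2, (W - 1) / 2)) {
  if (opening_angle <= 0 || opening_angle >= 180)
    stop("opening_angle must be in (0, 180)")
  if (apex[1] < 0 || apex[1] >= H || apex[2] < 0 || apex[2] >= W)
    stop("cone apex must lie inside the raster")
  structure(list(H = H, W = W, opening_angle = opening_angle,
                 radius = radius, apex = apex),
            class = "cone_geometry")
}

#' Logical mask of a cone
#' @param cone a `cone_geometry`.
#' @return H x W logical matrix, `TRUE` inside the sector.
#' @export
cone_mask <- function(cone) {
  i <- matrix(0:(cone$H - 1), cone$H, cone$W)
  j <- matrix(0:(cone$W - 1), cone$H, cone$W, byrow = TRUE)
  dy <- i - cone$apex[1]
  dx <- j - cone$apex[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) * 180 / pi  # 0 = straight down
  dy >= 0 & r <= cone$radius & abs(ang) <= cone$opening_angle / 2
}

# angle (deg, 0 = straight down) of each pixel relative to the cone apex
cone_angles <- function(cone) {
  i <- matrix(0:(cone$H - 1), cone$H, cone$W)
  j <- matrix(0:(cone$W - 1), cone$H, cone$W, byrow = TRUE)
  atan2(j - cone$apex[2], i - cone$apex[1]) * 180 / pi
}

# ---- task labels ------------------------------------------------------------

.TASK_STRUCTURES <- c("lv_endo", "lv_epi", "la")

#' Task label legend
#'
#' Structures are segmentation targets expressed from tissue compartments:
#' `lv_endo` is the LV blood pool, `lv_epi` the union of blood pool and
#' myocardium (its support strictly contains `lv_endo`), `la` the left
#' atrial pool. Codes are assigned in the fixed canonical order above;
#' background is 0.
#'
#' @param task character vector of structure names.
#' @return named integer vector (including `background = 0`).
#' @export
task_legend <- function(task = c("lv_endo", "lv_epi", "la")) {
  unknown <- setdiff(task, .TASK_STRUCTURES)
  if (length(unknown))
    stop("unknown task structure(s): ", paste(unknown, collapse = ", "))
  task <- .TASK_STRUCTURES[.TASK_STRUCTURES %in% task]
  c(background = 0L, stats::setNames(seq_along(task), task))
}

#' Derive a task label raster from a tissue label slice
#'
#' Nested structures are encoded by inner-first precedence: a pixel in the
#' LV blood pool gets the `lv_endo` code even when `lv_epi` is also
#' requested; the binary mask of `lv_epi` is then the union of the two
#' codes (see [task_structure_mask()]).
#'
#' @param slice a `label_slice` (or a plain integer tissue raster).
#' @param task structure names, see [task_legend()].
#' @return integer raster of task codes with attribute `"task_legend"`.
#' @export
derive_task_labels <- function(slice, task = c("lv_endo", "lv_epi", "la")) {
  lg <- task_legend(task)
  raster <- if (inherits(slice, "label_slice")) slice$raster else slice
  tl <- tissue_legend()
  out <- matrix(0L, nrow(raster), ncol(raster))
  if ("lv_epi" %in% names(lg))
    out[raster %in% c(tl[["lv_pool"]], tl[["lv_myo"]])] <- lg[["lv_epi"]]
  if ("lv_endo" %in% names(lg))
    out[raster == tl[["lv_pool"]]] <- lg[["lv_endo"]]
  if ("la" %in% names(lg))
    out[raster == tl[["la"]]] <- lg[["la"]]
  attr(out, "task_legend") <- lg
  out
}

#' Binary mask of one structure in a task label raster
#'
#' @param raster task label raster (as from [derive_task_labels()] or a
#'   predicted mask with the same legend).
#' @param structure structure name.
#' @param legend task legend (recovered from the raster attribute when
#'   present).
#' @return logical matrix.
#' @export
task_structure_mask <- function(raster, structure,
                                legend = attr(raster, "task_legend")) {
  if (is.null(legend)) stop("no task legend available")
  if (!structure %in% names(legend)) stop("structure not in task legend: ", structure)
  codes <- legend[[structure]]
  if (structure == "lv_epi" && "lv_endo" %in% names(legend))
    codes <- c(codes, legend[["lv_endo"]])  # epi support contains endo
  matrix(raster %in% codes, nrow(raster), ncol(raster))
}

# ---- affine warps -----------------------------------------------------------

# Warp by the inverse-mapped affine p_in = Minv %*% (p_out - c_out) + c_in,
# in 0-based (row, col) pixel coordinates. The identical mapping is used for
# image (bilinear) and label (nearest-neighbor) rasters so pairs never
# desynchronize; outside-input samples return 0.
warp_affine <- function(raster, Minv, c_out, c_in,
                        interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(raster); W <- ncol(raster)
  io <- matrix(0:(H - 1), H, W) - c_out[1]
  jo <- matrix(0:(W - 1), H, W, byrow = TRUE) - c_out[2]
  ii <- Minv[1, 1] * io + Minv[1, 2] * jo + c_in[1]
  jj <- Minv[2, 1] * io + Minv[2, 2] * jo + c_in[2]
  if (interp == "nearest") {
    ri <- round(ii); rj <- round(jj)
    ok <- ri >= 0 & ri <= H - 1 & rj >= 0 & rj <= W - 1
    out <- raster
    out[] <- if (is.integer(raster)) 0L else 0
    out[ok] <- raster[cbind(ri[ok] + 1, rj[ok] + 1)]
    return(out)
  }
  fi <- floor(ii); fj <- floor(jj)
  wi <- ii - fi; wj <- jj - fj
  ok <- fi >= 0 & fi <= H - 2 & fj >= 0 & fj <= W - 2
  out <- matrix(0, H, W)
  g <- function(di, dj) raster[cbind(fi[ok] + 1 + di, fj[ok] + 1 + dj)]
  out[ok] <- (1 - wi[ok]) * (1 - wj[ok]) * g(0, 0) +
    wi[ok] * (1 - wj[ok]) * g(1, 0) +
    (1 - wi[ok]) * wj[ok] * g(0, 1) +
    wi[ok] * wj[ok] * g(1, 1)
  out
}

# Largest scale at which the transformed ROI point cloud `q` (0-based
# (row, col) offsets about its centroid) fits inside the sector for some
# vertical placement of the centroid below the cone apex; returns the scale
# and the feasible band [dy_lo, dy_hi] of centroid depths.
fit_roi_in_cone <- function(q, cone, s_hi) {
  tanH <- tan(cone$opening_angle / 2 * pi / 180)
  feas <- function(s) {
    lo <- max(s * (abs(q[, 2]) / tanH - q[, 1]))
    hi <- min(sqrt(pmax(0, cone$radius^2 - (s * q[, 2])^2)) - s * q[, 1])
    c(max(lo, 0), hi)
  }
  s <- s_hi
  for (i in 1:40) {
    f <- feas(s)
    if (f[1] <= f[2] - 1) break
    s <- s * 0.94
  }
  f <- feas(s)
  if (f[1] > f[2]) stop("region of interest cannot fit inside the cone")
  list(s = 0.99 * s, dy_lo = f[1], dy_hi = f[2])
}

# ---- rendering configuration ------------------------------------------------

#' Rendering configuration
#'
#' Tunable parameters of the pseudo-ultrasound renderer. The defaults form
#' the package's standard extraction profile; per-dataset profiles are just
#' modified copies (see `profile`).
#'
#' @param rot_deg_range random in-plane rotation range (degrees).
#' @param squeeze_range anisotropic scale ("squeezing") range per axis.
#' @param jitter_frac random placement jitter as a fraction of cone radius.
#' @param lv_focus_depth LV-focused crop: LV span as a fraction of cone
#'   radius.
#' @param whole_heart_depth whole-heart crop: heart span fraction.
#' @param crop_prob probability of the `whole_heart` crop under random mode.
#' @param noise_amplitude uniform noise half-width `a` (intensity units).
#' @param n_shadows_range inclusive range for the number of shadow sectors.
#' @param shadow_width_range,shadow_attenuation shadow sector width
#'   (degrees) and multiplicative attenuation ranges.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param gray_levels intensity proxy per tissue (named, see
#'   [default_gray_levels()]).
#' @param max_retries affine re-draws before a sample is declared
#'   unplaceable.
#' @param profile one of `"default"`, `"cloudy"` (stronger noise and blur),
#'   `"high_gain"` (brighter myocardium, lighter blur); named presets that
#'   emulate acquisition-style differences between clinical datasets.
#' @return a list of settings.
#' @export
render_config <- function(rot_deg_range = c(-8, 8),
                          squeeze_range = c(0.85, 1.15),
                          jitter_frac = 0.03,
                          lv_focus_depth = 0.70,
                          whole_heart_depth = 0.80,
                          crop_prob = 0.5,
                          noise_amplitude = 0.08,
                          n_shadows_range = c(1L, 3L),
                          shadow_width_range = c(5, 20),
                          shadow_attenuation = c(0.3, 0.7),
                          blur_sigma = 2,
                          gray_levels = default_gray_levels(),
                          max_retries = 20L,
                          profile = c("default", "cloudy", "high_gain")) {
  profile <- match.arg(profile)
  cfg <- as.list(environment())
  if (profile == "cloudy") {
    cfg$noise_amplitude <- 0.12
    cfg$blur_sigma <- 3
  } else if (profile == "high_gain") {
    cfg$gray_levels[["lv_myo"]] <- 0.85
    cfg$blur_sigma <- 1.5
  }
  cfg
}

# ---- compose / noise / blur -------------------------------------------------

#' Compose a pseudo image and aligned task labels inside the cone
#'
#' Maps tissue codes to the configured gray levels, chooses a crop (whole
#' heart or LV focused), applies a random rotation + squeeze + fitted
#' scale/translation — the identical chain to intensity (bilinear) and label
#' (nearest-neighbor) rasters — masks with the cone, and verifies that every
#' label pixel of the crop's region of interest lies inside the cone (the LV
#' for `lv_focused`, every structure for `whole_heart`), re-drawing the
#' transform up to `config$max_retries` times otherwise. Structures outside
#' the region of interest (e.g. the LA in an LV-focused crop, as in real
#' LV-focused acquisitions) are clipped at the sector boundary, so no
#' emitted pair ever has a nonzero pixel outside the cone.
#'
#' @param slice a `label_slice`.
#' @param task structure names (see [task_legend()]).
#' @param cone a `cone_geometry` (default matches the slice size).
#' @param crop_mode `"random"`, `"whole_heart"` or `"lv_focused"`.
#' @param seed integer RNG seed.
#' @param config a [render_config()] list.
#' @return a `pseudo_pair`: `image` (H x W in `[0,1]`), `label` (H x W
#'   integer task codes), `cone`, `task_legend_map`, `provenance`.
#' @export
compose_view <- function(slice, task = c("lv_endo", "lv_epi", "la"),
                         cone = NULL,
                         crop_mode = c("random", "whole_heart", "lv_focused"),
                         seed = 0L, config = render_config()) {
  crop_mode <- match.arg(crop_mode)
  raster <- slice$raster
  H <- nrow(raster); W <- ncol(raster)
  if (is.null(cone)) cone <- cone_geometry(H, W)
  cmask <- cone_mask(cone)
  lg <- task_legend(task)
  task_r <- derive_task_labels(slice, task)
  gl <- config$gray_levels
  img <- matrix(gl[match(raster, tissue_legend())], H, W)

  set.seed(as.integer(seed))
  mode <- if (crop_mode == "random") {
    if (stats::runif(1) < config$crop_prob) "whole_heart" else "lv_focused"
  } else crop_mode
  # crop target: support whose extent is normalised into the cone
  target <- if (mode == "lv_focused") {
    raster %in% tissue_legend()[c("lv_pool", "lv_myo")]
  } else raster != 0L
  if (!any(target))
    stop("slice does not contain the crop target for mode ", mode)
  tij <- which(matrix(target, H, W), arr.ind = TRUE) - 1  # 0-based (row, col)
  c_in <- colMeans(tij)

  depth_frac <- if (mode == "lv_focused") config$lv_focus_depth else
    config$whole_heart_depth
  for (try in seq_len(config$max_retries)) {
    theta <- stats::runif(1, config$rot_deg_range[1], config$rot_deg_range[2]) * pi / 180
    sq <- stats::runif(2, config$squeeze_range[1], config$squeeze_range[2])
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    M0 <- R %*% diag(sq)
    q <- tij %*% t(M0)  # forward-transformed target (about its centroid)
    q <- sweep(q, 2, colMeans(q))
    fit <- fit_roi_in_cone(q, cone, s_hi = depth_frac * cone$radius /
                             diff(range(q[, 1])))
    s <- fit$s
    M <- s * M0
    # place the ROI centroid inside the feasible vertical band: near its top
    # for LV-focused crops (LV apex close to the cone apex), mid-band for
    # whole-heart, plus a bounded random jitter
    band <- fit$dy_hi - fit$dy_lo
    frac <- if (mode == "lv_focused") 0.15 else 0.5
    dy <- fit$dy_lo + band * min(1, max(0, frac +
        stats::runif(1, -1, 1) * config$jitter_frac * 3))
    dx <- stats::runif(1, -1, 1) * config$jitter_frac * cone$radius
    c_out <- cone$apex + c(dy, dx)
    Minv <- solve(M)
    lab <- warp_affine(task_r, Minv, c_out, c_in, interp = "nearest")
    roi_codes <- if (mode == "lv_focused") {
      lg[names(lg) %in% c("lv_endo", "lv_epi")]
    } else lg[names(lg) != "background"]
    if (!any(lab[!cmask] %in% roi_codes)) {
      lab[!cmask] <- 0L  # clip non-ROI structures at the sector boundary
      im <- warp_affine(img, Minv, c_out, c_in, interp = "bilinear")
      im[!cmask] <- 0
      prov <- list(model_id = slice$model_id, view = slice$plane$view,
                   crop_mode = mode, seed = as.integer(seed),
                   plane_perturbation = as.list(slice$plane$perturbation),
                   affine = list(rotation_deg = theta * 180 / pi,
                                 squeeze = sq, scale = s,
                                 center_in = c_in, center_out = c_out),
                   retries = try - 1L)
      attr(lab, "task_legend") <- lg
      return(structure(list(image = im, label = lab, cone = cone,
                            task_legend_map = lg, provenance = prov),
                       class = "pseudo_pair"))
    }
  }
  stop("could not fit region of interest inside the cone after ",
       config$max_retries, " transform re-draws")
}

#' Add uniform noise and angular shadow sectors
#'
#' Adds i.i.d. uniform noise on `[-a, a]` to every pixel inside the cone
#' (clipped back to `[0, 1]`), then multiplies random angular sectors
#' emanating from the cone apex by an attenuation factor. The label raster
#' is never modified.
#'
#' @param pair a `pseudo_pair`.
#' @param seed integer RNG seed.
#' @param noise_amplitude uniform half-width `a >= 0`.
#' @param n_shadows number of shadow sectors (draw from the config range
#'   with `NULL`).
#' @param config a [render_config()] list for the shadow parameter ranges.
#' @return the modified `pseudo_pair` (noise/shadow parameters appended to
#'   provenance).
#' @export
add_noise_and_shadows <- function(pair, seed = 0L,
                                  noise_amplitude = NULL, n_shadows = NULL,
                                  config = render_config()) {
  if (is.null(noise_amplitude)) noise_amplitude <- config$noise_amplitude
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  set.seed(as.integer(seed))
  cmask <- cone_mask(pair$cone)
  img <- pair$image
  if (noise_amplitude > 0) {
    noise <- matrix(stats::runif(length(img), -noise_amplitude,
                                 noise_amplitude), nrow(img))
    img[cmask] <- pmin(1, pmax(0, img[cmask] + noise[cmask]))
  }
  if (is.null(n_shadows))
    n_shadows <- sample(config$n_shadows_range[1]:config$n_shadows_range[2], 1)
  shadows <- list()
  if (n_shadows > 0) {
    ang <- cone_angles(pair$cone)
    half <- pair$cone$opening_angle / 2
    for (k in seq_len(n_shadows)) {
      ctr <- stats::runif(1, -half, half)
      wd <- stats::runif(1, config$shadow_width_range[1],
                         config$shadow_width_range[2])
      att <- stats::runif(1, config$shadow_attenuation[1],
                          config$shadow_attenuation[2])
      sel <- cmask & abs(ang - ctr) <= wd / 2
      img[sel] <- img[sel] * att
      shadows[[k]] <- list(center_deg = ctr, width_deg = wd, attenuation = att)
    }
  }
  pair$image <- img
  pair$provenance$noise <- list(amplitude = noise_amplitude, seed = as.integer(seed))
  pair$provenance$shadows <- shadows
  pair
}

#' Gaussian-blur the pseudo image
#'
#' Convolves the image with a Gaussian kernel (via `EBImage::gblur`) and
#' re-zeros pixels outside the cone. Labels are untouched; `sigma_px = 0`
#' is the identity.
#'
#' @param pair a `pseudo_pair`.
#' @param sigma_px kernel standard deviation in pixels (>= 0).
#' @return the blurred `pseudo_pair`.
#' @export
blur_pair <- function(pair, sigma_px = 2) {
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(pair$image, sigma = sigma_px))
    img[!cone_mask(pair$cone)] <- 0
    pair$image <- matrix(pmin(1, pmax(0, img)), nrow(img))
  }
  pair$provenance$blur_sigma <- sigma_px
  pair
}

#' @export
print.pseudo_pair <- function(x, ...) {
  cat("pseudo_pair ", nrow(x$image), "x", ncol(x$image), " (",
      x$provenance$view, ", ", x$provenance$crop_mode, ", model ",
      x$provenance$model_id, ")\n", sep = "")
  invisible(x)
}

# deterministic sub-seed stream (kept below 2^31)
sub_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 65521) * 32749 + idx * 104729 + 1) %% 2147483647L
}

#' Render a full pseudo-ultrasound dataset
#'
#' Runs the slicing + rendering chain for every model: per model,
#' `slices_per_model` independently perturbed view planes are sliced, and
#' each slice yields `pseudo_per_slice` rendered pairs — so the output is
#' exactly `length(models) * slices_per_model * pseudo_per_slice` pairs
#' (the canonical full-pipeline dataset is 99 x 3 x 3 = 891, the
#' no-shape-expansion variant 19 x 5 x 9 = 855). Samples whose region of
#' interest cannot be placed in the cone are re-drawn under fresh sub-seeds
#' so the count is exact.
#'
#' @param models list of `labeled_mesh`.
#' @param view `"a4c"` or `"a2c"`.
#' @param slices_per_model,pseudo_per_slice dataset arithmetic factors.
#' @param task structure names.
#' @param config a [render_config()] list.
#' @param seed master seed; output is deterministic under it.
#' @param H,W,pixel_spacing raster geometry passed to [slice_mesh()].
#' @param perturb_ranges plane perturbation ranges (see [perturb_plane()]).
#' @return list of `pseudo_pair`.
#' @export
render_dataset <- function(models, view = c("a4c", "a2c"),
                           slices_per_model = 3L, pseudo_per_slice = 3L,
                           task = c("lv_endo", "lv_epi", "la"),
                           config = render_config(), seed = 0L,
                           H = 256L, W = 256L, pixel_spacing = 0.6,
                           perturb_ranges = c(long = 10, short = 5)) {
  view <- match.arg(view)
  if (!length(models)) stop("need at least one model")
  out <- vector("list", length(models) * slices_per_model * pseudo_per_slice)
  n <- 0L
  idx <- 0L
  for (m in models) {
    base_plane <- if (view == "a4c") define_a4c_plane(m) else define_a2c_plane(m)
    for (si in seq_len(slices_per_model)) {
      idx <- idx + 1L
      pl <- perturb_plane(base_plane, m, seed = sub_seed(seed, idx),
                          ranges = perturb_ranges)
      sl <- slice_mesh(m, pl, H = H, W = W, pixel_spacing = pixel_spacing)
      for (pi in seq_len(pseudo_per_slice)) {
        idx <- idx + 1L
        pair <- NULL
        for (retry in 0:49) {
          s <- sub_seed(seed, idx + 1000000L * retry)
          pair <- tryCatch({
            p <- compose_view(sl, task = task, seed = s, config = config)
            p <- add_noise_and_shadows(p, seed = sub_seed(s, 1L), config = config)
            blur_pair(p, config$blur_sigma)
          }, error = function(e) NULL)
          if (!is.null(pair)) break
        }
        if (is.null(pair))
          stop("sample generation failed repeatedly for model ",
               m$model_id, " slice ", si)
        pair$provenance$slice_index <- si
        pair$provenance$pseudo_index <- pi
        n <- n + 1L
        out[[n]] <- pair
      }
    }
  }
  out
}
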