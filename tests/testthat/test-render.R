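make_slice <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- generate_phantom(seed = 0)
      cache <<- slice_mesh(m, define_a4c_plane(m), H = 128, W = 128,
                           pixel_spacing = 1.2)
    }
    cache
  }
})

test_that("task labels encode nesting with inner-first precedence", {
  sl <- make_slice()
  tr <- derive_task_labels(sl, c("lv_endo", "lv_epi", "la"))
  lg <- attr(tr, "task_legend")
  endo <- task_structure_mask(tr, "lv_endo")
  epi <- task_structure_mask(tr, "lv_epi")
  la <- task_structure_mask(tr, "la")
  expect_true(all(epi[endo]))              # epi support contains endo
  expect_gt(sum(epi), sum(endo))           # strictly
  ratio <- sum(endo) / sum(epi)
  expect_gt(ratio, 0); expect_lt(ratio, 1)
  expect_false(any(la & epi))
  expect_error(derive_task_labels(sl, c("lv_endo", "spleen")), "spleen")
  # empty structure: slice with no LV gives an all-zero raster
  empty <- sl
  empty$raster <- matrix(3L, 16, 16)  # LA only
  t2 <- derive_task_labels(empty, "lv_endo")
  expect_true(all(t2 == 0))
})

test_that("cone geometry validates and masks as a sector", {
  expect_error(cone_geometry(64, 64, opening_angle = 0), "opening_angle")
  expect_error(cone_geometry(64, 64, opening_angle = 185), "opening_angle")
  expect_error(cone_geometry(64, 64, apex = c(-3, 2)), "apex")
  cm <- cone_mask(cone_geometry(128, 128))
  expect_false(any(cm[1:2, ]))             # above the apex row
  expect_true(cm[64, 64])
})

test_that("composition keeps every emitted pixel inside the cone", {
  sl <- make_slice()
  for (s in 1:25) {
    p <- compose_view(sl, seed = s)
    cm <- cone_mask(p$cone)
    expect_true(all(p$label[!cm] == 0L))
    expect_true(all(p$image[!cm] == 0))
    expect_identical(dim(p$image), dim(p$label))
    expect_true(all(p$label %in% p$task_legend_map))
  }
})

test_that("composition is deterministic under a fixed seed", {
  sl <- make_slice()
  expect_identical(compose_view(sl, seed = 7), compose_view(sl, seed = 7))
  expect_false(identical(compose_view(sl, seed = 7)$label,
                         compose_view(sl, seed = 8)$label))
})

test_that("pairing survives the full render chain bit-exactly", {
  sl <- make_slice()
  render_once <- function() {
    p <- compose_view(sl, seed = 3)
    p <- add_noise_and_shadows(p, seed = 4)
    blur_pair(p, 2)
  }
  a <- render_once(); b <- render_once()
  expect_identical(a$label, b$label)
  expect_equal(dice(a$label != 0, b$label != 0), 100)
  expect_identical(a$image, b$image)
})

test_that("noise statistics and label immutability", {
  sl <- make_slice()
  p <- compose_view(sl, seed = 1)
  cm <- cone_mask(p$cone)
  # identity at zero amplitude / zero shadows
  p0 <- add_noise_and_shadows(p, seed = 2, noise_amplitude = 0, n_shadows = 0)
  expect_identical(p0$image, p$image)
  # uniform noise: std = a / sqrt(3) on a constant interior
  pc <- p
  pc$image[cm] <- 0.5
  pn <- add_noise_and_shadows(pc, seed = 3, noise_amplitude = 0.1, n_shadows = 0)
  expect_equal(stats::sd(pn$image[cm]), 0.1 / sqrt(3), tolerance = 0.05)
  expect_identical(pn$label, pc$label)
  # shadows only attenuate
  ps <- add_noise_and_shadows(pc, seed = 4, noise_amplitude = 0, n_shadows = 2)
  expect_true(all(ps$image <= pc$image + 1e-12))
  expect_error(add_noise_and_shadows(p, noise_amplitude = -0.1), "amplitude")
})

test_that("noise monotonicity: larger amplitude moves further from the clean render", {
  sl <- make_slice()
  p <- compose_view(sl, seed = 5)
  mads <- vapply(c(0.02, 0.05, 0.1, 0.2), function(a) {
    pn <- add_noise_and_shadows(p, seed = 11, noise_amplitude = a, n_shadows = 0)
    mean(abs(pn$image - p$image))
  }, numeric(1))
  expect_true(all(diff(mads) > 0))
})

test_that("blur is conservative and label-neutral", {
  sl <- make_slice()
  p <- compose_view(sl, seed = 6)
  expect_identical(blur_pair(p, 0)$image, p$image)
  # constant cone interior stays constant away from the boundary
  pc <- p
  cm <- cone_mask(p$cone)
  pc$image[cm] <- 0.5
  pb <- blur_pair(pc, 2)
  interior <- cm & !cone_mask(cone_geometry(128, 128, opening_angle = 55,
                                            radius = 0.8 * 128))
  # central band well inside the cone
  core <- matrix(FALSE, 128, 128); core[40:80, 55:75] <- TRUE
  expect_lt(max(abs(pb$image[core] - 0.5)), 1e-6)
  expect_identical(pb$label, pc$label)
  # kernel normalisation: total intensity of a compact blob is conserved
  pblob <- p
  pblob$image[] <- 0
  pblob$image[55:70, 55:70] <- 0.8
  pb2 <- blur_pair(pblob, 2)
  expect_equal(sum(pb2$image), sum(pblob$image), tolerance = 0.01 * sum(pblob$image))
  expect_error(blur_pair(p, -1), "sigma")
})

test_that("dataset arithmetic is exact and deterministic at small scale", {
  models <- generate_phantom_cohort(2, seed = 13)
  ds <- render_dataset(models, slices_per_model = 2, pseudo_per_slice = 3,
                       seed = 5, H = 128, W = 128, pixel_spacing = 1.2)
  expect_length(ds, 2 * 2 * 3)
  ds2 <- render_dataset(models, slices_per_model = 2, pseudo_per_slice = 3,
                        seed = 5, H = 128, W = 128, pixel_spacing = 1.2)
  expect_identical(ds, ds2)
  prov <- vapply(ds, function(p) p$provenance$model_id, character(1))
  expect_equal(as.vector(table(prov)[unique(prov)]), c(6, 6))
})

test_that("pair IO round-trips labels exactly and images to 8-bit", {
  sl <- make_slice()
  p <- blur_pair(add_noise_and_shadows(compose_view(sl, seed = 2), seed = 3), 2)
  d <- withr::local_tempdir()
  strip <- function(x) { attributes(x) <- list(dim = dim(x)); x }
  write_pseudo_pair(p, d, "t1")
  r <- read_pseudo_pair(d, "t1")
  expect_identical(strip(r$label), strip(p$label))
  expect_lt(max(abs(r$image - p$image)), 1 / 255)
  expect_equal(r$provenance$crop_mode, p$provenance$crop_mode)
  ds <- list(p, compose_view(sl, seed = 9))
  write_dataset(ds, file.path(d, "set"))
  back <- read_dataset(file.path(d, "set"))
  expect_length(back, 2)
  expect_identical(strip(back[[1]]$label), strip(ds[[1]]$label))
})
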