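test_that("Procrustes alignment removes rigid motions and is idempotent", {
  m0 <- generate_phantom(seed = 3)
  cohort <- list(m0,
                 rigid_move(m0, 0.5, c(0, 0, 1), c(10, -5, 3)),
                 rigid_move(m0, 1.2, c(1, 1, 0) / sqrt(2), c(-7, 2, 9)))
  al <- align_cohort(cohort)
  rmsd <- vapply(al[-1], function(m)
    sqrt(mean((m$vertices - al[[1]]$vertices)^2)), numeric(1))
  expect_true(all(rmsd < 1e-6))
  # idempotence on an already-aligned cohort
  al2 <- align_cohort(al)
  for (i in seq_along(al))
    expect_equal(al2[[i]]$vertices, al[[i]]$vertices, tolerance = 1e-9)
  # mean shape centroid at the origin
  mv <- Reduce(`+`, lapply(al, function(m) m$vertices)) / length(al)
  expect_equal(colMeans(mv), c(0, 0, 0), tolerance = 1e-8)
})

test_that("alignment refuses non-corresponded cohorts", {
  m <- generate_phantom(0)
  bad <- m
  bad$vertices <- bad$vertices[-1, ]
  bad$faces <- bad$faces[bad$face_labels == 1, ]
  bad$face_labels <- bad$face_labels[bad$face_labels == 1]
  expect_error(align_cohort(list(m, bad)), "corresponded")
})

test_that("mode count follows the variance target and the rank bounds", {
  # cohort with exactly 3 parametric degrees of freedom, no surface noise:
  # vertex positions are linear in these parameters, so rank <= 3
  co3 <- generate_phantom_cohort(
    n = 12, seed = 1,
    vary = list(lv_length = c(75, 95), lv_radius = c(22, 30), wall = c(7, 13)),
    params = utils::modifyList(phantom_params(), list(bump_amplitude = 0)))
  p3 <- fit_pdm(align_cohort(co3), variance_target = 0.999)
  expect_lte(p3$k, 3)

  co <- align_cohort(generate_phantom_cohort(n = 19, seed = 7))
  pf <- fit_pdm(co, variance_target = 1.0)
  expect_lte(pf$k, 18)         # rank bound n - 1
  expect_equal(pf$k, length(pf$all_variances))
  expect_error(fit_pdm(co, variance_target = 0), "variance_target")
  expect_error(fit_pdm(co, variance_target = 1.5), "variance_target")
})

test_that("modes are orthonormal, variances descend, eigenvalue sum is conserved", {
  al <- align_cohort(generate_phantom_cohort(n = 10, seed = 2))
  pdm <- fit_pdm(al, 0.95)
  G <- crossprod(pdm$modes)
  expect_lt(max(abs(G - diag(pdm$k))), 1e-8)
  expect_true(all(diff(pdm$mode_variances) <= 1e-12))
  expect_true(all(pdm$mode_variances >= 0))
  X <- do.call(rbind, lapply(al, echoforge:::flatten_mesh))
  total_var <- sum(scale(X, scale = FALSE)^2) / (nrow(X) - 1)
  expect_equal(sum(pdm$all_variances), total_var, tolerance = 1e-8)
  expect_gte(pdm$variance_captured, 0.95)
  expect_lte(pdm$variance_captured, 1)
})

test_that("training shapes are reconstructed exactly from the full mode set", {
  al <- align_cohort(generate_phantom_cohort(n = 8, seed = 5))
  pdm <- fit_pdm(al, 1.0)
  for (m in al[c(1, 4, 8)]) {
    cf <- echoforge:::pdm_project(pdm, m)
    r <- echoforge:::pdm_reconstruct(pdm, cf)
    expect_lt(sqrt(mean((r$vertices - m$vertices)^2)), 1e-6)
  }
})

test_that("a planted mode subspace and its variances are recovered", {
  # synthetic cohort: mean + 3 known orthonormal modes with known variances
  set.seed(42)
  base <- generate_phantom(seed = 0)
  p <- 3L * nrow(base$vertices)
  Q <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  sds <- c(6, 3, 1.5)
  n <- 200
  B <- matrix(rnorm(n * 3), n, 3)
  B <- sweep(scale(B), 2, sds, `*`)  # exact per-mode sample variances
  mu <- echoforge:::flatten_mesh(base)
  cohort <- lapply(seq_len(n), function(i) {
    m <- base
    m$vertices <- echoforge:::unflatten_verts(mu + as.vector(Q %*% B[i, ]))
    m$landmarks <- echoforge:::mesh_landmarks(m)
    m
  })
  pdm <- fit_pdm(cohort, 0.999)  # no alignment: displacements are the signal
  expect_equal(pdm$k, 3)
  # principal angles between recovered and planted subspaces < 1 degree
  sv <- svd(crossprod(Q, pdm$modes))$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 1)
  expect_equal(pdm$mode_variances, sds^2, tolerance = 0.1)
})

test_that("sampling honors the two-standard-deviation bound and mode linearity", {
  al <- align_cohort(generate_phantom_cohort(n = 10, seed = 3))
  pdm <- fit_pdm(al, 0.9)
  cf <- matrix(0, 10000, pdm$k)
  for (i in 1:10000) {
    set.seed(i)
    cf[i, ] <- stats::runif(pdm$k, -2, 2)
  }
  s <- sample_shape(pdm, seed = 123)
  expect_true(all(abs(s$coefficients) <= 2))
  expect_true(max(abs(cf)) <= 2)

  # forced zero coefficients give exactly the mean shape
  s0 <- sample_shape(pdm, coefficients = numeric(pdm$k))
  expect_equal(echoforge:::flatten_mesh(s0$mesh), pdm$mean_shape,
               tolerance = 1e-9)
  # +2 vs -2 on mode 1 differ by 4 * sqrt(lambda_1) * mode_1
  cp <- numeric(pdm$k); cp[1] <- 2
  cm <- numeric(pdm$k); cm[1] <- -2
  dv <- echoforge:::flatten_mesh(sample_shape(pdm, coefficients = cp)$mesh) -
    echoforge:::flatten_mesh(sample_shape(pdm, coefficients = cm)$mesh)
  expect_equal(dv, 4 * sqrt(pdm$mode_variances[1]) * pdm$modes[, 1],
               tolerance = 1e-9)
})

test_that("cohort expansion is deterministic with positive compartment volumes", {
  al <- align_cohort(generate_phantom_cohort(n = 10, seed = 3))
  pdm <- fit_pdm(al, 0.9)
  ex1 <- expand_cohort(pdm, n_new = 12, seed = 4)
  ex2 <- expand_cohort(pdm, n_new = 12, seed = 4)
  expect_identical(ex1, ex2)
  expect_length(ex1, 12)
  expect_error(expand_cohort(pdm, n_new = 0), "positive")
  for (m in ex1[c(1, 6, 12)]) expect_true(all(tissue_volumes(m) > 0))
})

test_that("PDM serialization round-trips and mode sweeps stay on one mode", {
  al <- align_cohort(generate_phantom_cohort(n = 8, seed = 9))
  pdm <- fit_pdm(al, 0.9)
  f <- withr::local_tempfile(fileext = ".json")
  save_pdm(pdm, f)
  p2 <- load_pdm(f)
  expect_equal(p2$modes, pdm$modes, tolerance = 1e-12)
  expect_equal(p2$mode_variances, pdm$mode_variances, tolerance = 1e-12)
  s1 <- sample_shape(pdm, seed = 11)
  s2 <- sample_shape(p2, seed = 11)
  expect_equal(s1$mesh$vertices, s2$mesh$vertices, tolerance = 1e-9)

  sw <- mode_sweep(pdm, mode = 1, coefs = c(-2, 0, 2))
  expect_equal(sw[[2]]$vertices,
               echoforge:::unflatten_verts(pdm$mean_shape), tolerance = 1e-9)
})
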