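# Exhaustive-oracle checks on small masks plus closed-form geometry cases.

set_arith_dice <- function(a, b) {
  # independent oracle: explicit set arithmetic over pixel index sets
  ia <- which(a); ib <- which(b)
  if (length(ia) + length(ib) == 0) return(0)
  200 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

exact_wilcoxon_p <- function(d) {
  # enumerate all 2^n sign assignments of the rank statistic
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mu <- sum(r) / 2
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
}

test_that("dice matches an exhaustive set-arithmetic oracle on small masks", {
  set.seed(1)
  for (rep in 1:25) {
    a <- matrix(stats::runif(64) < 0.4, 8, 8)
    b <- matrix(stats::runif(64) < 0.4, 8, 8)
    if (sum(a) + sum(b) == 0) next
    expect_identical(dice(a, b), set_arith_dice(a, b))
    expect_identical(dice(a, b), dice(b, a))  # symmetry
  }
  a <- raster_disk(20)
  expect_equal(dice(a, a), 100)
  expect_equal(dice(a, raster_disk(10, cx = 110, cy = 110)), 0)
  # 4-px squares overlapping by 2 px: 200 * 2 / 8 = 50
  p <- matrix(FALSE, 8, 8); p[2:3, 2:3] <- TRUE
  r <- matrix(FALSE, 8, 8); r[2:3, 3:4] <- TRUE
  expect_equal(dice(p, r), 50)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "dimensions")
  expect_warning(d0 <- dice(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "empty")
  expect_equal(d0, 0)
})

test_that("bias follows its closed form and antisymmetry", {
  p <- matrix(FALSE, 30, 30); p[1:15, 1:20] <- TRUE   # area 300
  r <- matrix(FALSE, 30, 30); r[1:10, 1:10] <- TRUE   # area 100
  expect_equal(bias(p, r), 100)  # 200 * 200 / 400
  expect_equal(bias(r, p), -100)
  expect_equal(bias(p, p), 0)
  set.seed(2)
  for (rep in 1:20) {
    a <- matrix(stats::runif(64) < 0.5, 8, 8)
    b <- matrix(stats::runif(64) < 0.5, 8, 8)
    if (!any(a) && !any(b)) next
    expect_equal(bias(a, b), 200 * (sum(a) - sum(b)) / (sum(a) + sum(b)))
    expect_equal(bias(a, b), -bias(b, a))
    expect_lte(abs(bias(a, b)), 200)
  }
  expect_error(bias(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "empty")
})

test_that("simplicity hits the closed forms for disks and strips", {
  expect_equal(simplicity(raster_disk(50)), 1, tolerance = 0.02)
  strip <- matrix(FALSE, 10, 110)
  strip[5, 6:105] <- TRUE
  expect_equal(simplicity(strip), sqrt(400 * pi) / 202, tolerance = 0.05)
  expect_identical(simplicity(matrix(FALSE, 8, 8)), 0)
})

test_that("simplicity stays near or below 1 and decreases with elongation", {
  sps <- vapply(seq(1, 3, by = 0.25), function(k)
    simplicity(raster_ellipse(40 / k, 40 * k)), numeric(1))
  expect_true(all(diff(sps) < 0))     # strictly decreasing along the sweep
  set.seed(3)
  for (rep in 1:10) {
    msk <- raster_ellipse(stats::runif(1, 5, 40), stats::runif(1, 5, 40))
    expect_lte(simplicity(msk), 1 + 0.03)
  }
  expect_gt(simplicity(raster_star(40)), 0)
  expect_lt(simplicity(raster_star(40)), simplicity(raster_disk(30)))
})

test_that("mean contour distance matches analytic geometry", {
  expect_equal(mean_distance(raster_disk(40), raster_disk(50)), 10,
               tolerance = 0.5)
  d_same <- mean_distance(raster_disk(30), raster_disk(30))
  expect_lt(d_same, 1e-9)
  # translation of a large square: d_m between 3 and |t| = 5
  sq <- matrix(FALSE, 128, 128); sq[30:90, 30:90] <- TRUE
  sq2 <- matrix(FALSE, 128, 128); sq2[33:93, 34:94] <- TRUE
  dm <- mean_distance(sq, sq2)
  expect_gte(dm, 3)
  expect_lte(dm, 5)
  # one-directional variant and symmetry of the default
  expect_equal(mean_distance(raster_disk(40), raster_disk(50)),
               mean_distance(raster_disk(50), raster_disk(40)),
               tolerance = 1e-9)
  expect_error(mean_distance(matrix(FALSE, 8, 8), raster_disk(3, 4, 4, 8, 8)),
               "empty")
})

test_that("contours are closed sub-pixel polygons", {
  cs <- mask_contours(raster_disk(20))
  expect_length(cs, 1)
  P <- cs[[1]]
  expect_gte(nrow(P), 3)
  expect_lt(sqrt(sum((P[1, ] - P[nrow(P), ])^2)), 1.5)
  # two components -> two polygons, total perimeter sums
  two <- raster_disk(10, 30, 30) | raster_disk(10, 90, 90)
  expect_length(mask_contours(two), 2)
})

test_that("aggregation produces medians and raw MADs", {
  expect_equal(mad_raw(c(1, 2, 3, 4, 5)), 1)
  expect_equal(mad_raw(rep(7, 5)), 0)
  recs <- do.call(rbind, lapply(1:5, function(i)
    metrics_record(raster_disk(20 + i), raster_disk(22), structure = "lv_endo",
                   image_id = i)))
  agg <- aggregate_metrics(recs)
  expect_equal(agg$n, 5)
  expect_equal(agg$D, stats::median(recs$D))
  expect_equal(agg$D_MAD, mad_raw(recs$D))
  single <- aggregate_metrics(recs[3, ])
  expect_equal(single$D_MAD, 0)
  expect_equal(single$D, recs$D[3])
  expect_error(aggregate_metrics(recs[0, ]), "records")
})

test_that("the paired Wilcoxon test matches exact sign enumeration", {
  # n = 6, all differences positive: two-sided p = 2/64
  expect_equal(compare_methods(c(11, 12, 13, 14, 15, 16), rep(10, 6)),
               2 / 64)
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    a <- stats::rnorm(n)
    b <- a - sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.1, 2)
    p_pkg <- compare_methods(a, b)
    p_ora <- exact_wilcoxon_p(a - b)
    expect_equal(p_pkg, p_ora, tolerance = 1e-12)
    expect_equal(compare_methods(b, a), p_pkg, tolerance = 1e-12)
  }
  expect_error(compare_methods(1:5, 1:5), "tied")
  expect_error(compare_methods(1:4, 1:5), "equal length")
  # zero differences are dropped
  expect_equal(compare_methods(c(5, 11, 12, 13, 14, 15, 16),
                               c(5, 10, 10, 10, 10, 10, 10)), 2 / 64)
  # pratt variant returns a valid p and keeps antisymmetry
  a <- c(5, 11, 12, 13, 14, 15, 16); b <- c(5, 10, 10, 10, 10, 10, 10)
  pp <- compare_methods(a, b, zero_method = "pratt")
  expect_gt(pp, 0); expect_lte(pp, 1)
  expect_equal(compare_methods(b, a, zero_method = "pratt"), pp)
})
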