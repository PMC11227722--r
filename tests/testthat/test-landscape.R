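test_that("canopy categorization uses the quartile bin edges", {
  r <- hs_raster(matrix(c(0, 25, 26, 50, 51, 75, 76, 100), 2, 4), res = 10)
  out <- categorize_canopy(r)
  expect_equal(as.vector(raster_values(out)), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(out$levels, c("sparse", "open", "moderate", "dense"))
  expect_error(categorize_canopy(hs_raster(matrix(c(5, 101), 1, 2))), "\\[0, 100\\]")
  expect_error(categorize_canopy(hs_raster(matrix(c(-1, 10), 1, 2))), "\\[0, 100\\]")
})

test_that("focal mode smooths isolated cells, keeps ties and constants", {
  u <- flat_raster(3, 6)
  expect_equal(raster_values(focal_mode(u)), raster_values(u))
  iso <- matrix(4, 5, 5); iso[3, 3] <- 1
  expect_equal(raster_values(focal_mode(hs_raster(iso, res = 10), passes = 1))[3, 3], 4)
  # 4 dense + 4 sparse around an open center: tie keeps the center
  tie <- matrix(c(4, 4, 4, 4, 2, 1, 1, 1, 1), 3, 3)
  expect_equal(raster_values(focal_mode(hs_raster(tie, res = 10), passes = 1))[2, 2], 2)
  expect_error(focal_mode(u, window = 4), "odd")
  expect_error(focal_mode(u, window = -1), "odd")
})

test_that("focal mode window matches a brute-force modal count", {
  set.seed(1)
  m <- matrix(sample(1:4, 20 * 20, TRUE), 20, 20)
  out <- raster_values(focal_mode(hs_raster(m, res = 10), passes = 1))
  for (pt in list(c(5, 7), c(1, 1), c(20, 13), c(12, 20))) {
    i <- pt[1]; j <- pt[2]
    win <- m[max(1, i - 1):min(20, i + 1), max(1, j - 1):min(20, j + 1)]
    tab <- table(win)
    modes <- as.integer(names(tab)[tab == max(tab)])
    expected <- if (length(modes) == 1) modes else m[i, j]
    expect_equal(out[i, j], expected)
  }
})

test_that("repeated focal mode reaches a fixed point or 2-cycle within 20 passes", {
  set.seed(7)
  for (rep in 1:3) {
    m <- hs_raster(matrix(sample(1:4, 30 * 30, TRUE), 30, 30), res = 10)
    states <- list(raster_values(m))
    converged <- FALSE
    for (p in 1:20) {
      m <- focal_mode(m, passes = 1)
      v <- raster_values(m)
      if (any(vapply(utils::tail(states, 2), identical, logical(1), v))) {
        converged <- TRUE
        break
      }
      states <- c(states, list(v))
    }
    expect_true(converged)
  }
})

test_that("patches below 0.4 ha are absorbed, at 0.4 ha retained", {
  mk <- function(ncell) {
    m <- matrix(90, 30, 30)
    m[cbind(rep(2:5, each = 10), rep(2:11, times = 4))[seq_len(ncell), ]] <- 10
    delineate_patches(categorize_canopy(hs_raster(m, res = 10)))
  }
  p39 <- mk(39)
  expect_equal(nrow(p39$patches), 1)
  p40 <- mk(40)
  expect_equal(nrow(p40$patches), 2)
  expect_equal(min(p40$patches$area_ha), 0.4)
  expect_setequal(p40$patches$cat_label, c("sparse", "dense"))
})

test_that("every cell belongs to exactly one retained patch", {
  set.seed(3)
  m <- matrix(runif(50 * 40, 0, 100), 50, 40)
  ps <- delineate_patches(focal_mode(categorize_canopy(hs_raster(m, res = 10))))
  labs <- raster_values(ps$labels)
  expect_true(all(labs %in% ps$patches$patch_id))
  expect_true(all(ps$patches$area_ha >= 0.4))
  expect_equal(sum(ps$patches$n_cells), 50 * 40)
  # rook components: same-label cells form connected sets of one category
  cat_by_lab <- ps$patches$category[labs]
  expect_equal(matrix(ps$patches$category[labs], 50, 40) * 1.0,
                   raster_values(ps$category))
})

test_that("single-class raster becomes one patch spanning the extent", {
  ps <- delineate_patches(categorize_canopy(flat_raster(90, 12)))
  expect_equal(nrow(ps$patches), 1)
  expect_equal(ps$patches$area_ha, 12 * 12 * 100 / 1e4)
  expect_equal(nrow(ps$segments), 0)
  expect_equal(ps$patches$perimeter_m, 4 * 120)
  expect_true(all(raster_values(edge_density(ps, 200)) == 0))
  expect_error(delineate_patches(hs_raster(matrix(numeric(0), 0, 0))), "empty")
})

test_that("edge density matches geometry and a brute-force window oracle", {
  m <- matrix(90, 120, 120); m[56:65, 56:65] <- 10
  ps <- delineate_patches(categorize_canopy(hs_raster(m, res = 10)))
  # one 100 m x 100 m interior patch: 400 m of boundary in a 400-m window
  expect_equal(raster_values(edge_density(ps, 400))[60, 60],
               0.4 / (pi * 0.4^2 / 1) / 1)
  expect_error(edge_density(ps, 5), "cell size")
  set.seed(11)
  m2 <- matrix(sample(c(20, 90), 45 * 38, TRUE, prob = c(0.3, 0.7)), 45, 38)
  ps2 <- delineate_patches(focal_mode(categorize_canopy(hs_raster(m2, res = 10))))
  for (radius in c(60, 150)) {
    got <- raster_values(edge_density(ps2, radius))
    want <- oracle_circular_sum(raster_values(ps2$edge_len), radius, 10)
    want <- (want / 1000) / (pi * radius^2 / 1e6)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-9)
  }
})

test_that("distance to edge is exact against a segment-by-segment oracle", {
  m <- matrix(90, 120, 120); m[56:65, 56:65] <- 10
  ps <- delineate_patches(categorize_canopy(hs_raster(m, res = 10)))
  expect_equal(distance_to_edge(ps, 600, 600), 50) # patch center
  expect_equal(distance_to_edge(ps, 550, 600), 0)  # on the boundary
  set.seed(5)
  px <- runif(25, 0, 1200); py <- runif(25, 0, 1200)
  got <- distance_to_edge(ps, px, py)
  want <- vapply(1:25, function(i) {
    oracle_point_segment_dist(px[i], py[i], ps$segments)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-6)
  expect_error(distance_to_edge(ps, -10, 50), "outside")
})

test_that("neighborhood mean equals the brute-force oracle and handles NA", {
  expect_equal(raster_values(neighborhood_mean(flat_raster(7, 8), 35)),
               matrix(7, 8, 8))
  set.seed(2)
  m <- matrix(runif(50 * 50, 0, 100), 50, 50)
  m[sample(2500, 30)] <- NA
  r <- hs_raster(m, res = 10)
  for (radius in c(5, 45, 120)) {
    got <- raster_values(neighborhood_mean(r, radius))
    want <- oracle_circular_stat(m, radius, 10)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1), na.rm = TRUE), 1e-9)
    expect_identical(is.na(got), is.na(want))
  }
  # radius below the cell size returns the cell itself
  expect_equal(raster_values(neighborhood_mean(r, 5)), m)
})

test_that("TPI is center minus neighborhood mean, antisymmetric in elevation", {
  expect_true(all(raster_values(tpi(flat_raster(300, 10), 30)) == 0))
  set.seed(4)
  m <- matrix(runif(40 * 40, 900, 1500), 40, 40)
  r <- hs_raster(m, res = 10)
  got <- raster_values(tpi(r, 100))
  want <- m - oracle_circular_stat(m, 100, 10, exclude_center = TRUE)
  expect_lt(max(abs(got - want)), 1e-9)
  neg <- raster_values(tpi(hs_raster(-m, res = 10), 100))
  expect_equal(neg, -got, tolerance = 1e-12)
  expect_error(tpi(r, 5), "cell size")
})

test_that("slope and linearized aspect match closed forms", {
  sa <- slope_linear_aspect(flat_raster(1000, 10))
  inner <- raster_values(sa$slope)[2:9, 2:9]
  expect_true(all(inner == 0))
  expect_true(all(raster_values(sa$aspect_lin)[2:9, 2:9] == 0.5))
  # inclined plane dz/dx = 0.1 -> slope atan(0.1); east-facing aspect
  z <- outer(1:20, 1:20, function(i, j) j * 1)
  sa2 <- slope_linear_aspect(hs_raster(z, res = 10))
  expect_equal(raster_values(sa2$slope)[10, 10], atan(0.1) * 180 / pi)
  # downslope azimuth 270 deg (west... east-up plane falls to the west)
  idx <- raster_values(sa2$aspect_lin)[10, 10]
  expect_equal(idx, (1 - cos((270 - 30) * pi / 180)) / 2)
  # a plane falling toward azimuth 30 deg has aspect index 0
  z30 <- outer(1:30, 1:30, function(i, j) {
    -(sin(30 * pi / 180) * j * 10 + cos(30 * pi / 180) * i * 10) * 0.1
  })
  expect_equal(raster_values(slope_linear_aspect(hs_raster(z30, res = 10))$aspect_lin)[15, 15],
               0, tolerance = 1e-8)
})

test_that("extract_covariates agrees with single-point recomputation", {
  ls <- generate_landscape(seed = 8, extent = c(600, 500), resolution = 10,
                           autocorrelation_range = 120)
  ps <- delineate_patches(focal_mode(categorize_canopy(ls$canopy)))
  pts <- tibble::tibble(x = c(105, 333, 471), y = c(77, 240, 455))
  out <- extract_covariates(pts, ls, ps, scales = c(100, 400))
  expect_equal(nrow(out), 3)
  for (i in 1:3) {
    cm <- oracle_circular_stat(raster_values(ls$canopy), 100, 10)
    idx <- cell_index(ls$canopy, pts$x[i], pts$y[i])
    expect_equal(out$canopy_100[i], cm[idx$row, idx$col], tolerance = 1e-9)
  }
  # vegclass proportions lie in [0, 1] and sum to 1 at each scale
  veg <- out[, grep("^veg[0-9]+_100$", names(out))]
  expect_true(all(veg >= 0 & veg <= 1))
  expect_equal(rowSums(veg), rep(1, 3), tolerance = 1e-9)
  expect_equal(out$patch_cat, ps$patches$cat_label[
    raster_extract(ps$labels, pts$x, pts$y)])
  # out-of-extent point warns and carries NA covariates
  expect_warning(out2 <- extract_covariates(tibble::tibble(x = -50, y = 10),
                                            ls, ps, scales = 100), "outside")
  expect_true(is.na(out2$canopy_100))
})

test_that("disturbed-area flags drop points before extraction", {
  ls <- generate_landscape(seed = 8, extent = c(300, 300))
  v <- matrix(0, 30, 30); v[, 1:15] <- 1 # west half disturbed after measurement
  flag <- hs_raster(v, res = 10)
  pts <- tibble::tibble(x = c(50, 250), y = c(150, 150))
  out <- extract_covariates(pts, ls, NULL, scales = 100, disturbed = flag)
  expect_equal(out$x, 250)
})
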