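test_that("generate_landscape is deterministic and validates inputs", {
  a <- generate_landscape(seed = 7, extent = c(500, 400))
  b <- generate_landscape(seed = 7, extent = c(500, 400))
  expect_identical(raster_values(a$canopy), raster_values(b$canopy))
  expect_identical(raster_values(a$vegclass), raster_values(b$vegclass))
  expect_true(all(raster_values(a$canopy) >= 0 & raster_values(a$canopy) <= 100))
  expect_error(generate_landscape(extent = c(-10, 100)), "positive")
  expect_error(generate_landscape(resolution = 0), "positive")
  expect_error(generate_landscape(autocorrelation_range = 5, resolution = 10),
               "autocorrelation_range")
})

test_that("autocorrelation range at the resolution gives white noise (Moran's I ~ 0)", {
  ls <- generate_landscape(seed = 3, extent = c(400, 400),
                           autocorrelation_range = 10, resolution = 10)
  i_white <- oracle_morans_i(raster_values(ls$canopy))
  expect_lt(abs(i_white), 0.06)
  ls2 <- generate_landscape(seed = 3, extent = c(400, 400),
                            autocorrelation_range = 200, resolution = 10)
  expect_gt(oracle_morans_i(raster_values(ls2$canopy)), 0.5)
})

test_that("degenerate class mixture yields a constant vegclass band", {
  ls <- generate_landscape(seed = 5, extent = c(300, 300),
                           class_mixture = c(0, 1, 0))
  expect_equal(unique(as.vector(raster_values(ls$vegclass))), 2)
})

test_that("dense-skewed default canopy puts ~79% of cells above 75%", {
  ls <- generate_landscape(seed = 9, extent = c(1500, 1500))
  expect_equal(mean(raster_values(ls$canopy) > 75), 0.79, tolerance = 0.05)
})

test_that("simulate_individual is deterministic and schedules fixes per state", {
  ls <- generate_landscape(seed = 2, extent = c(800, 800))
  tr <- sim_truth()
  a <- simulate_individual(ls, tr, n_fixes = 60, seed = 11)
  b <- simulate_individual(ls, tr, n_fixes = 60, seed = 11)
  expect_identical(a, b)
  gaps <- as.numeric(diff(a$timestamp), units = "mins")
  expect_equal(gaps, ifelse(a$true_state[-60] == "moving", 20, 120))
  # accelerometer values land on the right side of the behavior thresholds
  expect_true(all(a$activity[a$true_state == "resting"] < 6400))
  expect_true(all(a$activity[a$true_state == "moving"] > 6400))
})

test_that("with zero selection, used covariates match availability", {
  ls <- generate_landscape(seed = 4, extent = c(1000, 1000),
                           canopy_beta = c(1, 1))
  tr0 <- sim_truth(beta_moving = c(canopy = 0), beta_resting = c(canopy = 0),
                   relocation_radius = c(moving = 3000, resting = 3000))
  n_rej <- 0
  for (s in 1:100) {
    trk <- simulate_individual(ls, tr0, n_fixes = 80, seed = s)
    av <- sample_availability(rect_polygon(0, 1000, 0, 1000), 80, ratio = 2,
                              seed = 10000 + s)
    p <- stats::wilcox.test(raster_extract(ls$canopy, trk$x, trk$y),
                            raster_extract(ls$canopy, av$x, av$y))$p.value
    if (p < 0.01) n_rej <- n_rej + 1
  }
  expect_lte(n_rej, 5) # two-sample test rejects in <= 5% of 100 replicates
})

test_that("positive resting canopy selection raises used canopy above availability", {
  ls <- generate_landscape(seed = 6, extent = c(1200, 1200), canopy_beta = c(1, 1))
  tr <- sim_truth(beta_moving = c(canopy = 0), beta_resting = c(canopy = 0.08),
                  switch_prob = c(0.5, 0.2))
  trk <- simulate_individual(ls, tr, n_fixes = 1200, seed = 8)
  rest <- dplyr::filter(trk, true_state == "resting")
  expect_gt(nrow(rest), 500)
  av <- sample_availability(rect_polygon(0, 1200, 0, 1200), 1000, ratio = 1, seed = 1)
  expect_gt(mean(raster_extract(ls$canopy, rest$x, rest$y)),
            mean(raster_extract(ls$canopy, av$x, av$y)) + 5)
})

test_that("gamma_ssf kernel also prefers high-weight habitat and errors on tiny regions", {
  ls <- generate_landscape(seed = 6, extent = c(1200, 1200), canopy_beta = c(1, 1))
  tr <- sim_truth(beta_moving = c(canopy = 0.08), beta_resting = c(canopy = 0.08),
                  switch_prob = c(0, 0), step_mean = c(moving = 120, resting = 15))
  trk <- simulate_individual(ls, tr, n_fixes = 600, seed = 9, kernel = "gamma_ssf")
  av <- sample_availability(rect_polygon(0, 1200, 0, 1200), 1000, ratio = 1, seed = 2)
  expect_gt(mean(raster_extract(ls$canopy, trk$x, trk$y)),
            mean(raster_extract(ls$canopy, av$x, av$y)) + 5)
  expect_error(
    simulate_individual(ls, tr, n_fixes = 5, seed = 1, kernel = "gamma_ssf",
                        region = c(0, 100, 0, 100)),
    "too small"
  )
})

test_that("make_population spans an availability gradient and is deterministic", {
  spec <- list(seed = 13, extent = c(2400, 800), resolution = 10,
               autocorrelation_range = 150, canopy_beta = c(1, 1),
               canopy_gradient = 0.8)
  tr <- sim_truth(beta_moving = c(canopy = 0), beta_resting = c(canopy = 0))
  pop <- make_population(spec, tr, n_individuals = 12, n_fixes = 20, seed = 5,
                         availability_gradient = "canopy")
  expect_equal(nrow(pop$individuals), 12)
  expect_gt(diff(range(pop$individuals$mean_avail_canopy)), 10)
  # monotone west-east availability
  expect_gt(cor(seq_len(12), pop$individuals$mean_avail_canopy,
                method = "spearman"), 0.9)
  pop2 <- make_population(spec, tr, n_individuals = 12, n_fixes = 20, seed = 5,
                          availability_gradient = "canopy")
  expect_identical(pop$tracks, pop2$tracks)
})

test_that("gradient is refused on a flat landscape and ignored for one individual", {
  flat <- list(seed = 1, extent = c(1000, 600), canopy_beta = c(50, 1))
  tr <- sim_truth()
  expect_error(
    make_population(flat, tr, n_individuals = 6, n_fixes = 10, seed = 2,
                    availability_gradient = "canopy"),
    "infeasible"
  )
  expect_warning(
    make_population(flat, tr, n_individuals = 1, n_fixes = 10, seed = 2,
                    availability_gradient = "canopy"),
    "ignored"
  )
})
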