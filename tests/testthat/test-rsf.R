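toy_design <- function(seed = 1, n_id = 4, n_used = 30, ratio = 10) {
  set.seed(seed)
  ids <- sprintf("F%02d", seq_len(n_id))
  used <- tibble::tibble(
    individual_id = rep(ids, each = n_used),
    canopy_100 = runif(n_id * n_used, 40, 100),
    canopy_400 = runif(n_id * n_used, 40, 100),
    elev = rnorm(n_id * n_used, 1200, 80)
  )
  avail <- tibble::tibble(
    individual_id = rep(ids, each = n_used * ratio),
    canopy_100 = runif(n_id * n_used * ratio, 0, 100),
    canopy_400 = runif(n_id * n_used * ratio, 0, 100),
    elev = rnorm(n_id * n_used * ratio, 1200, 80)
  )
  build_design(used, avail, "moving", ratio = ratio)
}

test_that("build_design stacks 1 : ratio rows and shares the availability pool", {
  d <- toy_design(n_id = 3, n_used = 100, ratio = 20)
  expect_equal(nrow(d), 3 * (100 + 2000))
  counts <- dplyr::count(dplyr::group_by(d, individual_id), response)
  expect_true(all(counts$n[counts$response == 0] ==
                    20 * counts$n[counts$response == 1]))
  # a smaller design's availability is a prefix of the shared pool
  used1 <- tibble::tibble(individual_id = "A", cov = 1:5 * 1.0)
  pool <- tibble::tibble(individual_id = "A", cov = 1:200 * 1.0)
  d_small <- build_design(used1[1:2, ], pool, ratio = 20)
  d_big <- build_design(used1, pool, ratio = 20)
  small_avail <- d_small$cov[d_small$response == 0]
  big_avail <- d_big$cov[d_big$response == 0]
  expect_identical(small_avail, big_avail[seq_along(small_avail)])
  expect_error(build_design(used1, pool[0, ], ratio = 2), "no available")
  expect_error(build_design(used1[0, ], pool), "no used")
})

test_that("standardization z-scores columns and inverts exactly", {
  d <- toy_design()
  ds <- standardize_design(d)
  for (col in c("canopy_100", "canopy_400", "elev")) {
    expect_equal(mean(ds[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(ds[[col]]), 1, tolerance = 1e-12)
  }
  back <- unstandardize_design(ds)
  expect_equal(back$canopy_100, d$canopy_100, tolerance = 1e-12)
  d$flat <- 5
  expect_error(standardize_design(d), "flat")
})

test_that("correlation screen flags |r| > 0.6 strictly", {
  d <- toy_design()
  d$canopy_dup <- d$canopy_100
  sc <- screen_correlation(d)
  expect_false(sc$admissible["canopy_100", "canopy_dup"])
  # the rule is a strict ">": a pair exactly at the threshold stays admissible
  a <- c(-3, -1, 1, 3) / sqrt(20)
  b <- c(1, -1, -1, 1) / 2
  d2 <- tibble::tibble(response = c(1, 0, 0, 0), individual_id = "x",
                       u = a, v = 0.6 * a + 0.8 * b)
  r <- abs(cor(d2$u, d2$v)) # 0.6 up to rounding
  expect_equal(r, 0.6, tolerance = 1e-12)
  expect_true(screen_correlation(d2, threshold = r)$admissible["u", "v"])
  expect_false(screen_correlation(d2, threshold = r * 0.999)$admissible["u", "v"])
  # independent columns essentially never get flagged
  flags <- vapply(1:30, function(s) {
    set.seed(s)
    dd <- tibble::tibble(response = 0, individual_id = "x",
                         p = rnorm(10000), q = rnorm(10000))
    nrow(screen_correlation(dd)$inadmissible) > 0
  }, logical(1))
  expect_lte(mean(flags), 0.01)
  expect_error(screen_correlation(d[, c("response", "individual_id")]), ">= 2")
})

test_that("screened covariate pairs are refused by the model builder", {
  d <- standardize_design(toy_design())
  d$canopy_dup <- d$canopy_100
  sc <- screen_correlation(d)
  expect_error(fit_mixed_logistic(response ~ canopy_100 + canopy_dup, d,
                                  screen = sc), "collinear")
  expect_s3_class(fit_mixed_logistic(response ~ canopy_100 + elev, d,
                                     screen = sc), "rsf_fit")
})

test_that("the 2x2 design recovers the closed-form log odds ratio", {
  d <- tibble::tibble(
    response = c(rep(1, 100), rep(0, 2000)),
    at_a = c(rep(1, 80), rep(0, 20), rep(1, 1000), rep(0, 1000)),
    individual_id = "F01"
  )
  fit <- fit_mixed_logistic(response ~ at_a, d)
  expect_equal(fit$coefficients$estimate[2], log(4), tolerance = 1e-3)
  expect_equal(fit$K, 3) # intercept + covariate + random-intercept variance
})

test_that("a single individual reproduces plain logistic regression", {
  set.seed(31)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * x))
  d <- tibble::tibble(response = y, x = x, individual_id = "solo")
  fit <- fit_mixed_logistic(response ~ x, d)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$LL, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("null-covariate Wald CIs cover zero at about the nominal rate", {
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 2000
    d <- tibble::tibble(
      response = rep(c(1, 0), c(100, 1900)),
      x = rnorm(n),
      individual_id = rep(sprintf("I%d", 1:4), n / 4)
    )
    fit <- fit_mixed_logistic(response ~ x, d)
    fit$coefficients$conf_low[2] <= 0 && fit$coefficients$conf_high[2] >= 0
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.995)
})

test_that("AICc arithmetic matches the definition and its large-n limit", {
  expect_equal(aicc(-100, 3, 1000), 200 + 6 + 24 / 996)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "exceed")
})

test_that("model comparison sorts, zeroes the best delta and normalizes weights", {
  d <- standardize_design(toy_design(seed = 3))
  fits <- list(
    canopy = fit_mixed_logistic(response ~ canopy_100, d),
    both = fit_mixed_logistic(response ~ canopy_100 + elev, d),
    null = fit_mixed_logistic(response ~ 1, d)
  )
  tab <- compare_models(fits)
  expect_equal(tab$delta_AICc[1], 0)
  expect_equal(sum(tab$weight), 1)
  expect_true(!is.unsorted(tab$AICc))
  other <- toy_design(seed = 4, n_id = 2)
  fits$alien <- fit_mixed_logistic(response ~ canopy_100,
                                   standardize_design(other))
  expect_error(compare_models(fits), "identical data")
})

test_that("univariate scale selection finds the generative scale", {
  wins <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    set.seed(s + 400)
    n_id <- 4; n_used <- 50; ratio <- 10
    mk <- function(n) {
      z <- matrix(rnorm(n * 2), n, 2)
      tibble::tibble(canopy_100 = z[, 1] * 0.6 + z[, 2] * 0.8, canopy_400 = z[, 2])
    }
    av <- mk(n_id * n_used * ratio)
    av$individual_id <- rep(sprintf("I%d", 1:n_id), each = n_used * ratio)
    # used points tilted by the 400-m covariate only
    cand <- mk(n_id * n_used * 40)
    keep <- runif(nrow(cand)) < plogis(1.2 * cand$canopy_400 - 2)
    used <- cand[keep, ][seq_len(n_id * n_used), ]
    used$individual_id <- rep(sprintf("I%d", 1:n_id), each = n_used)
    d <- standardize_design(build_design(used, av, ratio = ratio))
    if (select_scale_univariate(d, "canopy") == 400) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("scale selection tie-breaks to the smallest scale", {
  d <- toy_design()
  d$canopy_400 <- d$canopy_100 # identical at both scales
  d <- standardize_design(d)
  expect_equal(as.numeric(select_scale_univariate(d, "canopy")), 100)
  expect_equal(as.numeric(select_scale_univariate(d, "canopy", scales = 100)), 100)
  expect_error(select_scale_univariate(d, "nonexistent"), "no scale")
})

test_that("relative selection predictions are normalized, monotone and stable", {
  d <- standardize_design(toy_design(seed = 5))
  fit <- fit_mixed_logistic(response ~ canopy_100, d)
  grid <- tibble::tibble(canopy_100 = seq(-1, 1, length.out = 11))
  pr <- predict_relative_selection(fit, grid)
  expect_equal(max(pr$relative_selection), 1)
  b <- fit$coefficients$estimate[2]
  expect_true(all(diff(pr$relative_selection) * sign(b) > 0))
  expect_error(predict_relative_selection(fit, tibble::tibble(zzz = 1)), "unknown")
  expect_warning(predict_relative_selection(
    fit, tibble::tibble(canopy_100 = 99)), "extrapolates")
  # duplicating availability rows leaves relative predictions unchanged
  d2 <- dplyr::bind_rows(unstandardize_design(d),
                         dplyr::filter(unstandardize_design(d), response == 0))
  fit2 <- fit_mixed_logistic(response ~ canopy_100, standardize_design(d2))
  grid_raw <- tibble::tibble(canopy_100 = c(30, 50, 70))
  to_std <- function(f, g) {
    sc <- f$scaling
    dplyr::mutate(g, canopy_100 = (canopy_100 - sc$mean[sc$column == "canopy_100"]) /
                    sc$sd[sc$column == "canopy_100"])
  }
  p1 <- predict_relative_selection(fit, to_std(fit, grid_raw))$relative_selection
  p2 <- predict_relative_selection(fit2, to_std(fit2, grid_raw))$relative_selection
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("behavior interaction models use dense canopy and moving as references", {
  set.seed(12)
  mk <- function(n_used, p_dense) {
    ids <- sprintf("F%02d", 1:6)
    purrr::map_dfr(ids, function(id) {
      cats <- function(n, pd) sample(canopy_levels, n, TRUE,
                                     prob = c((1 - pd) / 3, (1 - pd) / 3,
                                              (1 - pd) / 3, pd))
      tibble::tibble(
        response = c(rep(1, n_used), rep(0, n_used * 10)),
        individual_id = id,
        patch_cat = c(cats(n_used, p_dense), cats(n_used * 10, 0.5))
      )
    })
  }
  fits <- suppressWarnings(
    fit_behavior_interactions(mk(60, 0.7), mk(30, 0.9),
                              models = "canopy_category")
  )
  terms <- fits$canopy_category$coefficients$term
  # coefficients are reported for sparse/open/moderate relative to dense
  expect_false(any(grepl("canopy_catdense", terms)))
  expect_true(any(grepl("stateresting", terms)))
  expect_true(all(c("canopy_catsparse", "canopy_catopen", "canopy_catmoderate")
                  %in% terms))
})

test_that("state interactions are null-calibrated when behaviors share selection", {
  w <- validation_landscape("interaction", seed = 43)
  same <- sim_truth(beta_moving = c(canopy_100 = 0.05),
                    beta_resting = c(canopy_100 = 0.05),
                    switch_prob = c(0.10, 0.30),
                    relocation_radius = c(moving = 6000, resting = 6000))
  hits <- vapply(1:15, function(s) {
    d <- validation_designs(w, same, seed = s, n_fixes = 80,
                            placement = "shared")
    fits <- suppressWarnings(fit_behavior_interactions(
      d$design_moving, d$design_resting, models = "canopy_category"))
    co <- fits$canopy_category$coefficients
    i <- match("stateresting", co$term)
    co$conf_low[i] > 0 | co$conf_high[i] < 0
  }, logical(1))
  expect_lte(mean(hits), 0.27) # ~5% nominal; generous bound for 15 replicates
})
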