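# Simulation-validation scenarios: small synthetic worlds with known truth,
# shared by the test suite and the acceptance script. Problem sizes keep the
# study's design ratios (12 individuals, 1:20 availability, minority resting
# state) on landscapes a few kilometres across; within each replicate the
# animal's true home-range rectangle is the availability polygon, so the
# fitted model is correctly specified relative to the known coefficients.

#' Landscape and covariate layers for a validation scenario
#'
#' Three stock worlds: `"recovery"` (dense-skewed canopy, no gradient, truth
#' on 100-m canopy and TPI), `"proportional"` (log-scale west-east canopy
#' gradient, 15-90%, no selection) and `"specialist"` (full canopy support
#' everywhere but a west-east gradient in the dense fraction, the contrast
#' that lets a fixed dense-canopy preference show up as a decreasing
#' functional response).
#'
#' @param scenario scenario name.
#' @param seed landscape seed.
#' @return List with `landscape` and the selection-kernel `layers`.
#' @export
validation_landscape <- function(scenario = c("recovery", "proportional",
                                              "specialist", "interaction"),
                                 seed = 21L) {
  scenario <- match.arg(scenario)
  landscape <- switch(
    scenario,
    recovery = ,
    interaction = generate_landscape(
      seed = seed, extent = c(2000, 2000), resolution = 10,
      autocorrelation_range = 250, canopy_beta = c(5.4, 1)
    ),
    proportional = generate_landscape(
      seed = seed, extent = c(3000, 2000), resolution = 10,
      autocorrelation_range = 200, canopy_beta = c(1, 1),
      canopy_range = c(15, 90), canopy_scale = "log", canopy_gradient = 0.8
    ),
    specialist = generate_landscape(
      seed = seed, extent = c(3000, 2000), resolution = 10,
      autocorrelation_range = 200, canopy_shape_gradient = c(1, 2.5)
    )
  )
  layers <- list(canopy_100 = neighborhood_mean(landscape$canopy, 100))
  if (scenario == "recovery") {
    layers$tpi_100 <- tpi(landscape$elevation, 100)
    sa <- slope_linear_aspect(landscape$elevation)
    layers$elev <- landscape$elevation
    layers$slope <- sa$slope
  }
  out <- list(landscape = landscape, layers = layers)
  if (scenario == "interaction") {
    # smoothed canopy classes for the category x state models
    out$catsm <- focal_mode(categorize_canopy(landscape$canopy))
  }
  out
}

#' Truth used by each validation scenario
#'
#' Equilibrium sampling (relocation radius beyond the home-range diameter)
#' makes each state's fixes independent draws from its selection surface,
#' which is the regime where the use-availability estimator is correctly
#' specified and known coefficients are recoverable.
#'
#' @param scenario scenario name.
#' @return A [sim_truth].
#' @export
validation_truth <- function(scenario = c("recovery", "proportional",
                                          "specialist", "interaction")) {
  scenario <- match.arg(scenario)
  eq <- c(moving = 6000, resting = 6000)
  switch(
    scenario,
    recovery = sim_truth(
      beta_moving = c(canopy_100 = 0.05, tpi_100 = 0.02),
      beta_resting = c(canopy_100 = 0.09),
      switch_prob = c(0.06, 0.35), relocation_radius = eq
    ),
    proportional = sim_truth(
      beta_moving = c(canopy_100 = 0), beta_resting = c(canopy_100 = 0),
      switch_prob = c(0.12, 0.28), relocation_radius = eq
    ),
    specialist = sim_truth(
      beta_moving = c(canopy_100 = 0), beta_resting = c(canopy_100 = 0.10),
      switch_prob = c(0.12, 0.28), relocation_radius = eq
    ),
    # resting prefers canopy much more strongly than moving; resting fixes
    # ~25% of the schedule so the absolute resting sample is comparable to a
    # season of field data
    interaction = sim_truth(
      beta_moving = c(canopy_100 = 0.02), beta_resting = c(canopy_100 = 0.12),
      switch_prob = c(0.10, 0.30), relocation_radius = eq
    )
  )
}

#' Simulate one validation replicate and build its behavior designs
#'
#' Simulates a 12-animal population on the scenario landscape, samples each
#' individual's availability pool uniformly from its known home-range
#' rectangle (1:20 within each behavior dataset, resting availability nested
#' in moving's as a shared pool), extracts the kernel covariates at every
#' point, and returns the moving and resting use-availability designs.
#'
#' @param world result of [validation_landscape].
#' @param truth a [sim_truth] (see [validation_truth]).
#' @param seed replicate seed.
#' @param n_individuals,n_fixes population size (defaults 12 x 150).
#' @param ratio availability ratio (default 20).
#' @param placement home-range placement (see [make_population]): `"shared"`
#'   for the recovery/interaction scenarios, `"strips"` for the gradient
#'   (functional-response) scenarios.
#' @return List: `design_moving`, `design_resting` (unstandardized),
#'   `population`.
#' @export
validation_designs <- function(world, truth, seed, n_individuals = 12,
                               n_fixes = 150, ratio = 20,
                               placement = c("strips", "shared")) {
  placement <- match.arg(placement)
  pop <- make_population(world$landscape, truth,
                         n_individuals = n_individuals, n_fixes = n_fixes,
                         seed = seed, covariates = world$layers,
                         availability_gradient = "none", placement = placement)
  ids <- pop$individuals$individual_id
  used_m <- dplyr::filter(pop$tracks, .data$true_state == "moving")
  used_r <- dplyr::filter(pop$tracks, .data$true_state == "resting")
  av_seeds <- spawn_seeds(seed + 1L, length(ids))
  pool <- purrr::map_dfr(seq_along(ids), function(i) {
    rg <- pop$individuals$region[[i]]
    n <- max(sum(used_m$individual_id == ids[i]),
             sum(used_r$individual_id == ids[i]), 1)
    av <- sample_availability(rect_polygon(rg[1], rg[2], rg[3], rg[4]),
                              n, ratio = ratio, seed = av_seeds[i])
    dplyr::mutate(av, individual_id = ids[i])
  })
  ex <- function(p) {
    for (nm in names(world$layers)) {
      p[[nm]] <- raster_extract(world$layers[[nm]], p$x, p$y)
    }
    if (!is.null(world$catsm)) {
      p$patch_cat <- world$catsm$levels[raster_extract(world$catsm, p$x, p$y)]
    }
    p
  }
  list(
    design_moving = build_design(ex(used_m), ex(pool), "moving", ratio = ratio),
    design_resting = build_design(ex(used_r), ex(pool), "resting", ratio = ratio),
    population = pop
  )
}

#' Replicate-level validation runs
#'
#' Repeated-simulation checks of the whole estimation chain against known
#' truth. `validate_recovery` measures per-coefficient 95% CI coverage and
#' how often the generative hypothesis model wins the AICc competition;
#' `validate_functional_response` tallies functional-response labels under
#' the specialist and proportional worlds; `validate_interactions` tracks
#' the sign and significance of the resting-state contrast at dense canopy
#' when resting truly selects canopy more strongly than moving.
#'
#' @param n_reps number of simulation replicates.
#' @param seed master seed (replicate seeds are spawned from it).
#' @param n_fixes fixes per individual and replicate.
#' @param landscape_seed seed of the shared scenario landscape.
#' @return A tibble with one row per replicate.
#' @name validation-runs
NULL

#' @rdname validation-runs
#' @export
validate_recovery <- function(n_reps = 50, seed = 1L, n_fixes = 80,
                              landscape_seed = 21L) {
  world <- validation_landscape("recovery", seed = landscape_seed)
  truth <- validation_truth("recovery")
  seeds <- spawn_seeds(seed, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    d <- validation_designs(world, truth, seed = seeds[r], n_fixes = n_fixes,
                            placement = "shared")
    dm <- standardize_design(d$design_moving)
    dr <- standardize_design(d$design_resting)
    fits <- list(
      generative = fit_mixed_logistic(response ~ canopy_100 + tpi_100, dm),
      canopy = fit_mixed_logistic(response ~ canopy_100, dm),
      abiotic = fit_mixed_logistic(response ~ elev + slope, dm),
      null = fit_mixed_logistic(response ~ 1, dm)
    )
    fit_r <- fit_mixed_logistic(response ~ canopy_100, dr)
    tm <- tidy(fits$generative, unstandardize = TRUE)
    trr <- tidy(fit_r, unstandardize = TRUE)
    bm <- truth$beta$moving; br <- truth$beta$resting
    covers <- function(tab, term, value) {
      i <- match(term, tab$term)
      tab$conf_low[i] <= value & tab$conf_high[i] >= value
    }
    tibble::tibble(
      rep = r,
      cover_moving_canopy = covers(tm, "canopy_100", bm[["canopy_100"]]),
      cover_moving_tpi = covers(tm, "tpi_100", bm[["tpi_100"]]),
      cover_resting_canopy = covers(trr, "canopy_100", br[["canopy_100"]]),
      generative_wins = compare_models(fits)$model[1] == "generative"
    )
  })
}

#' @rdname validation-runs
#' @param scenario `"specialist"` or `"proportional"`.
#' @export
validate_functional_response <- function(scenario = c("specialist", "proportional"),
                                         n_reps = 50, seed = 1L, n_fixes = 150,
                                         landscape_seed = 21L) {
  scenario <- match.arg(scenario)
  world <- validation_landscape(scenario, seed = landscape_seed)
  truth <- validation_truth(scenario)
  seeds <- spawn_seeds(seed, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    d <- validation_designs(world, truth, seed = seeds[r], n_fixes = n_fixes,
                            placement = "strips")
    fr <- functional_response_suite(d$design_moving, d$design_resting,
                                    "canopy_100", min_used = 5)
    tibble::tibble(
      rep = r,
      label_moving = fr$label[fr$behavior == "moving"],
      label_resting = fr$label[fr$behavior == "resting"],
      slope_moving = fr$slope[fr$behavior == "moving"],
      slope_resting = fr$slope[fr$behavior == "resting"],
      false_fr_moving = fr$label[fr$behavior == "moving"] %in%
        c("decreasing_FR", "increasing_FR"),
      false_fr_resting = fr$label[fr$behavior == "resting"] %in%
        c("decreasing_FR", "increasing_FR")
    )
  })
}

#' @rdname validation-runs
#' @export
validate_interactions <- function(n_reps = 50, seed = 1L, n_fixes = 250,
                                  landscape_seed = 31L) {
  world <- validation_landscape("interaction", seed = landscape_seed)
  truth <- validation_truth("interaction")
  seeds <- spawn_seeds(seed, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    d <- validation_designs(world, truth, seed = seeds[r], n_fixes = n_fixes,
                            placement = "shared")
    fits <- suppressWarnings(fit_behavior_interactions(
      d$design_moving, d$design_resting, models = "canopy_category"))
    co <- fits$canopy_category$coefficients
    i <- match("stateresting", co$term)
    tibble::tibble(
      rep = r,
      resting_dense_contrast = co$estimate[i],
      conf_low = co$conf_low[i],
      conf_high = co$conf_high[i],
      significant_positive = co$conf_low[i] > 0
    )
  })
}
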