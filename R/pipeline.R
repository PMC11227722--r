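#' Build a pipeline run configuration
#'
#' Collects every constant the analysis depends on: the behavior thresholds
#' (accelerometer 6400/48000; 20-min movement and 120 +/- 5 min resting
#' intervals), availability design (1:20 ratio, 5-km home-range buffer),
#' patch rules (quartile canopy bins, two-pass 3x3 mode filter, 0.4-ha
#' minimum patch), the three neighborhood scales, the |r| > 0.6 collinearity
#' screen, the hypothesis model sets, and the synthetic-scenario parameters.
#' Override any element by name.
#'
#' @param ... named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    landscape = list(extent = c(3000, 3000), resolution = 10,
                     autocorrelation_range = 300,
                     class_mixture = c(0.5, 0.3, 0.2),
                     canopy_beta = c(5.4, 1), canopy_gradient = 0),
    population = list(n_individuals = 12, n_fixes = 200,
                      availability_gradient = "none", margin = 100),
    truth = list(beta_moving = c(canopy = 0.03),
                 beta_resting = c(canopy = 0.08),
                 switch_prob = c(0.05, 0.45)),
    thresholds = list(accel_rest = 6400, accel_fast = 48000,
                      rest_interval = 120, rest_tolerance = 5,
                      move_target = 20, move_tolerance = 2),
    availability = list(ratio = 20, buffer = 5000),
    patches = list(min_area_ha = 0.4, window = 3, passes = 2),
    scales = c(100, 400, 4000),
    correlation_threshold = 0.6,
    edge_scale = 400,
    hypotheses = list(
      canopy = c("canopy"),
      abiotic = c("elev", "slope", "tpi", "aspect_lin"),
      openings = c("edge_density", "patch_size_ha"),
      composition = c("veg1", "veg2", "veg3")
    ),
    fr_covariates = c("canopy", "edge_density"),
    fr_min_used = 5
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

covariate_registry <- function(config) {
  sc <- config$scales
  k <- length(config$landscape$class_mixture)
  c(
    paste0("canopy_", rep(sc, each = 1)),
    as.vector(outer(paste0("veg", seq_len(k), "_"), sc, paste0)),
    "elev", "slope", "aspect_lin",
    paste0("tpi_", sc),
    "patch_size_ha", "dist_edge", "canopy_cat",
    paste0("edge_density_", sc),
    # base names resolvable by univariate scale selection
    "canopy", paste0("veg", seq_len(k)), "tpi", "edge_density"
  )
}

#' Validate a run configuration
#'
#' Checks every invariant and reports all violations at once, not just the
#' first: positive thresholds, strictly increasing scales, ratio >= 1,
#' hypothesis covariates present in the covariate registry, and a sane
#' correlation threshold.
#'
#' @param config a [run_config].
#' @return Tibble of violations (`field`, `problem`); zero rows means valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, problem) v[[length(v) + 1]] <<- tibble::tibble(
    field = field, problem = problem)

  th <- config$thresholds
  for (nm in names(th)) {
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0) {
      bad(paste0("thresholds$", nm), "must be a positive number")
    }
  }
  if (is.null(config$availability$ratio) || config$availability$ratio < 1) {
    bad("availability$ratio", "must be >= 1")
  }
  if (config$availability$buffer < 0) bad("availability$buffer", "must be >= 0")
  if (is.unsorted(config$scales, strictly = TRUE)) {
    bad("scales", "must be strictly increasing")
  }
  if (any(config$scales <= 0)) bad("scales", "must be positive")
  if (config$patches$min_area_ha <= 0) bad("patches$min_area_ha", "must be > 0")
  if (config$correlation_threshold <= 0 || config$correlation_threshold > 1) {
    bad("correlation_threshold", "must be in (0, 1]")
  }
  reg <- covariate_registry(config)
  for (h in names(config$hypotheses)) {
    unknown <- setdiff(config$hypotheses[[h]], reg)
    if (length(unknown)) {
      bad(paste0("hypotheses$", h),
          paste("unknown covariate(s):", paste(unknown, collapse = ", ")))
    }
  }
  unknown <- setdiff(config$fr_covariates, reg)
  if (length(unknown)) {
    bad("fr_covariates",
        paste("unknown covariate(s):", paste(unknown, collapse = ", ")))
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), problem = character())
}

resolve_scale <- function(name, design, scales) {
  # base names without a _<scale> suffix get their scale picked univariately
  if (name %in% names(design)) return(name)
  s <- tryCatch(select_scale_univariate(design, name, scales),
                error = function(e) NULL)
  if (is.null(s)) stop("cannot resolve covariate ", name, call. = FALSE)
  paste0(name, "_", s)
}

#' Run the full synthetic-scenario pipeline
#'
#' Simulate -> classify and thin -> home ranges and availability ->
#' covariates -> behavior-specific RSFs with AICc competition -> behavior
#' interaction models -> functional responses. All stage seeds are spawned
#' deterministically from `config$seed`, so a rerun with the same config is
#' identical. Outputs (model-selection and coefficient CSVs, functional
#' response CSV, manifest JSON) are written under `out_dir`, each stamped
#' with the config hash.
#'
#' @param config a [run_config] (must validate).
#' @param out_dir output directory.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with all intermediate and final objects.
#' @export
run_pipeline <- function(config, out_dir = tempfile("habsel_run_"),
                         quiet = FALSE) {
  viol <- validate_config(config)
  if (nrow(viol)) {
    stop("invalid config:\n", paste0("  ", viol$field, ": ", viol$problem,
                                     collapse = "\n"), call. = FALSE)
  }
  hash <- rlang::hash(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[habsel] ", ...)
  seeds <- spawn_seeds(config$seed, 4L)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------------
  landscape <- stage("simulate", do.call(generate_landscape,
                                         c(config$landscape, list(seed = seeds[1]))))
  truth <- do.call(sim_truth, config$truth)
  pop <- stage("simulate", do.call(make_population, c(
    list(landscape = landscape, truth = truth, seed = seeds[2]),
    config$population
  )))
  say("simulated ", nrow(pop$tracks), " fixes for ",
      nrow(pop$individuals), " individuals")

  # -- preprocess -------------------------------------------------------------
  th <- config$thresholds
  tracks <- stage("preprocess", classify_behavior(
    pop$tracks,
    accel_rest_threshold = th$accel_rest, accel_fast_threshold = th$accel_fast,
    rest_interval = th$rest_interval, interval_tolerance = th$rest_tolerance
  ))
  moving_used <- thin_track(dplyr::filter(tracks, .data$behavior == "moving"),
                            target = th$move_target, tolerance = th$move_tolerance)
  resting_used <- dplyr::filter(tracks, .data$behavior == "resting")
  say(nrow(moving_used), " moving and ", nrow(resting_used), " resting used points")

  ext <- raster_extent(landscape$canopy)
  ids <- unique(tracks$individual_id)
  av_seeds <- spawn_seeds(seeds[3], length(ids))
  hulls <- list(); pools <- list()
  for (i in seq_along(ids)) {
    loc <- dplyr::filter(tracks, .data$individual_id == ids[i])
    hull <- compute_mcp(loc)
    buf <- buffer_home_range(hull, distance = config$availability$buffer)
    buf <- clip_to_rect(buf, ext[1], ext[2], ext[3], ext[4])
    hulls[[ids[i]]] <- hull
    n_used <- max(sum(moving_used$individual_id == ids[i]),
                  sum(resting_used$individual_id == ids[i]))
    pool <- sample_availability(buf, n_used, ratio = config$availability$ratio,
                                seed = av_seeds[i])
    pools[[ids[i]]] <- dplyr::mutate(pool, individual_id = ids[i])
  }
  pool <- dplyr::bind_rows(pools)
  write_home_ranges_geojson(hulls, file.path(out_dir, "home_ranges.geojson"))

  # -- covariates -------------------------------------------------------------
  patches <- stage("covariates", delineate_patches(
    focal_mode(categorize_canopy(landscape$canopy),
               window = config$patches$window, passes = config$patches$passes),
    min_area_ha = config$patches$min_area_ha
  ))
  say(nrow(patches$patches), " patches retained")
  scales_ok <- config$scales[config$scales <= min(ext[2] - ext[1], ext[4] - ext[3])]
  covs <- function(pts) extract_covariates(pts, landscape, patches,
                                           scales = scales_ok)
  moving_cov <- stage("covariates", covs(moving_used))
  resting_cov <- stage("covariates", covs(resting_used))
  pool_cov <- stage("covariates", covs(pool))
  write_points_csv(moving_cov, pool_cov, file.path(out_dir, "points_moving.csv"))

  # -- rsf --------------------------------------------------------------------
  res_rsf <- stage("rsf", {
    designs <- list(
      moving = standardize_design(build_design(moving_cov, pool_cov, "moving",
                                               ratio = config$availability$ratio)),
      resting = standardize_design(build_design(resting_cov, pool_cov, "resting",
                                                ratio = config$availability$ratio))
    )
    out <- list(designs = designs)
    for (b in names(designs)) {
      d <- designs[[b]]
      screen <- screen_correlation(d, threshold = config$correlation_threshold)
      fits <- list()
      for (h in names(config$hypotheses)) {
        cols <- vapply(config$hypotheses[[h]], resolve_scale, character(1),
                       design = d, scales = scales_ok)
        # drop screened-out partners, keeping the earlier-listed covariate
        keep <- character(0)
        for (cc in cols) {
          if (all(vapply(keep, function(k) screen$admissible[k, cc], logical(1)))) {
            keep <- c(keep, cc)
          }
        }
        f <- stats::reformulate(keep, response = "response")
        fits[[h]] <- fit_mixed_logistic(f, d, screen = screen)
      }
      fits$null <- fit_mixed_logistic(response ~ 1, d)
      sel <- compare_models(fits)
      write_csv_stamped(sel, file.path(out_dir, paste0("model_selection_", b, ".csv")),
                        hash)
      best <- fits[[sel$model[1]]]
      write_csv_stamped(tidy(best), file.path(out_dir, paste0("coefficients_", b, ".csv")),
                        hash)
      out[[b]] <- list(fits = fits, selection = sel, screen = screen)
      say(b, ": top model ", sel$model[1], " (w = ", round(sel$weight[1], 2), ")")
    }
    out
  })

  # -- interactions -----------------------------------------------------------
  inter <- stage("rsf", fit_behavior_interactions(
    res_rsf$designs$moving, res_rsf$designs$resting,
    edge_scale = max(scales_ok[scales_ok <= config$edge_scale])
  ))
  inter_tab <- purrr::imap_dfr(inter, function(f, nm) {
    dplyr::mutate(tidy(f), model = nm, .before = 1)
  })
  write_csv_stamped(inter_tab, file.path(out_dir, "interactions.csv"), hash)

  # -- funcresp ---------------------------------------------------------------
  fr_cols <- vapply(config$fr_covariates, resolve_scale, character(1),
                    design = res_rsf$designs$moving, scales = scales_ok)
  fr <- stage("funcresp", functional_response_suite(
    res_rsf$designs$moving, res_rsf$designs$resting, fr_cols,
    min_used = config$fr_min_used
  ))
  write_csv_stamped(dplyr::select(tibble::as_tibble(fr), -dplyr::any_of("note")),
                    file.path(out_dir, "functional_responses.csv"), hash)

  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    stage_seeds = seeds,
    package_version = as.character(utils::packageVersion("habsel")),
    counts = list(
      individuals = length(ids),
      fixes = nrow(tracks),
      moving_used = nrow(moving_used),
      resting_used = nrow(resting_used),
      available = nrow(pool),
      patches = nrow(patches$patches)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)

  invisible(list(
    out_dir = out_dir, manifest = manifest, landscape = landscape,
    population = pop, tracks = tracks, patches = patches,
    designs = res_rsf$designs,
    rsf = res_rsf[c("moving", "resting")],
    interactions = inter, functional_responses = fr
  ))
}
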