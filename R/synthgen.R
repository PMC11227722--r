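#' Generate a synthetic forest landscape
#'
#' Builds a co-registered stack of canopy cover, elevation and categorical
#' vegetation rasters. Fields are Gaussian random fields: white noise smoothed
#' with a Gaussian kernel whose width is set by `autocorrelation_range`
#' (`autocorrelation_range == resolution` gives pure white noise). Canopy
#' ranks are pushed through a Beta quantile so the default landscape is
#' dominated by dense (> 75%) cover the way montane fisher range is, with an
#' optional monotone west-east gradient for availability-gradient designs.
#'
#' @param seed RNG seed.
#' @param extent `c(width, height)` in m.
#' @param resolution cell size in m (default 10).
#' @param autocorrelation_range spatial correlation range in m
#'   (>= resolution).
#' @param class_mixture vegetation class areal proportions (normalized).
#' @param canopy_beta shape parameters of the Beta quantile transform for
#'   canopy; the default `c(5.4, 1)` puts ~79% of cells above 75% cover.
#' @param canopy_gradient in `[0, 1)`: weight of a deterministic west-east
#'   trend in the canopy rank field (0 = none).
#' @param canopy_range canopy bounds in percent (default `c(0, 100)`).
#' @param canopy_shape_gradient optional `c(a_west, a_east)`: overrides
#'   `canopy_beta`/`canopy_gradient` with a west-east gradient in the Beta
#'   shape `a` of `qbeta(u, a, 1)` (log-interpolated). Every home range then
#'   spans the full canopy range but ranges differ in how much dense cover
#'   they hold — the between-individual contrast behind specialist
#'   functional responses.
#' @param canopy_scale `"linear"` maps the Beta quantile linearly into
#'   `canopy_range`; `"log"` maps it log-linearly (requires a positive lower
#'   bound), which keeps relative canopy spread constant along a gradient —
#'   the regime in which log-log functional-response errors are roughly
#'   homoscedastic.
#' @param elev_range elevation range in m.
#' @return A `landscape_stack` with elements `canopy`, `elevation`,
#'   `vegclass` (all [hs_raster]) plus `veg_codes`, `res` and the call
#'   parameters.
#' @export
generate_landscape <- function(seed = 1L,
                               extent = c(3000, 3000),
                               resolution = 10,
                               autocorrelation_range = 300,
                               class_mixture = c(0.5, 0.3, 0.2),
                               canopy_beta = c(5.4, 1),
                               canopy_gradient = 0,
                               canopy_range = c(0, 100),
                               canopy_scale = c("linear", "log"),
                               canopy_shape_gradient = NULL,
                               elev_range = c(900, 1500)) {
  canopy_scale <- match.arg(canopy_scale)
  if (canopy_scale == "log" && canopy_range[1] <= 0) {
    stop("`canopy_scale = \"log\"` needs a positive lower `canopy_range`",
         call. = FALSE)
  }
  if (any(extent <= 0) || resolution <= 0) {
    stop("extent and resolution must be positive", call. = FALSE)
  }
  if (autocorrelation_range < resolution) {
    stop("`autocorrelation_range` must be >= resolution", call. = FALSE)
  }
  if (canopy_gradient < 0 || canopy_gradient >= 1) {
    stop("`canopy_gradient` must be in [0, 1)", call. = FALSE)
  }
  class_mixture <- class_mixture / sum(class_mixture)
  nc <- max(2L, round(extent[1] / resolution))
  nr <- max(2L, round(extent[2] / resolution))
  sigma <- max(0, (autocorrelation_range / resolution - 1) / 2)

  with_seed(seed, {
    grf <- function() gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)

    z <- grf()
    u <- matrix(rank(z, ties.method = "random") / (length(z) + 1), nr, nc)
    if (!is.null(canopy_shape_gradient)) {
      xfrac <- (rep(seq_len(nc), each = nr) - 0.5) / nc
      a <- exp(log(canopy_shape_gradient[1]) +
                 xfrac * diff(log(canopy_shape_gradient)))
      q <- matrix(stats::qbeta(as.vector(u), a, 1), nr, nc)
    } else {
      if (canopy_gradient > 0) {
        xfrac <- (rep(seq_len(nc), each = nr) - 0.5) / nc
        u <- matrix((1 - canopy_gradient) * as.vector(u) + canopy_gradient * xfrac,
                    nr, nc)
      }
      q <- stats::qbeta(u, canopy_beta[1], canopy_beta[2])
    }
    canopy <- if (canopy_scale == "log") {
      canopy_range[1] * (canopy_range[2] / canopy_range[1])^q
    } else {
      canopy_range[1] + q * diff(canopy_range)
    }

    e <- grf()
    e <- (e - min(e)) / max(max(e) - min(e), .Machine$double.eps)
    elevation <- elev_range[1] + e * diff(elev_range)

    vz <- grf()
    uv <- rank(vz, ties.method = "first") / length(vz)
    brk <- cumsum(class_mixture)[-length(class_mixture)]
    vegclass <- matrix(findInterval(uv, brk, left.open = TRUE) + 1, nr, nc)

    structure(
      list(
        canopy = hs_raster(canopy, res = resolution),
        elevation = hs_raster(elevation, res = resolution),
        vegclass = hs_raster(vegclass, res = resolution,
                             levels = paste0("veg", seq_along(class_mixture))),
        veg_codes = seq_along(class_mixture),
        res = resolution,
        params = list(seed = seed, extent = extent, resolution = resolution,
                      autocorrelation_range = autocorrelation_range,
                      class_mixture = class_mixture, canopy_beta = canopy_beta,
                      canopy_gradient = canopy_gradient,
                      canopy_range = canopy_range, canopy_scale = canopy_scale,
                      canopy_shape_gradient = canopy_shape_gradient,
                      elev_range = elev_range)
      ),
      class = "landscape_stack"
    )
  })
}

#' @export
print.landscape_stack <- function(x, ...) {
  e <- raster_extent(x$canopy)
  cat(sprintf("<landscape_stack> %g x %g m at %g m: canopy, elevation, vegclass (%d classes)\n",
              e[2] - e[1], e[4] - e[3], x$res, length(x$veg_codes)))
  invisible(x)
}

conv1 <- function(x, k) {
  kk <- (length(k) - 1L) / 2L
  y <- stats::filter(c(rep(0, kk), x, rep(0, kk)), k, sides = 2)
  as.numeric(y)[(kk + 1L):(kk + length(x))]
}

gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kk <- ceiling(3 * sigma)
  k <- stats::dnorm(-kk:kk, sd = sigma)
  k <- k / sum(k)
  sm <- t(apply(mat, 1L, conv1, k = k))
  sm <- apply(sm, 2L, conv1, k = k)
  # renormalize for the zero-padded boundary (separable, so exact)
  sm / outer(conv1(rep(1, nrow(mat)), k), conv1(rep(1, ncol(mat)), k))
}

#' Known simulation truth for a behavior-switching habitat selector
#'
#' Houses the generative parameters the downstream estimators try to recover:
#' state-specific selection coefficients on named covariate layers, the
#' two-state behavior-switch probabilities, and the movement-kernel scales.
#' The moving relocation scale defaults to an hourly displacement of about
#' 370 m (three 20-min steps averaging ~123 m).
#'
#' @param beta_moving,beta_resting named numeric vectors of selection
#'   coefficients per covariate layer (raw covariate units).
#' @param switch_prob `c(move_to_rest, rest_to_move)` per-fix transition
#'   probabilities, each in `[0, 1]`.
#' @param step_mean mean step length per state (m), for the `gamma_ssf`
#'   kernel.
#' @param step_shape gamma shape of step lengths (> 0).
#' @param relocation_radius local-Gibbs disc radius per state (m); set it
#'   at or above the home-range diameter to sample locations independently
#'   from the state's selection surface.
#' @param beta_sd between-individual SD added to every coefficient (0 =
#'   identical individuals).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(beta_moving = c(canopy = 0.05),
                      beta_resting = c(canopy = 0.08),
                      switch_prob = c(move_to_rest = 0.05, rest_to_move = 0.45),
                      step_mean = c(moving = 123, resting = 15),
                      step_shape = 2,
                      relocation_radius = c(moving = 150, resting = 40),
                      beta_sd = 0) {
  if (any(switch_prob < 0 | switch_prob > 1)) {
    stop("switch probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(step_mean <= 0) || step_shape <= 0 || any(relocation_radius <= 0)) {
    stop("step-length and relocation parameters must be positive", call. = FALSE)
  }
  structure(
    list(beta = list(moving = beta_moving, resting = beta_resting),
         switch_prob = stats::setNames(switch_prob, c("move_to_rest", "rest_to_move")),
         step_mean = stats::setNames(step_mean, c("moving", "resting")),
         step_shape = step_shape,
         relocation_radius = stats::setNames(relocation_radius, c("moving", "resting")),
         beta_sd = beta_sd),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n  moving beta: ",
      paste(names(x$beta$moving), signif(x$beta$moving, 3), sep = "=", collapse = ", "),
      "\n  resting beta:",
      paste(names(x$beta$resting), signif(x$beta$resting, 3), sep = "=", collapse = ", "),
      "\n  switch:", paste(signif(x$switch_prob, 3), collapse = "/"),
      " beta_sd:", x$beta_sd, "\n")
  invisible(x)
}

# log selection weights over the grid for one state
state_logw <- function(betas, layers) {
  unknown <- setdiff(names(betas), names(layers))
  if (length(unknown)) {
    stop("selection coefficients name unknown layers: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  acc <- 0
  for (nm in names(betas)) acc <- acc + betas[[nm]] * raster_values(layers[[nm]])
  if (length(names(betas)) == 0) acc <- matrix(0, nrow(raster_values(layers[[1]])),
                                               ncol(raster_values(layers[[1]])))
  acc
}

#' Simulate one behavior-switching, habitat-selecting track
#'
#' A two-state (moving/resting) Markov chain drives the fix schedule (20-min
#' fixes while moving, 120-min while resting) and the movement kernel. The
#' default `local_gibbs` kernel draws an intermediate disc center uniformly
#' within the state's relocation radius and then relocates to a cell chosen
#' with probability proportional to `exp(beta . x)` within that disc — its
#' long-run utilization is exactly the target selection surface. The
#' `gamma_ssf` kernel instead scores `n_candidates` gamma-step/uniform-turn
#' destinations by `exp(beta . x)`; it is the classical step-selection
#' simulator, whose equilibrium over-represents selection (roughly squaring
#' the weight on smooth fields), so use it for movement realism rather than
#' estimator validation.
#'
#' @param landscape a `landscape_stack`.
#' @param truth a [sim_truth].
#' @param n_fixes number of fixes to simulate.
#' @param seed RNG seed.
#' @param region `c(xmin, xmax, ymin, ymax)` home-range rectangle the animal
#'   is confined to (default: the full extent).
#' @param kernel movement kernel (see Details).
#' @param n_candidates candidate destinations per step for `gamma_ssf`
#'   (default 50).
#' @param covariates named list of [hs_raster] layers referenced by the
#'   selection coefficients; defaults to the landscape's canopy and
#'   elevation.
#' @param individual_id id stamped on the track.
#' @param t0 timestamp of the first fix.
#' @param betas optional per-individual override of `truth`'s coefficient
#'   list (`list(moving = , resting = )`).
#' @return Tibble with `individual_id`, `timestamp`, `x`, `y`, `activity`,
#'   `true_state`.
#' @export
simulate_individual <- function(landscape, truth, n_fixes = 200, seed = 1L,
                                region = NULL,
                                kernel = c("local_gibbs", "gamma_ssf"),
                                n_candidates = 50,
                                covariates = NULL,
                                individual_id = "F01",
                                t0 = as.POSIXct("2017-02-01 00:00:00", tz = "UTC"),
                                betas = NULL) {
  kernel <- match.arg(kernel)
  layers <- covariates %||% list(canopy = landscape$canopy,
                                 elevation = landscape$elevation)
  ref <- layers[[1]]
  ext <- raster_extent(ref)
  region <- region %||% ext
  if (region[1] < ext[1] || region[2] > ext[2] ||
      region[3] < ext[3] || region[4] > ext[4]) {
    stop("`region` must lie within the landscape extent", call. = FALSE)
  }
  res <- ref$res
  rw <- region[2] - region[1]; rh <- region[4] - region[3]
  if (min(rw, rh) < 4 * res) {
    stop("landscape region too small relative to the grid: region is ",
         round(min(rw, rh)), " m across but steps need at least ",
         4 * res, " m", call. = FALSE)
  }
  if (kernel == "gamma_ssf" && max(truth$step_mean) > min(rw, rh) / 2) {
    stop("landscape region too small for the step-length distribution (mean ",
         max(truth$step_mean), " m vs region ", round(min(rw, rh)), " m)",
         call. = FALSE)
  }
  betas <- betas %||% truth$beta
  logw <- list(moving = state_logw(betas$moving, layers),
               resting = state_logw(betas$resting, layers))

  # cells of the region, in matrix index and center coordinates
  rows <- which(ref$ymin + (seq_len(nrow(ref$values)) - 0.5) * res >= region[3] &
                ref$ymin + (seq_len(nrow(ref$values)) - 0.5) * res <= region[4])
  cols <- which(ref$xmin + (seq_len(ncol(ref$values)) - 0.5) * res >= region[1] &
                ref$xmin + (seq_len(ncol(ref$values)) - 0.5) * res <= region[2])
  cy <- ref$ymin + (rows - 0.5) * res
  cx <- ref$xmin + (cols - 0.5) * res
  diam <- sqrt(rw^2 + rh^2)

  with_seed(seed, {
    # state sequence
    states <- character(n_fixes)
    p_mr <- truth$switch_prob[["move_to_rest"]]
    p_rm <- truth$switch_prob[["rest_to_move"]]
    stat_m <- if (p_mr + p_rm > 0) p_rm / (p_mr + p_rm) else 1
    states[1] <- if (stats::runif(1) < stat_m) "moving" else "resting"
    for (i in seq_len(n_fixes - 1)) {
      p_sw <- if (states[i] == "moving") p_mr else p_rm
      states[i + 1] <- if (stats::runif(1) < p_sw) {
        setdiff(c("moving", "resting"), states[i])
      } else states[i]
    }

    xs <- numeric(n_fixes); ys <- numeric(n_fixes)

    cell_weights <- function(state) {
      lw <- logw[[state]][rows, cols, drop = FALSE]
      w <- exp(lw - max(lw, na.rm = TRUE))
      w[is.na(w)] <- 0
      w
    }

    iid_state <- vapply(c("moving", "resting"), function(s) {
      truth$relocation_radius[[s]] >= diam
    }, logical(1))

    if (kernel == "local_gibbs" && all(iid_state[unique(states)])) {
      # relocation disc covers the whole region: fixes are independent draws
      # from each state's selection surface, vectorized per state
      for (s in unique(states)) {
        w <- cell_weights(s)
        idx <- which(states == s)
        pick <- sample.int(length(w), length(idx), replace = TRUE, prob = as.vector(w))
        ri <- (pick - 1L) %% length(rows) + 1L
        ci <- (pick - 1L) %/% length(rows) + 1L
        xs[idx] <- cx[ci] + stats::runif(length(idx), -res / 2, res / 2)
        ys[idx] <- cy[ri] + stats::runif(length(idx), -res / 2, res / 2)
      }
    } else {
      # start from the first state's surface
      w0 <- cell_weights(states[1])
      pick <- sample.int(length(w0), 1, prob = as.vector(w0))
      ri <- (pick - 1L) %% length(rows) + 1L
      ci <- (pick - 1L) %/% length(rows) + 1L
      xs[1] <- cx[ci]; ys[1] <- cy[ri]
      for (i in seq_len(n_fixes)[-1]) {
        s <- states[i]
        if (kernel == "local_gibbs") {
          p <- local_gibbs_step(xs[i - 1], ys[i - 1],
                                truth$relocation_radius[[s]], logw[[s]],
                                ref, region, rows, cols, cx, cy)
        } else {
          p <- gamma_ssf_step(xs[i - 1], ys[i - 1], truth$step_mean[[s]],
                              truth$step_shape, n_candidates, logw[[s]],
                              ref, region)
        }
        xs[i] <- p[1]; ys[i] <- p[2]
      }
    }

    dt <- ifelse(states == "moving", 20, 120) # minutes until the next fix
    ts <- t0 + c(0, cumsum(utils::head(dt, -1))) * 60
    activity <- ifelse(states == "resting",
                       stats::runif(n_fixes, 500, 6300),
                       stats::runif(n_fixes, 8000, 60000))
    tibble::tibble(
      individual_id = individual_id,
      timestamp = ts,
      x = xs, y = ys,
      activity = activity,
      true_state = states
    )
  })
}

local_gibbs_step <- function(x, y, radius, logw, ref, region, rows, cols, cx, cy) {
  res <- ref$res
  # intermediate disc center, uniform on disc(p, r) intersected with region
  for (try in 1:200) {
    a <- stats::runif(1, 0, 2 * pi)
    r <- radius * sqrt(stats::runif(1))
    zx <- x + r * cos(a); zy <- y + r * sin(a)
    if (zx >= region[1] && zx <= region[2] && zy >= region[3] && zy <= region[4]) break
    if (try == 200) { zx <- x; zy <- y }
  }
  keep_r <- which(abs(cy - zy) <= radius)
  keep_c <- which(abs(cx - zx) <= radius)
  dy2 <- (cy[keep_r] - zy)^2
  dx2 <- (cx[keep_c] - zx)^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  lw <- logw[rows[keep_r], cols[keep_c], drop = FALSE]
  w <- exp(lw - max(lw[inside], na.rm = TRUE))
  w[!inside | is.na(w)] <- 0
  pick <- sample.int(length(w), 1, prob = as.vector(w))
  ri <- (pick - 1L) %% length(keep_r) + 1L
  ci <- (pick - 1L) %/% length(keep_r) + 1L
  px <- cx[keep_c][ci] + stats::runif(1, -res / 2, res / 2)
  py <- cy[keep_r][ri] + stats::runif(1, -res / 2, res / 2)
  c(min(max(px, region[1]), region[2]), min(max(py, region[3]), region[4]))
}

gamma_ssf_step <- function(x, y, mean_step, shape, k, logw, ref, region) {
  for (try in 1:20) {
    len <- stats::rgamma(k, shape = shape, scale = mean_step / shape)
    ang <- stats::runif(k, 0, 2 * pi)
    px <- x + len * cos(ang); py <- y + len * sin(ang)
    ok <- px >= region[1] & px <= region[2] & py >= region[3] & py <= region[4]
    if (!any(ok)) next
    px <- px[ok]; py <- py[ok]
    lw <- raster_extract(hs_raster(logw, ref$xmin, ref$ymin, ref$res), px, py)
    good <- !is.na(lw)
    if (!any(good)) next
    px <- px[good]; py <- py[good]; lw <- lw[good]
    w <- exp(lw - max(lw))
    i <- sample.int(length(w), 1, prob = w)
    return(c(px[i], py[i]))
  }
  c(x, y)
}

#' Simulate a population of individuals across an availability gradient
#'
#' Individuals are confined to side-by-side home-range rectangles spanning
#' the landscape west to east, so a west-east canopy gradient in the
#' landscape translates into a monotone between-individual gradient in
#' available canopy — the precondition for estimating functional responses.
#'
#' @param landscape a `landscape_stack`, or a named list of arguments for
#'   [generate_landscape] (a landscape spec).
#' @param truth a [sim_truth].
#' @param n_individuals number of animals (>= 2 for a gradient; with 1 the
#'   gradient is ignored with a warning).
#' @param availability_gradient `"none"` or `"canopy"`; with `"canopy"` the
#'   per-individual mean available canopy must span at least
#'   `min_gradient_span` percentage points, otherwise an error reports the
#'   gradient as infeasible.
#' @param n_fixes fixes per individual.
#' @param seed master seed; per-individual substreams are spawned from it.
#' @param kernel movement kernel, see [simulate_individual].
#' @param placement `"strips"` gives each individual its own west-east strip
#'   (availability differs between individuals, as a gradient design needs);
#'   `"shared"` overlaps all home ranges on the full (inset) extent, so every
#'   individual has the same availability distribution — the regime for
#'   validating coefficient recovery, where between-individual availability
#'   contrasts would otherwise attenuate pooled use-availability slopes.
#' @param margin margin kept between home ranges and the extent edge (m).
#' @param min_gradient_span required span of mean available canopy (%).
#' @param covariates optional named layer list for the selection kernel.
#' @return A list of class `sim_population`: `tracks` (one tibble),
#'   `individuals` (per-individual regions, seeds, coefficients, mean
#'   available canopy), `truth`, `landscape`.
#' @export
make_population <- function(landscape, truth, n_individuals = 12,
                            availability_gradient = c("none", "canopy"),
                            n_fixes = 200, seed = 1L,
                            kernel = c("local_gibbs", "gamma_ssf"),
                            placement = c("strips", "shared"),
                            margin = 100, min_gradient_span = 10,
                            covariates = NULL) {
  availability_gradient <- match.arg(availability_gradient)
  kernel <- match.arg(kernel)
  placement <- match.arg(placement)
  if (placement == "shared" && availability_gradient != "none") {
    stop("a gradient needs `placement = \"strips\"`", call. = FALSE)
  }
  if (n_individuals < 1) stop("`n_individuals` must be >= 1", call. = FALSE)
  if (!inherits(landscape, "landscape_stack")) {
    landscape <- do.call(generate_landscape, landscape)
  }
  if (n_individuals == 1 && availability_gradient != "none") {
    warning("gradient ignored with a single individual")
    availability_gradient <- "none"
  }
  ext <- raster_extent(landscape$canopy)
  res <- landscape$res
  snap <- function(v) round(v / res) * res # align regions to the cell grid
  ids <- sprintf("F%02d", seq_len(n_individuals))
  regions <- if (placement == "shared") {
    rep(list(snap(c(ext[1] + margin, ext[2] - margin,
                    ext[3] + margin, ext[4] - margin))), n_individuals)
  } else {
    usable_w <- (ext[2] - ext[1]) - 2 * margin
    strip_w <- usable_w / n_individuals
    lapply(seq_len(n_individuals), function(i) {
      snap(c(ext[1] + margin + (i - 1) * strip_w,
             ext[1] + margin + i * strip_w,
             ext[3] + margin, ext[4] - margin))
    })
  }

  avail_canopy <- vapply(regions, function(rg) {
    v <- raster_values(landscape$canopy)
    idx <- cell_index(landscape$canopy,
                      rep(seq(rg[1] + 5, rg[2] - 5, length.out = 40), each = 40),
                      rep(seq(rg[3] + 5, rg[4] - 5, length.out = 40), times = 40))
    mean(v[cbind(idx$row, idx$col)], na.rm = TRUE)
  }, numeric(1))
  if (availability_gradient == "canopy" &&
      diff(range(avail_canopy)) < min_gradient_span) {
    stop("availability gradient infeasible on this landscape: mean available ",
         "canopy spans only ", round(diff(range(avail_canopy)), 1),
         " percentage points (need >= ", min_gradient_span,
         "); generate the landscape with `canopy_gradient` > 0", call. = FALSE)
  }

  seeds <- spawn_seeds(seed, n_individuals + 1L)
  betas <- lapply(seq_len(n_individuals), function(i) {
    if (truth$beta_sd > 0) {
      with_seed(seeds[n_individuals + 1L] + i, list(
        moving = truth$beta$moving + stats::rnorm(length(truth$beta$moving),
                                                  0, truth$beta_sd),
        resting = truth$beta$resting + stats::rnorm(length(truth$beta$resting),
                                                    0, truth$beta_sd)
      ))
    } else truth$beta
  })

  tracks <- purrr::map_dfr(seq_len(n_individuals), function(i) {
    simulate_individual(landscape, truth, n_fixes = n_fixes, seed = seeds[i],
                        region = regions[[i]], kernel = kernel,
                        covariates = covariates, individual_id = ids[i],
                        betas = betas[[i]])
  })

  structure(
    list(
      tracks = tracks,
      individuals = tibble::tibble(
        individual_id = ids,
        seed = seeds[seq_len(n_individuals)],
        region = regions,
        beta_moving = lapply(betas, `[[`, "moving"),
        beta_resting = lapply(betas, `[[`, "resting"),
        mean_avail_canopy = avail_canopy
      ),
      truth = truth,
      landscape = landscape
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d individuals, %d fixes (%.0f%% resting)\n",
              nrow(x$individuals), nrow(x$tracks),
              100 * mean(x$tracks$true_state == "resting")))
  invisible(x)
}
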