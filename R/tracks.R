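#' Classify track fixes into moving and resting states
#'
#' When accelerometer activity is available, a fix with activity below
#' `accel_rest_threshold` is resting and anything else (including fast
#' movement above `accel_fast_threshold`) is moving. Without activity, the
#' interval to the next fix decides: within `rest_interval +/-
#' interval_tolerance` minutes means resting, near one of `move_intervals`
#' (within `move_tolerance`) means moving, and anything else is unknown.
#'
#' @param track tibble with `individual_id`, `timestamp` (POSIXct), `x`, `y`
#'   and optionally `activity`.
#' @param accel_rest_threshold activity below this is resting (default 6400).
#' @param accel_fast_threshold activity above this is fast movement, pooled
#'   into moving (default 48000).
#' @param rest_interval resting fix interval, minutes (default 120).
#' @param interval_tolerance tolerance around `rest_interval`, minutes
#'   (default 5).
#' @param move_intervals fix intervals treated as movement sampling, minutes
#'   (default `c(5, 20)`).
#' @param move_tolerance tolerance around `move_intervals`, minutes
#'   (default 2).
#' @return The track with `interval_to_next` (minutes) and `behavior`
#'   (`"moving"`, `"resting"`, `"unknown"`) columns.
#' @export
classify_behavior <- function(track,
                              accel_rest_threshold = 6400,
                              accel_fast_threshold = 48000,
                              rest_interval = 120,
                              interval_tolerance = 5,
                              move_intervals = c(5, 20),
                              move_tolerance = 2) {
  stopifnot(all(c("individual_id", "timestamp") %in% names(track)))
  track <- dplyr::arrange(tibble::as_tibble(track), .data$individual_id, .data$timestamp)
  check <- dplyr::summarise(
    dplyr::group_by(track, .data$individual_id),
    ok = !is.unsorted(.data$timestamp, strictly = TRUE), .groups = "drop"
  )
  if (!all(check$ok)) {
    stop("timestamps must be strictly increasing within an individual", call. = FALSE)
  }
  track <- dplyr::mutate(
    dplyr::group_by(track, .data$individual_id),
    interval_to_next = as.numeric(difftime(dplyr::lead(.data$timestamp),
                                           .data$timestamp, units = "mins")),
    .after = "timestamp"
  )
  track <- dplyr::ungroup(track)

  have_act <- "activity" %in% names(track) && any(!is.na(track$activity))
  if (have_act) {
    behavior <- dplyr::if_else(track$activity < accel_rest_threshold,
                               "resting", "moving", missing = "unknown")
  } else {
    iv <- track$interval_to_next
    near_move <- !is.na(iv) &
      purrr::reduce(purrr::map(move_intervals,
                               function(m) abs(iv - m) <= move_tolerance), `|`)
    behavior <- dplyr::case_when(
      !is.na(iv) & abs(iv - rest_interval) <= interval_tolerance ~ "resting",
      near_move ~ "moving",
      TRUE ~ "unknown"
    )
  }
  if (all(behavior == "unknown")) warning("all fixes classified as unknown")
  dplyr::mutate(track, behavior = behavior)
}

#' Thin a track to a uniform sampling interval
#'
#' Greedy forward pass per individual: keep the first fix, then keep the
#' earliest subsequent fix at least `target - tolerance` minutes after the
#' last kept fix. After a long gap the pass simply continues from the next
#' fix; nothing is interpolated. Applying the rule to an already-thinned
#' track changes nothing.
#'
#' @param track tibble with `individual_id` and sorted `timestamp`.
#' @param target target interval, minutes (default 20).
#' @param tolerance allowed shortfall, minutes (default 2).
#' @return The thinned track.
#' @export
thin_track <- function(track, target = 20, tolerance = 2) {
  if (nrow(track) == 0) return(tibble::as_tibble(track))
  track <- dplyr::arrange(tibble::as_tibble(track), .data$individual_id, .data$timestamp)
  keep_one <- function(ts) {
    keep <- logical(length(ts))
    keep[1] <- TRUE
    last <- ts[1]
    for (i in seq_along(ts)[-1]) {
      if (as.numeric(difftime(ts[i], last, units = "mins")) >= target - tolerance) {
        keep[i] <- TRUE
        last <- ts[i]
      }
    }
    keep
  }
  out <- dplyr::mutate(dplyr::group_by(track, .data$individual_id),
                       .keep_fix = keep_one(.data$timestamp))
  out <- dplyr::ungroup(out)
  dplyr::select(dplyr::filter(out, .data$.keep_fix), -".keep_fix")
}

#' Minimum convex polygon home range
#'
#' Convex hull of an individual's locations. For `percent < 100` the
#' `(100 - percent)%` of points farthest from the centroid are peeled off
#' before hulling.
#'
#' @param locations tibble with `x`, `y` (m).
#' @param percent percentage of points retained (default 100).
#' @return An `hs_polygon` with an `area_km2` element.
#' @export
compute_mcp <- function(locations, percent = 100) {
  stopifnot(all(c("x", "y") %in% names(locations)))
  pts <- unique(cbind(locations$x, locations$y))
  if (percent < 100) {
    d <- sqrt((pts[, 1] - mean(pts[, 1]))^2 + (pts[, 2] - mean(pts[, 2]))^2)
    keep <- d <= stats::quantile(d, percent / 100)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("need at least 3 distinct points for an MCP", call. = FALSE)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3 || polygon_area(hull) <= 0) {
    stop("points are collinear; MCP is degenerate", call. = FALSE)
  }
  p <- new_polygon(hull)
  p$area_km2 <- polygon_area(p) / 1e6
  p
}

#' Buffer a convex home range outward
#'
#' Outward Euclidean buffer (Minkowski sum with a disc); corner arcs are
#' discretized at `arc_step_deg` so areas agree with the closed form to well
#' under 0.1%.
#'
#' @param hull convex `hs_polygon` (e.g. from [compute_mcp]).
#' @param distance buffer distance in m (default 5000, matching an
#'   availability buffer of about one day's travel).
#' @param arc_step_deg arc discretization step, degrees (default 2).
#' @return Buffered convex `hs_polygon`.
#' @export
buffer_home_range <- function(hull, distance = 5000, arc_step_deg = 2) {
  if (distance < 0) stop("`distance` must be >= 0", call. = FALSE)
  xy <- ensure_ccw(polygon_coords(hull))
  if (distance == 0) return(new_polygon(xy))
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  out <- list()
  for (i in seq_len(n)) {
    # outward normals of the incoming and outgoing edges at vertex i
    ein <- xy[i, ] - xy[prv[i], ]
    eout <- xy[nxt[i], ] - xy[i, ]
    a1 <- atan2(-ein[1], ein[2])   # outward normal angle of incoming edge
    a2 <- atan2(-eout[1], eout[2]) # outward normal angle of outgoing edge
    if (a2 < a1) a2 <- a2 + 2 * pi
    ang <- seq(a1, a2, by = arc_step_deg * pi / 180)
    if (utils::tail(ang, 1) < a2) ang <- c(ang, a2)
    out[[i]] <- cbind(xy[i, 1] + distance * cos(ang),
                      xy[i, 2] + distance * sin(ang))
  }
  new_polygon(do.call(rbind, out))
}

#' Sample available locations uniformly within a polygon
#'
#' Rejection sampling from the bounding box gives an exactly uniform sample
#' over the (convex) availability polygon. One pool per individual can be
#' reused by both behavior designs.
#'
#' @param poly convex `hs_polygon` (typically the buffered home range).
#' @param n_used number of used locations.
#' @param ratio available : used ratio (default 20).
#' @param seed RNG seed.
#' @return Tibble of `ratio * n_used` points with columns `x`, `y`.
#' @export
sample_availability <- function(poly, n_used, ratio = 20, seed = 1L) {
  if (n_used < 1) stop("`n_used` must be >= 1", call. = FALSE)
  xy <- polygon_coords(poly)
  if (nrow(xy) < 3 || polygon_area(xy) <= 0) {
    stop("availability polygon is degenerate", call. = FALSE)
  }
  n <- as.integer(round(ratio * n_used))
  bx <- range(xy[, 1]); by <- range(xy[, 2])
  with_seed(seed, {
    got <- matrix(numeric(0), 0, 2)
    while (nrow(got) < n) {
      m <- max(1000L, ceiling((n - nrow(got)) * 2.5))
      px <- stats::runif(m, bx[1], bx[2])
      py <- stats::runif(m, by[1], by[2])
      ok <- in_convex(xy, px, py)
      got <- rbind(got, cbind(px[ok], py[ok]))
    }
    tibble::tibble(x = got[1:n, 1], y = got[1:n, 2])
  })
}

#' Screen GPS fix success for environmental bias
#'
#' Fits a mixed logistic regression of fix success on environmental
#' covariates with a per-individual random intercept, and flags the schedule
#' as environmentally biased when any environmental coefficient's 95%
#' confidence interval excludes zero. Collars that miss fixes specifically
#' under dense canopy would otherwise distort a selection analysis.
#'
#' @param attempts tibble of scheduled fix attempts: `individual_id`,
#'   logical/0-1 `success`, plus the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return A list with `coefficients` (tibble: term, estimate, SE, CI),
#'   `biased` flag, `fix_success_rate`, and the fitted model (or `NULL` when
#'   success does not vary, with a warning).
#' @export
assess_fix_bias <- function(attempts, covariates) {
  stopifnot(all(c("individual_id", "success") %in% names(attempts)),
            all(covariates %in% names(attempts)))
  if (dplyr::n_distinct(attempts$individual_id) < 2) {
    stop("need at least 2 individuals", call. = FALSE)
  }
  y <- as.numeric(attempts$success)
  rate <- mean(y)
  if (rate %in% c(0, 1)) {
    warning("fix success does not vary (all ",
            if (rate == 1) "successes" else "failures", "); no model fitted")
    return(list(coefficients = NULL, biased = NA, fix_success_rate = rate,
                model = NULL))
  }
  f <- stats::as.formula(paste("success ~", paste(covariates, collapse = " + "),
                               "+ (1 | individual_id)"))
  dat <- dplyr::mutate(attempts, success = y)
  fit <- glmmTMB::glmmTMB(f, data = dat, family = stats::binomial())
  est <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(stats::vcov(fit)$cond))
  co <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    conf_low = unname(est - 1.96 * se), conf_high = unname(est + 1.96 * se)
  )
  env <- co[co$term != "(Intercept)", ]
  list(
    coefficients = co,
    biased = any(env$conf_low > 0 | env$conf_high < 0),
    fix_success_rate = rate,
    model = fit
  )
}
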