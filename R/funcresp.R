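#' Per-individual mean use and mean availability of a covariate
#'
#' Means are computed on the original covariate scale (a standardized design
#' is back-transformed first): one row per individual with the covariate mean
#' over used rows and over available rows. Individuals lacking either row
#' type are excluded with a warning.
#'
#' @param design use-availability design.
#' @param covariate covariate column name.
#' @return Tibble with `individual_id`, `n_used`, `mean_use`, `mean_avail`.
#' @export
per_individual_means <- function(design, covariate) {
  stopifnot(covariate %in% names(design))
  design <- unstandardize_design(design)
  tab <- dplyr::summarise(
    dplyr::group_by(design, .data$individual_id),
    n_used = sum(.data$response == 1),
    n_avail = sum(.data$response == 0),
    mean_use = mean(.data[[covariate]][.data$response == 1], na.rm = TRUE),
    mean_avail = mean(.data[[covariate]][.data$response == 0], na.rm = TRUE),
    .groups = "drop"
  )
  bad <- tab$n_used == 0 | tab$n_avail == 0
  if (any(bad)) {
    warning("excluding individual(s) without both used and available rows: ",
            paste(tab$individual_id[bad], collapse = ", "))
    tab <- tab[!bad, ]
  }
  dplyr::select(tab, "individual_id", "n_used", "mean_use", "mean_avail")
}

#' Fit a functional response from per-individual means
#'
#' Ordinary least squares of `log(mean use)` on `log(mean availability)`
#' across individuals, with t-based confidence intervals (df = n - 2) on the
#' slope and intercept. Proportional use corresponds to slope 1 and intercept
#' 0; slopes below 1 mean use stays high where availability is low
#' (specialist-style selection). Covariates that can take non-positive means
#' (TPI is signed) need `offset_policy = "shift"`, which shifts both mean
#' columns by the global minimum minus a small epsilon before logging.
#'
#' @param means table from [per_individual_means].
#' @param offset_policy `"none"` (error on non-positive means) or `"shift"`.
#' @param conf_level confidence level for the intervals (default 0.90, the
#'   conventional level for declaring functional responses).
#' @return An object of class `fr_fit` with slope/intercept estimates and
#'   CIs, the offset used, and the (possibly shifted) means.
#' @export
fit_functional_response <- function(means, offset_policy = c("none", "shift"),
                                    conf_level = 0.90) {
  offset_policy <- match.arg(offset_policy)
  n <- nrow(means)
  if (n < 3) stop("need >= 3 individuals to fit a functional response", call. = FALSE)
  vals <- c(means$mean_use, means$mean_avail)
  offset <- 0
  if (any(vals <= 0)) {
    if (offset_policy == "none") {
      stop("non-positive means; use offset_policy = \"shift\" for signed covariates",
           call. = FALSE)
    }
    offset <- -min(vals) + 0.01 * max(diff(range(vals)), 1e-6)
  }
  lu <- log(means$mean_use + offset)
  la <- log(means$mean_avail + offset)
  fit <- stats::lm(lu ~ la)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(
    list(
      model = fit,
      n = n,
      conf_level = conf_level,
      offset = offset,
      intercept = unname(est[1]),
      intercept_ci = unname(est[1] + c(-1, 1) * tq * se[1]),
      slope = unname(est[2]),
      slope_ci = unname(est[2] + c(-1, 1) * tq * se[2]),
      means = means
    ),
    class = "fr_fit"
  )
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf(
    "<fr_fit> n = %d: slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f] (%.0f%% CI) -> %s\n",
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2],
    100 * x$conf_level, classify_response(x)))
  invisible(x)
}

#' Classify a fitted functional response
#'
#' Pure function of the confidence intervals: `proportional` when the slope
#' CI contains 1 and the intercept CI contains 0 (use tracks availability);
#' `decreasing_FR` when the slope CI lies entirely below 1 (use stays high at
#' low availability — the specialist signature); `increasing_FR` when it lies
#' entirely above 1; otherwise `indeterminate`.
#'
#' @param fit an `fr_fit`.
#' @return One of `"proportional"`, `"decreasing_FR"`, `"increasing_FR"`,
#'   `"indeterminate"`.
#' @export
classify_response <- function(fit) {
  s <- fit$slope_ci
  i <- fit$intercept_ci
  if (s[2] < 1) return("decreasing_FR")
  if (s[1] > 1) return("increasing_FR")
  if (s[1] <= 1 && s[2] >= 1 && i[1] <= 0 && i[2] >= 0) return("proportional")
  "indeterminate"
}

#' Functional responses for a set of covariates and both behaviors
#'
#' Runs [per_individual_means], [fit_functional_response] and
#' [classify_response] for every covariate in each behavior design.
#' Individuals with fewer than `min_used` used points are dropped from a
#' covariate's fit (sparse canopy classes may leave too few resting points to
#' say anything).
#'
#' @param design_moving,design_resting behavior designs.
#' @param covariates character vector of covariate columns.
#' @param min_used minimum used points per individual (default 5).
#' @param offset_policy passed to [fit_functional_response]; the default
#'   `"shift"` handles signed covariates and leaves positive ones untouched.
#' @param conf_level confidence level (default 0.90).
#' @return A tibble of class `fr_suite` (covariate, behavior, n, slope and
#'   intercept with CIs, label); the fitted `fr_fit`s are in the `"fits"`
#'   attribute.
#' @export
functional_response_suite <- function(design_moving, design_resting,
                                      covariates, min_used = 5,
                                      offset_policy = "shift",
                                      conf_level = 0.90) {
  designs <- list(moving = design_moving, resting = design_resting)
  fits <- list()
  rows <- list()
  for (cov in covariates) {
    for (b in names(designs)) {
      mt <- per_individual_means(designs[[b]], cov)
      mt <- mt[mt$n_used >= min_used, ]
      fit <- tryCatch(
        fit_functional_response(mt, offset_policy = offset_policy,
                                conf_level = conf_level),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows[[paste(cov, b)]] <- tibble::tibble(
          covariate = cov, behavior = b, n = nrow(mt),
          slope = NA_real_, slope_lo = NA_real_, slope_hi = NA_real_,
          intercept = NA_real_, intercept_lo = NA_real_, intercept_hi = NA_real_,
          label = "indeterminate", note = conditionMessage(fit)
        )
        next
      }
      fits[[paste(cov, b, sep = ".")]] <- fit
      rows[[paste(cov, b)]] <- tibble::tibble(
        covariate = cov, behavior = b, n = fit$n,
        slope = fit$slope, slope_lo = fit$slope_ci[1], slope_hi = fit$slope_ci[2],
        intercept = fit$intercept,
        intercept_lo = fit$intercept_ci[1], intercept_hi = fit$intercept_ci[2],
        label = classify_response(fit), note = NA_character_
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    covariate = character(), behavior = character(), n = integer(),
    slope = numeric(), slope_lo = numeric(), slope_hi = numeric(),
    intercept = numeric(), intercept_lo = numeric(), intercept_hi = numeric(),
    label = character(), note = character()
  )
  attr(out, "fits") <- fits
  class(out) <- c("fr_suite", class(out))
  out
}

#' Plot functional responses as mean use vs mean availability
#'
#' Natural-scale scatter of per-individual mean use against mean
#' availability, the 1:1 proportional-use reference line, and the fitted
#' power curve `use = exp(intercept) * availability^slope`, faceted by
#' covariate and behavior.
#'
#' @param object an `fr_suite`.
#' @param ... unused.
#' @export
autoplot.fr_suite <- function(object, ...) {
  fits <- attr(object, "fits")
  pts <- purrr::imap_dfr(fits, function(f, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    dplyr::mutate(f$means, covariate = parts[1], behavior = parts[2])
  })
  curves <- purrr::imap_dfr(fits, function(f, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    av <- seq(min(f$means$mean_avail), max(f$means$mean_avail), length.out = 50)
    tibble::tibble(
      covariate = parts[1], behavior = parts[2], mean_avail = av,
      mean_use = exp(f$intercept) * (av + f$offset)^f$slope - f$offset
    )
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean_avail, y = .data$mean_use)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "steelblue") +
    ggplot2::facet_wrap(~ covariate + behavior, scales = "free") +
    ggplot2::labs(x = "mean availability", y = "mean use")
}
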