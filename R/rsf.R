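id_cols <- c("individual_id", "behavior", "response", "x", "y", "timestamp",
             "activity", "true_state", "interval_to_next", "role", "patch_cat")

design_covariate_cols <- function(design, cols = NULL) {
  if (!is.null(cols)) return(cols)
  num <- names(design)[vapply(design, is.numeric, logical(1))]
  setdiff(num, id_cols)
}

#' Stack used and available points into a use-availability design
#'
#' Each individual contributes its used locations (response 1) and the first
#' `ratio` x `n_used` rows of its availability pool (response 0). Because the
#' availability rows are a deterministic prefix of the per-individual pool,
#' the moving and resting designs for one individual draw from the same
#' shared pool (the smaller design's availability is nested in the larger's).
#'
#' @param used tibble of used locations with covariates and `individual_id`.
#' @param available tibble: the per-individual availability pools, same
#'   covariate columns.
#' @param behavior label stamped on the design (`"moving"`, `"resting"`, or
#'   `"combined"`).
#' @param ratio available:used ratio (default 20).
#' @return Tibble with `response` (1 used / 0 available), `behavior`, ids and
#'   covariates.
#' @export
build_design <- function(used, available, behavior = "moving", ratio = 20) {
  stopifnot("individual_id" %in% names(used), "individual_id" %in% names(available))
  if (nrow(used) == 0) stop("no used locations", call. = FALSE)
  ids <- unique(used$individual_id)
  missing_avail <- setdiff(ids, unique(available$individual_id))
  if (length(missing_avail)) {
    stop("individual(s) with used but no available rows: ",
         paste(missing_avail, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(names(used), names(available))
  rows <- purrr::map_dfr(ids, function(id) {
    u <- dplyr::filter(used, .data$individual_id == id)
    a <- dplyr::filter(available, .data$individual_id == id)
    na <- min(nrow(a), ratio * nrow(u))
    if (na < ratio * nrow(u)) {
      warning("availability pool for ", id, " smaller than ratio x used (",
              nrow(a), " < ", ratio * nrow(u), ")")
    }
    dplyr::bind_rows(
      dplyr::mutate(u[, shared], response = 1),
      dplyr::mutate(a[seq_len(na), shared], response = 0)
    )
  })
  dplyr::relocate(dplyr::mutate(rows, behavior = behavior),
                  "response", "behavior", "individual_id")
}

#' Standardize design covariates to zero mean and unit variance
#'
#' Applies the conventional z-score `(x - mean) / sd` to every numeric
#' covariate column (ids, coordinates and the response are left alone) so
#' model coefficients are comparable across covariates. The per-column means
#' and SDs are stored in the `"scaling"` attribute for back-transformation.
#'
#' @param design a use-availability design from [build_design].
#' @param cols columns to standardize (default: all numeric covariates).
#' @return The design with standardized columns and a `"scaling"` attribute
#'   (tibble of column, mean, sd).
#' @export
standardize_design <- function(design, cols = NULL) {
  cols <- design_covariate_cols(design, cols)
  mu <- vapply(design[cols], mean, numeric(1), na.rm = TRUE)
  sd <- vapply(design[cols], stats::sd, numeric(1), na.rm = TRUE)
  if (any(sd == 0 | !is.finite(sd))) {
    bad <- cols[sd == 0 | !is.finite(sd)]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(cols)) {
    design[[cols[i]]] <- (design[[cols[i]]] - mu[i]) / sd[i]
  }
  attr(design, "scaling") <- tibble::tibble(column = cols, mean = unname(mu),
                                            sd = unname(sd))
  design
}

#' Invert [standardize_design]
#'
#' @param design standardized design carrying a `"scaling"` attribute.
#' @return The design on the original covariate scale.
#' @export
unstandardize_design <- function(design) {
  sc <- attr(design, "scaling")
  if (is.null(sc)) return(design)
  for (i in seq_len(nrow(sc))) {
    design[[sc$column[i]]] <- design[[sc$column[i]]] * sc$sd[i] + sc$mean[i]
  }
  attr(design, "scaling") <- NULL
  design
}

#' Pairwise collinearity screen
#'
#' Flags covariate pairs whose absolute Pearson correlation exceeds the
#' threshold (strictly: `|r| = 0.6` stays admissible at the default); flagged
#' pairs are refused by [fit_mixed_logistic] when the screen is passed along.
#'
#' @param design use-availability design.
#' @param threshold admissibility threshold on `|r|` (default 0.6).
#' @param cols covariate columns (default: all numeric covariates).
#' @return An object of class `cor_screen`: correlation matrix, logical
#'   admissibility matrix, and a tibble of inadmissible pairs.
#' @export
screen_correlation <- function(design, threshold = 0.6, cols = NULL) {
  cols <- design_covariate_cols(design, cols)
  if (length(cols) < 2) stop("need >= 2 numeric covariates", call. = FALSE)
  r <- stats::cor(design[cols], use = "pairwise.complete.obs")
  admissible <- abs(r) <= threshold
  diag(admissible) <- TRUE
  pr <- which(!admissible & upper.tri(r), arr.ind = TRUE)
  structure(
    list(
      r = r,
      admissible = admissible,
      threshold = threshold,
      inadmissible = tibble::tibble(
        var1 = rownames(r)[pr[, 1]], var2 = colnames(r)[pr[, 2]],
        r = r[pr]
      )
    ),
    class = "cor_screen"
  )
}

#' @export
print.cor_screen <- function(x, ...) {
  cat(sprintf("<cor_screen> |r| > %g flags %d of %d pairs\n", x$threshold,
              nrow(x$inadmissible), sum(upper.tri(x$r))))
  if (nrow(x$inadmissible)) print(x$inadmissible)
  invisible(x)
}

strip_bars <- function(formula) {
  tl <- attr(stats::terms(formula), "term.labels")
  fixed <- tl[!grepl("|", tl, fixed = TRUE)]
  stats::reformulate(if (length(fixed)) fixed else "1",
                     response = if (length(formula) == 3) formula[[2]])
}

#' Fit a use-availability mixed logistic regression
#'
#' Binomial GLMM with a per-individual random intercept, the standard
#' exponential-RSF estimator for used-versus-available designs, fitted by
#' maximum likelihood (Laplace approximation via glmmTMB). If the formula has
#' no random-effect term, `(1 | individual_id)` is appended. The parameter
#' count `K` is the number of fixed effects (intercept included) plus one
#' variance parameter.
#'
#' @param formula model formula, e.g. `response ~ canopy_100 + tpi_100`.
#' @param design (standardized) use-availability design.
#' @param screen optional [screen_correlation] result; the fit refuses any
#'   covariate pair the screen flags.
#' @param allow_wide_ci downgrade convergence/identifiability failures to
#'   warnings (used by the interaction models, where near-empty
#'   category-state cells legitimately produce huge CIs).
#' @return An object of class `rsf_fit`: the glmmTMB model plus `K`, `LL`,
#'   `n`, `AICc`, a coefficient tibble with Wald 95% CIs, and the
#'   random-intercept SD.
#' @export
fit_mixed_logistic <- function(formula, design, screen = NULL,
                               allow_wide_ci = FALSE) {
  if (!any(grepl("|", all.names(formula), fixed = TRUE))) {
    formula <- stats::update(formula, . ~ . + (1 | individual_id))
  }
  fixed <- strip_bars(formula)
  vars <- all.vars(fixed[[3]])
  if (!is.null(screen)) {
    vv <- intersect(vars, rownames(screen$r))
    if (length(vv) > 1) {
      for (i in seq_along(vv)) for (j in seq_len(i - 1)) {
        if (!screen$admissible[vv[i], vv[j]]) {
          stop("covariates ", vv[j], " and ", vv[i],
               " are collinear (|r| > ", screen$threshold,
               ") and may not share a model", call. = FALSE)
        }
      }
    }
  }
  fit <- glmmTMB::glmmTMB(formula, data = design, family = stats::binomial())
  complain <- if (allow_wide_ci) warning else function(...) stop(..., call. = FALSE)
  if (!isTRUE(fit$fit$convergence == 0)) {
    complain("model did not converge: ", fit$fit$message)
  }
  est <- glmmTMB::fixef(fit)$cond
  vc <- tryCatch(stats::vcov(fit)$cond, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(est)) else sqrt(diag(vc))
  if (any(!is.finite(se))) {
    complain("non-finite standard errors (possible complete separation)")
  }
  if (!isTRUE(fit$sdr$pdHess)) {
    complain("Hessian not positive definite (possible separation or boundary fit)")
  }
  ll <- as.numeric(stats::logLik(fit))
  n <- nrow(design)
  k <- length(est) + 1L
  ransd <- tryCatch(
    sqrt(glmmTMB::VarCorr(fit)$cond[[1]][1, 1]),
    error = function(e) NA_real_
  )
  structure(
    list(
      model = fit,
      formula = formula,
      fixed_formula = fixed,
      K = k, LL = ll, n = n,
      AICc = aicc(ll, k, n),
      coefficients = tibble::tibble(
        term = names(est), estimate = unname(est), std_error = unname(se),
        conf_low = unname(est - 1.96 * se), conf_high = unname(est + 1.96 * se)
      ),
      ranef_sd = ransd,
      response_checksum = sum(design[[all.vars(formula)[1]]]),
      scaling = attr(design, "scaling")
    ),
    class = "rsf_fit"
  )
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("<rsf_fit> ", deparse(x$fixed_formula), "\n",
      sprintf("  n = %d, K = %d, LL = %.2f, AICc = %.2f, ranef SD = %.3f\n",
              x$n, x$K, x$LL, x$AICc, x$ranef_sd), sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param LL maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n sample size (must exceed `K + 1`).
#' @return AICc value.
#' @export
aicc <- function(LL, K, n) {
  if (any(n <= K + 1)) stop("`n` must exceed K + 1", call. = FALSE)
  -2 * LL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Compare candidate models by AICc
#'
#' @param fits a (preferably named) list of [fit_mixed_logistic] results
#'   fitted to the same data.
#' @return Tibble sorted by AICc with `delta_AICc` and Akaike weights
#'   (weights sum to 1; the best model's delta is 0).
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "rsf_fit")) fits <- list(fits)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  cks <- vapply(fits, `[[`, numeric(1), "response_checksum")
  if (length(unique(ns)) > 1 || length(unique(cks)) > 1) {
    stop("models were not fitted to identical data", call. = FALSE)
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  tab <- tibble::tibble(
    model = nm,
    covariates = vapply(fits, function(f) {
      paste(attr(stats::terms(f$fixed_formula), "term.labels"), collapse = " + ")
    }, character(1)),
    K = unname(vapply(fits, `[[`, numeric(1), "K")),
    LL = unname(vapply(fits, `[[`, numeric(1), "LL")),
    AICc = unname(vapply(fits, `[[`, numeric(1), "AICc"))
  )
  tab <- dplyr::arrange(tab, .data$AICc)
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  tab$weight <- exp(-tab$delta_AICc / 2) / sum(exp(-tab$delta_AICc / 2))
  dplyr::relocate(tab, "model", "covariates", "K", "AICc", "delta_AICc",
                  "weight", "LL")
}

#' Choose the most predictive spatial scale for one covariate
#'
#' Fits one univariate mixed logistic model per scale-suffixed column
#' (`<covariate>_<scale>`) and returns the scale with the lowest AICc; ties
#' go to the smallest scale.
#'
#' @param design (standardized) use-availability design.
#' @param covariate base covariate name (e.g. `"canopy"`).
#' @param scales candidate scales; defaults to every `covariate_<scale>`
#'   column present.
#' @return The chosen scale (numeric), with the per-scale AICc table in the
#'   `"table"` attribute.
#' @export
select_scale_univariate <- function(design, covariate, scales = NULL) {
  if (is.null(scales)) {
    pat <- paste0("^", covariate, "_([0-9]+)$")
    hits <- grep(pat, names(design), value = TRUE)
    scales <- as.numeric(sub(pat, "\\1", hits))
  }
  scales <- sort(scales)
  if (length(scales) == 0) stop("no scale-suffixed columns for ", covariate, call. = FALSE)
  rows <- purrr::map(scales, function(s) {
    col <- paste0(covariate, "_", s)
    f <- stats::reformulate(col, response = "response")
    fit <- tryCatch(fit_mixed_logistic(f, design), error = function(e) NULL)
    if (is.null(fit)) return(tibble::tibble(scale = s, AICc = NA_real_))
    tibble::tibble(scale = s, AICc = fit$AICc)
  })
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$AICc))) {
    stop("univariate fit failed at every scale for ", covariate, call. = FALSE)
  }
  best <- tab$scale[which(tab$AICc <= min(tab$AICc, na.rm = TRUE) + 1e-9)]
  out <- min(best) # tie -> smallest scale
  attr(out, "table") <- tab
  out
}

#' Behavior-state interaction models for management covariates
#'
#' Stacks the moving and resting designs (their availability rows come from
#' the same per-individual pool) and fits the four combined-behavior models:
#' canopy category x state, edge density x state, and the three-way patch
#' size and distance-to-edge interactions with canopy category and state.
#' Dense canopy is the reference category and moving the reference state, so
#' the `Resting` main effect is the resting-vs-moving selection contrast in
#' dense canopy. Near-empty category-state cells (rare resting use of sparse
#' canopy) produce wide CIs with a warning rather than an error.
#'
#' @param design_moving,design_resting behavior designs from [build_design]
#'   carrying `patch_cat`, `patch_size_ha`, `dist_edge` and
#'   `edge_density_<edge_scale>` columns (only the columns the selected
#'   `models` use are required).
#' @param edge_scale which edge-density scale enters the state interaction
#'   model (default 400).
#' @param models which of the four interaction models to fit.
#' @return Named list of `rsf_fit`s (`canopy_category`, `edge_density`,
#'   `patch_size`, `distance_to_edge`) plus the combined design as
#'   `"design"` attribute.
#' @export
fit_behavior_interactions <- function(design_moving, design_resting,
                                      edge_scale = 400,
                                      models = c("canopy_category",
                                                 "edge_density", "patch_size",
                                                 "distance_to_edge")) {
  models <- match.arg(models, several.ok = TRUE)
  ed_col <- paste0("edge_density_", edge_scale)
  need <- unique(c(
    if (any(models != "edge_density")) "patch_cat",
    if ("patch_size" %in% models) "patch_size_ha",
    if ("distance_to_edge" %in% models) "dist_edge",
    if ("edge_density" %in% models) ed_col
  ))
  for (d in list(design_moving, design_resting)) {
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("design lacks column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  comb <- dplyr::bind_rows(
    dplyr::mutate(unstandardize_design(design_moving), state = "moving"),
    dplyr::mutate(unstandardize_design(design_resting), state = "resting")
  )
  comb$state <- factor(comb$state, levels = c("moving", "resting"))
  if ("patch_cat" %in% need) {
    comb$canopy_cat <- factor(comb$patch_cat,
                              levels = c("dense", "sparse", "open", "moderate"))
    cells <- table(comb$canopy_cat[comb$response == 1],
                   comb$state[comb$response == 1])
    if (any(cells <= 1)) {
      warning("near-empty used category-state cell(s); interaction CIs will be wide")
    }
  }
  std_cols <- intersect(c("patch_size_ha", "dist_edge", ed_col), need)
  if (length(std_cols)) comb <- standardize_design(comb, cols = std_cols)

  forms <- list(
    canopy_category = response ~ canopy_cat * state,
    edge_density = stats::reformulate(paste0(ed_col, " * state"),
                                      response = "response"),
    patch_size = response ~ patch_size_ha * canopy_cat * state,
    distance_to_edge = response ~ dist_edge * canopy_cat * state
  )[models]
  fits <- purrr::map(forms, fit_mixed_logistic, design = comb,
                     allow_wide_ci = TRUE)
  attr(fits, "design") <- comb
  fits
}

#' Relative selection strength over a covariate grid
#'
#' `exp(fixed-effect linear predictor)` with the random intercept at zero,
#' normalized to the grid maximum — the standard way to draw RSF response
#' curves. The grid is interpreted on the same (standardized) scale the model
#' was fitted on; values outside the fitted covariate range trigger an
#' extrapolation warning.
#'
#' @param fit an `rsf_fit`.
#' @param newdata tibble of covariate values (factors as in the fit).
#' @return `newdata` with a `relative_selection` column (max 1).
#' @export
predict_relative_selection <- function(fit, newdata) {
  fixed <- fit$fixed_formula
  vars <- all.vars(fixed[[3]])
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("unknown covariate(s) in grid: model needs ",
                         paste(miss, collapse = ", "), call. = FALSE)
  fr <- fit$model$frame
  for (v in vars) {
    if (is.numeric(fr[[v]]) && is.numeric(newdata[[v]])) {
      rng <- range(fr[[v]], na.rm = TRUE)
      if (any(newdata[[v]] < rng[1] - 1e-9 | newdata[[v]] > rng[2] + 1e-9)) {
        warning("grid extrapolates beyond the fitted range of ", v)
      }
    }
    if (is.factor(fr[[v]]) && !is.factor(newdata[[v]])) {
      newdata[[v]] <- factor(newdata[[v]], levels = levels(fr[[v]]))
    }
  }
  tt <- stats::delete.response(stats::terms(stats::reformulate(
    attr(stats::terms(fixed), "term.labels"))))
  X <- stats::model.matrix(tt, newdata)
  est <- glmmTMB::fixef(fit$model)$cond
  eta <- drop(X[, names(est), drop = FALSE] %*% est)
  w <- exp(eta - max(eta))
  dplyr::mutate(tibble::as_tibble(newdata), relative_selection = w)
}
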