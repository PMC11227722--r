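#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an RSF fit
#'
#' @param x an `rsf_fit` from [fit_mixed_logistic].
#' @param unstandardize return estimates on the original covariate scale
#'   (divides each main-effect coefficient and its CI by the covariate's SD
#'   from the stored scaling record).
#' @param ... unused.
#' @return Tibble with term, estimate, std_error, conf_low, conf_high.
#' @export
tidy.rsf_fit <- function(x, unstandardize = FALSE, ...) {
  co <- x$coefficients
  if (unstandardize && !is.null(x$scaling)) {
    sc <- x$scaling
    m <- match(co$term, sc$column)
    f <- ifelse(is.na(m), 1, sc$sd[m])
    co <- dplyr::mutate(co,
                        estimate = .data$estimate / f,
                        std_error = .data$std_error / f,
                        conf_low = .data$conf_low / f,
                        conf_high = .data$conf_high / f)
  }
  co
}

#' @rdname tidy.rsf_fit
#' @export
glance.rsf_fit <- function(x, ...) {
  tibble::tibble(n = x$n, K = x$K, logLik = x$LL, AICc = x$AICc,
                 ranef_sd = x$ranef_sd)
}

#' Tidy a functional-response fit
#'
#' @param x an `fr_fit` from [fit_functional_response].
#' @param ... unused.
#' @export
tidy.fr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf_low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf_high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' @rdname tidy.fr_fit
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    conf_level = x$conf_level,
    offset = x$offset,
    r_squared = summary(x$model)$r.squared,
    label = classify_response(x)
  )
}
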