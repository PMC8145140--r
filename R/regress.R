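#' Simple linear dependency of one report column on another
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination `R^2 = 1 - SSE/SST`, the summary used to judge whether a
#' hotspot property (area, membership fluctuation) linearly explains
#' reliability.
#'
#' @param data Data frame.
#' @param x,y Column names (unquoted or strings) of the predictor and the
#'   response. At least 3 observations; `x` must not be constant. A constant
#'   `y` yields `r_squared = 0` with a warning.
#' @return One-row tibble: `predictor`, `response`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' linear_fit(naples_hotspots(), membership_std, reliability)
#' @export
linear_fit <- function(data, x, y) {
  xq <- rlang::as_name(rlang::enquo(x))
  yq <- rlang::as_name(rlang::enquo(y))
  xv <- data[[xq]]
  yv <- data[[yq]]
  if (is.null(xv) || is.null(yv)) {
    abort("both columns must exist in `data`.",
          class = "hotspotr_input_error")
  }
  if (length(xv) != length(yv)) {
    abort("`x` and `y` must have the same length.",
          class = "hotspotr_input_error")
  }
  if (length(xv) < 3) {
    abort("need at least 3 observations.", class = "hotspotr_input_error")
  }
  if (diff(range(xv)) == 0) {
    abort("constant predictor: the fit is degenerate.",
          class = "hotspotr_degenerate_fit")
  }
  fit <- lm(yv ~ xv)
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst == 0) {
    warn("constant response: r_squared set to 0.")
    0
  } else {
    1 - sum(stats::residuals(fit)^2) / sst
  }
  tibble(
    predictor = xq, response = yq,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, n = length(xv)
  )
}

#' Linear dependency of reliability on hotspot area and fluctuation
#'
#' Fits reliability against the hotspot area (km^2) and against the
#' standard deviation of the membership degrees, reporting both `R^2`
#' values. On reference hotspot tables the area explains almost nothing of
#' the reliability while the membership fluctuation explains most of it.
#'
#' @param report Data frame with columns `reliability`, `area_km2` and
#'   `membership_std` (a [hotspot_reliability()] report, or
#'   [naples_hotspots()]).
#' @return Two-row tibble, one row per predictor (see [linear_fit()]).
#' @examples
#' analyze_reliability(naples_hotspots())
#' @export
analyze_reliability <- function(report) {
  need <- c("reliability", "area_km2", "membership_std")
  if (!all(need %in% names(report))) {
    abort(paste("`report` must contain columns:",
                paste(need, collapse = ", ")),
          class = "hotspotr_input_error")
  }
  dplyr::bind_rows(
    linear_fit(report, area_km2, reliability),
    linear_fit(report, membership_std, reliability)
  )
}

#' Reliability-dependency scatter plots
#'
#' Scatter of reliability against a chosen hotspot property with the OLS
#' line and its `R^2` in the subtitle.
#'
#' @param report Data frame with a `reliability` column.
#' @param predictor Unquoted column name to put on the x axis
#'   (default `membership_std`).
#' @return A ggplot object.
#' @export
plot_reliability_trend <- function(report, predictor = membership_std) {
  pq <- rlang::enquo(predictor)
  fit <- linear_fit(report, !!pq, reliability)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = !!pq, y = .data$reliability)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      subtitle = sprintf("R² = %.3f (n = %d)", fit$r_squared, fit$n),
      y = "reliability"
    )
}
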