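#' Fuzzy entropy and hotspot reliability
#'
#' `binary_entropy()` is Shannon's function
#' `h(u) = -u log2(u) - (1 - u) log2(1 - u)` (with `h(0) = h(1) = 0`), the
#' De Luca-Termini entropy of a single membership degree: it is 0 for crisp
#' degrees, 1 at `u = 1/2`, symmetric about 1/2, increasing on `[0, 1/2]`
#' and decreasing on `[1/2, 1]`.
#'
#' `fuzzy_entropy()` is the normalised De Luca-Termini entropy of a whole
#' membership vector, `H = mean(h(u))`: 0 exactly when every degree is 0 or
#' 1 (a crisp set) and 1 exactly when every degree is 1/2 (maximal
#' fuzziness).
#'
#' `reliability_score()` is `R = 1 - H`: the reliability assigned to a
#' hotspot from the membership degrees of all events to its cluster. A
#' hotspot whose memberships are polarised near 0/1 is reliable (`R` near
#' 1); one whose memberships hover near 1/2 is not (`R` near 0).
#'
#' `membership_std()` is the population standard deviation (divisor `N`) of
#' a membership vector — the "fluctuation" of the degrees of belonging,
#' which tracks reliability approximately linearly in practice.
#'
#' @param u Numeric vector of membership degrees in `[0, 1]`. Values outside
#'   the unit interval by more than a small numerical slack are an error.
#' @return `binary_entropy()`: entropies, same length as `u`. The others: a
#'   single number in `[0, 1]` (`membership_std()` in `[0, 1/2]`).
#' @examples
#' binary_entropy(c(0, 0.25, 0.5, 1))
#' fuzzy_entropy(c(1, 0.5, 0))      # 1/3
#' reliability_score(c(1, 1, 0, 0)) # crisp -> 1
#' membership_std(c(0, 1))          # 0.5
#' @export
binary_entropy <- function(u) {
  u <- check_unit_interval(u, "membership degrees")
  h <- numeric(length(u))
  mid <- u > 0 & u < 1
  um <- u[mid]
  h[mid] <- -um * log2(um) - (1 - um) * log2(1 - um)
  h
}

#' @rdname binary_entropy
#' @export
fuzzy_entropy <- function(u) {
  if (length(u) < 1) {
    abort("empty membership vector.", class = "hotspotr_domain_error")
  }
  mean(binary_entropy(u))
}

#' @rdname binary_entropy
#' @export
reliability_score <- function(u) {
  1 - fuzzy_entropy(u)
}

#' @rdname binary_entropy
#' @export
membership_std <- function(u) {
  u <- check_unit_interval(u, "membership degrees")
  if (length(u) < 1) {
    abort("empty membership vector.", class = "hotspotr_domain_error")
  }
  sqrt(mean((u - mean(u))^2))
}

check_unit_interval <- function(u, what, tol = 1e-9) {
  if (!is.numeric(u) || anyNA(u)) {
    abort(paste0(what, " must be numeric and non-missing."),
          class = "hotspotr_domain_error")
  }
  if (any(u < -tol | u > 1 + tol)) {
    abort(paste0(what, " must lie in [0, 1]."),
          class = "hotspotr_domain_error")
  }
  pmin(pmax(u, 0), 1)
}

#' Per-hotspot reliability report from an EFCM fit
#'
#' For every cluster of a converged [efcm()] fit, computes the normalised
#' De Luca-Termini fuzzy entropy `H` of its membership row (over all `N`
#' events, including any background noise), the reliability `R = 1 - H`,
#' the population standard deviation of the memberships, and the circle
#' area `pi * radius^2` converted to km^2 (coordinates are assumed to be in
#' meters). If the events carry projection metadata (see
#' [project_events()]), hotspot centers are also reported as
#' longitude/latitude.
#'
#' @param fit An `"efcm"` object.
#' @return A tibble of class `"hotspot_report"` with one row per hotspot:
#'   `hotspot`, `x`, `y` (center, meters), `lat`, `lon` (when projection
#'   metadata is available), `radius_m`, `area_km2`, `membership_std`,
#'   `entropy`, `reliability`.
#' @examples
#' field <- simulate_events(
#'   clusters = tibble::tibble(x = c(2000, 8000), y = c(2000, 8000),
#'                             sd = 300, n = 100),
#'   noise_fraction = 0.02, bbox = c(0, 10000, 0, 10000), seed = 1
#' )
#' fit <- efcm(field, c0 = 6, m = 3, radius_mode = "half", seed = 1)
#' hotspot_reliability(fit)
#' @export
hotspot_reliability <- function(fit) {
  if (!inherits(fit, "efcm")) {
    abort("`fit` must be an efcm() fit.", class = "hotspotr_input_error")
  }
  h <- apply(fit$u, 1, fuzzy_entropy)
  rep <- fit$prototypes |>
    dplyr::transmute(
      hotspot = .data$hotspot,
      x = .data$x, y = .data$y,
      radius_m = .data$radius,
      area_km2 = pi * .data$radius^2 * 1e-6,
      membership_std = apply(fit$u, 1, membership_std),
      entropy = h,
      reliability = 1 - h
    )
  proj <- attr(fit$events, "projection", exact = TRUE)
  if (!is.null(proj)) {
    ll <- utm_to_latlon(rep$x, rep$y, zone = proj$zone, south = proj$south)
    rep <- dplyr::mutate(rep, lat = ll$lat, lon = ll$lon,
                         .after = "y")
  }
  new_hotspot_report(rep, projection = proj)
}

new_hotspot_report <- function(x, projection = NULL) {
  x <- as_tibble(x)
  attr(x, "projection") <- projection
  class(x) <- c("hotspot_report", class(x))
  x
}

#' Detect hotspots and score their reliability
#'
#' The end-to-end pipeline: runs EFCM on planar events, then attaches the
#' entropy-based reliability to every detected hotspot, and (optionally)
#' classifies the reliabilities into Low/Mean/High.
#'
#' @param events Planar events, as for [efcm()].
#' @param ... Passed on to [efcm()] (`c0`, `m`, `seed`, ...).
#' @param scheme Optional [reliability_scheme()] used to add a
#'   `reliability_class` column; `NULL` skips classification.
#' @return A `"hotspot_report"` tibble (see [hotspot_reliability()]); the
#'   underlying `"efcm"` fit is attached as attribute `"fit"`.
#' @examples
#' field <- simulate_events(
#'   clusters = tibble::tibble(x = c(2000, 8000), y = c(2000, 8000),
#'                             sd = 300, n = 100),
#'   noise_fraction = 0.02, bbox = c(0, 10000, 0, 10000), seed = 1
#' )
#' detect_hotspots(field, c0 = 6, m = 3, radius_mode = "half", seed = 1,
#'                 scheme = reliability_scheme())
#' @export
detect_hotspots <- function(events, ..., scheme = NULL) {
  fit <- efcm(events, ...)
  rep <- hotspot_reliability(fit)
  if (!is.null(scheme)) {
    rep <- classify_reliability(rep, scheme = scheme)
  }
  attr(rep, "fit") <- fit
  rep
}

#' Map of classified hotspot reliabilities
#'
#' Draws each hotspot circle at its planar center, coloured by reliability
#' (or by reliability class when present) — a minimal counterpart of a
#' reliability thematic map.
#'
#' @param object A `"hotspot_report"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hotspot_report
#' @export
autoplot.hotspot_report <- function(object, ...) {
  circles <- tidyr::crossing(
    as_tibble(object),
    theta = seq(0, 2 * pi, length.out = 97)
  ) |>
    dplyr::mutate(cx = .data$x + .data$radius_m * cos(.data$theta),
                  cy = .data$y + .data$radius_m * sin(.data$theta))
  fill_var <- if ("reliability_class" %in% names(object)) {
    "reliability_class"
  } else {
    "reliability"
  }
  ggplot2::ggplot(circles,
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               group = .data$hotspot,
                               fill = .data[[fill_var]])) +
    ggplot2::geom_polygon(alpha = 0.6, colour = "grey30",
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = fill_var)
}
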