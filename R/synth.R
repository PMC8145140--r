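#' Simulate a spatial event field
#'
#' Generates point events with the structure circular-hotspot detection
#' assumes: several compact isotropic Gaussian clusters of events over a
#' bounded planar study region, plus uniform background noise. Used to
#' study the detector where no real patient-residence data can be shared.
#'
#' @param clusters Data frame with one row per cluster and columns `x`,
#'   `y` (mean, meters), `sd` (isotropic standard deviation, meters, `> 0`)
#'   and `n` (event count, `>= 1`). Cluster means must lie inside `bbox`.
#' @param noise_fraction Fraction of `sum(n)` added as uniform background
#'   events over the bounding box, in `[0, 1)`. The noise count is
#'   `ceiling(noise_fraction * sum(n))`.
#' @param bbox Bounding box `c(xmin, xmax, ymin, ymax)` in meters. When
#'   `NULL`, the box spans the cluster means plus a 4-`sd` margin.
#' @param seed Optional integer seed; identical seeds reproduce the field
#'   exactly. The caller's RNG state is preserved.
#' @return Tibble with one row per event: `event_id`, `x`, `y` and
#'   `cluster` (generating cluster index; `-1` for background noise).
#' @examples
#' field <- simulate_events(
#'   clusters = tibble::tibble(x = c(2000, 8000), y = c(2000, 8000),
#'                             sd = 300, n = 150),
#'   noise_fraction = 0.02, bbox = c(0, 10000, 0, 10000), seed = 7
#' )
#' dplyr::count(field, cluster)
#' @export
simulate_events <- function(clusters, noise_fraction = 0.02, bbox = NULL,
                            seed = NULL) {
  check_cluster_spec(clusters)
  if (!is.numeric(noise_fraction) || noise_fraction < 0 ||
        noise_fraction >= 1) {
    abort("`noise_fraction` must lie in [0, 1).",
          class = "hotspotr_config_error")
  }
  if (is.null(bbox)) {
    pad <- 4 * max(clusters$sd)
    bbox <- c(min(clusters$x) - pad, max(clusters$x) + pad,
              min(clusters$y) - pad, max(clusters$y) + pad)
  }
  if (length(bbox) != 4 || bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    abort("`bbox` must be c(xmin, xmax, ymin, ymax) with positive extent.",
          class = "hotspotr_config_error")
  }
  if (any(clusters$x < bbox[1] | clusters$x > bbox[2] |
            clusters$y < bbox[3] | clusters$y > bbox[4])) {
    abort("all cluster means must lie inside `bbox`.",
          class = "hotspotr_config_error")
  }
  draw <- function() {
    pts <- purrr::pmap_dfr(clusters, function(x, y, sd, n, ...) {
      tibble(x = rnorm(n, x, sd), y = rnorm(n, y, sd))
    })
    pts$cluster <- rep(seq_len(nrow(clusters)), clusters$n)
    n_noise <- ceiling(noise_fraction * sum(clusters$n))
    if (n_noise > 0) {
      pts <- dplyr::bind_rows(pts, tibble(
        x = runif(n_noise, bbox[1], bbox[2]),
        y = runif(n_noise, bbox[3], bbox[4]),
        cluster = -1L
      ))
    }
    pts
  }
  pts <- if (is.null(seed)) draw() else {
    withr::with_seed(as.integer(seed), draw())
  }
  dplyr::mutate(pts, event_id = dplyr::row_number(), .before = 1)
}

check_cluster_spec <- function(clusters) {
  if (!is.data.frame(clusters) || nrow(clusters) == 0) {
    abort("`clusters` must be a non-empty data frame.",
          class = "hotspotr_config_error")
  }
  need <- c("x", "y", "sd", "n")
  if (!all(need %in% names(clusters))) {
    abort("`clusters` needs columns x, y, sd, n.",
          class = "hotspotr_config_error")
  }
  if (any(clusters$sd <= 0)) {
    abort("cluster `sd` must be positive.", class = "hotspotr_config_error")
  }
  if (any(clusters$n < 1)) {
    abort("cluster `n` must be >= 1.", class = "hotspotr_config_error")
  }
  invisible(clusters)
}

#' Rescale the compactness of a simulated field
#'
#' Multiplies every cluster standard deviation by `scale`, leaving means,
#' counts and everything else unchanged. Sweeping `scale` upward spreads
#' the clusters, which raises membership fluctuation and therefore lowers
#' the reliability of the recovered hotspots.
#'
#' @param clusters Cluster specification (see [simulate_events()]).
#' @param scale Positive multiplier.
#' @return The rescaled cluster specification.
#' @examples
#' spec <- tibble::tibble(x = 0, y = 0, sd = 100, n = 50)
#' perturb_compactness(spec, 2)$sd
#' @export
perturb_compactness <- function(clusters, scale) {
  check_cluster_spec(clusters)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("`scale` must be a positive number.",
          class = "hotspotr_config_error")
  }
  dplyr::mutate(clusters, sd = .data$sd * scale)
}
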