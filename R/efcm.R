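#' Extended fuzzy c-means clustering with circular volume prototypes
#'
#' Runs the extended fuzzy c-means (EFCM) algorithm on a set of planar point
#' events. Unlike classical fuzzy c-means, each cluster prototype is a circle
#' (a center plus a radius derived from the fuzzy covariance of the cluster),
#' the dissimilarity between an event and a prototype is the Euclidean
#' distance to the center minus the radius, floored at zero, and the number
#' of clusters is *not* fixed: starting from `c0` clusters, the two most
#' mutually inclusive clusters are merged whenever their inclusion similarity
#' has stabilised and exceeds the adaptive threshold `1 / (C - 1)`. The
#' fuzziness of the converged partition feeds the hotspot reliability score
#' (see [hotspot_reliability()]).
#'
#' Cluster radii are released gradually: at every iteration the radius of each
#' cluster is scaled by `beta / C`, where the integer `beta` starts at 1 and
#' grows toward the current cluster count `C` while the merging process
#' stalls. This keeps prototypes point-like early on (so that co-located
#' clusters stay similar and can merge) and lets them attain their full
#' volume once the cluster count settles.
#'
#' @param events Data frame with numeric columns `x` and `y`, planar
#'   coordinates in meters (see [project_events()] for longitude/latitude
#'   input). Clustering raw geographic degrees is refused because the
#'   prototype dissimilarity is Euclidean.
#' @param c0 Initial number of clusters (`>= 2`, `<= nrow(events)`). The
#'   algorithm only ever reduces the cluster count, so `c0` is an upper bound
#'   on the number of detected hotspots.
#' @param m Fuzzifier exponent, `> 1`. Larger values give softer memberships;
#'   `m = 2` is the classical choice.
#' @param epsilon Convergence tolerance on the maximum absolute change of the
#'   partition matrix between consecutive iterations.
#' @param eta Merge-stability tolerance: a merge (or a `beta` increment) is
#'   only considered once the maximum inter-cluster similarity changed by
#'   less than `eta` since the previous iteration.
#' @param max_iter Iteration cap. If reached before convergence the best
#'   state is returned with `converged = FALSE`.
#' @param seed Optional integer seed for the random initialisation of the
#'   partition matrix; identical seeds give identical runs. The caller's RNG
#'   state is preserved.
#' @param radius_mode How the radius is derived from the fuzzy covariance
#'   `P` of a cluster: `"full"` uses `det(P)^(1/n)` (with `n = 2` features),
#'   `"half"` uses `det(P)^(1/(2n))`. `"full"` matches the method as
#'   published; note that for `n = 2` it has units of area, so its magnitude
#'   depends on the coordinate scale. `"half"` yields a proper length (the
#'   geometric mean standard deviation of the cluster) and is recommended for
#'   meter-scale coordinates.
#' @param beta_mode When the radius-release parameter `beta` is incremented
#'   while no merge happens: `"gated"` increments only once the similarity
#'   has stabilised (`|S* - S*_prev| < eta`) and the top similarity is at or
#'   below the adaptive threshold; `"eager"` increments whenever the top
#'   similarity exceeds the threshold but the stability gate blocked the
#'   merge. Both appear in published statements of the algorithm; `"gated"`
#'   follows its operational pseudocode and is the default.
#' @param verbose Print a one-line summary of every iteration.
#'
#' @return An object of class `"efcm"`: a list with elements
#'   * `u` — final `C x N` partition matrix (columns sum to 1),
#'   * `prototypes` — tibble with one row per cluster: `hotspot`, center
#'     `x`, `y`, `radius`, and covariance entries `sxx`, `sxy`, `syy`,
#'   * `trace` — per-iteration tibble (`iteration`, `n_clusters`, `beta`,
#'     `s_star`, `delta_u`, `merged`, `dropped`),
#'   * `converged`, `iterations`, `n_events`, `config`, and the input
#'     `events` (with projection metadata, if any, preserved).
#'
#' @examples
#' field <- simulate_events(
#'   clusters = tibble::tibble(x = c(2000, 8000), y = c(2000, 8000),
#'                             sd = 300, n = 100),
#'   noise_fraction = 0.02, bbox = c(0, 10000, 0, 10000), seed = 1
#' )
#' fit <- efcm(field, c0 = 6, m = 3, radius_mode = "half", seed = 1)
#' fit
#' tidy(fit)
#' @seealso [hotspot_reliability()], [detect_hotspots()]
#' @export
efcm <- function(events, c0 = 30, m = 2, epsilon = 1e-4, eta = 0.01,
                 max_iter = 200, seed = NULL,
                 radius_mode = c("full", "half"),
                 beta_mode = c("gated", "eager"),
                 verbose = FALSE) {
  radius_mode <- match.arg(radius_mode)
  beta_mode <- match.arg(beta_mode)
  x <- as_event_matrix(events)
  n_pts <- nrow(x)
  if (!is.numeric(c0) || c0 < 2) {
    abort("`c0` must be an integer >= 2.", class = "hotspotr_config_error")
  }
  if (c0 > n_pts) {
    abort("`c0` cannot exceed the number of events.",
          class = "hotspotr_config_error")
  }
  if (!is.numeric(m) || m <= 1) {
    abort("fuzzifier `m` must be > 1.", class = "hotspotr_config_error")
  }
  if (epsilon <= 0 || eta <= 0) {
    abort("`epsilon` and `eta` must be positive.",
          class = "hotspotr_config_error")
  }
  c0 <- as.integer(c0)

  u <- if (is.null(seed)) {
    init_partition(c0, n_pts)
  } else {
    withr::with_seed(as.integer(seed), init_partition(c0, n_pts))
  }

  n_clusters <- c0
  beta <- 1L
  s_star_prev <- 1 # so no merge can fire before similarity stabilises
  trace <- vector("list", max_iter)
  converged <- FALSE
  centers <- NULL
  radii <- NULL

  for (iter in seq_len(max_iter)) {
    structural <- FALSE

    # drop clusters that captured no membership mass
    mass <- rowSums(u)
    dropped <- sum(mass <= .mass_tol)
    if (dropped > 0) {
      u <- u[mass > .mass_tol, , drop = FALSE]
      u <- sweep(u, 2, colSums(u), "/")
      n_clusters <- nrow(u)
      beta <- min(beta, n_clusters)
      structural <- TRUE
    }

    centers <- efcm_centers(u, x, m)
    covs <- efcm_covariances(u, x, centers, m)
    radii <- vapply(covs, efcm_radius, numeric(1), mode = radius_mode)
    radii <- efcm_enlarge_radius(radii, beta, n_clusters)

    delta <- efcm_distances(x, centers, radii)
    u_new <- efcm_memberships(delta, m)

    s_star <- NA_real_
    merged <- FALSE
    if (n_clusters >= 2) {
      s <- efcm_similarity(u_new)
      step <- efcm_merge_step(u_new, beta, s_star_prev, eta,
                              beta_mode = beta_mode, similarity = s)
      s_star <- step$s_star
      merged <- step$merged
      u_new <- step$u
      beta <- step$beta
      n_clusters <- nrow(u_new)
      s_star_prev <- s_star
      if (merged) structural <- TRUE
    }

    delta_u <- if (structural || nrow(u_new) != nrow(u)) {
      NA_real_
    } else {
      max(abs(u_new - u))
    }
    u <- u_new
    trace[[iter]] <- tibble(
      iteration = iter, n_clusters = n_clusters, beta = beta,
      s_star = s_star, delta_u = delta_u, merged = merged,
      dropped = as.integer(dropped)
    )
    if (verbose) {
      message(sprintf("iter %3d  C=%2d  beta=%2d  S*=%s  max|dU|=%s%s",
                      iter, n_clusters, beta,
                      formatC(s_star, digits = 3, format = "f"),
                      formatC(delta_u, digits = 2, format = "g"),
                      if (merged) "  [merge]" else ""))
    }
    if (!is.na(delta_u) && delta_u <= epsilon) {
      converged <- TRUE
      break
    }
  }

  # final volume prototypes, recomputed from the converged partition
  centers <- efcm_centers(u, x, m)
  covs <- efcm_covariances(u, x, centers, m)
  radii <- vapply(covs, efcm_radius, numeric(1), mode = radius_mode)
  radii <- efcm_enlarge_radius(radii, beta, n_clusters)

  prototypes <- tibble(
    hotspot = seq_len(n_clusters),
    x = centers[, 1], y = centers[, 2],
    radius = radii,
    sxx = vapply(covs, function(p) p[1, 1], numeric(1)),
    sxy = vapply(covs, function(p) p[1, 2], numeric(1)),
    syy = vapply(covs, function(p) p[2, 2], numeric(1))
  )

  structure(
    list(
      u = u,
      prototypes = prototypes,
      trace = dplyr::bind_rows(trace),
      converged = converged,
      iterations = if (converged) iter else max_iter,
      n_events = n_pts,
      config = list(c0 = c0, m = m, epsilon = epsilon, eta = eta,
                    max_iter = max_iter, seed = seed,
                    radius_mode = radius_mode, beta_mode = beta_mode),
      events = events
    ),
    class = "efcm"
  )
}

.mass_tol <- 1e-12
# distances below this are "inside the circle" for the membership update
.zero_tol <- 1e-12

init_partition <- function(c0, n_pts) {
  u <- matrix(runif(c0 * n_pts), c0, n_pts)
  sweep(u, 2, colSums(u), "/")
}

as_event_matrix <- function(events) {
  if (is.matrix(events)) {
    x <- events
  } else {
    if (!is.data.frame(events)) {
      abort("`events` must be a data frame (or matrix) of planar coordinates.",
            class = "hotspotr_input_error")
    }
    if (!all(c("x", "y") %in% names(events))) {
      if (all(c("lat", "lon") %in% names(events))) {
        abort(paste0(
          "`events` has lat/lon but no planar x/y columns. The prototype ",
          "dissimilarity is Euclidean, so cluster projected coordinates: ",
          "see project_events()."
        ), class = "hotspotr_input_error")
      }
      abort("`events` must have numeric columns `x` and `y`.",
            class = "hotspotr_input_error")
    }
    x <- cbind(events$x, events$y)
  }
  storage.mode(x) <- "double"
  if (nrow(x) < 2 || ncol(x) != 2 || !all(is.finite(x))) {
    abort("`events` must hold >= 2 finite 2-D points.",
          class = "hotspotr_input_error")
  }
  x
}

#' Low-level EFCM update steps
#'
#' The individual estimation steps of one EFCM iteration, exposed for
#' inspection and testing. `efcm_centers()` returns the membership-weighted
#' cluster centers; `efcm_covariances()` the fuzzy covariance matrix of each
#' cluster; `efcm_radius()` converts one covariance matrix into a circle
#' radius; `efcm_enlarge_radius()` applies the `beta / C` release factor;
#' `efcm_distances()` computes the prototype dissimilarity
#' `max(0, d - r)` of every event to every circle; `efcm_memberships()`
#' performs the constrained membership update; `efcm_similarity()` computes
#' the pairwise inclusion index of the clusters; and `efcm_merge_step()`
#' merges the most similar pair (or advances `beta`) under the stability and
#' adaptive-threshold rules.
#'
#' @param u Partition matrix, `C x N`, columns summing to 1.
#' @param x Event coordinates, `N x 2`.
#' @param m Fuzzifier (`> 1`).
#' @param centers `C x 2` matrix of cluster centers.
#' @param p A single `2 x 2` symmetric positive semi-definite covariance.
#' @param mode `"full"` for `det(p)^(1/2)`, `"half"` for `det(p)^(1/4)`.
#' @param radius Radius (or vector of radii) to enlarge.
#' @param beta Integer radius-release parameter, clamped to `[1, n_clusters]`.
#' @param n_clusters Current number of clusters.
#' @param radii Vector of `C` circle radii.
#' @param delta `C x N` matrix of prototype dissimilarities (`>= 0`).
#' @param s_star_prev Maximum inter-cluster similarity at the previous
#'   iteration.
#' @param eta Merge-stability tolerance.
#' @param beta_mode `"gated"` or `"eager"`; see [efcm()].
#' @param similarity Optional precomputed similarity matrix (as returned by
#'   `efcm_similarity()`); computed from `u` when omitted.
#'
#' @return `efcm_centers()`: `C x 2` matrix. `efcm_covariances()`: list of
#'   `2 x 2` matrices. `efcm_radius()` / `efcm_enlarge_radius()`:
#'   non-negative numeric. `efcm_distances()`: `C x N` matrix.
#'   `efcm_memberships()`: `C x N` partition matrix with unit column sums.
#'   `efcm_similarity()`: symmetric `C x C` matrix with zero diagonal.
#'   `efcm_merge_step()`: list with `u`, `beta`, `s_star`, `merged`, `pair`.
#'
#' @examples
#' x <- cbind(c(0, 2, 10), c(0, 0, 0))
#' u <- matrix(c(0.8, 0.7, 0.1,
#'               0.2, 0.3, 0.9), nrow = 2, byrow = TRUE)
#' efcm_centers(u, x, m = 2)
#' @name efcm_steps
NULL

#' @rdname efcm_steps
#' @export
efcm_centers <- function(u, x, m) {
  um <- u^m
  mass <- rowSums(um)
  if (any(mass <= .mass_tol)) {
    abort("degenerate cluster: a membership row carries no mass.",
          class = "hotspotr_degenerate_cluster")
  }
  (um %*% x) / mass
}

#' @rdname efcm_steps
#' @export
efcm_covariances <- function(u, x, centers, m) {
  um <- u^m
  mass <- rowSums(um)
  if (any(mass <= .mass_tol)) {
    abort("degenerate cluster: a membership row carries no mass.",
          class = "hotspotr_degenerate_cluster")
  }
  lapply(seq_len(nrow(u)), function(i) {
    d <- sweep(x, 2, centers[i, ])
    p <- crossprod(d * um[i, ], d) / mass[i]
    (p + t(p)) / 2
  })
}

#' @rdname efcm_steps
#' @export
efcm_radius <- function(p, mode = c("full", "half")) {
  mode <- match.arg(mode)
  dt <- p[1, 1] * p[2, 2] - p[1, 2] * p[2, 1]
  scale <- max(abs(p))^2
  if (dt < -1e-10 * max(scale, 1)) {
    abort("invalid covariance: negative determinant.",
          class = "hotspotr_invalid_covariance")
  }
  dt <- max(dt, 0)
  if (mode == "full") dt^(1 / 2) else dt^(1 / 4)
}

#' @rdname efcm_steps
#' @export
efcm_enlarge_radius <- function(radius, beta, n_clusters) {
  beta <- pmin(pmax(beta, 1), n_clusters)
  radius * beta / n_clusters
}

#' @rdname efcm_steps
#' @export
efcm_distances <- function(x, centers, radii) {
  d2 <- outer(rowSums(centers^2), rep(1, nrow(x))) -
    2 * centers %*% t(x) +
    outer(rep(1, nrow(centers)), rowSums(x^2))
  d <- sqrt(pmax(d2, 0))
  pmax(d - radii, 0)
}

#' @rdname efcm_steps
#' @export
efcm_memberships <- function(delta, m) {
  c_n <- nrow(delta)
  n_pts <- ncol(delta)
  u <- matrix(0, c_n, n_pts)
  inside <- delta <= .zero_tol
  phi <- colSums(inside)
  # events inside at least one circle share membership equally among those
  zero_cols <- phi > 0
  if (any(zero_cols)) {
    u[, zero_cols] <- inside[, zero_cols, drop = FALSE] /
      rep(phi[zero_cols], each = c_n)
  }
  if (any(!zero_cols)) {
    # ratio form of the update, scaled by the column minimum so that the
    # negative power can never overflow
    d <- delta[, !zero_cols, drop = FALSE]
    dmin <- apply(d, 2, min)
    inv <- sweep(d, 2, dmin, "/")^(-2 / (m - 1))
    u[, !zero_cols] <- sweep(inv, 2, colSums(inv), "/")
  }
  u
}

#' @rdname efcm_steps
#' @export
efcm_similarity <- function(u) {
  c_n <- nrow(u)
  if (c_n < 2) {
    abort("similarity needs at least two clusters.",
          class = "hotspotr_input_error")
  }
  mass <- rowSums(u)
  if (any(mass <= .mass_tol)) {
    abort("degenerate cluster: a membership row carries no mass.",
          class = "hotspotr_degenerate_cluster")
  }
  s <- matrix(0, c_n, c_n)
  for (i in seq_len(c_n - 1)) {
    for (k in seq.int(i + 1, c_n)) {
      s[i, k] <- sum(pmin(u[i, ], u[k, ])) / min(mass[i], mass[k])
      s[k, i] <- s[i, k]
    }
  }
  diag(s) <- 0
  s
}

#' @rdname efcm_steps
#' @export
efcm_merge_step <- function(u, beta, s_star_prev, eta,
                            beta_mode = c("gated", "eager"),
                            similarity = NULL) {
  beta_mode <- match.arg(beta_mode)
  s <- similarity %||% efcm_similarity(u)
  c_n <- nrow(u)
  # most similar pair; ties broken by lowest (i, k) lexicographically
  s_star <- max(s)
  cand <- which(s == s_star & upper.tri(s), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  pair <- cand[1, ]
  merged <- FALSE
  alpha <- 1 / (c_n - 1)
  if (abs(s_star - s_star_prev) < eta) {
    if (s_star > alpha) {
      u[pair[1], ] <- u[pair[1], ] + u[pair[2], ]
      u <- u[-pair[2], , drop = FALSE]
      merged <- TRUE
    } else if (beta_mode == "gated") {
      beta <- min(c_n, beta + 1)
    }
  } else if (beta_mode == "eager" && s_star > alpha) {
    beta <- min(c_n, beta + 1)
  }
  list(u = u, beta = as.integer(beta), s_star = s_star, merged = merged,
       pair = as.integer(pair))
}

#' @export
print.efcm <- function(x, ...) {
  cat(sprintf(
    "EFCM fit: %d events, %d -> %d clusters, %d iterations (%s)\n",
    x$n_events, x$config$c0, nrow(x$u), x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat(sprintf("  m = %g, epsilon = %g, eta = %g, radius_mode = %s\n",
              x$config$m, x$config$epsilon, x$config$eta,
              x$config$radius_mode))
  print(x$prototypes)
  invisible(x)
}

#' Tidiers for EFCM fits
#'
#' `tidy()` returns one row per detected cluster (center, radius, covariance
#' entries and total membership mass); `glance()` returns a one-row summary
#' of the run.
#'
#' @param x An `"efcm"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy efcm
#' @export
tidy.efcm <- function(x, ...) {
  dplyr::mutate(x$prototypes, mass = rowSums(x$u))
}

#' @rdname tidy.efcm
#' @method glance efcm
#' @export
glance.efcm <- function(x, ...) {
  tibble(
    n_events = x$n_events,
    c0 = x$config$c0,
    n_clusters = nrow(x$u),
    iterations = x$iterations,
    converged = x$converged,
    beta = dplyr::last(x$trace$beta),
    s_star = dplyr::last(x$trace$s_star)
  )
}

#' Plot an EFCM fit
#'
#' Events are drawn in their planar coordinates, coloured by their
#' highest-membership cluster, with each volume prototype overlaid as a
#' circle.
#'
#' @param object An `"efcm"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot efcm
#' @export
autoplot.efcm <- function(object, ...) {
  x <- as_event_matrix(object$events)
  pts <- tibble(
    x = x[, 1], y = x[, 2],
    cluster = factor(apply(object$u, 2, which.max))
  )
  circles <- tidyr::crossing(object$prototypes,
                             theta = seq(0, 2 * pi, length.out = 97)) |>
    dplyr::mutate(cx = .data$x + .data$radius * cos(.data$theta),
                  cy = .data$y + .data$radius * sin(.data$theta))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                        alpha = 0.6, size = 0.8) +
    ggplot2::geom_path(
      data = circles,
      ggplot2::aes(x = .data$cx, y = .data$cy, group = .data$hotspot),
      linewidth = 0.4
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "cluster")
}
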