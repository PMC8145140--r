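# Independent numeric oracles and shared synthetic study fields.

# Constrained minimiser of sum_i u_i^m * delta_i^2 over the probability
# simplex, solved numerically (golden-section for C = 2, Nelder-Mead on the
# reduced simplex for C = 3). Independent of the closed-form membership
# update it is used to check.
oracle_memberships <- function(delta, m) {
  stopifnot(all(delta > 0), length(delta) %in% 2:3)
  obj <- function(u) sum(u^m * delta^2)
  if (length(delta) == 2) {
    opt <- optimize(function(u1) obj(c(u1, 1 - u1)),
                    interval = c(0, 1), tol = 1e-12)
    u <- c(opt$minimum, 1 - opt$minimum)
  } else {
    f <- function(p) {
      u <- c(p, 1 - sum(p))
      if (any(u < 0)) return(1e9 + sum(pmax(-u, 0)))
      obj(u)
    }
    best <- NULL
    for (start in list(c(1, 1) / 3, c(0.6, 0.2), c(0.2, 0.6))) {
      o <- stats::optim(start, f, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # polish with a second restart from the incumbent
    o <- stats::optim(best$par, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (o$value < best$value) best <- o
    u <- c(best$par, 1 - sum(best$par))
  }
  u
}

# Exhaustive Jenks oracle: tries every contiguous partition of the sorted
# values into k classes and returns the minimal total within-class SSE and
# its boundaries (class maxima).
oracle_jenks <- function(values, k) {
  s <- sort(values)
  n <- length(s)
  sse <- function(v) sum((v - mean(v))^2)
  best <- list(cost = Inf, breaks = NULL)
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    b <- cuts[, j]
    idx <- findInterval(seq_len(n) - 1, b) + 1 # class of each position
    cost <- sum(vapply(split(s, idx), sse, numeric(1)))
    if (cost < best$cost - 1e-12) {
      best <- list(cost = cost, breaks = s[b])
    }
  }
  best
}

# Frozen synthetic study fields (meter-scale coordinates). Two or three
# isotropic Gaussian blobs with separation 10x the blob standard deviation
# and 2% uniform background noise over a 10 x 10 km study box.
blob_spec <- function(k, sd = 300) {
  sep <- 10 * sd
  if (k == 2) {
    tibble::tibble(x = 5000 + c(-sep / 2, sep / 2), y = 5000,
                   sd = sd, n = 150)
  } else {
    tibble::tibble(
      x = 5000 + sep * c(-0.5, 0.5, 0),
      y = 5000 + sep * c(-0.289, -0.289, 0.577),
      sd = sd, n = 150
    )
  }
}

blob_field <- function(k, seed, sd = 300, noise = 0.02) {
  simulate_events(blob_spec(k, sd), noise_fraction = noise,
                  bbox = c(0, 10000, 0, 10000), seed = seed)
}

# Fit used throughout the synthetic studies: fuzzifier 3 keeps memberships
# graded so that co-located prototypes stay mutually inclusive and merge;
# the length-mode radius suits meter-scale coordinates.
blob_fit <- function(field, k, seed) {
  efcm(field, c0 = 2 * k + 2, m = 3, radius_mode = "half", seed = seed)
}

# TRUE when the fit found exactly k clusters, each matched to a distinct
# generating mean within `tol_sd` blob standard deviations.
recovers_blobs <- function(fit, spec, tol_sd = 0.5) {
  k <- nrow(spec)
  if (nrow(fit$u) != k) return(FALSE)
  centers <- as.matrix(fit$prototypes[, c("x", "y")])
  d <- as.matrix(stats::dist(rbind(as.matrix(spec[, c("x", "y")]), centers)))
  d <- d[seq_len(k), k + seq_len(k), drop = FALSE] # true means x centers
  perms <- if (k == 2) list(1:2, 2:1) else {
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
         c(3, 1, 2), c(3, 2, 1))
  }
  best <- min(vapply(perms, function(p) {
    max(d[cbind(seq_len(k), p)])
  }, numeric(1)))
  best < tol_sd * spec$sd[1]
}
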