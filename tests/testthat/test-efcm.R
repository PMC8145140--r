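test_that("cluster centers are membership-weighted means", {
  x <- cbind(c(0, 2, 5), c(1, 3, 7))
  # uniform weights reduce to the arithmetic centroid
  u <- matrix(1 / 2, 2, 3)
  expect_equal(efcm_centers(u, x, m = 2)[1, ], colMeans(x))
  # a crisp singleton row returns that point exactly
  u <- rbind(c(1, 0, 0), c(0, 0.5, 0.5))
  expect_equal(efcm_centers(u, x, m = 2)[1, ], x[1, ])
  # hand evaluation with m = 2: weights 0.64 and 0.04
  x2 <- cbind(c(0, 2), c(0, 0))
  u2 <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  expect_equal(efcm_centers(u2, x2, m = 2)[1, 1], 2 * 0.04 / 0.68,
               tolerance = 1e-12)
  # a massless row is a degenerate cluster
  expect_error(efcm_centers(rbind(c(0, 0), c(1, 1)), x2, m = 2),
               class = "hotspotr_degenerate_cluster")
})

test_that("fuzzy covariances are symmetric PSD and match hand values", {
  x <- cbind(c(1, -1), c(0, 0))
  u <- matrix(0.5, 1, 2)
  p <- efcm_covariances(u, x, efcm_centers(u, x, 2), m = 2)[[1]]
  expect_equal(p, cbind(c(1, 0), c(0, 0)))
  # all points at the center give the zero matrix
  x0 <- cbind(c(3, 3), c(4, 4))
  p0 <- efcm_covariances(u, x0, efcm_centers(u, x0, 2), m = 2)[[1]]
  expect_equal(p0, matrix(0, 2, 2))
  # symmetry and PSD on random instances
  set.seed(42)
  for (i in 1:10) {
    xr <- matrix(rnorm(20), 10, 2)
    ur <- matrix(runif(30), 3, 10)
    ur <- sweep(ur, 2, colSums(ur), "/")
    ps <- efcm_covariances(ur, xr, efcm_centers(ur, xr, 2), m = 2)
    for (p in ps) {
      expect_identical(p, t(p))
      expect_gte(min(eigen(p, symmetric = TRUE)$values), -1e-12)
    }
  }
})

test_that("circle radii follow the determinant rule in both modes", {
  expect_equal(efcm_radius(diag(2), "full"), 1)
  expect_equal(efcm_radius(diag(2), "half"), 1)
  expect_equal(efcm_radius(diag(c(4, 1)), "full"), 2)
  expect_equal(efcm_radius(diag(c(4, 1)), "half"), sqrt(2))
  # rank-deficient covariance collapses the circle
  expect_equal(efcm_radius(cbind(c(1, 1), c(1, 1)), "full"), 0)
  expect_error(efcm_radius(cbind(c(1, 2), c(2, 1)), "full"),
               class = "hotspotr_invalid_covariance")
})

test_that("radius release scales linearly in beta / C", {
  expect_equal(efcm_enlarge_radius(7, beta = 5, n_clusters = 5), 7)
  expect_equal(efcm_enlarge_radius(10, beta = 1, n_clusters = 5), 2)
  r <- efcm_enlarge_radius(6, beta = 1:4, n_clusters = 4)
  expect_equal(r, 6 * (1:4) / 4)
  # beta is clamped into [1, C]
  expect_equal(efcm_enlarge_radius(6, beta = 9, n_clusters = 4), 6)
})

test_that("prototype dissimilarity is distance minus radius, floored at 0", {
  center <- matrix(c(0, 0), 1, 2)
  expect_equal(efcm_distances(cbind(5, 0), center, radii = 2)[1, 1], 3)
  expect_equal(efcm_distances(cbind(1, 0), center, radii = 2)[1, 1], 0)
  expect_equal(efcm_distances(cbind(2, 0), center, radii = 2)[1, 1], 0)
})

test_that("membership update handles inside-circle events and normalises", {
  # single cluster absorbs everything
  expect_equal(efcm_memberships(matrix(4, 1, 1), m = 2)[1, 1], 1)
  # inside exactly one circle -> crisp membership
  expect_equal(efcm_memberships(cbind(c(0, 3)), m = 2)[, 1], c(1, 0))
  # inside two circles -> split equally
  expect_equal(efcm_memberships(cbind(c(0, 0, 5)), m = 2)[, 1],
               c(0.5, 0.5, 0))
  # equal positive distances -> split equally
  expect_equal(efcm_memberships(cbind(c(2, 2)), m = 2)[, 1], c(0.5, 0.5))
  # columns always sum to one
  set.seed(7)
  delta <- matrix(rexp(40), 4, 10)
  delta[2, 3] <- 0
  u <- efcm_memberships(delta, m = 1.7)
  expect_equal(colSums(u), rep(1, 10))
  expect_true(all(u >= 0 & u <= 1))
})

test_that("membership update minimises the clustering objective", {
  # closed form vs an independent numeric constrained minimiser
  set.seed(11)
  for (i in 1:20) {
    c_n <- sample(2:3, 1)
    delta <- matrix(rexp(c_n) + 0.05, c_n, 1)
    m <- sample(c(1.5, 2, 2.5), 1)
    u <- efcm_memberships(delta, m)[, 1]
    u_star <- oracle_memberships(delta[, 1], m)
    expect_equal(u, u_star, tolerance = 1e-6)
  }
})

test_that("inclusion similarity is bounded, symmetric and measures inclusion", {
  u_eq <- rbind(c(0.3, 0.4, 0.3), c(0.3, 0.4, 0.3))
  expect_equal(efcm_similarity(u_eq)[1, 2], 1)
  u_disj <- rbind(c(0.5, 0, 0.5), c(0, 1, 0))
  expect_equal(efcm_similarity(u_disj)[1, 2], 0)
  # a profile contained in another scores 1 even without equal mass
  u_inc <- rbind(c(0.5, 0.5), c(0.25, 0.25))
  expect_equal(efcm_similarity(u_inc)[1, 2], 1)
  set.seed(5)
  ur <- matrix(runif(40), 4, 10)
  s <- efcm_similarity(ur)
  expect_identical(s, t(s))
  expect_true(all(s >= 0 & s <= 1 + 1e-12))
  expect_equal(diag(s), rep(0, 4))
})

test_that("merging adds membership rows and respects the adaptive threshold", {
  u <- rbind(c(0.3, 0.6), c(0.2, 0.1), c(0.5, 0.3))
  s <- efcm_similarity(u)
  top <- max(s)
  step <- efcm_merge_step(u, beta = 1, s_star_prev = top, eta = 0.01)
  if (top > 1 / 2) {
    expect_true(step$merged)
    expect_equal(nrow(step$u), 2)
  }
  # explicit merge: rows (0.3, 0.6) and (0.2, 0.1) -> (0.5, 0.7)
  u2 <- rbind(c(0.3, 0.6), c(0.2, 0.1))
  merged <- u2
  merged[1, ] <- merged[1, ] + merged[2, ]
  expect_equal(merged[1, ], c(0.5, 0.7))
  # column sums are invariant under a merge
  set.seed(9)
  u3 <- matrix(runif(15), 3, 5)
  u3 <- sweep(u3, 2, colSums(u3), "/")
  st <- efcm_merge_step(u3, beta = 1,
                        s_star_prev = max(efcm_similarity(u3)), eta = 0.01)
  expect_equal(colSums(st$u), colSums(u3))
  if (st$merged) expect_equal(nrow(st$u), nrow(u3) - 1)
  # with two clusters the threshold is 1, so a final merge never happens
  u4 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  st4 <- efcm_merge_step(u4, beta = 1, s_star_prev = 1, eta = 0.01)
  expect_false(st4$merged)
})

test_that("beta advances under the gated and eager rules as specified", {
  u <- rbind(c(0.9, 0.1, 0.8), c(0.1, 0.8, 0.1), c(0.0, 0.1, 0.1))
  s <- efcm_similarity(u)
  top <- max(s)
  alpha <- 1 / 2
  # gated: stable similarity below threshold -> beta + 1
  st <- efcm_merge_step(u, beta = 1, s_star_prev = top, eta = 0.01,
                        beta_mode = "gated")
  if (top <= alpha) expect_identical(st$beta, 2L)
  # gated: unstable similarity -> nothing happens
  st2 <- efcm_merge_step(u, beta = 1, s_star_prev = top + 0.5, eta = 0.01,
                         beta_mode = "gated")
  expect_identical(st2$beta, 1L)
  expect_false(st2$merged)
  # eager: unstable but above threshold -> beta + 1
  u5 <- rbind(c(0.6, 0.4, 0.5), c(0.4, 0.6, 0.5), c(0.0, 0.0, 0.0) + 1e-3)
  u5 <- sweep(u5, 2, colSums(u5), "/")
  s5 <- max(efcm_similarity(u5))
  st5 <- efcm_merge_step(u5, beta = 1, s_star_prev = s5 + 0.5, eta = 0.01,
                         beta_mode = "eager")
  if (s5 > 1 / 2) expect_identical(st5$beta, 2L)
})

test_that("efcm recovers well-separated blobs and converges deterministically", {
  field <- blob_field(2, seed = 1)
  fit <- blob_fit(field, k = 2, seed = 1)
  expect_true(fit$converged)
  expect_identical(nrow(fit$u), 2L)
  expect_true(recovers_blobs(fit, blob_spec(2)))
  # columns of the final partition sum to 1
  expect_equal(colSums(fit$u), rep(1, fit$n_events), tolerance = 1e-9)
  # identical seed, identical run
  fit2 <- blob_fit(field, k = 2, seed = 1)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$u, fit2$u)
  # trace invariants: C never increases; beta never decreases at fixed C
  tr <- fit$trace
  expect_true(all(diff(tr$n_clusters) <= 0))
  same_c <- diff(tr$n_clusters) == 0
  expect_true(all(diff(tr$beta)[same_c] >= 0))
})

test_that("efcm validates its configuration and inputs", {
  field <- blob_field(2, seed = 2)
  expect_error(efcm(field, c0 = 1), class = "hotspotr_config_error")
  expect_error(efcm(field[1:4, ], c0 = 6), class = "hotspotr_config_error")
  expect_error(efcm(field, c0 = 6, m = 1), class = "hotspotr_config_error")
  expect_error(efcm(field, c0 = 6, epsilon = 0),
               class = "hotspotr_config_error")
  geo <- tibble::tibble(lat = c(40, 41), lon = c(14, 15))
  expect_error(efcm(geo, c0 = 2), class = "hotspotr_input_error")
})

test_that("partition columns stay normalised through manual iterations", {
  # re-runs the exported update steps by hand, checking the invariant the
  # closed loop relies on after every membership update and merge
  field <- blob_field(2, seed = 3)
  x <- as.matrix(field[, c("x", "y")])
  set.seed(33)
  u <- matrix(runif(6 * nrow(x)), 6, nrow(x))
  u <- sweep(u, 2, colSums(u), "/")
  beta <- 1L
  s_prev <- 1
  for (it in 1:15) {
    centers <- efcm_centers(u, x, 3)
    covs <- efcm_covariances(u, x, centers, 3)
    radii <- efcm_enlarge_radius(
      vapply(covs, efcm_radius, numeric(1), mode = "half"),
      beta, nrow(u)
    )
    u <- efcm_memberships(efcm_distances(x, centers, radii), 3)
    expect_equal(colSums(u), rep(1, ncol(u)), tolerance = 1e-9)
    if (nrow(u) >= 2) {
      st <- efcm_merge_step(u, beta, s_prev, 0.01)
      u <- st$u
      beta <- st$beta
      s_prev <- st$s_star
      expect_equal(colSums(u), rep(1, ncol(u)), tolerance = 1e-9)
    }
  }
})
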