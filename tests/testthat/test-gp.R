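ub <- bounds_box(c(0, 1), c(0, 1), c(0, 1))

test_that("posterior interpolates noiseless data and reverts to the prior", {
  set.seed(1)
  X <- matrix(runif(24), 8, 3)
  y <- 3 + predict(reference_surface("Y2"), X * 1.5 + 0.5) / 10
  g <- fit_gp(X, y, ub, restarts = fast_gp$restarts, seed = 1)
  p <- gp_posterior(g, X)
  expect_equal(p$mean, y, tolerance = 1e-4)      # near-noiseless nugget
  # single training point: exact interpolation, sd -> 0 as nugget -> 0
  g1 <- fit_gp(X[1, , drop = FALSE], y[1], ub, nugget = 1e-13)
  p1 <- gp_posterior(g1, X[1, ])
  expect_equal(p1$mean, y[1], tolerance = 1e-6)
  expect_lt(p1$sd, 2e-6)  # sqrt(2 * nugget) plus float cancellation
  # far from all data the posterior reverts to the constant prior mean
  far <- matrix(1e3, 1, 3)
  pf <- gp_posterior(g1, far)
  expect_equal(pf$mean, g1$hyperparams$mean_const, tolerance = 1e-6)
  expect_equal(pf$sd^2, g1$y_sd^2 * g1$hyperparams$signal_variance,
               tolerance = 1e-6)
})

test_that("posterior matches hand-computed 2x2 kernel algebra", {
  X <- rbind(c(0.2, 0.5, 0.5), c(0.8, 0.5, 0.5))
  y <- c(1, 3)
  g <- fit_gp(X, y, ub, restarts = fast_gp$restarts, seed = 2, nugget = 1e-8)
  hp <- g$hyperparams
  xq <- c(0.4, 0.6, 0.45)
  # independent reimplementation of the conditional normal, dense algebra
  m32 <- function(a, b) {
    r <- sqrt(sum(((a - b) / hp$lengthscales)^2))
    hp$signal_variance * (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
  }
  K <- matrix(c(m32(g$Xs[1, ], g$Xs[1, ]) + hp$noise_variance,
                m32(g$Xs[1, ], g$Xs[2, ]),
                m32(g$Xs[2, ], g$Xs[1, ]),
                m32(g$Xs[2, ], g$Xs[2, ]) + hp$noise_variance), 2, 2)
  ks <- c(m32(xq, g$Xs[1, ]), m32(xq, g$Xs[2, ]))
  ys <- (y - g$y_mean) / g$y_sd
  mu_s <- sum(ks * solve(K, ys))
  var_s <- m32(xq, xq) - drop(t(ks) %*% solve(K, ks))
  p <- gp_posterior(g, xq)   # xq already on the unit cube = original scale
  expect_equal(p$mean, g$y_mean + g$y_sd * mu_s, tolerance = 1e-8)
  expect_equal(p$sd, g$y_sd * sqrt(max(var_s, 0)), tolerance = 1e-8)
})

test_that("expected improvement closed form behaves at its anchors", {
  expect_equal(ei_gaussian(0.5, 0, 1), 0)           # sd 0, mu <= best
  expect_equal(ei_gaussian(2, 0, 1), 1)             # sd 0, mu > best
  expect_equal(ei_gaussian(1, 1, 1), 1 / sqrt(2 * pi))
  expect_true(all(ei_gaussian(rnorm(50), abs(rnorm(50)), rnorm(50)) >= 0))
  # EI -> 0 as sd -> 0 with mu below the incumbent
  expect_equal(ei_gaussian(0, 1e-12, 1), 0, tolerance = 1e-12)
})

test_that("EI matches a Monte-Carlo oracle on random inputs", {
  set.seed(42)
  n_draw <- 2e5
  for (i in 1:12) {
    mu <- rnorm(1); sd <- runif(1, 0.1, 2)
    best <- mu - sd * runif(1, -3.5, 4)  # keep MC oracle in-regime
    draws <- pmax(rnorm(n_draw, mu, sd) - best, 0)
    mc_se <- sd(draws) / sqrt(n_draw)
    expect_lt(abs(ei_gaussian(mu, sd, best) - mean(draws)),
              3.5 * mc_se + 1e-10)
  }
})

test_that("confidence bound is mu + kappa * sd", {
  set.seed(3)
  X <- matrix(runif(15), 5, 3)
  g <- fit_gp(X, rowSums(X), ub, restarts = fast_gp$restarts, seed = 3)
  xq <- c(0.5, 0.5, 0.5)
  p <- gp_posterior(g, xq)
  expect_equal(confidence_bound(g, xq, 2), p$mean + 2 * p$sd)
  expect_equal(confidence_bound(g, xq, 0), p$mean)
})

test_that("proposals reach the acquisition grid maximum", {
  set.seed(4)
  X <- matrix(runif(30, 0, 1), 10, 3)
  y <- -colSums((t(X) - 0.3)^2) * 10
  g <- fit_gp(X, y, ub, restarts = fast_gp$restarts, seed = 4)
  props <- propose_batch(g, seed = 5, n_starts = fast_gp$n_starts)
  expect_equal(nrow(props), 2L)
  expect_setequal(props$acquisition,
                  c("expected_improvement", "confidence_bound"))
  # oracle: acquisition values on a 21^3 grid
  ax <- seq(0, 1, length.out = 21)
  grid <- as.matrix(expand.grid(ax, ax, ax))
  inc <- max(y)
  ei_grid <- max(expected_improvement(g, grid, inc))
  cb_grid <- max(confidence_bound(g, grid, 2))
  expect_gte(props$acq_value[props$acquisition == "expected_improvement"],
             ei_grid - 1e-3)
  expect_gte(props$acq_value[props$acquisition == "confidence_bound"],
             cb_grid - 1e-3)
  # proposals respect the box
  P <- as.matrix(props[, c("X1", "X2", "X3")])
  expect_true(all(P >= 0 - 1e-12 & P <= 1 + 1e-12))
})

test_that("duplicate acquisitions give duplicate proposals", {
  set.seed(6)
  X <- matrix(runif(18), 6, 3)
  g <- fit_gp(X, rowSums(X^2), ub, restarts = fast_gp$restarts, seed = 6)
  acqs <- list(acquisition_spec("expected_improvement"),
               acquisition_spec("expected_improvement"))
  props <- propose_batch(g, acqs, seed = 7, n_starts = fast_gp$n_starts)
  expect_equal(props[1, 1:3], props[2, 1:3], ignore_attr = TRUE)
})

test_that("a flat acquisition falls back to the bounds centre", {
  # degenerate surrogate with zero signal variance: posterior mean and sd
  # are constant, so every acquisition is flat
  X <- matrix(runif(12), 4, 3)
  g <- fit_gp(X, rep(2, 4), ub, restarts = 2, seed = 8)
  g$hyperparams$signal_variance <- 0
  g$alpha <- rep(0, 4)
  expect_warning(
    props <- propose_batch(g, list(acquisition_spec("expected_improvement")),
                           seed = 8, n_starts = 10),
    "flat")
  expect_equal(as.numeric(props[1, 1:3]), c(0.5, 0.5, 0.5))
})
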