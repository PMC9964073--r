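## Gaussian-process surrogate with an ARD Matern 3/2 kernel.
## Inputs are scaled to the unit cube via the search bounds and outputs are
## standardized before fitting; hyperparameters maximize the log marginal
## likelihood with seeded multistarts.

# Matern 3/2 cross-covariance between row sets X1, X2 (already scaled),
# with per-dimension lengthscales ls and signal variance s2.
.matern32_K <- function(X1, X2, ls, s2) {
  r2 <- matrix(0, nrow(X1), nrow(X2))
  for (d in seq_len(ncol(X1))) {
    dd <- outer(X1[, d], X2[, d], "-") / ls[d]
    r2 <- r2 + dd * dd
  }
  r <- sqrt(r2)
  sr <- sqrt(3) * r
  s2 * (1 + sr) * exp(-sr)
}

# Negative log marginal likelihood (optionally penalized) for
# standardized data. `ls_prior = c(median, sdlog)` adds a weak lognormal
# MAP penalty on the lengthscales; pure maximum likelihood can drift to
# near-infinite lengthscales on noise-free smooth responses (the
# likelihood is almost flat there), which collapses the posterior
# variance and stalls acquisition-driven exploration.
.gp_nlml <- function(par, Xs, ys, nugget, estimate_nugget,
                     ls_prior = NULL) {
  k <- ncol(Xs)
  s2 <- exp(par[1])
  ls <- exp(par[2:(1 + k)])
  if (estimate_nugget) nugget <- exp(par[2 + k])
  pen <- 0
  if (!is.null(ls_prior))
    pen <- sum((log(ls) - log(ls_prior[1]))^2) / (2 * ls_prior[2]^2)
  n <- nrow(Xs)
  K <- .matern32_K(Xs, Xs, ls, s2)
  diag(K) <- diag(K) + nugget
  L <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-10
  while (is.null(L) && jit < 1e-2) {
    L <- tryCatch(chol(K + diag(jit, n)), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), ys))
  as.numeric(0.5 * sum(ys * a) + sum(log(diag(L))) +
               0.5 * n * log(2 * pi) + pen)
}

#' Fit a Gaussian-process surrogate (Matern 3/2, ARD)
#'
#' Scales inputs to the unit cube using `bounds`, standardizes outputs,
#' and fits signal variance plus per-dimension lengthscales by maximizing
#' the log marginal likelihood (`L-BFGS-B`, `restarts` seeded starts).
#' Lengthscales are bounded in \[1e-3, 1e3\] on the unit-cube scale. The
#' prior mean is the constant sample mean (absorbed by standardization).
#'
#' @param X n x k numeric matrix of inputs (original units).
#' @param y Numeric response vector of length n.
#' @param bounds 2 x k bounds matrix ([bounds_box()]) delimiting the
#'   search/scaling box.
#' @param restarts Number of seeded hyperparameter multistarts.
#' @param seed Integer seed making the fit deterministic.
#' @param nugget Observation-noise variance on the standardized scale
#'   (default 1e-6: near-noiseless interpolation).
#' @param estimate_nugget Estimate the nugget by marginal likelihood
#'   instead of fixing it?
#' @param ls_prior Length-2 vector `c(median, sdlog)` of a weak lognormal
#'   MAP prior on the unit-cube lengthscales (default `c(0.5, 1.5)`), or
#'   `NULL` for pure maximum likelihood. On noise-free smooth responses
#'   the marginal likelihood is nearly flat in the lengthscales and can
#'   select near-infinite values, collapsing the posterior variance that
#'   acquisition functions rely on; the weak prior resolves that
#'   degeneracy while being negligible wherever the data are informative.
#' @return Object of class `gp_model` with the scaled training data,
#'   hyperparameters (`signal_variance`, `lengthscales`, `noise_variance`,
#'   `mean_const`) and a cached Cholesky factorization.
#' @examples
#' b <- bounds_box(c(0, 1), c(0, 1), c(0, 1))
#' X <- matrix(runif(15), 5, 3)
#' g <- fit_gp(X, rowSums(X), b, restarts = 3, seed = 1)
#' gp_posterior(g, X[1, ])$mean
#' @export
fit_gp <- function(X, y, bounds, restarts = 10L, seed = 1L, nugget = 1e-6,
                   estimate_nugget = FALSE, ls_prior = c(0.5, 1.5)) {
  if (!is.null(ls_prior))
    stopifnot(length(ls_prior) == 2L, all(ls_prior > 0))
  X <- as.matrix(X)
  y <- as.numeric(y)
  b <- as_bounds(bounds)
  k <- ncol(X)
  stopifnot(ncol(b) == k, nrow(X) == length(y), nrow(X) >= 1L,
            all(is.finite(X)), all(is.finite(y)), nugget >= 0)

  rng <- b[2, ] - b[1, ]
  Xs <- sweep(sweep(X, 2, b[1, ]), 2, rng, "/")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (length(y) < 2L || !is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd
  nugget <- max(nugget, 1e-12)

  if (nrow(X) >= 2L) {
    lower <- c(log(1e-6), rep(log(1e-3), k),
               if (estimate_nugget) log(1e-8))
    upper <- c(log(1e6), rep(log(1e3), k),
               if (estimate_nugget) log(1))
    set.seed(as.integer(seed))
    inits <- lapply(seq_len(max(1L, as.integer(restarts))), function(i) {
      if (i == 1L) c(0, rep(log(0.5), k), if (estimate_nugget) log(nugget))
      else c(stats::runif(1, log(0.1), log(10)),
             stats::runif(k, log(0.05), log(2)),
             if (estimate_nugget) stats::runif(1, log(1e-6), log(0.1)))
    })
    best <- NULL
    for (p0 in inits) {
      fit <- tryCatch(
        stats::optim(p0, .gp_nlml, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     Xs = Xs, ys = ys, nugget = nugget,
                     estimate_nugget = estimate_nugget,
                     ls_prior = ls_prior,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("GP hyperparameter optimization failed",
                            call. = FALSE)
    par <- best$par
  } else {
    par <- c(0, rep(log(0.5), k), if (estimate_nugget) log(nugget))
  }
  s2 <- exp(par[1])
  ls <- exp(par[2:(1 + k)])
  if (estimate_nugget) nugget <- exp(par[2 + k])

  K <- .matern32_K(Xs, Xs, ls, s2)
  diag(K) <- diag(K) + nugget
  L <- tryCatch(chol(K), error = function(e) NULL)
  jit <- 1e-10
  while (is.null(L) && jit < 1e-2) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(L))
    stop("kernel matrix is not positive definite even after jitter",
         call. = FALSE)
  alpha <- backsolve(L, forwardsolve(t(L), ys))

  structure(
    list(X = X, y = y, Xs = Xs, ys = ys, bounds = b,
         y_mean = y_mean, y_sd = y_sd,
         hyperparams = list(signal_variance = s2, lengthscales = ls,
                            noise_variance = nugget, mean_const = y_mean),
         L = L, alpha = alpha),
    class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "<gp_model> Matern 3/2 ARD, n = %d\n  signal var %.3g, lengthscales (%s), nugget %.1g\n",
    nrow(x$X), hp$signal_variance,
    paste(sprintf("%.3g", hp$lengthscales), collapse = ", "),
    hp$noise_variance))
  invisible(x)
}

#' GP posterior mean and standard deviation
#'
#' @param model A [fit_gp()] result.
#' @param x Numeric vector of length k or an m x k matrix of query points
#'   (original units).
#' @return List with numeric vectors `mean` and `sd` in response units.
#' @export
gp_posterior <- function(model, x) {
  stopifnot(inherits(model, "gp_model"))
  if (is.null(dim(x))) x <- matrix(x, 1L)
  x <- as.matrix(x)
  stopifnot(ncol(x) == ncol(model$X))
  b <- model$bounds
  xs <- sweep(sweep(x, 2, b[1, ]), 2, b[2, ] - b[1, ], "/")
  hp <- model$hyperparams
  ks <- .matern32_K(xs, model$Xs, hp$lengthscales, hp$signal_variance)
  mu_s <- drop(ks %*% model$alpha)
  v <- forwardsolve(t(model$L), t(ks))
  var_s <- pmax(hp$signal_variance - colSums(v * v), 0)
  list(mean = model$y_mean + model$y_sd * mu_s,
       sd = model$y_sd * sqrt(var_s))
}

#' Expected improvement of a Gaussian predictive distribution
#'
#' Closed form for maximization:
#' `EI = (mu - best) * pnorm(z) + sd * dnorm(z)` with
#' `z = (mu - best)/sd`; at `sd = 0` it degenerates to
#' `max(mu - best, 0)`.
#'
#' @param mu,sd Posterior mean(s) and standard deviation(s).
#' @param incumbent Best observed response so far.
#' @return Non-negative numeric vector.
#' @examples
#' ei_gaussian(0, 1, 0)  # 1/sqrt(2*pi)
#' @export
ei_gaussian <- function(mu, sd, incumbent) {
  stopifnot(all(sd >= 0))
  imp <- mu - incumbent
  out <- pmax(imp, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- imp[pos] / sd[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Expected Improvement acquisition at a point
#'
#' @param model A [fit_gp()] result.
#' @param x Query point (vector) or matrix of points.
#' @param incumbent Best observed response (maximization convention).
#' @return EI value(s), >= 0.
#' @export
expected_improvement <- function(model, x, incumbent) {
  p <- gp_posterior(model, x)
  ei_gaussian(p$mean, p$sd, incumbent)
}

#' (Upper) Confidence Bound acquisition at a point
#'
#' `CB = mu + kappa * sd` (maximization convention).
#'
#' @inheritParams expected_improvement
#' @param kappa Non-negative exploration weight (default 2).
#' @return CB value(s).
#' @export
confidence_bound <- function(model, x, kappa = 2) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  p <- gp_posterior(model, x)
  p$mean + kappa * p$sd
}

#' Specify an acquisition function
#'
#' @param kind `"expected_improvement"` or `"confidence_bound"`.
#' @param cb_kappa Exploration weight for the confidence bound.
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(kind = c("expected_improvement",
                                      "confidence_bound"),
                             cb_kappa = 2) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(cb_kappa), is.finite(cb_kappa), cb_kappa > 0)
  structure(list(kind = kind, cb_kappa = cb_kappa, maximize = TRUE),
            class = "acquisition_spec")
}

# Evaluate one acquisition on a matrix of candidate points.
.acq_eval <- function(model, acq, X, incumbent) {
  switch(acq$kind,
         expected_improvement = expected_improvement(model, X, incumbent),
         confidence_bound = confidence_bound(model, X, acq$cb_kappa))
}

#' Propose the next batch of experiments
#'
#' One proposal per acquisition in `acqs`, each the argmax of its
#' acquisition over the model's bounds found by seeded random multistart
#' (`n_starts` uniform candidates, the best few polished with box-bounded
#' `L-BFGS-B`). All proposals are computed from the same posterior (no
#' fantasizing), matching lab practice where the whole batch is run before
#' the model is updated; duplicate acquisitions therefore yield duplicate
#' proposals.
#'
#' @param model A [fit_gp()] result.
#' @param acqs List of [acquisition_spec()]s; default one EI and one CB.
#' @param seed Integer seed for the multistart.
#' @param n_starts Random candidate points per acquisition.
#' @param n_refine How many of the best candidates to polish locally.
#' @return Data frame with one row per proposal: factor columns,
#'   `acquisition` and `acq_value`.
#' @export
propose_batch <- function(model, acqs = list(acquisition_spec("expected_improvement"),
                                             acquisition_spec("confidence_bound")),
                          seed = 1L, n_starts = 50L, n_refine = 5L) {
  stopifnot(inherits(model, "gp_model"), length(acqs) >= 1L)
  b <- model$bounds
  k <- ncol(b)
  incumbent <- max(model$y)
  set.seed(as.integer(seed))
  cand <- sapply(seq_len(k), function(j)
    stats::runif(n_starts, b[1, j], b[2, j]))
  cand <- rbind(matrix(cand, ncol = k), model$X)  # include data locations

  out <- vector("list", length(acqs))
  for (a in seq_along(acqs)) {
    acq <- acqs[[a]]
    stopifnot(inherits(acq, "acquisition_spec"))
    vals <- .acq_eval(model, acq, cand, incumbent)
    if (max(vals) - min(vals) < 1e-12) {
      warning("flat acquisition surface; proposing the centre of the bounds")
      best_x <- (b[1, ] + b[2, ]) / 2
      best_v <- .acq_eval(model, acq, matrix(best_x, 1), incumbent)
    } else {
      top <- order(-vals)[seq_len(min(n_refine, nrow(cand)))]
      best_x <- cand[top[1], ]
      best_v <- vals[top[1]]
      for (i in top) {
        opt <- tryCatch(
          stats::optim(cand[i, ],
                       function(p) -.acq_eval(model, acq, matrix(p, 1),
                                              incumbent),
                       method = "L-BFGS-B", lower = b[1, ], upper = b[2, ],
                       control = list(maxit = 100)),
          error = function(e) NULL)
        if (!is.null(opt) && -opt$value > best_v) {
          best_v <- -opt$value
          best_x <- pmin(pmax(opt$par, b[1, ]), b[2, ])
        }
      }
      # focus search: resample in boxes shrinking around the running best,
      # so interior optima missed by the global multistart are recovered
      width <- (b[2, ] - b[1, ]) / 2
      for (round in 1:3) {
        lo <- pmax(best_x - width / 2, b[1, ])
        hi <- pmin(best_x + width / 2, b[2, ])
        fc <- sapply(seq_len(k), function(j)
          stats::runif(n_starts, lo[j], hi[j]))
        fc <- matrix(fc, ncol = k)
        fv <- .acq_eval(model, acq, fc, incumbent)
        i <- which.max(fv)
        start <- if (fv[i] > best_v) fc[i, ] else best_x
        opt <- tryCatch(
          stats::optim(start,
                       function(p) -.acq_eval(model, acq, matrix(p, 1),
                                              incumbent),
                       method = "L-BFGS-B", lower = b[1, ], upper = b[2, ],
                       control = list(maxit = 100)),
          error = function(e) NULL)
        if (!is.null(opt) && -opt$value > best_v) {
          best_v <- -opt$value
          best_x <- pmin(pmax(opt$par, b[1, ]), b[2, ])
        } else if (fv[i] > best_v) {
          best_v <- fv[i]
          best_x <- fc[i, ]
        }
        width <- width / 2
      }
    }
    row <- as.data.frame(matrix(best_x, 1))
    names(row) <- colnames(b)
    row$acquisition <- acq$kind
    row$acq_value <- as.numeric(best_v)
    out[[a]] <- row
  }
  do.call(rbind, out)
}
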