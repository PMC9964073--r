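#' Run a batch Bayesian-optimization loop
#'
#' Iteratively fits a Matern 3/2 GP surrogate to all data so far, proposes
#' one experiment per acquisition function (default: Expected Improvement
#' and upper Confidence Bound, both from the same posterior), evaluates the
#' experiment callback at the proposals, and appends the results. The
#' default configuration mirrors small-batch lab campaigns: 8 initial
#' runs, 2 proposals per iteration, 6 iterations.
#'
#' @param oracle Function mapping a length-k numeric vector to a single
#'   response value (an in-silico simulator such as [oracle_fn()], or a
#'   wrapper around real experiments).
#' @param init_X n0 x k matrix of initial design points (original units).
#' @param init_y Numeric vector of initial responses.
#' @param bounds 2 x k bounds matrix ([bounds_box()]).
#' @param n_iterations Number of propose/evaluate/refit cycles (default 6).
#' @param acqs List of [acquisition_spec()]s evaluated each iteration.
#' @param seed Integer seed; drives GP restarts and acquisition
#'   multistarts deterministically.
#' @param restarts GP hyperparameter multistarts per refit.
#' @param n_starts Acquisition multistart candidates.
#' @param nugget GP nugget (standardized scale).
#' @param early_stop Stop early once the improvement of the incumbent over
#'   the last two complete iterations falls below `tol`?
#' @param tol Early-stopping improvement threshold (response units).
#' @return Object of class `bo_trace`: `data` (all runs with `iteration`,
#'   `acquisition`, response `y` and running `incumbent`), `init_n`,
#'   `incumbent_best`, `stop_reason`, `bounds`, `models` (last GP).
#' @examples
#' cfg <- oracle_config("Y2")
#' tab2 <- load_fixture("table2_init")
#' tr <- run_bo(oracle_fn(cfg), as.matrix(tab2[, 1:3]), tab2$Y2,
#'              bounds_box(c(0.5, 2), c(0, 0.2), c(0.5, 2)),
#'              n_iterations = 1, seed = 1, restarts = 3, n_starts = 20)
#' tr$incumbent_best
#' @export
run_bo <- function(oracle, init_X, init_y, bounds,
                   n_iterations = 6L,
                   acqs = list(acquisition_spec("expected_improvement"),
                               acquisition_spec("confidence_bound")),
                   seed = 1L, restarts = 10L, n_starts = 50L,
                   nugget = 1e-6, early_stop = FALSE, tol = 0.5) {
  stopifnot(is.function(oracle))
  b <- as_bounds(bounds)
  X <- as.matrix(init_X)
  y <- as.numeric(init_y)
  stopifnot(nrow(X) == length(y), ncol(X) == ncol(b), nrow(X) >= 1L)
  if (any(sweep(X, 2, b[1, ]) < -1e-9) || any(sweep(X, 2, b[2, ]) > 1e-9))
    stop("initial design points must lie inside the bounds", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 0L)
  seed <- as.integer(seed)

  nms <- colnames(b)
  recs <- data.frame(iteration = 0L, acquisition = "init",
                     as.data.frame(X) |> stats::setNames(nms),
                     y = y, incumbent = cummax(y),
                     stringsAsFactors = FALSE)
  incumbents <- max(y)
  stop_reason <- sprintf("completed %d iterations", n_iterations)
  model <- NULL

  it <- 0L
  while (it < n_iterations) {
    it <- it + 1L
    model <- fit_gp(X, y, b, restarts = restarts,
                    seed = seed + 1000L * it, nugget = nugget)
    props <- propose_batch(model, acqs, seed = seed + 1000L * it + 500L,
                           n_starts = n_starts)
    Xp <- as.matrix(props[, nms, drop = FALSE])
    yp <- numeric(nrow(Xp))
    for (i in seq_len(nrow(Xp))) {
      yi <- tryCatch(oracle(as.numeric(Xp[i, ])), error = function(e) e)
      if (inherits(yi, "error")) {
        stop_reason <- paste("oracle failure:", conditionMessage(yi))
        if (i > 1L) {
          X <- rbind(X, Xp[seq_len(i - 1L), , drop = FALSE])
          y <- c(y, yp[seq_len(i - 1L)])
        }
        return(.bo_finish(recs, X, y, incumbents, stop_reason, b, model,
                          length(init_y)))
      }
      yp[i] <- yi
    }
    X <- rbind(X, Xp)
    y <- c(y, yp)
    recs <- rbind(recs, data.frame(
      iteration = it, acquisition = props$acquisition,
      as.data.frame(Xp) |> stats::setNames(nms),
      y = yp, incumbent = cummax(y)[length(y) - nrow(Xp) + seq_len(nrow(Xp))],
      stringsAsFactors = FALSE))
    incumbents <- c(incumbents, max(y))
    if (isTRUE(early_stop) && it >= 2L) {
      gain <- incumbents[it + 1L] - incumbents[it - 1L]
      if (gain < tol) {
        stop_reason <- "converged"
        break
      }
    }
  }
  .bo_finish(recs, X, y, incumbents, stop_reason, b, model, length(init_y))
}

.bo_finish <- function(recs, X, y, incumbents, stop_reason, bounds, model,
                       init_n) {
  structure(
    list(data = recs, X = X, y = y, init_n = init_n,
         incumbent_best = max(y), incumbents = incumbents,
         stop_reason = stop_reason, bounds = bounds, model = model),
    class = "bo_trace")
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf(
    "<bo_trace> %d runs (%d initial), incumbent best %.3f\n  stop: %s\n",
    length(x$y), x$init_n, x$incumbent_best, x$stop_reason))
  invisible(x)
}

#' Write / read a BO trace as CSV
#'
#' Columns: `iteration`, `acquisition`, one column per factor, `y`,
#' `incumbent`.
#'
#' @param trace A `bo_trace`.
#' @param path File path.
#' @export
write_bo_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bo_trace"))
  utils::write.csv(trace$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
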