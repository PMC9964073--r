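#' One-sided (maximize) desirability specification
#'
#' Derringer-Suich ramp for a response to be maximized: desirability is 0
#' at or below `lower`, 1 at or above `target`, and
#' `((y - lower)/(target - lower))^weight` in between.
#'
#' @param lower Response value at/below which desirability is 0 (the CQA
#'   floor, e.g. 70 mg/cm2 for the pH 12 response of the case study).
#' @param target Response value at/above which desirability is 1.
#' @param weight Positive ramp exponent (1 = linear).
#' @return An object of class `desirability_spec`.
#' @export
desirability_spec <- function(lower, target, weight = 1) {
  stopifnot(is.numeric(lower), is.numeric(target), is.numeric(weight),
            length(lower) == 1L, length(target) == 1L, length(weight) == 1L)
  if (!(lower < target)) stop("`lower` must be < `target`", call. = FALSE)
  if (!(weight > 0)) stop("`weight` must be > 0", call. = FALSE)
  structure(list(direction = "maximize", lower = as.numeric(lower),
                 target = as.numeric(target), weight = as.numeric(weight)),
            class = "desirability_spec")
}

#' Desirability of a single response value
#'
#' @param y Numeric vector of response values.
#' @param spec A [desirability_spec()].
#' @return Numeric vector in \[0, 1\].
#' @examples
#' s <- desirability_spec(70, 90)
#' desirability_value(c(60, 80, 95), s)  # 0, 0.5, 1
#' @export
desirability_value <- function(y, spec) {
  stopifnot(inherits(spec, "desirability_spec"), is.numeric(y))
  d <- (y - spec$lower) / (spec$target - spec$lower)
  d <- pmin(pmax(d, 0), 1)
  d^spec$weight
}

#' Composite desirability (geometric mean)
#'
#' @param values Numeric vector of per-response desirabilities in \[0, 1\].
#' @return Geometric mean; 0 if any component is 0 (veto property).
#' @examples
#' composite_desirability(c(1, 0.25))  # 0.5
#' @export
composite_desirability <- function(values) {
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  stopifnot(is.numeric(values), all(values >= 0), all(values <= 1))
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

#' Multi-response desirability optimization over quadratic surfaces
#'
#' Scans a regular grid over the factor box, computes the composite
#' (geometric-mean) desirability of the predicted responses at every grid
#' point, then optionally polishes the best grid point with Nelder-Mead
#' (box-clipped). Deterministic: ties are broken by lexicographic grid
#' order (first factor varies fastest).
#'
#' @param models Named list of [quadratic_model()]s (all on the same
#'   scale), names matching `specs`.
#' @param specs Named list of [desirability_spec()]s, one per model.
#' @param bounds 2 x 3 matrix (rows `lower`, `upper`) or list of length-2
#'   vectors giving the search box on the models' scale.
#' @param grid_density Grid points per axis (default 51).
#' @param refine Polish with Nelder-Mead from the best grid point?
#' @return List of class `desirability_result`: `best_point` (named),
#'   `predicted_responses`, `composite_desirability`, `grid_best` (the
#'   pre-refinement optimum) and `search_trace` (top grid rows).
#' @examples
#' mods <- list(Y1 = reference_surface("Y1"), Y2 = reference_surface("Y2"))
#' sp <- list(Y1 = desirability_spec(70, 90), Y2 = desirability_spec(40, 50))
#' optimize_desirability(mods, sp, bounds_box(c(0.5, 1.5), c(0, 0.2), c(0.5, 1.5)),
#'                       grid_density = 21)
#' @export
optimize_desirability <- function(models, specs, bounds, grid_density = 51L,
                                  refine = TRUE) {
  stopifnot(is.list(models), is.list(specs), length(models) >= 1L)
  if (is.null(names(models)) || !setequal(names(models), names(specs)))
    stop("`models` and `specs` must share the same names", call. = FALSE)
  b <- as_bounds(bounds)
  grid_density <- as.integer(grid_density)
  stopifnot(grid_density >= 2L)

  axes <- lapply(1:3, function(j) seq(b[1, j], b[2, j],
                                      length.out = grid_density))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- colnames(b)

  comp_at <- function(X) {
    dmat <- vapply(names(models), function(nm) {
      desirability_value(predict(models[[nm]], X), specs[[nm]])
    }, numeric(nrow(X)))
    dmat <- matrix(dmat, nrow = nrow(X))
    apply(dmat, 1, function(v) if (any(v == 0)) 0 else exp(mean(log(v))))
  }
  dcomp <- comp_at(grid)
  best_i <- which.max(dcomp)  # which.max takes the first maximum: grid order
  grid_best <- grid[best_i, ]
  grid_val <- dcomp[best_i]

  best <- grid_best
  best_val <- grid_val
  if (isTRUE(refine) && grid_val > 0) {
    obj <- function(p) {
      p <- pmin(pmax(p, b[1, ]), b[2, ])
      -comp_at(matrix(p, 1))
    }
    opt <- stats::optim(grid_best, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    cand <- pmin(pmax(opt$par, b[1, ]), b[2, ])
    cand_val <- comp_at(matrix(cand, 1))
    if (cand_val >= best_val) {  # refinement never loses to the grid
      best <- cand
      best_val <- cand_val
    }
  }
  names(best) <- colnames(b)
  pred <- vapply(models, function(m) predict(m, best), numeric(1))
  ord <- order(-dcomp)[seq_len(min(10L, length(dcomp)))]
  trace <- data.frame(grid[ord, , drop = FALSE], desirability = dcomp[ord])
  structure(list(best_point = best,
                 predicted_responses = pred,
                 composite_desirability = as.numeric(best_val),
                 grid_best = grid_best,
                 grid_desirability = grid_val,
                 search_trace = trace,
                 all_zero = best_val == 0),
            class = "desirability_result")
}

#' @export
print.desirability_result <- function(x, ...) {
  cat("<desirability_result>\n  best point: ",
      paste(sprintf("%s = %.4g", names(x$best_point), x$best_point),
            collapse = ", "),
      sprintf("\n  composite desirability: %.4f\n", x$composite_desirability))
  if (x$all_zero)
    cat("  NOTE: desirability is zero everywhere on the grid\n")
  invisible(x)
}

#' Build a 2 x k bounds matrix from per-factor ranges
#'
#' @param ... Length-2 numeric vectors `c(lower, upper)`, optionally named.
#' @return Matrix with rows `lower`, `upper`.
#' @examples
#' bounds_box(X1 = c(0.5, 2), X2 = c(0, 0.2), X3 = c(0.5, 2))
#' @export
bounds_box <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, length, integer(1)) == 2L))
  b <- vapply(parts, as.numeric, numeric(2))
  if (any(b[1, ] >= b[2, ]))
    stop("each bound must satisfy lower < upper", call. = FALSE)
  rownames(b) <- c("lower", "upper")
  if (is.null(colnames(b)))
    colnames(b) <- paste0("X", seq_len(ncol(b)))
  b
}

# Accept a bounds matrix or list; validate shape.
as_bounds <- function(bounds) {
  if (is.list(bounds)) bounds <- do.call(bounds_box, bounds)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L)
    stop("`bounds` must be a 2 x k matrix (rows lower, upper)", call. = FALSE)
  if (any(!is.finite(bounds))) stop("bounds must be finite", call. = FALSE)
  if (any(bounds[1, ] >= bounds[2, ]))
    stop("each bound must satisfy lower < upper", call. = FALSE)
  if (is.null(colnames(bounds)))
    colnames(bounds) <- paste0("X", seq_len(ncol(bounds)))
  rownames(bounds) <- c("lower", "upper")
  bounds
}
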