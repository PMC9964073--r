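# Shared fixtures and settings for the suite.

# the study's BO scan box: X1, X3 in [0.5, 2], X2 in [0, 0.2]
scan_bounds <- function() bounds_box(X1 = c(0.5, 2), X2 = c(0, 0.2),
                                     X3 = c(0.5, 2))

# fast GP settings for unit tests (acceptance uses the defaults)
fast_gp <- list(restarts = 3L, n_starts = 25L)

# brute-force grid maximum of a quadratic surface over a box, evaluated in
# slices to bound memory; an independent oracle for optimizer tests
grid_max_quadratic <- function(model, bounds, n = 201L) {
  b <- as_bounds <- bounds
  ax <- lapply(1:3, function(j) seq(b[1, j], b[2, j], length.out = n))
  best <- -Inf
  best_x <- NULL
  for (x1 in ax[[1]]) {
    g <- expand.grid(x1, ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE)
    v <- predict(model, as.matrix(g))
    i <- which.max(v)
    if (v[i] > best) {
      best <- v[i]
      best_x <- as.numeric(g[i, ])
    }
  }
  list(value = best, point = best_x)
}
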