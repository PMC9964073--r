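#' Published quadratic response surfaces of the celecoxib case study
#'
#' The fitted full quadratic surfaces (actual scale) for the two critical
#' quality attributes of the packaged co-milled celecoxib study:
#' `"Y1"` = dissolved drug amount in pH 12 at 30 min and `"Y2"` = dissolved
#' drug amount in pH 1.2 + 0.2% SLS at 120 min, as functions of the
#' PVP/CXB (X1), SLS/CXB (X2) and MAN/CXB (X3) weight ratios. These are
#' the ground-truth surfaces of the synthetic experiment simulator.
#'
#' @param response `"Y1"` or `"Y2"`.
#' @return A [quadratic_model()] on the actual scale.
#' @examples
#' predict(reference_surface("Y1"), c(1.5, 0.2, 0.5))  # ~83.1
#' @export
reference_surface <- function(response = c("Y1", "Y2")) {
  response <- match.arg(response)
  m <- if (response == "Y1")
    quadratic_model(c("X1", "X2", "X3"),
                    intercept = -7.3,
                    linear = c(-7.0, -157.8, 26.1),
                    interaction = c(250.5, 2.7, -105.0),
                    quadratic = c(12.8, 608.9, -1.7),
                    scale = "actual")
  else
    quadratic_model(c("X1", "X2", "X3"),
                    intercept = -14.8,
                    linear = c(16.1, 1.8, 37.0),
                    interaction = c(188.2, 0.25, -4.3),
                    quadratic = c(-7.79, -309.2, -19.19),
                    scale = "actual")
  attr(m, "response") <- response
  m
}

#' Configure the synthetic experiment oracle
#'
#' @param surface `"Y1"`, `"Y2"` (the published case-study surfaces) or a
#'   custom [quadratic_model()].
#' @param noise_sd Gaussian replicate noise SD in response units
#'   (default 0: noise-free algorithm testing).
#' @param bounds 2 x 3 bounds matrix; default is the study's scan box
#'   (X1, X3 in \[0.5, 2\], X2 in \[0, 0.2\]).
#' @param seed Integer base seed for the replicate-noise streams.
#' @return Object of class `oracle_config`.
#' @export
oracle_config <- function(surface = "Y2", noise_sd = 0,
                          bounds = bounds_box(X1 = c(0.5, 2),
                                              X2 = c(0, 0.2),
                                              X3 = c(0.5, 2)),
                          seed = 1L) {
  if (is.character(surface)) surface <- reference_surface(surface)
  stopifnot(inherits(surface, "quadratic_model"),
            is.numeric(noise_sd), length(noise_sd) == 1L,
            is.finite(noise_sd), noise_sd >= 0)
  structure(list(surface = surface, noise_sd = as.numeric(noise_sd),
                 bounds = as_bounds(bounds), seed = as.integer(seed)),
            class = "oracle_config")
}

#' Noise-free ground-truth response of the oracle
#'
#' Global polynomial evaluation; points outside the configured bounds are
#' still evaluated, with a warning.
#'
#' @param config An [oracle_config()].
#' @param x Length-3 vector or matrix of factor settings (actual scale).
#' @return Numeric response value(s).
#' @export
true_response <- function(config, x) {
  stopifnot(inherits(config, "oracle_config"))
  xm <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  b <- config$bounds
  if (any(sweep(xm, 2, b[1, ]) < -1e-9) || any(sweep(xm, 2, b[2, ]) > 1e-9))
    warning("evaluating the oracle surface outside its bounds")
  predict(config$surface, xm)
}

# Deterministic, order-independent stream seed from (seed, replicate, x).
.stream_seed <- function(seed, replicate_id, x) {
  key <- paste(seed, replicate_id, paste(signif(x, 12), collapse = ","),
               sep = "|")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

#' Simulate one noisy experiment
#'
#' Adds `N(0, noise_sd^2)` replicate noise to the ground-truth response.
#' The noise stream is counter-based: the draw depends only on
#' `(seed, replicate_id, x)`, so replicates can be generated in any order
#' and are bit-reproducible.
#'
#' @inheritParams true_response
#' @param replicate_id Integer replicate counter (>= 1).
#' @return Single simulated response value.
#' @export
simulate_experiment <- function(config, x, replicate_id = 1L) {
  mu <- true_response(config, x)
  stopifnot(length(mu) == 1L)
  if (config$noise_sd == 0) return(mu)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.stream_seed(config$seed, replicate_id, x))
  mu + stats::rnorm(1L, 0, config$noise_sd)
}

#' Wrap an oracle config as an experiment callback for [run_bo()]
#'
#' Each call increments an internal replicate counter.
#'
#' @param config An [oracle_config()].
#' @return Function mapping a length-3 vector to a response value.
#' @export
oracle_fn <- function(config) {
  stopifnot(inherits(config, "oracle_config"))
  counter <- 0L
  function(x) {
    counter <<- counter + 1L
    suppressWarnings(simulate_experiment(config, x, counter))
  }
}

#' Simulate a designed-experiment response table from a known truth
#'
#' The parameter-recovery harness: evaluates a known quadratic surface at
#' every design run and adds Gaussian noise, returning a response table
#' keyed by run code that can be refitted with [fit_quadratic()].
#'
#' @param design A `design_matrix` (CCD or PB).
#' @param truth A [quadratic_model()] (its `scale` selects which design
#'   levels are used).
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed Integer seed.
#' @param response Name for the response column.
#' @return Data frame with columns `code` and the response.
#' @export
generate_doe_dataset <- function(design, truth, noise_sd = 0, seed = 1L,
                                 response = NULL) {
  stopifnot(inherits(design, "design_matrix"),
            inherits(truth, "quadratic_model"), noise_sd >= 0)
  if (is.null(response))
    response <- attr(truth, "response") %||% "Y"
  X <- design_levels(design, truth$scale)
  mu <- predict(truth, X)
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    mu <- mu + stats::rnorm(length(mu), 0, noise_sd)
  }
  out <- data.frame(code = design$code, y = mu, stringsAsFactors = FALSE)
  names(out)[2] <- response
  out
}

#' Configure a one-compartment oral PK simulation
#'
#' @param dose Dose (mg/kg).
#' @param ka First-order absorption rate constant (1/h).
#' @param ke First-order elimination rate constant (1/h); must differ
#'   from `ka`.
#' @param volume_over_F Apparent distribution volume over bioavailability
#'   (L/kg).
#' @param sample_times Strictly increasing, non-negative sampling times (h).
#' @param noise_cv Lognormal multiplicative noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return Object of class `pk_sim_config`.
#' @export
pk_sim_config <- function(dose, ka, ke, volume_over_F,
                          sample_times = c(0, 0.5, 1, 2, 3, 4, 6, 12, 24),
                          noise_cv = 0, seed = 1L) {
  stopifnot(dose > 0, ka > 0, ke > 0, volume_over_F > 0, noise_cv >= 0)
  if (abs(ka - ke) < 1e-12)
    stop("ka must differ from ke (degenerate one-compartment profile)",
         call. = FALSE)
  st <- as.numeric(sample_times)
  if (any(st < 0) || is.unsorted(st, strictly = TRUE))
    stop("sample_times must be non-negative and strictly increasing",
         call. = FALSE)
  structure(list(dose = dose, ka = ka, ke = ke,
                 volume_over_F = volume_over_F, sample_times = st,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "pk_sim_config")
}

#' Simulate a one-compartment oral concentration-time profile
#'
#' `C(t) = dose * ka / (V/F * (ka - ke)) * (exp(-ke t) - exp(-ka t))`,
#' optionally multiplied by lognormal noise with coefficient of variation
#' `noise_cv`.
#'
#' @param config A [pk_sim_config()].
#' @return A [pk_profile()].
#' @examples
#' p <- simulate_pk_profile(pk_sim_config(10, ka = 1.5, ke = 0.1,
#'                                        volume_over_F = 5))
#' nca(p)
#' @export
simulate_pk_profile <- function(config) {
  stopifnot(inherits(config, "pk_sim_config"))
  t <- config$sample_times
  co <- config$dose * config$ka /
    (config$volume_over_F * (config$ka - config$ke))
  conc <- co * (exp(-config$ke * t) - exp(-config$ka * t))
  conc <- pmax(conc, 0)
  if (config$noise_cv > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    conc <- conc * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog)
    conc[t == 0] <- 0
  }
  pk_profile(t, conc, dose = config$dose)
}

.fixture_files <- c(
  table1_levels = "table1_levels.csv",
  table2_init = "table2_init.csv",
  table3_bo_proposals = "table3_bo_proposals.csv",
  table4_ccd = "table4_ccd.csv",
  table5_anova = "table5_anova.csv",
  table6_validation = "table6_validation.csv",
  table7_bo_results = "table7_bo_results.csv",
  table9_pk = "table9_pk.csv")

#' Load a packaged case-study fixture
#'
#' Verbatim CSV copies of the co-milled celecoxib study's printed data
#' tables. Known internal inconsistencies of the printed record (e.g. the
#' same run appearing with response 42.70 in `table2_init` and 42.3 in
#' `table4_ccd`) are preserved as-is: fixtures are historical records,
#' not cleaned data.
#'
#' @param name One of `"table1_levels"` (factor level map),
#'   `"table2_init"` (8 BO starting runs), `"table3_bo_proposals"`,
#'   `"table4_ccd"` (20 CCD runs with both responses), `"table5_anova"`
#'   (printed Y1 ANOVA summary), `"table6_validation"`,
#'   `"table7_bo_results"`, `"table9_pk"` (NCA summary statistics).
#' @return A data frame.
#' @examples
#' load_fixture("table4_ccd")
#' @export
load_fixture <- function(name) {
  if (!name %in% names(.fixture_files))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(.fixture_files), collapse = ", ")),
         call. = FALSE)
  path <- system.file("extdata", .fixture_files[[name]], package = "qbdoe",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' List available fixtures / export them to a directory
#'
#' @param dir Target directory (created if missing).
#' @return `list_fixtures` returns the fixture names; `export_fixtures`
#'   the written paths, invisibly.
#' @export
list_fixtures <- function() names(.fixture_files)

#' @rdname list_fixtures
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(0)
  for (nm in names(.fixture_files)) {
    src <- system.file("extdata", .fixture_files[[nm]], package = "qbdoe",
                       mustWork = TRUE)
    dst <- file.path(dir, .fixture_files[[nm]])
    file.copy(src, dst, overwrite = TRUE)
    out <- c(out, dst)
  }
  invisible(out)
}

#' Pooled centre-point noise SD of the packaged CCD data
#'
#' A "realistic" replicate-noise preset for [oracle_config()]: the pooled
#' standard deviation of the response over the centre-point replicate
#' groups (per block) of the packaged 20-run CCD.
#'
#' @param response `"Y1"` or `"Y2"`.
#' @return Pooled SD (response units).
#' @export
center_point_sd <- function(response = c("Y2", "Y1")) {
  response <- match.arg(response)
  tab <- load_fixture("table4_ccd")
  ctr <- tab[tab$point_type == "center", ]
  groups <- split(ctr[[response]], ctr$block)
  ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- sum(vapply(groups, length, integer(1)) - 1L)
  sqrt(ss / df)
}
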