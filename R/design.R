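#' Define a design factor
#'
#' A factor is described on two scales: the *coded* scale used by the design
#' (centre 0, cube levels at +/-1, axial levels at +/-alpha) and the *actual*
#' scale in physical units (here dimensionless excipient/drug weight ratios).
#' The two are linked by the affine map
#' `actual = center + coded * half_range`.
#'
#' @param name Factor name (single string), e.g. `"X1"`.
#' @param center Actual value at coded level 0.
#' @param half_range Actual-scale change per one coded unit; must be > 0.
#' @return An object of class `factor_spec` with fields `name`, `center`,
#'   `half_range`, `low_actual` (coded -1) and `high_actual` (coded +1).
#' @examples
#' f <- factor_spec("X2", center = 0.1, half_range = 0.1)
#' coded_to_actual(f, 1.633)   # axial high level
#' @export
factor_spec <- function(name, center, half_range) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  stopifnot(is.numeric(half_range), length(half_range) == 1L,
            is.finite(half_range))
  if (half_range <= 0) stop("`half_range` must be > 0", call. = FALSE)
  structure(
    list(name = name, center = as.numeric(center),
         half_range = as.numeric(half_range),
         low_actual = center - half_range,
         high_actual = center + half_range),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: center %g, half-range %g (-1 -> %g, +1 -> %g)\n",
              x$name, x$center, x$half_range, x$low_actual, x$high_actual))
  invisible(x)
}

#' Factor specifications of the co-milled celecoxib case study
#'
#' The three critical formulation factors of the packaged case study:
#' X1 = PVP/CXB, X2 = SLS/CXB and X3 = MAN/CXB weight ratios, with the
#' centre/half-range level maps used by its five-level central composite
#' design (axial distance 1.633).
#'
#' @return A named list of three [factor_spec()] objects.
#' @examples
#' fs <- celecoxib_factors()
#' coded_to_actual(fs$X1, -1.633)  # 0.1835
#' @export
celecoxib_factors <- function() {
  list(
    X1 = factor_spec("X1", center = 1.0, half_range = 0.5),
    X2 = factor_spec("X2", center = 0.1, half_range = 0.1),
    X3 = factor_spec("X3", center = 1.0, half_range = 0.5))
}

#' Convert between coded and actual factor levels
#'
#' Mutually inverse affine maps between the coded design scale and the
#' actual (physical) scale of a factor.
#'
#' @param f A [factor_spec()].
#' @param coded,actual Numeric vector of levels to convert.
#' @return Numeric vector of converted levels.
#' @examples
#' f <- factor_spec("X1", 1.0, 0.5)
#' coded_to_actual(f, c(-1.633, 0, 1.633))
#' actual_to_coded(f, 1.5)
#' @export
coded_to_actual <- function(f, coded) {
  stopifnot(inherits(f, "factor_spec"), is.numeric(coded))
  f$center + coded * f$half_range
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(f, actual) {
  stopifnot(inherits(f, "factor_spec"), is.numeric(actual))
  (actual - f$center) / f$half_range
}

# Canonical 12-run Plackett-Burman generator row (first column cycles this).
.pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate a 12-run Plackett-Burman screening design
#'
#' Builds the canonical 12-run two-level Plackett-Burman design from the
#' cyclic generator (+ + - + + + - - - + -) plus a final all-minus row.
#' The first `n_factors` columns are assigned to real factors; the
#' remaining columns (up to 11) are kept as dummy columns, whose apparent
#' "effects" estimate experimental error for [screen_effects()].
#'
#' @param n_factors Number of real factors, between 2 and 11.
#' @param factor_names Optional names for the real factors (default
#'   `F1..Fn`); dummy columns are named `D1..Dk`.
#' @param randomize Randomize run order? Default `FALSE` so that designs
#'   are reproducible fixtures; when `TRUE`, `seed` controls the shuffle.
#' @param seed Integer seed used only when `randomize = TRUE`.
#' @return A `design_matrix` data frame with columns `run_order`, `code`,
#'   `block`, `point_type` and one coded-level column per design column.
#'   Attributes: `design_kind = "plackett_burman"`, `n_factors`,
#'   `factor_columns`, `dummy_columns`.
#' @examples
#' pb <- generate_plackett_burman(6)
#' crossprod(as.matrix(pb[, attr(pb, "factor_columns")]))  # diagonal
#' @export
generate_plackett_burman <- function(n_factors, factor_names = NULL,
                                     randomize = FALSE, seed = 1L) {
  stopifnot(length(n_factors) == 1L, is.numeric(n_factors))
  n_factors <- as.integer(n_factors)
  if (n_factors < 2L || n_factors > 11L)
    stop("`n_factors` must be between 2 and 11 for the 12-run design",
         call. = FALSE)
  g <- .pb12_generator
  m <- matrix(0, 12L, 11L)
  for (i in 1:11) m[i, ] <- g[((seq.int(0L, 10L) + (i - 1L)) %% 11L) + 1L]
  m[12L, ] <- -1  # 12 x 11; rows = runs
  if (is.null(factor_names)) factor_names <- paste0("F", seq_len(n_factors))
  stopifnot(length(factor_names) == n_factors)
  n_dummy <- 11L - n_factors
  cn <- c(factor_names, if (n_dummy > 0) paste0("D", seq_len(n_dummy)))
  colnames(m) <- cn
  ord <- seq_len(12L)
  if (isTRUE(randomize)) {
    set.seed(as.integer(seed))
    ord <- sample(ord)
  }
  out <- data.frame(run_order = seq_len(12L),
                    code = sprintf("PB%02d", seq_len(12L)),
                    block = 1L, point_type = "cube",
                    m[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out,
            design_kind = "plackett_burman",
            n_factors = n_factors,
            factor_columns = factor_names,
            dummy_columns = if (n_dummy > 0) paste0("D", seq_len(n_dummy))
                            else character(0),
            class = c("design_matrix", "data.frame"))
}

#' Generate a blocked central composite design (CCD)
#'
#' Builds the three-factor, five-level, two-block CCD used in formulation
#' optimization: a full 2^3 factorial cube plus `n_center_cube` centre
#' replicates in block 1, and six axial ("star") points at coded distance
#' `+/-alpha` plus `n_center_axial` centre replicates in block 2. Run codes
#' `CC01..CCnn` are assigned deterministically; the default matches the
#' celecoxib case study (`alpha = 1.633`, 4 + 2 centre points, 20 runs).
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param alpha Axial distance on the coded scale, > 0.
#' @param n_center_cube,n_center_axial Number of centre replicates in the
#'   cube and axial blocks (non-negative integers).
#' @param randomize,seed Optional seed-controlled shuffle of run order
#'   (codes stay attached to their points).
#' @return A `design_matrix` data frame with columns `run_order`, `code`,
#'   `block`, `point_type`, coded levels (`coded_<name>`) and actual levels
#'   (`<name>`). Attributes: `factors`, `alpha`, `design_kind = "ccd"`.
#' @examples
#' d <- generate_ccd(celecoxib_factors())
#' table(d$point_type)  # 8 cube, 6 axial, 6 center
#' @export
generate_ccd <- function(factors, alpha = 1.633, n_center_cube = 4L,
                         n_center_axial = 2L, randomize = FALSE, seed = 1L) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("`factors` must be a list of exactly 3 factor_spec objects",
         call. = FALSE)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  n_center_cube <- as.integer(n_center_cube)
  n_center_axial <- as.integer(n_center_axial)
  stopifnot(n_center_cube >= 0L, n_center_axial >= 0L)

  nms <- vapply(factors, `[[`, character(1), "name")
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  axial <- matrix(0, 6, 3)
  for (i in 1:3) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  zero <- matrix(0, 1, 3)
  coded <- rbind(cube,
                 zero[rep(1, n_center_cube), , drop = FALSE],
                 axial,
                 zero[rep(1, n_center_axial), , drop = FALSE])
  point_type <- c(rep("cube", 8L), rep("center", n_center_cube),
                  rep("axial", 6L), rep("center", n_center_axial))
  block <- c(rep(1L, 8L + n_center_cube), rep(2L, 6L + n_center_axial))
  n <- nrow(coded)
  actual <- coded
  for (j in 1:3) actual[, j] <- coded_to_actual(factors[[j]], coded[, j])
  colnames(coded) <- paste0("coded_", nms)
  colnames(actual) <- nms

  ord <- seq_len(n)
  if (isTRUE(randomize)) {
    set.seed(as.integer(seed))
    ord <- sample(ord)
  }
  out <- data.frame(run_order = seq_len(n),
                    code = sprintf("CC%02d", seq_len(n)),
                    block = block[ord], point_type = point_type[ord],
                    coded[ord, , drop = FALSE], actual[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out,
            factors = stats::setNames(factors, nms), alpha = alpha,
            design_kind = "ccd",
            factor_columns = nms,
            class = c("design_matrix", "data.frame"))
}

#' @export
print.design_matrix <- function(x, ...) {
  kind <- attr(x, "design_kind")
  cat(sprintf("<design_matrix> %s, %d runs\n", kind, nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Extract coded or actual levels of the real factors as a matrix
#'
#' @param design A `design_matrix`.
#' @param scale `"actual"` or `"coded"` (PB designs are coded-only).
#' @return Numeric matrix, one row per run, one column per real factor.
#' @export
design_levels <- function(design, scale = c("actual", "coded")) {
  scale <- match.arg(scale)
  stopifnot(inherits(design, "design_matrix"))
  nms <- attr(design, "factor_columns")
  if (attr(design, "design_kind") == "plackett_burman") {
    m <- as.matrix(design[, nms, drop = FALSE])
  } else {
    cols <- if (scale == "actual") nms else paste0("coded_", nms)
    m <- as.matrix(design[, cols, drop = FALSE])
    colnames(m) <- nms
  }
  storage.mode(m) <- "double"
  rownames(m) <- design$code
  m
}

#' Read / write a design matrix as CSV
#'
#' The CSV dialect has header columns `run_order`, `code`, `block`,
#' `point_type`, then the factor-level columns (`coded_*` columns optional).
#'
#' @param design A `design_matrix`.
#' @param path File path.
#' @param design_kind Design kind to stamp on the re-read object.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   `design_matrix` (without `factor_spec` attributes, which are not part
#'   of the CSV dialect).
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, design_kind = c("ccd", "plackett_burman")) {
  design_kind <- match.arg(design_kind)
  d <- read_table(path, required = c("run_order", "code", "block",
                                     "point_type"))
  meta <- c("run_order", "code", "block", "point_type")
  lvl <- setdiff(names(d), meta)
  nms <- setdiff(lvl, grep("^coded_", lvl, value = TRUE))
  structure(d, design_kind = design_kind, factor_columns = nms,
            class = c("design_matrix", "data.frame"))
}

# Internal validation used by tests and fitters.
.check_ccd_structure <- function(design) {
  tab <- table(design$point_type)
  cs <- design[, paste0("coded_", attr(design, "factor_columns")),
               drop = FALSE]
  ok_center <- all(abs(as.matrix(cs[design$point_type == "center", ])) < 1e-12)
  ok_cube <- all(abs(abs(as.matrix(cs[design$point_type == "cube", ])) - 1)
                 < 1e-12)
  ax <- as.matrix(cs[design$point_type == "axial", , drop = FALSE])
  ok_axial <- all(rowSums(ax != 0) == 1L)
  isTRUE(ok_center && ok_cube && ok_axial) && length(tab) > 0
}
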