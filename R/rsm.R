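#' Construct a full quadratic response-surface model
#'
#' The 10-coefficient second-order polynomial in three factors,
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
#'       + \sum_i \beta_{ii} x_i^2,}
#' either fitted by [fit_quadratic()] or assembled from explicit
#' coefficients (e.g. published coefficient sets).
#'
#' @param factor_names Character vector of 3 factor names.
#' @param intercept Intercept \eqn{\beta_0}.
#' @param linear Numeric length-3 vector of linear coefficients (order of
#'   `factor_names`).
#' @param interaction Numeric length-3 vector of two-way interaction
#'   coefficients, order (1,2), (1,3), (2,3).
#' @param quadratic Numeric length-3 vector of pure quadratic coefficients.
#' @param scale `"actual"` or `"coded"`: the scale the coefficients act on.
#' @param block_effects Optional named numeric vector of additive block
#'   offsets (centred; used only by fitted models for diagnostics, never by
#'   [predict.quadratic_model()]).
#' @return An object of class `quadratic_model`.
#' @examples
#' m <- quadratic_model(c("X1", "X2", "X3"), 1, c(0, 0, 0),
#'                      c(0, 0, 0), c(1, 1, 1))
#' predict(m, c(1, 2, 3))  # 1 + 1 + 4 + 9
#' @export
quadratic_model <- function(factor_names, intercept, linear, interaction,
                            quadratic, scale = c("actual", "coded"),
                            block_effects = NULL) {
  scale <- match.arg(scale)
  stopifnot(length(factor_names) == 3L, length(linear) == 3L,
            length(interaction) == 3L, length(quadratic) == 3L,
            is.numeric(intercept), length(intercept) == 1L)
  pair_names <- c(paste0(factor_names[1], ":", factor_names[2]),
                  paste0(factor_names[1], ":", factor_names[3]),
                  paste0(factor_names[2], ":", factor_names[3]))
  structure(
    list(factor_names = as.character(factor_names),
         intercept = as.numeric(intercept),
         linear = stats::setNames(as.numeric(linear), factor_names),
         interaction = stats::setNames(as.numeric(interaction), pair_names),
         quadratic = stats::setNames(as.numeric(quadratic),
                                     paste0(factor_names, "^2")),
         scale = scale,
         block_effects = block_effects),
    class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat(sprintf("<quadratic_model> in (%s), %s scale\n",
              paste(x$factor_names, collapse = ", "), x$scale))
  co <- c("(Intercept)" = x$intercept, x$linear, x$interaction, x$quadratic)
  print(round(co, digits))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$linear, object$interaction,
    object$quadratic)
}

# Feature columns of the full quadratic, in canonical order (no intercept).
.quad_features <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3L)
  cbind(X,
        X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 2] * X[, 3],
        X[, 1]^2, X[, 2]^2, X[, 3]^2)
}

#' Predict from a quadratic response-surface model
#'
#' Pure polynomial evaluation; block effects of fitted models are ignored
#' (predictions are for the average block).
#'
#' @param object A [quadratic_model()].
#' @param newdata Either a numeric vector of length 3 or a matrix /
#'   data frame with 3 columns (order of `object$factor_names`).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (all(object$factor_names %in% names(newdata)))
      newdata <- newdata[, object$factor_names, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata))) {
    if (length(newdata) != 3L)
      stop("`newdata` must have 3 factor values", call. = FALSE)
    newdata <- matrix(newdata, 1L)
  }
  if (ncol(newdata) != 3L)
    stop("`newdata` must have 3 columns", call. = FALSE)
  feats <- .quad_features(newdata)
  beta <- c(object$linear, object$interaction, object$quadratic)
  drop(object$intercept + feats %*% beta)
}

# Align a response data frame (keyed by run code) with a design.
.align_responses <- function(design, responses, response_name) {
  stopifnot(is.data.frame(responses))
  if (!response_name %in% names(responses))
    stop(sprintf("response column '%s' not found", response_name),
         call. = FALSE)
  if ("code" %in% names(responses)) {
    idx <- match(design$code, responses$code)
    if (anyNA(idx))
      stop("responses do not cover every design run (alignment error)",
           call. = FALSE)
    y <- responses[[response_name]][idx]
  } else {
    if (nrow(responses) != nrow(design))
      stop("responses and design have different numbers of rows",
           call. = FALSE)
    y <- responses[[response_name]]
  }
  if (anyNA(y) || !all(is.finite(y)))
    stop("responses must be finite and complete", call. = FALSE)
  as.numeric(y)
}

#' Fit a full quadratic response-surface model to a designed experiment
#'
#' Ordinary least squares on the 10-term full quadratic model matrix, with
#' the design's blocks optionally absorbed as centred fixed effects (the
#' default for blocked CCDs). Block offsets do not enter predictions.
#'
#' @param design A CCD `design_matrix` (or any design with >= 11 runs and
#'   3 factor columns).
#' @param responses Data frame with a `code` key column (or row-aligned)
#'   and the response column.
#' @param response Name of the response column, e.g. `"Y1"`.
#' @param scale Fit on `"actual"` (default) or `"coded"` factor levels.
#' @param block_handling `"fixed_effect"` (default) absorbs block
#'   differences; `"ignore"` fits the surface only.
#' @return A [quadratic_model()] with attributes `fitted`, `residuals` and
#'   `lm` (the underlying stats::lm fit) attached.
#' @examples
#' d <- generate_ccd(celecoxib_factors())
#' truth <- reference_surface("Y2")
#' resp <- generate_doe_dataset(d, truth, noise_sd = 0, seed = 1)
#' fit <- fit_quadratic(d, resp, "Y2")
#' max(abs(coef(fit) - coef(truth)))  # ~1e-12
#' @export
fit_quadratic <- function(design, responses, response,
                          scale = c("actual", "coded"),
                          block_handling = c("fixed_effect", "ignore")) {
  scale <- match.arg(scale)
  block_handling <- match.arg(block_handling)
  stopifnot(inherits(design, "design_matrix"))
  X <- design_levels(design, scale)
  nms <- colnames(X)
  y <- .align_responses(design, responses, response)
  if (nrow(X) < 11L)
    stop("need at least 11 runs to fit 10 coefficients", call. = FALSE)

  dat <- as.data.frame(.quad_features(X))
  names(dat) <- c("L1", "L2", "L3", "I12", "I13", "I23", "Q1", "Q2", "Q3")
  dat$y <- y
  use_block <- block_handling == "fixed_effect" &&
    length(unique(design$block)) > 1L
  if (use_block) {
    dat$block <- factor(design$block)
    contrasts(dat$block) <- stats::contr.sum(nlevels(dat$block))
    fml <- y ~ block + L1 + L2 + L3 + I12 + I13 + I23 + Q1 + Q2 + Q3
  } else {
    fml <- y ~ L1 + L2 + L3 + I12 + I13 + I23 + Q1 + Q2 + Q3
  }
  fit <- stats::lm(fml, data = dat)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("singular design: model matrix is rank deficient", call. = FALSE)

  blk <- NULL
  if (use_block) {
    bcoef <- co[grep("^block", names(co))]
    lv <- levels(dat$block)
    eff <- c(bcoef, -sum(bcoef))
    blk <- stats::setNames(as.numeric(eff), lv)
  }
  m <- quadratic_model(nms,
                       intercept = co[["(Intercept)"]],
                       linear = co[c("L1", "L2", "L3")],
                       interaction = co[c("I12", "I13", "I23")],
                       quadratic = co[c("Q1", "Q2", "Q3")],
                       scale = scale, block_effects = blk)
  attr(m, "fitted") <- stats::fitted(fit)
  attr(m, "residuals") <- stats::residuals(fit)
  attr(m, "lm") <- fit
  attr(m, "response") <- response
  m
}

#' ANOVA for a full quadratic response-surface fit
#'
#' Decomposes the corrected total sum of squares into block (sequential),
#' model (all 9 surface terms jointly, after block), and residual; the
#' residual is further split into lack-of-fit and pure error using
#' replicate groups (runs with identical factor levels within a block).
#' Per-term rows carry partial (Type-III) sums of squares with
#' F = MS(term)/MS(Residual); the lack-of-fit F uses MS(LOF)/MS(PE).
#' R-squared is `1 - SS(Residual)/SS(Corrected Total)`.
#'
#' @inheritParams fit_quadratic
#' @param model Optional [fit_quadratic()] result for the same data; when
#'   omitted it is fitted internally with the given options.
#' @return Data frame of class `rsm_anova` with columns `term`, `sum_sq`,
#'   `df`, `f_value`, `p_value`, plus attribute `r_squared`.
#' @examples
#' d <- generate_ccd(celecoxib_factors())
#' resp <- generate_doe_dataset(d, reference_surface("Y1"), 5, seed = 2)
#' rsm_anova(d, resp, "Y1")
#' @export
rsm_anova <- function(design, responses, response, model = NULL,
                      scale = c("actual", "coded"),
                      block_handling = c("fixed_effect", "ignore")) {
  scale <- match.arg(scale)
  block_handling <- match.arg(block_handling)
  if (is.null(model))
    model <- fit_quadratic(design, responses, response, scale, block_handling)
  fit <- attr(model, "lm")
  y <- .align_responses(design, responses, response)
  n <- length(y)
  use_block <- !is.null(model$block_effects)

  rss <- function(mm) {
    f <- stats::lm.fit(mm, y)
    sum(f$residuals^2)
  }
  mm_full <- stats::model.matrix(fit)
  ss_ct <- sum((y - mean(y))^2)
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- fit$df.residual

  if (use_block) {
    bcols <- grep("^block", colnames(mm_full))
    rss_blk <- rss(mm_full[, c(1L, bcols), drop = FALSE])
    ss_block <- ss_ct - rss_blk
    df_block <- length(bcols)
  } else {
    rss_blk <- ss_ct
    ss_block <- NA_real_
    df_block <- NA_integer_
  }
  ss_model <- rss_blk - rss_full

  term_cols <- c(L1 = "L1", L2 = "L2", L3 = "L3", I12 = "I12", I13 = "I13",
                 I23 = "I23", Q1 = "Q1", Q2 = "Q2", Q3 = "Q3")
  fn <- model$factor_names
  term_labels <- c(fn,
                   paste0(fn[1], fn[2]), paste0(fn[1], fn[3]),
                   paste0(fn[2], fn[3]), paste0(fn, "^2"))
  ss_terms <- vapply(term_cols, function(cn) {
    keep <- setdiff(colnames(mm_full), cn)
    rss(mm_full[, keep, drop = FALSE]) - rss_full
  }, numeric(1))

  # replicate groups: identical factor levels within a block
  X <- design_levels(design, scale)
  key <- apply(cbind(design$block, signif(X, 12)), 1, paste, collapse = "|")
  groups <- split(seq_len(n), key)
  reps <- groups[lengths(groups) >= 2L]
  ss_pe <- sum(vapply(reps, function(ix) sum((y[ix] - mean(y[ix]))^2),
                      numeric(1)))
  df_pe <- sum(vapply(reps, length, integer(1)) - 1L)
  have_lof <- length(reps) > 0L && df_res > df_pe
  ss_lof <- rss_full - ss_pe
  df_lof <- df_res - df_pe

  mse <- if (df_res > 0) rss_full / df_res else NA_real_
  f_of <- function(ss, df) if (df > 0 && is.finite(mse) && mse > 0)
    (ss / df) / mse else NA_real_
  p_of <- function(f, df1) if (is.finite(f))
    stats::pf(f, df1, df_res, lower.tail = FALSE) else NA_real_

  rows <- list()
  add <- function(term, ss, df, f = NA_real_, p = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, sum_sq = ss, df = df, f_value = f, p_value = p,
      stringsAsFactors = FALSE)
  if (use_block) add("Block", ss_block, df_block)
  f_model <- if (df_res > 0 && mse > 0) (ss_model / 9) / mse else NA_real_
  add("Model", ss_model, 9L, f_model, p_of(f_model, 9L))
  for (k in seq_along(ss_terms)) {
    fv <- f_of(ss_terms[k], 1L)
    add(term_labels[k], ss_terms[k], 1L, fv, p_of(fv, 1L))
  }
  add("Residual", rss_full, df_res)
  if (have_lof) {
    mspe <- if (df_pe > 0) ss_pe / df_pe else NA_real_
    flof <- if (df_lof > 0 && is.finite(mspe) && mspe > 0)
      (ss_lof / df_lof) / mspe else NA_real_
    plof <- if (is.finite(flof))
      stats::pf(flof, df_lof, df_pe, lower.tail = FALSE) else NA_real_
    add("Lack of Fit", ss_lof, df_lof, flof, plof)
    add("Pure Error", ss_pe, df_pe)
  }
  add("Cor Total", ss_ct, n - 1L)
  out <- do.call(rbind, rows)
  attr(out, "r_squared") <- 1 - rss_full / ss_ct
  attr(out, "response") <- response
  class(out) <- c("rsm_anova", "data.frame")
  out
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA for response %s (R^2 = %.4f)\n",
              attr(x, "response") %||% "?", attr(x, "r_squared")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen main effects from a Plackett-Burman experiment
#'
#' Effects are `mean(response at +1) - mean(response at -1)` per column.
#' The standard error is estimated from the dummy (unassigned) columns as
#' the root mean square of their apparent effects; two-sided t-tests use
#' as many degrees of freedom as there are dummy columns. With no dummy
#' columns the effects are returned without tests.
#'
#' @param design A Plackett-Burman `design_matrix`.
#' @param responses Data frame with `code` key (or row-aligned) and the
#'   response column.
#' @param response Name of the response column.
#' @param alpha_level Significance threshold for the `significant` flag.
#' @return Data frame of class `pb_effects`, one row per real factor,
#'   sorted by decreasing `|effect|`: columns `factor`, `effect`,
#'   `standard_error`, `t_value`, `p_value`, `significant`.
#' @export
screen_effects <- function(design, responses, response, alpha_level = 0.05) {
  stopifnot(inherits(design, "design_matrix"),
            attr(design, "design_kind") == "plackett_burman")
  y <- .align_responses(design, responses, response)
  fcols <- attr(design, "factor_columns")
  dcols <- attr(design, "dummy_columns")
  eff_of <- function(col) {
    v <- design[[col]]
    mean(y[v > 0]) - mean(y[v < 0])
  }
  eff <- vapply(fcols, eff_of, numeric(1))
  if (length(dcols) > 0L) {
    deff <- vapply(dcols, eff_of, numeric(1))
    se <- sqrt(mean(deff^2))
    df <- length(dcols)
    tv <- eff / se
    pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    sig <- pv < alpha_level
  } else {
    warning("no dummy columns: effects returned without p-values")
    se <- NA_real_; tv <- rep(NA_real_, length(eff))
    pv <- rep(NA_real_, length(eff)); sig <- rep(NA, length(eff))
  }
  out <- data.frame(factor = fcols, effect = eff, standard_error = se,
                    t_value = tv, p_value = pv, significant = sig,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$effect)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pb_effects", "data.frame")
  out
}
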