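## Shared CSV I/O dialect, pipeline runner and command-line entry point.

#' Read / write a CSV table in the package dialect
#'
#' UTF-8 CSV with a header row and '.' decimal separator; numeric columns
#' are written with 12 significant digits so that a write/read round trip
#' is lossless at that precision.
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @param numeric_cols Columns that must parse as numeric; a cell that
#'   does not parse raises an error naming the row and column.
#' @return `read_table` returns a data frame; `write_table` returns
#'   `path` invisibly.
#' @export
read_table <- function(path, required = character(0),
                       numeric_cols = character(0)) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L && ncol(d) == 0L)
    stop(sprintf("empty table: %s", path), call. = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (cn in intersect(numeric_cols, names(d))) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !is.na(d[[cn]]) & nzchar(trimws(d[[cn]])))
    if (length(bad) > 0L)
      stop(sprintf("%s: non-numeric value in column '%s', row %d ('%s')",
                   path, cn, bad[1], d[[cn]][bad[1]]), call. = FALSE)
    d[[cn]] <- v
  }
  d
}

#' @rdname read_table
#' @param table Data frame to write.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (cn in names(out))
    if (is.numeric(out[[cn]]))
      out[[cn]] <- formatC(out[[cn]], digits = 12, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the fit-and-optimize pipeline from a configuration list
#'
#' Mirrors the case study's workflow: load a design + response table,
#' fit a full quadratic model per response, and (optionally) run the
#' desirability optimization over a factor box. The returned report
#' records inputs, seeds and all numeric outputs and can be serialized
#' to JSON.
#'
#' @param config Named list with elements:
#'   \describe{
#'     \item{design}{path to a design CSV, or a `design_matrix`.}
#'     \item{responses}{path to a response CSV (keyed by `code`), or a
#'       data frame.}
#'     \item{response_names}{character vector of response columns to fit.}
#'     \item{scale, block_handling}{passed to [fit_quadratic()].}
#'     \item{desirability}{optional list with `specs` (named list of
#'       `lower`/`target`/`weight` lists), `bounds` (list of ranges) and
#'       `grid_density`.}
#'     \item{seed}{integer; recorded in the report.}
#'   }
#'   Unknown keys are rejected.
#' @param out Optional path: write the report as JSON.
#' @return List of class `qbd_report`.
#' @export
run_pipeline <- function(config, out = NULL) {
  known <- c("design", "responses", "response_names", "scale",
             "block_handling", "desirability", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (is.null(config$response_names))
    stop("config$response_names is required", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  design <- config$design
  if (is.character(design)) design <- read_design(design)
  responses <- config$responses
  if (is.character(responses))
    responses <- read_table(responses, required = "code")

  scale <- config$scale %||% "actual"
  blocks <- config$block_handling %||% "fixed_effect"
  fits <- list()
  anovas <- list()
  for (rn in config$response_names) {
    fits[[rn]] <- fit_quadratic(design, responses, rn, scale, blocks)
    anovas[[rn]] <- rsm_anova(design, responses, rn, model = fits[[rn]],
                              scale = scale, block_handling = blocks)
  }

  opt <- NULL
  if (!is.null(config$desirability)) {
    dz <- config$desirability
    specs <- lapply(dz$specs, function(s)
      desirability_spec(s$lower, s$target, s$weight %||% 1))
    opt <- optimize_desirability(fits[names(specs)], specs,
                                 bounds = dz$bounds,
                                 grid_density = dz$grid_density %||% 51L)
  }

  report <- structure(
    list(package_version = as.character(utils::packageVersion("qbdoe")),
         seed = seed,
         n_runs = nrow(design),
         coefficients = lapply(fits, coef),
         r_squared = lapply(anovas, attr, "r_squared"),
         anova = lapply(anovas, as.data.frame),
         optimum = if (!is.null(opt))
           list(best_point = as.list(opt$best_point),
                predicted_responses = as.list(opt$predicted_responses),
                composite_desirability = opt$composite_desirability)),
    class = "qbd_report")
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  report
}

#' @export
print.qbd_report <- function(x, ...) {
  cat(sprintf("<qbd_report> qbdoe %s, seed %d, %d runs\n",
              x$package_version, x$seed, x$n_runs))
  for (rn in names(x$coefficients)) {
    cat(sprintf("\nresponse %s (R^2 = %.4f):\n", rn, x$r_squared[[rn]]))
    print(round(x$coefficients[[rn]], 4))
  }
  if (!is.null(x$optimum)) {
    cat("\noptimum: ",
        paste(sprintf("%s = %.4g", names(x$optimum$best_point),
                      unlist(x$optimum$best_point)), collapse = ", "),
        sprintf("\ncomposite desirability %.4f\n",
                x$optimum$composite_desirability))
  }
  invisible(x)
}

#' Command-line interface
#'
#' A minimal subcommand dispatcher (`design`, `fit`, `bo`, `nca`,
#' `fixtures`) intended to be called from `Rscript`; see
#' `system.file("cli", "qbdoe", package = "qbdoe")` for the launcher.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
qbdoe_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: qbdoe <command> [options]",
    "  design ccd --out design.csv [--alpha 1.633]",
    "  design pb --factors 6 --out design.csv",
    "  fit --design design.csv --responses resp.csv --response Y1",
    "      [--scale actual] [--out report.json]",
    "  fixtures --dir out/",
    sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  cmd <- args[1]
  status <- 0L
  tryCatch({
    if (cmd == "design") {
      kind <- args[2]
      outp <- opt("--out", "design.csv")
      if (identical(kind, "ccd")) {
        d <- generate_ccd(celecoxib_factors(),
                          alpha = as.numeric(opt("--alpha", "1.633")),
                          n_center_cube = as.integer(opt("--centers-cube", "4")),
                          n_center_axial = as.integer(opt("--centers-axial", "2")))
      } else if (identical(kind, "pb")) {
        d <- generate_plackett_burman(as.integer(opt("--factors", "6")))
      } else stop("unknown design kind: ", kind)
      write_design(d, outp)
      message("wrote ", outp)
    } else if (cmd == "fit") {
      report <- run_pipeline(list(
        design = opt("--design"), responses = opt("--responses"),
        response_names = opt("--response", "Y1"),
        scale = opt("--scale", "actual"),
        seed = as.integer(opt("--seed", "1"))),
        out = opt("--out"))
      print(report)
    } else if (cmd == "fixtures") {
      export_fixtures(opt("--dir", "."))
      message("exported fixtures")
    } else {
      message(usage)
      status <- 1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}
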