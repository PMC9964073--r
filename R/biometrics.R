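## Closed-form in-vitro / in-vivo evaluation metrics: MTT viability,
## apparent permeability, withdrawal-corrected intrinsic dissolution rate,
## fold changes, and non-compartmental PK analysis.

# round-half-up at d decimals (base round() is round-half-even; printed
# pharmacology tables use half-up)
.round_half_up <- function(x, d = 0) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' MTT assay plate summary
#'
#' @param group_absorbance Mean absorbance (570 nm) of the treated group.
#' @param blank_absorbance Mean absorbance of the blank wells.
#' @param negative_control_absorbance Mean absorbance of the untreated
#'   (100% viability) control; must exceed the blank.
#' @return Object of class `viability_plate`.
#' @export
viability_plate <- function(group_absorbance, blank_absorbance,
                            negative_control_absorbance) {
  stopifnot(is.numeric(group_absorbance), is.numeric(blank_absorbance),
            is.numeric(negative_control_absorbance))
  if (!(negative_control_absorbance > blank_absorbance))
    stop("invalid assay: negative control must exceed the blank",
         call. = FALSE)
  structure(list(group_absorbance = group_absorbance,
                 blank_absorbance = blank_absorbance,
                 negative_control_absorbance = negative_control_absorbance),
            class = "viability_plate")
}

#' Cell viability percentage from an MTT plate
#'
#' `100 * (group - blank) / (control - blank)`.
#'
#' @param plate A [viability_plate()].
#' @return Viability in percent.
#' @examples
#' cell_viability_percent(viability_plate(0.6, 0.1, 1.1))  # 50
#' @export
cell_viability_percent <- function(plate) {
  stopifnot(inherits(plate, "viability_plate"))
  100 * (plate$group_absorbance - plate$blank_absorbance) /
    (plate$negative_control_absorbance - plate$blank_absorbance)
}

#' Caco-2 permeability assay summary
#'
#' @param flux Transport rate dQ/dt in amount per time (`time_unit`).
#' @param area Insert surface area in cm^2 (default 1.13, a standard
#'   12-well insert).
#' @param initial_conc Initial apical (donor) concentration, same amount
#'   units as `flux`.
#' @param time_unit Time unit of `flux`: `"min"` (converted to seconds)
#'   or `"s"`.
#' @return Object of class `permeability_assay`.
#' @export
permeability_assay <- function(flux, area = 1.13, initial_conc,
                               time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(flux), flux >= 0)
  if (!(area > 0)) stop("`area` must be > 0", call. = FALSE)
  if (!(initial_conc > 0)) stop("`initial_conc` must be > 0", call. = FALSE)
  structure(list(flux = flux, area = area, initial_conc = initial_conc,
                 time_unit = time_unit),
            class = "permeability_assay")
}

#' Apparent permeability coefficient (cm/s)
#'
#' `Papp = (dQ/dt) / (A * C0)`, converted to per-second when the flux is
#' given per minute.
#'
#' @param assay A [permeability_assay()].
#' @return Papp in cm/s.
#' @examples
#' # flux chosen so Papp = 1e-6 cm/s on a 1.13 cm^2 insert
#' apparent_permeability(permeability_assay(
#'   flux = 1e-6 * 1.13 * 100 * 60, initial_conc = 100))
#' @export
apparent_permeability <- function(assay) {
  stopifnot(inherits(assay, "permeability_assay"))
  per_time <- assay$flux / (assay$area * assay$initial_conc)
  if (assay$time_unit == "min") per_time / 60 else per_time
}

#' Dissolution profile from a constant-surface (Wood apparatus) disc test
#'
#' @param times Sampling times (min), strictly increasing.
#' @param concentrations Measured concentrations (ug/mL), non-negative.
#' @param medium_volume Dissolution medium volume (mL), kept constant by
#'   replacing each withdrawn sample with fresh medium.
#' @param sample_volume Withdrawn sample volume (mL), < `medium_volume`.
#' @param disc_area Exposed disc surface area (cm^2); 0.5 cm^2 for the
#'   standard Wood apparatus die.
#' @return Object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, concentrations, medium_volume = 500,
                                sample_volume = 5, disc_area = 0.5) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  stopifnot(length(times) == length(concentrations),
            all(is.finite(times)), all(is.finite(concentrations)),
            all(concentrations >= 0), medium_volume > 0, sample_volume >= 0,
            disc_area > 0)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!(sample_volume < medium_volume))
    stop("`sample_volume` must be smaller than `medium_volume`",
         call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 medium_volume = medium_volume, sample_volume = sample_volume,
                 disc_area = disc_area),
            class = "dissolution_profile")
}

#' Withdrawal-corrected cumulative concentrations
#'
#' Sampling removes dissolved drug and dilutes the medium with fresh
#' buffer; the standard correction adds back the fraction lost to all
#' earlier withdrawals:
#' `C_corr[n] = C[n] + (Vs/V) * sum(C[1..n-1])`.
#'
#' @param profile A [dissolution_profile()].
#' @return Corrected concentration vector (same units as measured).
#' @examples
#' p <- dissolution_profile(1:3, c(10, 10, 10), 500, 5)
#' withdrawal_corrected_cumulative(p)  # 10, 10.1, 10.2
#' @export
withdrawal_corrected_cumulative <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  cc <- profile$concentrations
  f <- profile$sample_volume / profile$medium_volume
  cc + f * (cumsum(cc) - cc)
}

#' Intrinsic dissolution rate (mg/min/cm^2)
#'
#' Ordinary-least-squares slope of the withdrawal-corrected dissolved mass
#' per unit disc area versus time over the requested window. Measured
#' concentrations in ug/mL and the medium volume in mL give dissolved mass
#' in ug, converted to mg.
#'
#' @param profile A [dissolution_profile()].
#' @param window Length-2 time range `c(from, to)` in minutes; defaults to
#'   the whole profile. At least 3 samples must fall inside it.
#' @return IDR slope in mg/min/cm^2.
#' @export
intrinsic_dissolution_rate <- function(profile, window = NULL) {
  stopifnot(inherits(profile, "dissolution_profile"))
  t <- profile$times
  if (is.null(window)) window <- range(t)
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 3L)
    stop("insufficient data: need >= 3 samples inside the window",
         call. = FALSE)
  cc <- withdrawal_corrected_cumulative(profile)
  mass_mg <- cc * profile$medium_volume / 1000
  y <- mass_mg[keep] / profile$disc_area
  x <- t[keep]
  as.numeric(stats::coef(stats::lm(y ~ x))[["x"]])
}

#' Rounded fold change
#'
#' `round(a / b, decimals)` with half-up rounding (the convention of
#' printed pharmacology tables, where base R's round-half-even can differ
#' in the last digit).
#'
#' @param a,b Numerator and denominator; `b` must be > 0.
#' @param decimals Decimal places to round to.
#' @return Rounded ratio.
#' @examples
#' fold_change(8.6, 1.8, 1)       # 4.8
#' fold_change(6.43, 0.0667, 0)   # 96
#' @export
fold_change <- function(a, b, decimals = 1) {
  if (!is.numeric(b) || any(b <= 0))
    stop("`b` must be > 0", call. = FALSE)
  .round_half_up(a / b, decimals)
}

#' Concentration-time profile for non-compartmental analysis
#'
#' @param times Sampling times (h), strictly increasing, >= 0.
#' @param concentrations Plasma concentrations (ug/mL), >= 0.
#' @param dose Administered dose (mg/kg); used for dose normalization.
#' @param subject_id Optional subject label.
#' @return Object of class `pk_profile`.
#' @export
pk_profile <- function(times, concentrations, dose = NA_real_,
                       subject_id = NULL) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  stopifnot(length(times) == length(concentrations), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(concentrations)),
            all(times >= 0), all(concentrations >= 0))
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 dose = dose, subject_id = subject_id),
            class = "pk_profile")
}

#' Linear trapezoidal AUC
#'
#' @param times,concentrations Paired numeric vectors (times increasing).
#' @return Area under the linear interpolant.
#' @export
auc_linear <- function(times, concentrations) {
  stopifnot(length(times) == length(concentrations), length(times) >= 2L)
  dt <- diff(times)
  sum(dt * (utils::head(concentrations, -1) +
              utils::tail(concentrations, -1)) / 2)
}

#' Non-compartmental pharmacokinetic analysis
#'
#' Computes Cmax/tmax by direct lookup, AUC0-t by the linear (linear-up /
#' linear-down) trapezoid over the observed profile, the terminal
#' elimination rate `ke` as minus the OLS slope of `log(C)` over the last
#' `terminal_points` positive samples, and from these
#' `AUC0-inf = AUC0-t + C_last/ke`, `t1/2 = log(2)/ke`, and
#' `MRT = AUMC0-inf / AUC0-inf` with the standard tail
#' `C_last*t_last/ke + C_last/ke^2` on the `t*C` trapezoid. If the fitted
#' terminal slope is not negative, `ke` and the extrapolated quantities
#' are returned as `NA` with a warning.
#'
#' @param profile A [pk_profile()].
#' @param terminal_points Number of trailing positive-concentration
#'   samples used for the terminal log-linear fit (>= 2, default 3).
#' @return Object of class `pk_params`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf`, `ke`, `t_half`, `mrt`, plus `n_terminal` and `dose`.
#' @examples
#' p <- simulate_pk_profile(pk_sim_config(10, 1.5, 0.1, 5,
#'        sample_times = c(0, 0.5, 1, 2, 4, 8, 16, 24, 48, 72)))
#' nca(p)
#' @export
nca <- function(profile, terminal_points = 3L) {
  stopifnot(inherits(profile, "pk_profile"))
  terminal_points <- as.integer(terminal_points)
  stopifnot(terminal_points >= 2L)
  t <- profile$times
  cc <- profile$concentrations

  imax <- which.max(cc)
  cmax <- cc[imax]
  tmax <- t[imax]
  auc_t <- auc_linear(t, cc)

  pos <- which(cc > 0)
  if (length(pos) < terminal_points)
    stop("insufficient positive concentrations for the terminal fit",
         call. = FALSE)
  term <- utils::tail(pos, terminal_points)
  slope <- as.numeric(stats::coef(
    stats::lm(log(cc[term]) ~ t[term]))[2])
  ilast <- utils::tail(pos, 1L)
  c_last <- cc[ilast]
  t_last <- t[ilast]

  if (!is.finite(slope) || slope >= 0) {
    warning("nonpositive terminal slope: ke undefined; ",
            "extrapolated parameters reported as NA")
    ke <- t_half <- auc_inf <- mrt <- NA_real_
  } else {
    ke <- -slope
    t_half <- log(2) / ke
    auc_inf <- auc_t + c_last / ke
    aumc_t <- auc_linear(t, t * cc)
    aumc_inf <- aumc_t + c_last * t_last / ke + c_last / ke^2
    mrt <- aumc_inf / auc_inf
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_t,
                 auc_0_inf = auc_inf, ke = ke, t_half = t_half, mrt = mrt,
                 n_terminal = terminal_points, dose = profile$dose),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, digits = 4, ...) {
  cat("<pk_params>\n")
  v <- unlist(x[c("cmax", "tmax", "auc_0_t", "auc_0_inf", "ke", "t_half",
                  "mrt")])
  print(signif(v, digits))
  invisible(x)
}

#' Relative bioavailability (%)
#'
#' Dose-normalized AUC ratio of a test formulation to a reference:
#' `100 * (auc_test/dose_test) / (auc_ref/dose_ref)`.
#'
#' @param auc_test,auc_ref AUC values (same units), > 0.
#' @param dose_test,dose_ref Doses (default equal).
#' @return Relative bioavailability in percent (unrounded).
#' @examples
#' round(relative_bioavailability(110.94, 76.42), 1)  # 145.2
#' @export
relative_bioavailability <- function(auc_test, auc_ref, dose_test = 1,
                                     dose_ref = 1) {
  if (!all(c(auc_test, auc_ref, dose_test, dose_ref) > 0))
    stop("all AUCs and doses must be > 0", call. = FALSE)
  100 * (auc_test / dose_test) / (auc_ref / dose_ref)
}
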