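# Standard-curve fitting of dilution series and conversion of slopes to
# molar extinction coefficients.

#' Molar extinction coefficient set for the two-wavelength DAR
#'
#' The four constants of the UV DAR inversion: antibody and drug molar
#' extinction coefficients at the drug's absorbance maximum (252 nm for
#' DM1) and the protein wavelength (280 nm), all in 1/(M cm).
#'
#' @param eAb252,eAb280 Antibody extinction coefficients at 252/280 nm.
#' @param eD252,eD280 Drug extinction coefficients at 252/280 nm.
#' @return An `extinction_set` object.
#' @export
extinction_set <- function(eAb252, eAb280, eD252, eD280) {
  for (nm in c("eAb252", "eAb280", "eD252", "eD280"))
    check_number(get(nm), nm, positive = TRUE)
  structure(list(eAb252 = eAb252, eAb280 = eAb280,
                 eD252 = eD252, eD280 = eD280),
            class = "extinction_set")
}

#' @export
print.extinction_set <- function(x, ...) {
  cat(sprintf(paste0("<extinction_set> antibody: %g (252), %g (280); ",
                     "drug: %g (252), %g (280) 1/(M cm)\n"),
              x$eAb252, x$eAb280, x$eD252, x$eD280))
  invisible(x)
}

#' Published trastuzumab/DM1 extinction coefficients
#'
#' Convenience constructor for the determined coefficient set shipped in
#' the package configuration (trastuzumab 74311/209409, DM1 25600/4410
#' 1/(M cm) at 252/280 nm).
#'
#' @param config Constants list from [load_constants()].
#' @return An [extinction_set()].
#' @export
published_extinctions <- function(config = load_constants()) {
  e <- config$extinctions
  extinction_set(e$eAb252, e$eAb280, e$eD252, e$eD280)
}

#' Fit a Beer-Lambert standard curve
#'
#' Ordinary least squares of absorbance on concentration over all replicate
#' points, `Y = aX + b`. The intercept is estimated (not forced through
#' zero) and reported as a blanking diagnostic; Beer-Lambert predicts
#' b = 0. Points above `max_abs` AU are excluded by default as outside the
#' detector's linear range.
#'
#' @param series A [dilution_series()].
#' @param max_abs Absorbance ceiling for inclusion, AU (default 2.5).
#' @return A `standard_curve` with `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `n_points`, `n_excluded` and the series' wavelength and
#'   concentration unit.
#' @export
fit_standard_curve <- function(series, max_abs = 2.5) {
  stopifnot(inherits(series, "dilution_series"))
  keep <- series$absorbance <= max_abs
  df <- series[keep, , drop = FALSE]
  if (length(unique(df$conc)) < 2L)
    stop_arg("degenerate design: need >= 2 distinct concentrations in range")
  fit <- lm(absorbance ~ conc, data = df)
  # noiseless round trips fit perfectly; lm's warning about that is expected
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 slope_se = sm$coefficients["conc", "Std. Error"],
                 n_points = nrow(df),
                 n_excluded = sum(!keep),
                 wavelength_nm = attr(series, "wavelength_nm"),
                 conc_unit = attr(series, "conc_unit")),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(paste0("<standard_curve> %g nm: slope %.5g +/- %.2g, ",
                     "intercept %.3g, r2 %.5f (n=%d, excluded=%d)\n"),
              x$wavelength_nm, x$slope, x$slope_se, x$intercept,
              x$r_squared, x$n_points, x$n_excluded))
  invisible(x)
}

#' Convert a standard-curve slope to an extinction coefficient
#'
#' Beer-Lambert gives `A = eps * C * L`, so the fitted slope a = eps * L
#' and `eps = a / L`, in AU mL/(mg cm) for mass-per-volume series or
#' 1/(mM cm) for millimolar series.
#'
#' @param curve A [fit_standard_curve()] result (or a bare slope).
#' @param path_cm Optical path length, cm (0.56 for the UV microplate).
#' @return Extinction coefficient per concentration unit.
#' @export
slope_to_extinction <- function(curve, path_cm) {
  check_number(path_cm, "path_cm", positive = TRUE)
  slope <- if (inherits(curve, "standard_curve")) curve$slope else curve
  slope / path_cm
}

#' Convert a per-unit extinction coefficient to molar
#'
#' Mass-per-volume (0.1% solution) coefficients scale by the molecular
#' weight; millimolar coefficients scale by 1000.
#'
#' @param extinction Extinction coefficient per concentration unit.
#' @param conc_unit `"mass_per_volume"` or `"millimolar"`.
#' @param mw_Da Molecular weight, Da (mass branch only).
#' @return Molar extinction coefficient, 1/(M cm).
#' @export
#' @examples
#' to_molar(1.44, "mass_per_volume", mw_Da = 145423)  # ~209409
#' to_molar(25.6, "millimolar")                       # 25600
to_molar <- function(extinction,
                     conc_unit = c("mass_per_volume", "millimolar"),
                     mw_Da = NULL) {
  conc_unit <- match.arg(conc_unit)
  check_number(extinction, "extinction", nonneg = TRUE)
  if (conc_unit == "mass_per_volume") {
    if (is.null(mw_Da))
      stop_arg("mw_Da is required to convert a mass-per-volume coefficient")
    check_number(mw_Da, "mw_Da", positive = TRUE)
    extinction * mw_Da
  } else {
    extinction * 1000
  }
}

#' Fit a dilution series through to a molar extinction coefficient
#'
#' Convenience composition of [fit_standard_curve()],
#' [slope_to_extinction()] and [to_molar()].
#'
#' @param series A [dilution_series()].
#' @param path_cm Optical path length, cm.
#' @param mw_Da Molecular weight, Da (mass-per-volume series only).
#' @param max_abs Linear-range ceiling passed to [fit_standard_curve()].
#' @return List with the `curve` and `epsilon_molar`.
#' @export
fit_extinction <- function(series, path_cm, mw_Da = NULL, max_abs = 2.5) {
  curve <- fit_standard_curve(series, max_abs = max_abs)
  eps <- slope_to_extinction(curve, path_cm)
  list(curve = curve,
       epsilon_molar = to_molar(eps, attr(series, "conc_unit"), mw_Da))
}
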