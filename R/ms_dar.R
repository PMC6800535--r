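# Intact-mass DAR: spectral processing (baseline, smoothing, centroid) and
# the mass-shift ratio.

#' Subtract a rolling-minimum baseline
#'
#' Estimates the baseline as the rolling minimum over `window_Da`, computed
#' on a lightly pre-averaged copy (so noise spikes do not drive the
#' minimum) and smoothed with a running mean of the same window. The median
#' of the residual floor (points below 5% of the residual maximum) is added
#' back to the estimate, re-zeroing the baseline region: without this, the
#' minimum of noise undershoots by about three standard deviations and
#' leaves a positive floor across the spectrum. Negative residuals are
#' clipped to zero.
#'
#' The window must exceed the width of the broadest real peak envelope --
#' for an intact ADC with up to 8 drug loads that envelope spans ~8 kDa,
#' hence the 10-kDa default used by [dar_from_spectrum()].
#'
#' @param s A [mass_spectrum()] on a uniform grid.
#' @param window_Da Baseline window, Da; must not exceed the spectrum span.
#' @param preavg_Da Pre-averaging width before the rolling minimum, Da.
#' @return Baseline-subtracted [mass_spectrum()].
#' @export
baseline_subtract <- function(s, window_Da, preavg_Da = 50) {
  stopifnot(inherits(s, "mass_spectrum"))
  check_number(window_Da, "window_Da", positive = TRUE)
  span <- max(s$mz) - min(s$mz)
  if (window_Da > span)
    stop_arg("baseline window (%g Da) exceeds spectrum span (%g Da)",
             window_Da, span)
  step <- median(diff(s$mz))
  w <- max(3L, as.integer(round(window_Da / step)))
  pw <- max(1L, as.integer(round(preavg_Da / step)))
  bl <- run_mean(run_min(run_mean(s$intensity, pw), w), w)
  r <- s$intensity - bl
  floor_pts <- r < 0.05 * max(r)
  if (any(floor_pts)) bl <- bl + median(r[floor_pts])
  out <- s
  out$intensity <- pmax(s$intensity - bl, 0)
  out
}

#' Savitzky-Golay smoothing
#'
#' Moving-window least-squares polynomial smoothing of the intensities; the
#' m/z grid is unchanged. Edge points are fitted with the same polynomial
#' over the first/last full window evaluated at their offset, so any signal
#' that is globally a polynomial of degree `<= poly_order` is reproduced
#' exactly, edges included. `window_points = 1` is the identity.
#'
#' @param s A [mass_spectrum()].
#' @param window_points Odd window length in grid points (default 51).
#' @param poly_order Polynomial degree (default 2; must be < window).
#' @return Smoothed [mass_spectrum()].
#' @export
smooth_spectrum <- function(s, window_points = 51L, poly_order = 2L) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (window_points %% 2L == 0L)
    stop_arg("window_points must be odd (got %d)", window_points)
  if (window_points <= poly_order)
    stop_arg("window_points (%d) must exceed poly_order (%d)",
             window_points, poly_order)
  if (window_points == 1L) return(s)
  n <- length(s$intensity)
  if (n < window_points)
    stop_arg("spectrum has %d points, fewer than the %d-point window",
             n, window_points)
  m <- (window_points - 1L) %/% 2L
  Cmat <- sg_coefficients(window_points, poly_order)  # (p+1) x window
  centre_kernel <- Cmat[1L, ]
  y <- s$intensity
  sm <- as.numeric(stats::filter(y, rev(centre_kernel), sides = 2L))
  # edges: evaluate the boundary-window polynomial fit at each edge offset
  offs <- seq(-m, m)
  poly_eval <- function(coefs, x) drop(outer(x, 0:poly_order, `^`) %*% coefs)
  head_fit <- Cmat %*% y[seq_len(window_points)]
  sm[seq_len(m)] <- poly_eval(head_fit, offs[seq_len(m)])
  tail_fit <- Cmat %*% y[(n - window_points + 1L):n]
  sm[(n - m + 1L):n] <- poly_eval(tail_fit, offs[(m + 2L):window_points])
  out <- s
  out$intensity <- sm
  out
}

#' Centroid of the main peak region
#'
#' Finds the global intensity maximum and expands a contiguous region
#' around it while intensity stays at or above `threshold_frac` times the
#' maximum; returns the intensity-weighted mean m/z over that region. For a
#' broad unresolved conjugate envelope the threshold must be low enough for
#' the region to span the whole envelope (see [dar_from_spectrum()]).
#'
#' @param s A [mass_spectrum()], baseline-subtracted.
#' @param threshold_frac Region threshold as a fraction of the apex, in
#'   (0, 1) (default 0.10).
#' @return Centroid m/z, Da.
#' @export
main_peak_centroid <- function(s, threshold_frac = 0.10) {
  stopifnot(inherits(s, "mass_spectrum"))
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop_arg("threshold_frac must lie in (0, 1)")
  it <- s$intensity
  if (all(it <= 0)) stop_arg("no peak: spectrum has no positive intensity")
  i0 <- which.max(it)
  cut <- threshold_frac * it[i0]
  lo <- i0; while (lo > 1L && it[lo - 1L] >= cut) lo <- lo - 1L
  hi <- i0; while (hi < length(it) && it[hi + 1L] >= cut) hi <- hi + 1L
  idx <- lo:hi
  sum(s$mz[idx] * it[idx]) / sum(it[idx])
}

#' Neutral mass from a centroid m/z
#'
#' @param centroid_mz_Da Centroid m/z, Da.
#' @param charge Charge state (>= 1).
#' @param proton_mass_Da Proton mass, Da.
#' @return Neutral mass `charge * mz - charge * m_proton`, Da.
#' @export
neutral_mass <- function(centroid_mz_Da, charge = 1L,
                         proton_mass_Da = 1.00728) {
  if (charge < 1) stop_arg("charge must be >= 1")
  charge * centroid_mz_Da - charge * proton_mass_Da
}

#' DAR from intact masses
#'
#' The mass-shift ratio: the conjugate's mass excess over the unconjugated
#' antibody, divided by the mass added per conjugated drug-linker
#' (drug + linker - NHS leaving group; see [per_drug_mass_addition()]).
#'
#' @param conjugate_mass_Da Measured conjugate mass, Da.
#' @param antibody_mass_Da Measured unconjugated antibody mass, Da.
#' @param per_drug_mass_Da Mass addition per conjugated drug-linker, Da.
#' @return An `ms_dar_result` with `mass_shift_Da`, unrounded `dar` and
#'   one-decimal `dar_display`.
#' @export
#' @examples
#' dar_from_mass(150832.2, 147836.9, 957.4)  # shift 2995.3, DAR 3.1
dar_from_mass <- function(conjugate_mass_Da, antibody_mass_Da,
                          per_drug_mass_Da) {
  check_number(conjugate_mass_Da, "conjugate_mass_Da", positive = TRUE)
  check_number(antibody_mass_Da, "antibody_mass_Da", positive = TRUE)
  check_number(per_drug_mass_Da, "per_drug_mass_Da", positive = TRUE)
  shift <- conjugate_mass_Da - antibody_mass_Da
  dar <- shift / per_drug_mass_Da
  structure(list(method = "intact_ms",
                 conjugate_mass_Da = conjugate_mass_Da,
                 antibody_mass_Da = antibody_mass_Da,
                 mass_shift_Da = shift,
                 per_drug_mass_Da = per_drug_mass_Da,
                 dar = dar, dar_display = round(dar, 1L)),
            class = "ms_dar_result")
}

#' @export
print.ms_dar_result <- function(x, ...) {
  cat(sprintf(paste0("<ms_dar_result> shift %.1f Da / %.1f Da per drug ",
                     "= DAR %.3f (display %.1f)\n"),
              x$mass_shift_Da, x$per_drug_mass_Da, x$dar, x$dar_display))
  invisible(x)
}

#' Full intact-MS DAR pipeline on spectra
#'
#' Applies baseline subtraction, Savitzky-Golay smoothing, main-peak
#' centroiding and proton correction to both the conjugate and the
#' reference (unconjugated antibody) spectra, then forms the mass-shift
#' DAR with the design's per-drug-linker mass. The reference may instead be
#' a bare neutral mass (Table mode), in which case no proton correction is
#' applied to it.
#'
#' Defaults are tuned for partially-resolved linear-mode envelopes
#' (resolution ~300 at ~148 kDa): a 10-kDa baseline window wider than the
#' full load envelope, and a 0.5%-of-apex centroid threshold so the region
#' spans every load species rather than clipping at inter-species valleys.
#' The baseline window is capped at 80% of the narrower spectrum's span.
#'
#' @param conjugate A [mass_spectrum()] of the conjugate.
#' @param reference A [mass_spectrum()] of the unconjugated antibody, or a
#'   single neutral mass in Da.
#' @param design A [conjugate_design()].
#' @param baseline_window_Da Rolling-minimum window, Da.
#' @param smooth_window,poly_order Savitzky-Golay parameters.
#' @param threshold_frac Centroid region threshold (fraction of apex).
#' @param proton_mass_Da Proton mass, Da.
#' @return An `ms_dar_result`; also carries both centroids.
#' @export
dar_from_spectrum <- function(conjugate, reference, design,
                              baseline_window_Da = 10000,
                              smooth_window = 51L, poly_order = 2L,
                              threshold_frac = 0.005,
                              proton_mass_Da = 1.00728) {
  stopifnot(inherits(conjugate, "mass_spectrum"))
  process <- function(s) {
    win <- min(baseline_window_Da, 0.8 * (max(s$mz) - min(s$mz)))
    s <- baseline_subtract(s, win)
    s <- smooth_spectrum(s, smooth_window, poly_order)
    cmz <- main_peak_centroid(s, threshold_frac)
    neutral_mass(cmz, s$charge, proton_mass_Da)
  }
  conj_mass <- process(conjugate)
  ref_mass <- if (inherits(reference, "mass_spectrum")) process(reference)
              else {
                check_number(reference, "reference", positive = TRUE)
                reference
              }
  res <- dar_from_mass(conj_mass, ref_mass,
                       per_drug_mass_addition(design))
  res$conjugate_centroid_mass_Da <- conj_mass
  res$reference_centroid_mass_Da <- ref_mass
  res
}

#' Write a DAR result as JSON
#'
#' @param result A `uv_dar_result` or `ms_dar_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dar_json <- function(result, path) {
  out <- unclass(result)
  out$extinctions <- if (!is.null(out$extinctions)) unclass(out$extinctions)
  out <- Filter(Negate(is.null), out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
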