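# Synthetic-data generators: Beer-Lambert dilution series, additive
# drug+antibody UV spectra, and linear-mode intact-mass spectra of
# conjugate ensembles. Every generator is a pure function of its arguments
# and seed, so downstream stages are testable without instrument data.

#' Drug-load distribution across an antibody population
#'
#' Lysine-directed conjugation yields a mixture of conjugates carrying
#' 0, 1, 2, ... drugs. The load distribution is modelled as Poisson
#' (truncated at the number of accessible coupling sites and renormalized),
#' binomial over discrete sites, or a fixed load.
#'
#' @param kind `"poisson"`, `"binomial"`, or `"fixed"`.
#' @param mean_load Expected drugs per antibody (Poisson lambda, or the
#'   fixed load).
#' @param max_load Truncation bound: number of accessible coupling sites
#'   (default 8).
#' @param site_count,per_site_prob Binomial parameters (binomial kind only).
#' @return A `load_distribution` object.
#' @export
load_distribution <- function(kind = c("poisson", "binomial", "fixed"),
                              mean_load = NULL, max_load = 8L,
                              site_count = NULL, per_site_prob = NULL) {
  kind <- match.arg(kind)
  check_number(max_load, "max_load", positive = TRUE)
  if (kind == "binomial") {
    check_number(site_count, "site_count", positive = TRUE)
    check_number(per_site_prob, "per_site_prob", nonneg = TRUE)
    if (per_site_prob > 1) stop_arg("per_site_prob must be <= 1")
    mean_load <- site_count * per_site_prob
  } else {
    check_number(mean_load, "mean_load", nonneg = TRUE)
  }
  if (mean_load > max_load)
    stop_arg("mean_load (%g) exceeds max_load (%g)", mean_load, max_load)
  structure(list(kind = kind, mean_load = mean_load,
                 max_load = as.integer(max_load),
                 site_count = site_count, per_site_prob = per_site_prob),
            class = "load_distribution")
}

#' Species probabilities of a load distribution
#'
#' Probability of carrying k = 0..max_load drugs, renormalized to sum to 1
#' after truncation.
#'
#' @param load A [load_distribution()].
#' @return Numeric vector of length `max_load + 1`, names `0..max_load`.
#' @export
load_probabilities <- function(load) {
  k <- 0:load$max_load
  p <- switch(load$kind,
    poisson  = dpois(k, load$mean_load),
    binomial = dbinom(k, size = load$site_count, prob = load$per_site_prob),
    fixed    = as.numeric(k == round(load$mean_load)))
  p <- p / sum(p)
  setNames(p, k)
}

#' Mean drug load after truncation
#'
#' Direct summation `sum(k * P(k))` over the renormalized species
#' probabilities -- the ground truth an intact-MS DAR estimate targets.
#'
#' @param load A [load_distribution()].
#' @return Truncated mean load.
#' @export
truncated_mean_load <- function(load) {
  p <- load_probabilities(load)
  sum(as.numeric(names(p)) * p)
}

#' Instrument model for linear-mode intact-mass simulation
#'
#' @param resolution Mass resolution m/dm, FWHM-based (dimensionless;
#'   default 300, typical of linear-mode TOF on intact IgG).
#' @param baseline_level Constant intensity offset.
#' @param baseline_slope Intensity change per Da (chemical-background ramp).
#' @param noise_sd Additive Gaussian intensity noise, absolute units.
#' @param mz_step Uniform m/z grid spacing, Da (default 2).
#' @param charge Integer charge (default 1).
#' @param proton_mass_Da Proton mass, Da.
#' @return An `instrument_model` object.
#' @export
instrument_model <- function(resolution = 300, baseline_level = 0,
                             baseline_slope = 0, noise_sd = 0, mz_step = 2,
                             charge = 1L, proton_mass_Da = 1.00728) {
  check_number(resolution, "resolution", positive = TRUE)
  check_number(mz_step, "mz_step", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (charge < 1) stop_arg("charge must be >= 1")
  structure(list(resolution = resolution, baseline_level = baseline_level,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 mz_step = mz_step, charge = as.integer(charge),
                 proton_mass_Da = proton_mass_Da),
            class = "instrument_model")
}

#' Simulate a Beer-Lambert two-fold serial dilution series
#'
#' Concentrations are `start_conc / 2^i`, i = 0..n_dilutions-1, each
#' measured `n_replicates` times; absorbance is
#' `(epsilon_molar / mw_Da) * conc * path_cm + N(0, noise_sd)` for
#' mass-per-volume concentrations, or
#' `(epsilon_molar / 1000) * conc_mM * path_cm + noise` for millimolar.
#'
#' @param epsilon_molar Generating molar extinction coefficient, 1/(M cm).
#' @param mw_Da Molecular weight, Da (required for the mass branch).
#' @param path_cm Optical path length, cm.
#' @param start_conc Top concentration (mg/mL or mM per `conc_unit`).
#' @param n_dilutions Number of two-fold dilution steps.
#' @param n_replicates Replicates per concentration (3 in the standard
#'   protocol).
#' @param noise_sd Gaussian absorbance noise, AU.
#' @param seed RNG seed; the same seed reproduces the same table.
#' @param wavelength_nm Wavelength label attached to the series.
#' @param conc_unit `"mass_per_volume"` or `"millimolar"`.
#' @return A [dilution_series()].
#' @export
#' @examples
#' s <- gen_dilution_series(209409, 145423, 0.56, start_conc = 1,
#'                          n_dilutions = 8, n_replicates = 3,
#'                          noise_sd = 0, seed = 1, wavelength_nm = 280)
#' max(s$absorbance)  # 0.8064 at 1 mg/mL
gen_dilution_series <- function(epsilon_molar, mw_Da = NULL, path_cm,
                                start_conc, n_dilutions = 8L,
                                n_replicates = 3L, noise_sd = 0, seed = NULL,
                                wavelength_nm = 280,
                                conc_unit = c("mass_per_volume",
                                              "millimolar")) {
  conc_unit <- match.arg(conc_unit)
  check_number(epsilon_molar, "epsilon_molar", positive = TRUE)
  check_number(path_cm, "path_cm", positive = TRUE)
  check_number(start_conc, "start_conc", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  conc <- start_conc / 2^(seq_len(n_dilutions) - 1L)
  eps_per_unit <- if (conc_unit == "mass_per_volume") {
    check_number(mw_Da, "mw_Da", positive = TRUE)
    epsilon_molar / mw_Da          # AU mL / (mg cm)
  } else epsilon_molar / 1000      # 1/(mM cm)
  grid <- expand.grid(replicate = seq_len(n_replicates), conc = conc)
  ab <- eps_per_unit * grid$conc * path_cm
  if (noise_sd > 0)
    ab <- ab + with_seed(seed, rnorm(length(ab), 0, noise_sd))
  dilution_series(grid$conc, pmax(ab, -0.049), replicate = grid$replicate,
                  wavelength_nm = wavelength_nm, conc_unit = conc_unit)
}

# Two-band spectral basis: Gaussian bands centred at the antibody (280 nm,
# sigma 15) and drug (252 nm, sigma 18) absorbance maxima. Each species'
# spectral shape is the linear combination of the two bands that
# interpolates its printed extinction pair at (252, 280); only those two
# wavelengths are contract-bearing.
uv_basis <- function(wavelengths) {
  cbind(ab = exp(-(wavelengths - 280)^2 / (2 * 15^2)),
        d  = exp(-(wavelengths - 252)^2 / (2 * 18^2)))
}

uv_species_curve <- function(wavelengths, e252, e280) {
  B <- uv_basis(c(252, 280))
  coefs <- solve(B, c(e252, e280))
  drop(uv_basis(wavelengths) %*% coefs)
}

#' Simulate a conjugate UV spectrum
#'
#' Forward model of absorbance additivity: the conjugate extinction at each
#' wavelength is the antibody curve plus `dar_true` times the drug curve,
#' with each species' curve pinned to its extinction coefficients at 252
#' and 280 nm. `A(lambda) = [eAb(lambda) + dar_true * eD(lambda)] * C * L
#' + N(0, noise_sd)`.
#'
#' @param extinctions An [extinction_set()].
#' @param dar_true True drug-to-antibody ratio (>= 0).
#' @param ab_conc_molar Antibody concentration, mol/L.
#' @param path_cm Optical path length, cm.
#' @param wavelengths Wavelength grid, nm; must lie in \[200, 400\].
#' @param noise_sd Gaussian absorbance noise, AU.
#' @param seed RNG seed.
#' @param sample_id Sample label.
#' @return A [uv_spectrum()] whose `metadata`-like fields include the
#'   generating truth (attribute `dar_true`).
#' @export
gen_uv_spectrum <- function(extinctions, dar_true, ab_conc_molar,
                            path_cm = 0.56,
                            wavelengths = seq(200, 360, by = 0.5),
                            noise_sd = 0, seed = NULL,
                            sample_id = "synthetic_conjugate") {
  stopifnot(inherits(extinctions, "extinction_set"))
  check_number(dar_true, "dar_true", nonneg = TRUE)
  check_number(ab_conc_molar, "ab_conc_molar", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(wavelengths < 200 | wavelengths > 400))
    stop_arg("wavelengths must lie within 200-400 nm")
  e_ab <- uv_species_curve(wavelengths, extinctions$eAb252, extinctions$eAb280)
  e_d  <- uv_species_curve(wavelengths, extinctions$eD252, extinctions$eD280)
  A <- (e_ab + dar_true * e_d) * ab_conc_molar * path_cm
  if (noise_sd > 0)
    A <- A + with_seed(seed, rnorm(length(A), 0, noise_sd))
  s <- uv_spectrum(wavelengths, A, sample_id = sample_id, path_cm = path_cm)
  attr(s, "dar_true") <- dar_true
  s
}

#' Simulate a linear-mode intact-mass spectrum of a conjugate ensemble
#'
#' Species k = 0..max_load has neutral mass
#' `M_k = antibody mass + k * per_drug_mass_addition(design)` and
#' contributes a Gaussian at `(M_k + z * m_proton) / z` with
#' `FWHM = centre / resolution` and area proportional to `P(k)`. A linear
#' baseline and additive Gaussian noise complete the instrument model. The
#' antibody's measured (glycosylated) mass is used when present, otherwise
#' the formula mass.
#'
#' @param design A [conjugate_design()].
#' @param load A [load_distribution()].
#' @param instrument An [instrument_model()].
#' @param mz_range Length-2 m/z window; defaults to all species peaks
#'   +/- 5 FWHM.
#' @param seed RNG seed for the noise stream.
#' @return A [mass_spectrum()] on a uniform m/z grid; `metadata` carries the
#'   ground truth (`true_mean_load`, species probabilities and centres).
#' @export
gen_maldi_spectrum <- function(design, load, instrument = instrument_model(),
                               mz_range = NULL, seed = NULL) {
  stopifnot(inherits(design, "conjugate_design"),
            inherits(load, "load_distribution"),
            inherits(instrument, "instrument_model"))
  ab_mass <- design$antibody$mw_measured_Da %||% design$antibody$mw_formula_Da
  delta <- per_drug_mass_addition(design)
  p <- load_probabilities(load)
  k <- as.numeric(names(p))
  z <- instrument$charge
  centers <- (ab_mass + k * delta + z * instrument$proton_mass_Da) / z
  fwhm <- centers / instrument$resolution
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  keep <- p > 0
  if (is.null(mz_range))
    mz_range <- c(min((centers - 5 * fwhm)[keep]),
                  max((centers + 5 * fwhm)[keep]))
  if (length(mz_range) != 2L || diff(mz_range) <= 0)
    stop_arg("mz_range must be an increasing length-2 window")
  mz <- seq(mz_range[1L], mz_range[2L], by = instrument$mz_step)
  if (length(mz) < 10L) stop_arg("mz_range too narrow for the grid step")
  it <- rowSums(vapply(which(keep), function(i) {
    p[i] / (sigma[i] * sqrt(2 * pi)) *
      exp(-(mz - centers[i])^2 / (2 * sigma[i]^2))
  }, numeric(length(mz))))
  it <- it + instrument$baseline_level +
    instrument$baseline_slope * (mz - mz_range[1L])
  if (instrument$noise_sd > 0)
    it <- it + with_seed(seed, rnorm(length(it), 0, instrument$noise_sd))
  mass_spectrum(mz, it, charge = z, metadata = list(
    true_mean_load = truncated_mean_load(load),
    antibody_mass_Da = ab_mass,
    per_drug_mass_Da = delta,
    species_probabilities = unname(p),
    species_centers_mz = centers,
    instrument = instrument))
}

#' Write the generator ground truth as a JSON sidecar
#'
#' @param spectrum A spectrum produced by [gen_maldi_spectrum()] or
#'   [gen_uv_spectrum()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(spectrum, path) {
  gt <- if (inherits(spectrum, "mass_spectrum")) {
    md <- spectrum$metadata
    list(true_mean_load = md$true_mean_load,
         antibody_mass_Da = md$antibody_mass_Da,
         per_drug_mass_Da = md$per_drug_mass_Da,
         species_probabilities = md$species_probabilities)
  } else list(dar_true = attr(spectrum, "dar_true"))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
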