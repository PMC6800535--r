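test_that("dilution series follows Beer-Lambert exactly at zero noise", {
  s <- gen_dilution_series(209409, 145423, 0.56, start_conc = 1,
                           n_dilutions = 8, n_replicates = 3,
                           noise_sd = 0, seed = 1, wavelength_nm = 280)
  expect_equal(nrow(s), 24L)
  expect_equal(sort(unique(s$conc)), 1 / 2^(7:0))
  # hand Beer-Lambert at the top concentration: 209409/145423 * 1 * 0.56
  expect_equal(max(s$absorbance), 0.8064, tolerance = 1e-4)
  # linear through the origin at every dilution
  expect_equal(s$absorbance, 209409 / 145423 * s$conc * 0.56,
               tolerance = 1e-12)
  expect_error(gen_dilution_series(1000, 145423, 0.56, 1, noise_sd = -1),
               "noise_sd")
})

test_that("generators are pure functions of (arguments, seed)", {
  a <- gen_dilution_series(209409, 145423, 0.56, 1, noise_sd = 0.01,
                           seed = 7, wavelength_nm = 280)
  b <- gen_dilution_series(209409, 145423, 0.56, 1, noise_sd = 0.01,
                           seed = 7, wavelength_nm = 280)
  expect_identical(a, b)
  u1 <- gen_uv_spectrum(PUB_EXT, 2, 6.9e-6, noise_sd = 0.002, seed = 3)
  u2 <- gen_uv_spectrum(PUB_EXT, 2, 6.9e-6, noise_sd = 0.002, seed = 3)
  expect_identical(u1, u2)
  p1 <- gen_ms_pair(3.5, noise_frac = 0.01, seed = 11)
  p2 <- gen_ms_pair(3.5, noise_frac = 0.01, seed = 11)
  expect_identical(p1$conjugate, p2$conjugate)
  # and the seed restores the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_uv_spectrum(PUB_EXT, 2, 6.9e-6,
                                          noise_sd = 0.002, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("UV forward model pins the contract-bearing wavelengths", {
  # no drug: ratio is the antibody's intrinsic 252/280 ratio
  s0 <- gen_uv_spectrum(PUB_EXT, 0, 6.88e-6, noise_sd = 0)
  r0 <- absorbance_at(s0, 252) / absorbance_at(s0, 280)
  expect_equal(r0, 74311 / 209409, tolerance = 1e-12)
  # DAR 3.5 with the published set: R = 0.72900 to 5 s.f.
  s35 <- gen_uv_spectrum(PUB_EXT, 3.5, 6.88e-6, noise_sd = 0)
  r35 <- absorbance_at(s35, 252) / absorbance_at(s35, 280)
  expect_equal(r35, 0.72900, tolerance = 5e-6)
  expect_error(gen_uv_spectrum(PUB_EXT, 1, 1e-6, wavelengths = 150:250),
               "200-400")
})

test_that("truncated load probabilities renormalize and average correctly", {
  for (lam in c(0.5, 1, 3.5, 6, 8)) {
    ld <- load_distribution("poisson", mean_load = lam, max_load = 8)
    p <- load_probabilities(ld)
    expect_lt(abs(sum(p) - 1), 1e-12)
    # oracle: direct summation over k = 0..8
    expect_equal(truncated_mean_load(ld),
                 sum(0:8 * dpois(0:8, lam)) / sum(dpois(0:8, lam)),
                 tolerance = 1e-12)
  }
  ld_b <- load_distribution("binomial", max_load = 8, site_count = 8,
                            per_site_prob = 0.4)
  expect_lt(abs(sum(load_probabilities(ld_b)) - 1), 1e-12)
  expect_equal(truncated_mean_load(ld_b), 3.2, tolerance = 1e-12)
})

test_that("MALDI simulation places centroids where the mixture mean says", {
  design <- make_design("SMCC", override = 957.4)
  inst <- instrument_model(resolution = 300, mz_step = 2)
  # single species: centroid at antibody mass + proton within 0.01%
  s0 <- gen_maldi_spectrum(design,
                           load_distribution("fixed", 0, max_load = 8), inst)
  cen <- sum(s0$mz * s0$intensity) / sum(s0$intensity)
  expect_equal(cen, 147836.9 + 1.00728, tolerance = 1e-4)
  # Poisson mixture: intensity-weighted centroid = ab + mean * delta (0.05%)
  ld <- load_distribution("poisson", 3.5, max_load = 8)
  s <- gen_maldi_spectrum(design, ld, inst)
  cen <- sum(s$mz * s$intensity) / sum(s$intensity)
  mu <- truncated_mean_load(ld)
  expect_equal(cen, 147836.9 + mu * 957.4 + 1.00728,
               tolerance = 5e-4)
  expect_equal(s$metadata$true_mean_load, mu)
})

test_that("total ion intensity is invariant to resolution (area conservation)", {
  design <- make_design("SMCC", override = 957.4)
  ld <- load_distribution("poisson", 3.5, max_load = 8)
  rng <- c(138000, 162000)
  tic <- vapply(c(150, 300, 600), function(res) {
    s <- gen_maldi_spectrum(design, ld,
                            instrument_model(resolution = res, mz_step = 2),
                            mz_range = rng)
    sum(s$intensity) * 2
  }, 0)
  expect_lt(max(abs(tic / tic[1L] - 1)), 1e-3)
})

test_that("simulated spectra round-trip through TSV and mzML writers", {
  design <- make_design("SMCC", override = 957.4)
  s <- gen_maldi_spectrum(design, load_distribution("poisson", 2, 8),
                          instrument_model(noise_sd = 1e-5, mz_step = 5),
                          seed = 5)
  tsv <- tempfile(fileext = ".tsv"); mzml <- tempfile(fileext = ".mzML")
  write_spectrum_tsv(s, tsv)
  write_spectrum_mzml(s, mzml)
  s_tsv <- load_spectrum(tsv)
  s_mzml <- load_spectrum(mzml)
  expect_equal(s_mzml$mz, s$mz, tolerance = 1e-12)
  expect_equal(s_mzml$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(s_tsv$mz, s_mzml$mz, tolerance = 1e-6)
  expect_equal(s_tsv$intensity, s_mzml$intensity, tolerance = 1e-6)
  # ground-truth sidecar carries the truncated mean
  gt <- tempfile(fileext = ".json")
  write_ground_truth_json(s, gt)
  expect_equal(jsonlite::read_json(gt)$true_mean_load,
               s$metadata$true_mean_load, tolerance = 1e-12)
})
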