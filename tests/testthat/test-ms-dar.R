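gaussian_spectrum <- function(center = 148000, sigma = 200, span = 4000,
                              step = 2, amp = 1, offset = 0) {
  mz <- seq(center - span, center + span, by = step)
  mass_spectrum(mz, amp * exp(-(mz - center)^2 / (2 * sigma^2)) + offset)
}

test_that("load_spectrum parses, sorts and rejects malformed TSV", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%d\t%d", c(100, 300, 200, 150:156), 1:10), tmp)
  s <- load_spectrum(tmp)
  expect_identical(s$mz, sort(c(100, 300, 200, 150:156)))
  expect_equal(sum(s$intensity), sum(1:10))

  writeLines(c("100\t1", "botched line", "300\t3"), tmp)
  expect_error(load_spectrum(tmp), "line 2")
  writeLines(sprintf("%d\t1", 1:5), tmp)
  expect_error(load_spectrum(tmp), "at least 10")
  expect_error(load_spectrum(tempfile(fileext = ".xyz")), "not found")

  # duplicated m/z values merge by summing
  writeLines(sprintf("%d\t%d", c(1:9, 5), c(1:9, 10)), tmp)
  expect_equal(sum(load_spectrum(tmp)$intensity == 15), 1L)
})

test_that("baseline subtraction removes flat and sloped backgrounds", {
  flat <- mass_spectrum(seq(1000, 3000, 2), rep(5, 1001))
  out <- baseline_subtract(flat, 500)
  expect_true(all(out$intensity == 0))

  peak <- gaussian_spectrum(center = 148000, sigma = 50, span = 1500,
                            offset = 50)
  sub <- baseline_subtract(peak, 600)
  apex <- max(sub$intensity)
  edge <- abs(sub$mz - 148000) > 400
  expect_lt(max(sub$intensity[edge]), 0.01 * apex)
  expect_equal(apex, 1, tolerance = 0.02)

  clean <- gaussian_spectrum(sigma = 50, span = 1500)
  out2 <- baseline_subtract(clean, 600)
  expect_equal(out2$intensity[!abs(out2$mz - 148000) > 400],
               clean$intensity[!abs(clean$mz - 148000) > 400],
               tolerance = 0.02)

  expect_error(baseline_subtract(flat, 5000), "span")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and cuts noise", {
  mz <- seq(1000, 1999, 1)
  x <- (mz - 1500) / 500
  poly2 <- mass_spectrum(mz, 3 + 2 * x + 0.5 * x^2)
  out <- smooth_spectrum(poly2, 21, 2)
  expect_equal(out$intensity, poly2$intensity, tolerance = 1e-9)
  expect_identical(out$mz, poly2$mz)

  set.seed(1)
  noise <- mass_spectrum(mz, rnorm(1000))
  sm <- smooth_spectrum(noise, 21, 2)
  expect_gt(var(noise$intensity) / var(sm$intensity), 5)

  expect_identical(smooth_spectrum(noise, 1, 0)$intensity, noise$intensity)
  expect_error(smooth_spectrum(noise, 20, 2), "odd")
  expect_error(smooth_spectrum(noise, 3, 4), "exceed")
})

test_that("main-peak centroid handles symmetric, mixed and clipped peaks", {
  g <- gaussian_spectrum(center = 148000, sigma = 250)
  expect_equal(main_peak_centroid(g, 0.10), 148000, tolerance = 148000 * 1e-4)

  # overlapping two-species mixture: centroid = weighted mean of centres
  w <- 0.3; c1 <- 148000; c2 <- c1 + 957.4; sigma <- 400
  mz <- seq(144000, 152000, 2)
  mix <- mass_spectrum(mz, w * exp(-(mz - c1)^2 / (2 * sigma^2)) +
                         (1 - w) * exp(-(mz - c2)^2 / (2 * sigma^2)))
  expected <- w * c1 + (1 - w) * c2
  expect_equal(main_peak_centroid(mix, 0.005), expected,
               tolerance = expected * 5e-4)

  # a 99% threshold keeps only the apex neighbourhood
  expect_equal(main_peak_centroid(g, 0.99), 148000, tolerance = 2)
  expect_error(main_peak_centroid(mass_spectrum(1:20, rep(0, 20)), 0.1),
               "no peak")
  expect_error(main_peak_centroid(g, 1.2), "threshold_frac")
})

test_that("centroid is invariant under uniform intensity scaling", {
  p <- gen_ms_pair(3.5, seed = 1)
  s <- p$conjugate
  scaled <- mass_spectrum(s$mz, s$intensity * 1234.5)
  expect_identical(main_peak_centroid(s, 0.01),
                   main_peak_centroid(scaled, 0.01))
})

test_that("neutral mass applies the proton correction per charge", {
  expect_equal(neutral_mass(147837.9, 1), 147836.89, tolerance = 0.01)
  expect_equal(neutral_mass((147836.89 + 2 * 1.00728) / 2, 2), 147836.89,
               tolerance = 1e-9)
  expect_equal(neutral_mass(500, 1, proton_mass_Da = 0), 500)
})

test_that("dar_from_mass reproduces the published mass-shift table", {
  kad <- dar_from_mass(150832.2, 147836.9, 957.4)
  expect_equal(kad$mass_shift_Da, 2995.3, tolerance = 1e-9)
  expect_equal(kad$dar_display, 3.1)
  tspd12 <- dar_from_mass(149148.6, 147836.9, 1488.7)
  expect_equal(tspd12$mass_shift_Da, 1311.7, tolerance = 1e-9)
  expect_equal(tspd12$dar_display, 0.9)
  expect_equal(dar_from_mass(147836.9, 147836.9, 957.4)$dar, 0)
  expect_error(dar_from_mass(150000, 147836.9, -1), "per_drug_mass_Da")
})

test_that("dar_from_mass is linear in the conjugate mass", {
  base <- dar_from_mass(150000, 147836.9, 957.4)$dar
  for (delta in c(100, 957.4, 5000))
    expect_equal(dar_from_mass(150000 + delta, 147836.9, 957.4)$dar - base,
                 delta / 957.4, tolerance = 1e-12)
})

test_that("full spectral pipeline recovers the mean load", {
  # identical spectra give DAR 0
  p <- gen_ms_pair(0, kind = "fixed", seed = 1)
  same <- dar_from_spectrum(p$conjugate, p$conjugate, p$design)
  expect_lt(abs(same$dar), 0.02)

  # single-species load 2: DAR 2.00 +/- 0.05
  p2 <- gen_ms_pair(2, kind = "fixed", noise_frac = 0.01, seed = 2)
  expect_lt(abs(dar_from_spectrum(p2$conjugate, p2$reference,
                                  p2$design)$dar - 2), 0.05)

  # noiseless Poisson mixtures: within 2% relative for the stated lambdas
  for (lam in c(1, 2, 3.5, 6)) {
    p <- gen_ms_pair(lam, seed = NULL)
    got <- dar_from_spectrum(p$conjugate, p$reference, p$design)$dar
    expect_lt(abs(got - p$true_mean) / p$true_mean, 0.02)
  }

  # numeric reference (Table mode) agrees with spectral reference
  p3 <- gen_ms_pair(3.5, seed = 3)
  via_spec <- dar_from_spectrum(p3$conjugate, p3$reference, p3$design)$dar
  via_mass <- dar_from_spectrum(p3$conjugate, 147836.9, p3$design)$dar
  expect_lt(abs(via_spec - via_mass), 0.02)
})

test_that("DAR result JSON serializes the fields the report consumes", {
  res <- dar_from_mass(150832.2, 147836.9, 957.4)
  tmp <- tempfile(fileext = ".json")
  write_dar_json(res, tmp)
  j <- jsonlite::read_json(tmp)
  expect_equal(j$method, "intact_ms")
  expect_equal(j$dar, res$dar, tolerance = 1e-12)
})
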