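published_table <- function() {
  path <- system.file("extdata", "published_conjugates.csv",
                      package = "adcdar")
  read.csv(path, stringsAsFactors = FALSE)
}

test_that("the published conjugate masses give the published MS DAR column", {
  pub <- published_table()
  ref_mass <- pub$measured_mass_Da[pub$sample == "Trastuzumab"]
  conj <- pub[pub$sample != "Trastuzumab", ]
  results <- lapply(seq_len(nrow(conj)), function(i)
    list(ms = dar_from_mass(conj$measured_mass_Da[i], ref_mass,
                            conj$per_drug_mass_Da[i])))
  names(results) <- conj$sample
  tab <- build_dar_table(results,
                         reference = list(name = "Trastuzumab",
                                          mass_Da = ref_mass))
  expect_identical(tab$sample[1L], "Trastuzumab")
  expect_true(all(is.na(tab[1L, c("mass_shift_Da", "dar_ms", "dar_uv")])))
  expect_equal(round(tab$dar_ms[-1L], 1), c(3.1, 1.8, 3.4, 0.9))
  expect_equal(tab$mass_shift_Da[-1L], c(2995.3, 1740.8, 3533.1, 1311.7),
               tolerance = 1e-9)
})

test_that("partial and empty inputs build valid tables", {
  one <- build_dar_table(list(s1 = list(uv = dar_from_uv(0.6, PUB_EXT))))
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$dar_ms) && is.na(one$measured_mass_Da))
  expect_false(is.na(one$dar_uv))

  empty <- build_dar_table(list())
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("sample", "measured_mass_Da", "mass_shift_Da",
                     "per_drug_mass_Da", "dar_ms", "dar_uv"))

  expect_error(build_dar_table(list(a = list(ms = 1))), "aggregation")
  dup <- list(list(ms = dar_from_mass(150000, 147836.9, 957.4)),
              list(ms = dar_from_mass(150100, 147836.9, 957.4)))
  names(dup) <- c("s", "s")
  expect_error(build_dar_table(dup), "aggregation")
})

test_that("method agreement reproduces the printed-column differences", {
  pub <- published_table()
  conj <- pub[pub$sample != "Trastuzumab", ]
  dar_ms_printed <- c(3.1, 1.8, 3.4, 0.9)
  # construct results whose DARs equal the printed columns exactly
  results <- lapply(seq_len(nrow(conj)), function(i) list(
    ms = dar_from_mass(147836.9 + dar_ms_printed[i] *
                         conj$per_drug_mass_Da[i],
                       147836.9, conj$per_drug_mass_Da[i]),
    uv = dar_from_uv(forward_ratio(conj$dar_uv_published[i]), PUB_EXT)))
  names(results) <- conj$sample
  agree <- method_agreement(build_dar_table(results))
  expect_equal(agree$differences$difference, c(-0.2, -0.9, -0.6, -1.1),
               tolerance = 1e-6)
  expect_equal(agree$mean_abs_difference, 0.7, tolerance = 1e-6)

  # identical columns agree exactly; a lone complete row is its own summary
  same <- lapply(results, function(r)
    list(ms = r$ms, uv = dar_from_uv(forward_ratio(r$ms$dar), PUB_EXT)))
  expect_true(all(abs(method_agreement(build_dar_table(same))
                      $differences$difference) < 1e-9))
  lone <- build_dar_table(results[1L])
  expect_equal(method_agreement(lone)$mean_abs_difference, 0.2,
               tolerance = 1e-6)
  ms_only <- build_dar_table(lapply(results, function(r) list(ms = r$ms)))
  expect_warning(method_agreement(ms_only), "no rows")
})

test_that("machine CSV round-trips losslessly; display CSV is 1-decimal", {
  results <- list(
    Kadcyla = list(ms = dar_from_mass(150832.2, 147836.9, 957.4),
                   uv = dar_from_uv(0.729, PUB_EXT)))
  tab <- build_dar_table(results,
                         reference = list(name = "Trastuzumab",
                                          mass_Da = 147836.9))
  machine <- tempfile(fileext = ".csv")
  write_dar_table(tab, machine)
  back <- read_dar_table(machine)
  expect_equal(back$dar_ms, tab$dar_ms, tolerance = 1e-15)
  expect_equal(back$measured_mass_Da, tab$measured_mass_Da,
               tolerance = 1e-15)

  display <- tempfile(fileext = ".csv")
  write_dar_table(tab, display, display = TRUE)
  disp <- read.csv(display, colClasses = "character")
  expect_identical(disp$measured_mass_Da[2L], "150,832.2")
  expect_identical(disp$dar_ms[2L], "3.1")
  expect_identical(disp$mass_shift_Da[1L], "")
})
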