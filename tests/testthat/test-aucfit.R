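test_that("predict_sw hits its limits and the mid-occupancy arithmetic", {
  k <- two_site_params(21.5, 5990)
  expect_identical(predict_sw(0.61, 1.48, k, 50, 0), 0.61)
  # saturating titrant drives the occupancy fraction to 2
  expect_equal(predict_sw(0.61, 1.48, k, 50, 1e9), 0.61 + 2 * 1.48,
               tolerance = 1e-4)
  # occupancy fraction 0.5: one live site at S_free = Kd with no depletion
  theta <- predict_sw(0.61, 1.48, two_site_params(100, 1e12), 1e-9, 100)
  expect_equal(theta, 1.35, tolerance = 1e-6)
})

test_that("predict_sw is monotone nondecreasing in titrant", {
  k <- two_site_params(101, 8330)
  th <- predict_sw(0.61, 1.48, k, 50, default_titrant_grid(25))
  expect_true(all(diff(th) >= -1e-12))
})

test_that("integrate_sw recovers peak positions and matches fine-grid quadrature", {
  one <- gen_cs_distribution(data.frame(s = 1.45, area = 1, width = 0.04))
  expect_equal(integrate_sw(one$s_grid, one$c), 1.45, tolerance = 1e-4)

  two <- gen_cs_distribution(data.frame(s = c(1, 3), area = c(1, 1),
                                        width = c(0.05, 0.05)))
  expect_equal(integrate_sw(two$s_grid, two$c), 2.0, tolerance = 1e-6)

  # peak partially outside the window: compare against a fine-grid oracle
  peaks <- data.frame(s = c(0.4, 2.2), area = c(0.7, 1.3),
                      width = c(0.15, 0.3))
  d <- gen_cs_distribution(peaks, grid = seq(0, 5, by = 5e-4))
  expect_equal(integrate_sw(d$s_grid, d$c),
               oracle_sw_gaussians(peaks, 0.5, 4.0),
               tolerance = 1e-6)
})

test_that("integrate_sw reports a no-signal window distinctly", {
  d <- gen_cs_distribution(data.frame(s = 6, area = 1, width = 0.05),
                           grid = seq(0, 8, by = 0.01))
  expect_warning(sw <- integrate_sw(d$s_grid, d$c, 0.5, 4.0), "no signal")
  expect_true(is.na(sw))
  # grid entirely outside the window
  expect_warning(
    sw2 <- integrate_sw(seq(5, 8, by = 0.1), rep(1, 31), 0.5, 4.0),
    "does not overlap")
  expect_true(is.na(sw2))
})

test_that("noise-free isotherms refit to the generative constants", {
  for (kds in list(c(21.5, 5990), c(101, 8330))) {
    iso <- gen_sw_isotherm(0.61, 1.48, two_site_params(kds[1], kds[2]),
                           noise = noise_spec(0, 1))
    fit <- fit_sw_isotherm(iso)
    expect_lt(rel_err(fit$params$k$Kd1, kds[1]), 1e-4)
    expect_lt(rel_err(fit$params$k$Kd2, kds[2]), 1e-3)
  }
})

test_that("floating b recovers a non-default generative b", {
  iso <- gen_sw_isotherm(0.61, 1.04, two_site_params(101, 8330),
                         noise = noise_spec(0, 1))
  fit <- fit_sw_isotherm(iso, float_b = TRUE)
  expect_lt(rel_err(fit$params$b, 1.04), 1e-3)
  expect_true(fit$floated["b"])
  expect_false(is.na(fit$se$b))
})

test_that("a Kd driven to the search bound is flagged and labelled '>'", {
  # site 2 effectively dead: Kd2 runs to the upper bound
  iso <- gen_sw_isotherm(0.61, 1.48, two_site_params(50, 1e9),
                         noise = noise_spec(0, 2))
  fit <- fit_sw_isotherm(iso)
  expect_true(fit$at_bound["kd2"])
  expect_match(fit$kd_labels[["kd2"]], "^> ")
  # Kd2 truncates at the search bound, leaving a small residual bias in Kd1
  expect_lt(rel_err(fit$params$k$Kd1, 50), 5e-3)
})

test_that("noise-free parameter recovery holds across random draws", {
  set.seed(404)
  for (i in 1:6) {
    kd1 <- 10^runif(1, 0.5, 2.5)
    kd2 <- kd1 * 10^runif(1, 0.5, 2)
    iso <- gen_sw_isotherm(0.61, 1.48, two_site_params(kd1, kd2),
                           noise = noise_spec(0, i))
    fit <- fit_sw_isotherm(iso)
    expect_lt(rel_err(fit$params$k$Kd1, kd1), 1e-3)
    expect_lt(rel_err(fit$params$k$Kd2, kd2), 1e-2)
  }
})

test_that("Kd1 recovery error grows with noise in expectation", {
  rmse <- vapply(c(0.005, 0.08), function(sd) {
    errs <- vapply(1:4, function(s) {
      r <- recover_sw_isotherm(21.5, 5990, sd = sd, seed = 500 + s)
      rel_err(r$Kd1, 21.5)
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_lt(rmse[1], rmse[2])
})

test_that("isotherm CSV round-trips through the reader/writer", {
  iso <- gen_sw_isotherm(0.61, 1.48, two_site_params(21.5, 5990),
                         noise = noise_spec(0.01, 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sw_isotherm(iso, path)
  back <- read_sw_isotherm(path, peptide_total = 50)
  expect_equal(back$titrant_total, iso$titrant_total)
  expect_equal(back$sw, iso$sw)
  expect_error(read_sw_isotherm(path, peptide_total = 0), "positive")
})

test_that("underdetermined isotherms are rejected", {
  iso <- sw_isotherm(c(1, 10, 100), c(0.7, 1.0, 1.5), 50)
  expect_error(fit_sw_isotherm(iso), ">= 4 points")
})
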