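make_series <- function(Kd, dbound, P = 100, ratios = default_ratio_grid(3),
                        id = 1L, phi = 0.7, sd = 0, seed = 1) {
  L <- ratios * P
  fb <- solve_single_site(P, L, Kd) / P
  set.seed(seed)
  titration_series(
    residue_id = id, L_total = L,
    dH = 8 + dbound * cos(phi) * fb + rnorm(length(L), 0, sd),
    dN = 118 + 5 * dbound * sin(phi) * fb + rnorm(length(L), 0, 5 * sd),
    P_total = P)
}

test_that("CSP equation evaluates the 1H/15N combination with the 5x nitrogen scale", {
  s <- titration_series(1L, c(0, 50, 100),
                        dH = c(8, 8, 8.03), dN = c(118, 118.5, 118.15),
                        P_total = 100)
  rec <- compute_csp(s)
  expect_identical(rec$csp[1], 0)
  expect_equal(rec$csp[2], 0.1, tolerance = 1e-12)          # 0.5 / 5
  expect_equal(rec$csp[3], sqrt(0.03^2 + 0.03^2), tolerance = 1e-12)
  expect_equal(rec$endpoint_csp, 0.0424264069, tolerance = 1e-8)
})

test_that("CSP is invariant to uniform referencing offsets", {
  s <- make_series(50, 0.2)
  shifted <- titration_series(1L, s$L_total, s$dH + 0.37, s$dN - 1.2,
                              P_total = s$P_total)
  expect_equal(compute_csp(shifted)$csp, compute_csp(s)$csp,
               tolerance = 1e-12)
})

test_that("broadened points carry no CSP and the reference is required", {
  s <- make_series(50, 0.2)
  s$broadened[3] <- TRUE
  rec <- compute_csp(s)
  expect_true(is.na(rec$csp[3]))
  expect_error(titration_series(1L, c(10, 20), c(8, 8), c(118, 118), 100),
               "apo reference")
})

test_that("noise-free residue fits recover Kd and delta_bound", {
  s <- make_series(50, 0.2)
  fit <- fit_residue_kd(s)
  expect_true(fit$ok)
  expect_lt(rel_err(fit$Kd, 50), 1e-3)
  expect_lt(rel_err(fit$delta_bound, 0.2), 1e-3)
})

test_that("flat titrations yield a failure record, not a Kd", {
  s <- titration_series(1L, c(0, 50, 100, 200, 300),
                        dH = rep(8, 5), dN = rep(118, 5), P_total = 100)
  fit <- fit_residue_kd(s)
  expect_false(fit$ok)
  expect_match(fit$reason, "no perturbation")
  expect_true(is.na(fit$Kd))
})

test_that("stoichiometric-regime fits pin delta_bound at the endpoint CSP", {
  s <- make_series(0.05, 0.3)  # Kd << P_total: titration is nearly linear
  fit <- fit_residue_kd(s)
  rec <- compute_csp(s)
  expect_true(fit$ok)
  expect_lt(abs(fit$delta_bound - rec$endpoint_csp) / rec$endpoint_csp, 0.01)
})

test_that("aggregation averages threshold-passing residues with population SD", {
  mk_fit <- function(id, kd, ok = TRUE) {
    structure(list(residue_id = id, residue_name = NA, ok = ok, Kd = kd,
                   delta_bound = 0.2, se_Kd = 1, se_delta_bound = 0.01,
                   rss = 0, n = 10L,
                   reason = if (ok) NA_character_ else "synthetic failure"),
              class = "residue_fit")
  }
  mk_csp <- function(id, ep) {
    structure(list(residue_id = id, residue_name = NA, L_total = 0:3,
                   csp = rep(ep, 4), endpoint_csp = ep,
                   broadened = rep(FALSE, 4)),
              class = "csp_record")
  }
  same <- aggregate_kd(lapply(1:3, mk_fit, kd = 10),
                       lapply(1:3, mk_csp, ep = 0.1))
  expect_equal(same$mean_Kd, 10)
  expect_equal(same$sd_Kd, 0)

  agg <- aggregate_kd(list(mk_fit(1L, 5), mk_fit(2L, 10), mk_fit(3L, 15),
                           mk_fit(4L, 99), mk_fit(5L, 77, ok = FALSE)),
                      list(mk_csp(1L, 0.1), mk_csp(2L, 0.2), mk_csp(3L, 0.3),
                           mk_csp(4L, 0.02), mk_csp(5L, 0.2)))
  expect_equal(agg$mean_Kd, 10)
  expect_equal(agg$sd_Kd, sqrt(50 / 3), tolerance = 1e-9)  # ~4.082
  expect_identical(agg$n, 3L)
  expect_identical(sort(agg$contributing), 1:3)
  expect_identical(nrow(agg$exclusions), 2L)
  expect_match(agg$exclusions$reason[agg$exclusions$residue_id == 4L],
               "threshold")
  expect_match(agg$exclusions$reason[agg$exclusions$residue_id == 5L],
               "fit failed")
  # bounded by the contributing extremes
  expect_gte(agg$mean_Kd, 5)
  expect_lte(agg$mean_Kd, 15)

  empty <- aggregate_kd(list(mk_fit(1L, 5)), list(mk_csp(1L, 0.001)))
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mean_Kd))
})

test_that("endpoint CSPs classify at the 0.03/0.1 ppm thresholds", {
  expect_identical(classify_csp(0.2), "strong")
  expect_identical(classify_csp(0.05), "moderate")
  expect_identical(classify_csp(0.01), "none")
  expect_identical(classify_csp(0.03), "none")    # strict inequality
  expect_identical(classify_csp(0.1), "moderate") # strict inequality
  expect_identical(classify_csp(0.5, broadened = TRUE), "broadened")
  expect_identical(classify_csp(NA_real_, broadened = TRUE), "broadened")
  expect_identical(classify_csp(c(0.2, 0.05, 0.01), c(FALSE, TRUE, FALSE)),
                   c("strong", "broadened", "none"))
})

test_that("assignment completeness reports exact and rounded percentages", {
  expect_identical(assignment_completeness(154, 162)$rounded, 95)
  expect_identical(assignment_completeness(141, 151)$rounded, 93)
  expect_identical(assignment_completeness(0, 100)$percent, 0)
  expect_equal(assignment_completeness(154, 162)$percent, 15400 / 162)
  expect_error(assignment_completeness(1, 0), "positive")
  expect_error(assignment_completeness(5, 4), "assigned")
})

test_that("per-residue Kd recovery is accurate and unbiased across 100 simulated residues", {
  series <- gen_hsqc_titration(100L, Kd = 50, P_total = 100,
                               ratios = default_ratio_grid(3),
                               noise = noise_spec(0.002, 42))
  fits <- lapply(series, fit_residue_kd)
  kds <- vapply(fits[vapply(fits, `[[`, logical(1), "ok")], `[[`,
                numeric(1), "Kd")
  # with noise on both the apo and bound spectra the per-residue median
  # relative error sits near 7%; the residue-averaged estimate is much tighter
  expect_lt(stats::median(rel_err(kds, 50)), 0.10)
  expect_lt(rel_err(mean(kds), 50), 0.03)
})

test_that("peak-table CSVs round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  series <- gen_hsqc_titration(4L, Kd = 40, noise = noise_spec(0.001, 5))
  L <- series[[1]]$L_total
  files <- sprintf("point%02d.csv", seq_along(L))
  for (j in seq_along(L)) {
    tab <- data.frame(
      residue_id = vapply(series, `[[`, integer(1), "residue_id"),
      residue_name = "X",
      dH_ppm = vapply(series, function(s) s$dH[j], numeric(1)),
      dN_ppm = vapply(series, function(s) s$dN[j], numeric(1)),
      broadened = 0L)
    utils::write.csv(tab, file.path(dir, files[j]), row.names = FALSE)
  }
  utils::write.csv(data.frame(file = files, L_total_uM = L),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  back <- read_titration_set(file.path(dir, "manifest.csv"), P_total = 100)
  expect_length(back, 4L)
  expect_equal(back[[2]]$dH, series[[2]]$dH, tolerance = 1e-9)
  fit_direct <- fit_residue_kd(series[[1]])
  fit_csv <- fit_residue_kd(back[[1]])
  expect_equal(fit_csv$Kd, fit_direct$Kd, tolerance = 1e-6)
})
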