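test_that("standard curves fit exactly on collinear points and flag degeneracy", {
  cur <- fit_standard_curve(
    data.frame(concentration = c(0, 1, 5, 10), response = c(0, 2, 10, 20)),
    analyte = "8oxoG"
  )
  expect_equal(cur$slope, 2)
  expect_equal(cur$intercept, 0)
  expect_equal(cur$r_squared, 1)
  expect_true(cur$usable)
  expect_equal(glance(cur)$n_points, 4)

  flat <- fit_standard_curve(
    data.frame(concentration = c(0, 10), response = c(1, 1)), "G")
  expect_false(flat$usable)
  expect_error(
    fit_standard_curve(data.frame(concentration = c(5, 5), response = c(1, 2))),
    "distinct concentrations"
  )
  expect_s3_class(autoplot(cur), "ggplot")
})

test_that("noisy calibration recovers the slope within the closed-form OLS bound", {
  conc <- c(0, 1, 5, 10, 25, 50)
  sigma <- 0.5
  sd_slope <- sigma / sqrt(sum((conc - mean(conc))^2))  # closed-form OLS sd
  slopes <- withr::with_seed(101, {
    vapply(1:100, function(i) {
      resp <- 3 * conc + 1 + rnorm(length(conc), 0, sigma)
      fit_standard_curve(data.frame(concentration = conc, response = resp))$slope
    }, numeric(1))
  })
  expect_true(all(abs(slopes - 3) < 4 * sd_slope))
  expect_lt(abs(mean(slopes) - 3), 4 * sd_slope / sqrt(100))
  expect_lt(abs(sd(slopes) / sd_slope - 1), 0.5)
})

test_that("8-oxoG/G quantification handles units, blanks and scaling", {
  conc <- c(0, 1, 5, 10, 25, 50)
  cur8 <- fit_standard_curve(
    data.frame(concentration = conc, response = 2 * conc), "8oxoG")
  curG <- fit_standard_curve(
    data.frame(concentration = conc, response = 3 * conc), "G")

  # hand unit-conversion arithmetic: 10 ng/mL over 10 ug/mL
  res <- quantify_oxog_ratio(20, 30, cur8, curG)
  expect_equal(res$conc_8oxoG_ng_ml, 10)
  expect_equal(res$conc_G_ug_ml, 10)
  expect_equal(res$ratio_per_1e5_G,
               (10e-9 / 299.2) / (10e-6 / 283.2) * 1e5, tolerance = 1e-12)
  expect_equal(res$ratio_per_1e5_G, 94.652, tolerance = 1e-4)

  # blank responses give zero ratio
  expect_equal(quantify_oxog_ratio(0, 0, cur8, curG)$ratio_per_1e5_G, 0)

  # doubling both responses on zero-intercept curves leaves the ratio unchanged
  doubled <- suppressWarnings(quantify_oxog_ratio(40, 60, cur8, curG))
  expect_equal(doubled$ratio_per_1e5_G, res$ratio_per_1e5_G)

  # below-blank responses clamp to zero with a warning
  with_int <- fit_standard_curve(
    data.frame(concentration = conc, response = 2 * conc + 5), "8oxoG")
  w <- testthat::capture_warnings(out <- quantify_oxog_ratio(1, 30, with_int, curG))
  expect_match(w, "clamped", all = FALSE)
  expect_equal(out$conc_8oxoG_ng_ml, 0)
  expect_true(out$clamped)
  # out-of-range responses warn
  expect_warning(quantify_oxog_ratio(500, 30, cur8, curG), "calibrated range")
})

test_that("transcript oxidation reproduces the Poisson arithmetic", {
  est <- transcript_oxidation(20e-5, 1500, 0.25)
  expect_equal(est$lambda_events, 0.075)
  expect_equal(est$pct_transcripts_linear, 7.5)
  expect_equal(est$p_any, 1 - exp(-0.075))
  expect_equal(est$p_any, 0.0723, tolerance = 1e-3)
  expect_equal(est$competence, exp(-0.075))
  expect_equal(est$p_any + est$competence, 1)

  # per-residue interpretation applies the rate to every nucleotide
  expect_equal(transcript_oxidation(20e-5, 1500, per = "residue")$lambda_events, 0.3)

  null <- transcript_oxidation(0)
  expect_equal(null$lambda_events, 0)
  expect_equal(null$p_any, 0)
  expect_equal(null$competence, 1)

  # partial per-event attenuation relaxes the full-block competence
  soft <- transcript_oxidation(20e-5, attenuation_per_event = 0.5)
  expect_equal(soft$competence, exp(-0.075 * 0.5))
})

test_that("p_any matches a Bernoulli-site simulation oracle", {
  cases <- list(c(20e-5, 1500, 0.25), c(5e-3, 1000, 0.3), c(1e-3, 3000, 0.25))
  withr::with_seed(77, {
    for (cs in cases) {
      n_sites <- round(cs[2] * cs[3])
      events <- stats::rbinom(1e5, size = n_sites, prob = cs[1])
      sim_p <- mean(events > 0)
      se <- sqrt(sim_p * (1 - sim_p) / 1e5)
      est <- transcript_oxidation(cs[1], cs[2], cs[3])
      expect_lt(abs(est$p_any - sim_p), 3 * se + 1e-4)
    }
  })
})

test_that("oxidation load is monotone and linearly bounded", {
  grid <- expand.grid(r = c(1e-5, 1e-4, 1e-3), L = c(500, 1500, 3000),
                      g = c(0.2, 0.25, 0.4))
  p <- purrr::pmap_dbl(grid, function(r, L, g) {
    transcript_oxidation(r, L, g)$p_any
  })
  lam <- purrr::pmap_dbl(grid, function(r, L, g) {
    transcript_oxidation(r, L, g)$lambda_events
  })
  # p_any <= lambda with equality only at zero
  expect_true(all(p <= lam))
  expect_true(all(p < lam | lam == 0))
  # strictly increasing in each argument
  expect_true(all(diff(sapply(c(1e-5, 1e-4, 1e-3), function(r)
    transcript_oxidation(r, 1500, 0.25)$p_any)) > 0))
  expect_true(all(diff(sapply(c(500, 1500, 3000), function(L)
    transcript_oxidation(1e-4, L, 0.25)$p_any)) > 0))
  expect_true(all(diff(sapply(c(0.2, 0.3, 0.4), function(g)
    transcript_oxidation(1e-4, 1500, g)$competence)) < 0))
  # small-lambda linear approximation bound
  est <- transcript_oxidation(20e-5, 1500, 0.25)
  expect_lte(abs(est$p_any - est$lambda_events), est$lambda_events^2 / 2)
})
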