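test_that("reference simulation is reproducible with exact induced allocation", {
  a <- simulate_reference_profile(n_genes = 2000, seed = 42)
  b <- simulate_reference_profile(n_genes = 2000, seed = 42)
  expect_identical(as.data.frame(a$profile), as.data.frame(b$profile))
  expect_identical(a$induced, b$induced)
  c <- simulate_reference_profile(n_genes = 2000, seed = 43)
  expect_false(identical(as.data.frame(a$profile), as.data.frame(c$profile)))

  sim <- simulate_reference_profile(n_genes = 10000, frac_induced = 0.1, seed = 1)
  expect_length(sim$induced, 1000)
  expect_length(sim$background, 9000)
  expect_equal(nrow(sim$profile), 10000)

  # induced genes are positive at the Gaussian tail rate Phi(mean/sd) = Phi(4)
  induced_fc <- sim$profile$log2fc[sim$profile$gene_id %in% sim$induced]
  expect_gte(mean(induced_fc > 0), 0.999)
  # background signs exactly balanced by construction
  bg_fc <- sim$profile$log2fc[sim$profile$gene_id %in% sim$background]
  expect_equal(sum(bg_fc > 0), sum(bg_fc < 0))
})

test_that("query mixtures yield the closed-form expected TAI", {
  sim <- simulate_reference_profile(n_genes = 10000, seed = 8)

  # f = 1: TAI ~ induced positive rate (~1 for strong effects)
  q1 <- simulate_query_set(sim, n_up = 500, mixing_fraction = 1, seed = 1)
  expect_gte(compute_tai(q1, sim$profile)$tai, 0.99)
  expect_equal(attr(q1, "true_f"), 1)

  # f = 0: sign-symmetric background, TAI ~ 0.5
  tais0 <- vapply(1:20, function(s) {
    q <- simulate_query_set(sim, n_up = 500, mixing_fraction = 0, seed = s)
    compute_tai(q, sim$profile)$tai
  }, numeric(1))
  expect_lt(abs(mean(tais0) - 0.5), 0.02)

  # f = 0.5: mean TAI ~ f + (1 - f) / 2 = 0.75
  tais5 <- vapply(1:50, function(s) {
    q <- simulate_query_set(sim, n_up = 1000, mixing_fraction = 0.5, seed = s)
    compute_tai(q, sim$profile)$tai
  }, numeric(1))
  expect_lt(abs(mean(tais5) - 0.75), 0.01)

  expect_error(simulate_query_set(sim, n_up = 5000, mixing_fraction = 1),
               "pools")
  same <- simulate_query_set(sim, n_up = 100, mixing_fraction = 0.3, seed = 9)
  again <- simulate_query_set(sim, n_up = 100, mixing_fraction = 0.3, seed = 9)
  expect_identical(same$gene_id, again$gene_id)
})

test_that("mixing-fraction recovery inverts the two-component model", {
  expect_equal(recover_mixing_fraction(0.75), 0.5)
  expect_equal(recover_mixing_fraction(0.5), 0)
  expect_equal(recover_mixing_fraction(1.0), 1)
  # clipping
  expect_equal(recover_mixing_fraction(0.4), 0)
  expect_equal(recover_mixing_fraction(1.2), 1)
  # custom rates
  expect_equal(recover_mixing_fraction(0.6, 0.4, 0.9), 0.4, tolerance = 1e-12)
  expect_error(recover_mixing_fraction(0.5, 0.7, 0.7), "must differ")
})

test_that("mechanistic derepression follows the repressor-decay model", {
  # no oxidation: competence 1, every true fold change is 0
  null <- simulate_mechanistic_derepression(n_genes = 200, lambda_events = 0,
                                            seed = 4)
  expect_true(all(sim_ground_truth(null)$true_log2fc == 0))

  # long exposure: fold change approaches -h*log2(c) for every half-life
  lam <- 0.3
  long <- simulate_mechanistic_derepression(n_genes = 200, lambda_events = lam,
                                            exposure_time = 1e6, seed = 4)
  expect_equal(sim_ground_truth(long)$true_log2fc,
               rep(-log2(exp(-lam)), 200), tolerance = 1e-6)

  # at fixed time and positive load, true fold change is strictly
  # decreasing in repressor half-life
  m <- simulate_mechanistic_derepression(n_genes = 500, lambda_events = 0.2,
                                         seed = 4)
  gt <- sim_ground_truth(m)
  expect_true(all(diff(gt$half_life) > 0))
  expect_true(all(diff(gt$true_log2fc) < 0))

  # hill exponent scales the response
  m2 <- simulate_mechanistic_derepression(n_genes = 500, lambda_events = 0.2,
                                          hill_h = 2, seed = 4)
  expect_equal(sim_ground_truth(m2)$true_log2fc, 2 * gt$true_log2fc)

  # reproducibility and p-value validity
  m3 <- simulate_mechanistic_derepression(n_genes = 500, lambda_events = 0.2,
                                          seed = 4)
  expect_identical(as.data.frame(m), as.data.frame(m3))
  expect_true(all(m$p_value >= 0 & m$p_value <= 1))
  expect_true(all(m$adj_p >= m$p_value))

  # p-values are monotone in |log2fc| when undisturbed
  ord <- order(abs(m$log2fc), decreasing = TRUE)
  expect_true(all(diff(m$p_value[ord]) >= 0))
})

test_that("gene to half-life assignment is stable across oxidation loads", {
  lo <- simulate_mechanistic_derepression(n_genes = 300, lambda_events = 0.05,
                                          seed = 1)
  hi <- simulate_mechanistic_derepression(n_genes = 300, lambda_events = 1,
                                          seed = 2)
  expect_identical(sim_ground_truth(lo)$half_life, sim_ground_truth(hi)$half_life)
  expect_identical(lo$gene_id, hi$gene_id)
})
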