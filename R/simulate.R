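#' Simulate a translational-arrest reference transcriptome
#'
#' Generates a reference profile emulating a cycloheximide-like arrest
#' transcriptome with known ground truth: a fraction of genes is truly
#' induced (log2 fold changes drawn from a positive-mean Gaussian, small
#' p-values), while the remaining background genes carry noise fold changes
#' whose signs are exactly balanced by construction — half positive, half
#' negative — so that the TAI of a random background query is 0.5 in
#' expectation, analytically.
#'
#' @param n_genes Number of genes (default 10000).
#' @param frac_induced Fraction of genes truly induced (default 0.1); the
#'   induced count is `round(frac_induced * n_genes)`, exactly.
#' @param effect_mean,effect_sd Mean and sd of induced genes' log2 fold
#'   changes (defaults 2 and 0.5; with these, essentially every induced gene
#'   is positive).
#' @param noise_sd Sd of background log2 fold-change magnitudes (default 0.5).
#' @param seed Integer seed; the profile is bit-reproducible given
#'   `(config, seed)`.
#' @param condition_label Label for the profile (default `"sim_reference"`).
#' @return A list of class `sim_reference`: `profile` (a [de_profile()]),
#'   `induced` / `background` (gene identifier vectors — the ground truth),
#'   and `config`.
#' @export
simulate_reference_profile <- function(n_genes = 10000, frac_induced = 0.1,
                                       effect_mean = 2, effect_sd = 0.5,
                                       noise_sd = 0.5, seed = 1,
                                       condition_label = "sim_reference") {
  stopifnot(n_genes >= 10)
  if (!(frac_induced > 0 && frac_induced < 1)) {
    abort_data("frac_induced must lie in (0, 1)")
  }
  if (effect_mean <= 0 || effect_sd <= 0 || noise_sd <= 0) {
    abort_data("effect_mean, effect_sd and noise_sd must be positive")
  }
  n_induced <- round(frac_induced * n_genes)
  gene_id <- sprintf("SIMG%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    induced_idx <- sample(n_genes, n_induced)
    log2fc <- numeric(n_genes)
    log2fc[induced_idx] <- rnorm(n_induced, effect_mean, effect_sd)
    n_bg <- n_genes - n_induced
    # exactly sign-balanced background: half +, half - (odd leftover random)
    signs <- sample(rep(c(1, -1), length.out = n_bg))
    log2fc[-induced_idx] <- signs * abs(rnorm(n_bg, 0, noise_sd))
    p_value <- numeric(n_genes)
    p_value[induced_idx] <- pmin(rbeta(n_induced, 0.5, 20), 1)
    p_value[-induced_idx] <- runif(n_bg)
  })
  profile <- de_profile(
    tibble(gene_id = gene_id, log2fc = log2fc, p_value = p_value,
           adj_p = bh_adjust(p_value)),
    condition_label = condition_label,
    source_note = sprintf(
      "synthetic arrest reference (n=%d, frac_induced=%g, seed=%d)",
      n_genes, frac_induced, seed),
    normalize = FALSE
  )
  list2_class(
    list(profile = profile,
         induced = gene_id[sort(induced_idx)],
         background = gene_id[-sort(induced_idx)],
         config = list(n_genes = n_genes, frac_induced = frac_induced,
                       effect_mean = effect_mean, effect_sd = effect_sd,
                       noise_sd = noise_sd, seed = seed)),
    "sim_reference"
  )
}

list2_class <- function(x, cls) structure(x, class = cls)

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("Synthetic reference: %d genes, %d induced (seed %d)\n",
              x$config$n_genes, length(x$induced), x$config$seed))
  invisible(x)
}

#' Simulate a query up-regulated gene set with known mixing fraction
#'
#' Draws an up-regulated query set as a mixture: `round(f * n_up)` genes from
#' the reference's truly-induced pool (the "cytosolic-arrest-like" share) and
#' the remainder from the sign-symmetric background, both without
#' replacement. Because induced genes are essentially all positive in the
#' reference and background signs are balanced, the expected TAI of such a
#' query is `f + (1 - f) / 2`.
#'
#' @param reference_sim A `sim_reference` from
#'   [simulate_reference_profile()].
#' @param n_up Query size (default 1000).
#' @param mixing_fraction Ground-truth fraction `f` in `[0, 1]` drawn from
#'   the induced pool (default 0.5).
#' @param seed Integer seed.
#' @param label Set label.
#' @return A `gene_set` (direction `"up"`) with attribute `true_f`.
#' @export
simulate_query_set <- function(reference_sim, n_up = 1000,
                               mixing_fraction = 0.5, seed = 1,
                               label = "sim_query") {
  stopifnot(inherits(reference_sim, "sim_reference"))
  if (!(mixing_fraction >= 0 && mixing_fraction <= 1)) {
    abort_data("mixing_fraction must lie in [0, 1]")
  }
  n_induced_draw <- round(mixing_fraction * n_up)
  n_bg_draw <- n_up - n_induced_draw
  if (n_induced_draw > length(reference_sim$induced) ||
      n_bg_draw > length(reference_sim$background)) {
    abort_data("query size exceeds the available simulation pools")
  }
  withr::with_seed(seed, {
    picked <- c(
      sample(reference_sim$induced, n_induced_draw),
      sample(reference_sim$background, n_bg_draw)
    )
  })
  out <- gene_set(picked, label = label, direction = "up",
                  selection = list(simulated = TRUE,
                                   mixing_fraction = mixing_fraction,
                                   seed = seed),
                  parent_size = reference_sim$config$n_genes,
                  normalize = FALSE)
  attr(out, "true_f") <- mixing_fraction
  out
}

#' Invert the TAI mixing model to recover the mixing fraction
#'
#' Under the two-component model `TAI = f * q1 + (1 - f) * q0`, where `q1` is
#' the positive-sign rate of reference-induced genes and `q0` that of
#' background genes, the mixing fraction is recovered as
#' `(tai - q0) / (q1 - q0)`, clipped to `[0, 1]`.
#'
#' @param tai Observed TAI value(s).
#' @param background_positive_rate `q0`, default 0.5 (sign-symmetric
#'   background).
#' @param induced_positive_rate `q1`, default 1.
#' @return Estimated mixing fraction(s) in `[0, 1]`.
#' @export
recover_mixing_fraction <- function(tai, background_positive_rate = 0.5,
                                    induced_positive_rate = 1.0) {
  if (induced_positive_rate == background_positive_rate) {
    abort_data("induced and background positive rates must differ")
  }
  f_hat <- (tai - background_positive_rate) /
    (induced_positive_rate - background_positive_rate)
  pmin(pmax(f_hat, 0), 1)
}

#' Simulate derepression driven by oxidative translational attenuation
#'
#' Mechanistic generator for the cytosolic branch of the singlet-oxygen
#' response: RNA oxidation attenuates translation, short-lived repressor
#' proteins decay and are not replenished, and the genes they control are
#' derepressed. Each gene `i` is assigned a repressor half-life on a
#' log-spaced grid over `half_life_range` (the equally-spaced quantiles of a
#' log-uniform law, so the gene -> half-life map is identical across runs with
#' the same `n_genes` and range and a panel can be scored against a reference
#' generated at a different oxidation load). With decay rate
#' `k = ln(2) / halflife` and translational competence
#' `c = exp(-lambda_events)`, the repressor level relative to baseline after
#' `exposure_time` hours is
#' \deqn{\rho_i = c + (1 - c) e^{-k_i t}}
#' and the reported log2 fold change of the target gene is
#' `-hill_h * log2(rho_i)` plus Gaussian noise (`fc_noise_sd`). P-values are
#' Wald-type, monotone in `|log2fc|`, with optional log-scale noise
#' (`p_noise_sd`); adjusted p-values are added by [bh_adjust()].
#'
#' With no oxidation (`lambda_events = 0`) every true fold change is 0; as
#' `exposure_time` grows, every gene's fold change approaches
#' `-hill_h * log2(c)` regardless of half-life; at fixed time and positive
#' load, fold change is strictly decreasing in repressor half-life.
#'
#' @param n_genes Number of genes (default 2000).
#' @param half_life_range Min/max repressor half-lives in hours (default
#'   `c(0.25, 24)`).
#' @param lambda_events Oxidation load per repressor transcript (expected
#'   events; see [transcript_oxidation()]).
#' @param exposure_time Exposure time in hours (default 6).
#' @param hill_h Derepression exponent (default 1).
#' @param fc_noise_sd Gaussian noise sd on reported log2 fold changes
#'   (default 0.4, a realistic replicate-level sd for DE estimates).
#' @param p_noise_sd Sd of log-scale noise on reported p-values (default 0).
#' @param seed Integer seed.
#' @param condition_label Label for the profile.
#' @return A [de_profile()] with attribute `ground_truth`: a tibble with
#'   `gene_id`, `half_life`, `true_log2fc`, `competence`.
#' @export
simulate_mechanistic_derepression <- function(n_genes = 2000,
                                              half_life_range = c(0.25, 24),
                                              lambda_events = 0.1,
                                              exposure_time = 6,
                                              hill_h = 1,
                                              fc_noise_sd = 0.4,
                                              p_noise_sd = 0,
                                              seed = 1,
                                              condition_label = "sim_mechanistic") {
  stopifnot(length(half_life_range) == 2)
  if (any(half_life_range <= 0)) abort_data("half-lives must be positive")
  if (lambda_events < 0) abort_data("lambda_events must be >= 0")
  if (exposure_time < 0) abort_data("exposure_time must be >= 0")
  if (fc_noise_sd <= 0) abort_data("fc_noise_sd must be positive")

  gene_id <- sprintf("SIMG%05d", seq_len(n_genes))
  half_life <- exp(seq(log(half_life_range[[1]]), log(half_life_range[[2]]),
                       length.out = n_genes))
  k <- log(2) / half_life
  competence <- exp(-lambda_events)
  rho <- competence + (1 - competence) * exp(-k * exposure_time)
  true_fc <- -hill_h * log2(rho)
  withr::with_seed(seed, {
    log2fc <- true_fc + rnorm(n_genes, 0, fc_noise_sd)
    p_value <- 2 * pnorm(-abs(log2fc) / fc_noise_sd)
    if (p_noise_sd > 0) {
      p_value <- pmin(exp(log(p_value) + rnorm(n_genes, 0, p_noise_sd)), 1)
    }
  })
  profile <- de_profile(
    tibble(gene_id = gene_id, log2fc = log2fc, p_value = p_value,
           adj_p = bh_adjust(p_value)),
    condition_label = condition_label,
    source_note = sprintf(
      "mechanistic derepression simulation (lambda=%g, t=%gh, seed=%d); model is this package's own",
      lambda_events, exposure_time, seed),
    normalize = FALSE
  )
  attr(profile, "ground_truth") <- tibble(
    gene_id = gene_id, half_life = half_life, true_log2fc = true_fc,
    competence = competence
  )
  attr(profile, "sim_config") <- list(
    n_genes = n_genes, half_life_range = half_life_range,
    lambda_events = lambda_events, exposure_time = exposure_time,
    hill_h = hill_h, fc_noise_sd = fc_noise_sd, p_noise_sd = p_noise_sd,
    seed = seed
  )
  profile
}

#' Ground truth attached to a simulated profile
#'
#' @param x A profile from [simulate_mechanistic_derepression()].
#' @return Tibble of ground-truth values, or `NULL` if none attached.
#' @export
sim_ground_truth <- function(x) attr(x, "ground_truth")
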