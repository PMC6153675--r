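test_that("Langevin coefficient reflects averaged fluxes only", {
  sp <- spec_high_mean()
  expect_equal(langevin_b(sp, 12.5), 25)          # 2 nu3 v* at equilibrium
  expect_equal(langevin_b(sp, 0), 12.5)           # pure production at v = 0
  # strict under-coverage whenever gene and mRNA noise are present
  set.seed(31)
  for (i in 1:60) {
    mode <- c("neutral", "negative", "positive")[1 + i %% 3]
    sp_i <- random_spec(mode)
    v <- equilibrium(sp_i)$v_star
    if (v <= 0) next
    expect_lt(langevin_b(sp_i, v), diffusion_c(sp_i, v))
  }
})

test_that("diffusion coefficient has the stated limits and matched invariance", {
  sp <- spec_high_mean()
  expect_equal(diffusion_c(sp, 12.5), 2 * 12.5 * (1 + 5 + 30 / 144))
  m <- matched_specs(sp)
  expect_equal(diffusion_c(m$negative, 12.5), diffusion_c(sp, 12.5),
               tolerance = 1e-14)
  expect_equal(diffusion_c(m$positive, 12.5), diffusion_c(sp, 12.5),
               tolerance = 1e-14)
  # no transcription: only death noise remains
  dead <- model_spec("neutral", kappa1_plus = 1, kappa1_minus = 1,
                     kappa2 = 0, nu2 = 1, kappa3 = 5, nu3 = 2)
  expect_equal(diffusion_c(dead, 3), 2 * 3)
  # matched triplets share c(v*) across a random sweep
  set.seed(32)
  for (i in 1:50) {
    sp_i <- random_spec("neutral")
    v <- equilibrium(sp_i)$v_star
    m_i <- matched_specs(sp_i)
    cc <- diffusion_c(sp_i, v)
    expect_equal(diffusion_c(m_i$negative, v), cc, tolerance = 1e-12)
    expect_equal(diffusion_c(m_i$positive, v), cc, tolerance = 1e-12)
  }
})

test_that("drift derivative at equilibrium encodes the feedback denominator", {
  sp <- spec_high_mean()
  m <- matched_specs(sp)
  expect_equal(drift_deriv(sp, 12.5), -1)
  expect_equal(drift_deriv(m$negative, 12.5), -7 / 6)  # 1 + 2/12 faster
  expect_equal(drift_deriv(m$positive, 12.5), -5 / 6)  # 1 - 2/12 slower
})

test_that("equilibrium Fano factors match the closed forms and each other", {
  sp <- spec_high_mean()
  m <- matched_specs(sp)
  f0 <- fano_equilibrium(sp)
  expect_equal(f0$fano, 1 + 5 + 30 / 144)
  expect_equal(f0$decomposition$mrna_term, 5)
  expect_equal(f0$decomposition$gene_term, 30 / 144)
  expect_equal(f0$decomposition$feedback_denominator, 1)
  expect_equal(fano_equilibrium(m$negative)$fano, f0$fano * 6 / 7)
  expect_equal(fano_equilibrium(m$positive)$fano, f0$fano * 6 / 5)
  expect_equal(fano_equilibrium(spec_low_mean())$fano, 1.45)
  expect_error(fano_equilibrium(
    model_spec("positive", kappa1_oplus = 0.01, kappa1_minus = 10,
               kappa2 = 1, nu2 = 1, kappa3 = 1, nu3 = 1)),
    "equilibrium")
})

test_that("negative-feedback Fano equals the fully printed expression", {
  # independent evaluation of the exact closed form for the repressed model
  printed_negative_fano <- function(sp) {
    p <- sp$params
    v <- equilibrium(sp)$v_star
    kv <- p$kappa1_ominus * v
    num <- kv * p$kappa2 * p$kappa3 / ((p$kappa1_plus + kv)^2 * p$nu2) +
      p$kappa3 / p$nu2 + 1
    num / (1 + kv / (kv + p$kappa1_plus))
  }
  set.seed(33)
  for (i in 1:200) {
    sp <- random_spec("negative")
    expect_equal(fano_equilibrium(sp)$fano, printed_negative_fano(sp),
                 tolerance = 1e-12)
  }
})

test_that("both Fano routes agree to 1e-10 across modes", {
  set.seed(34)
  for (i in 1:150) {
    mode <- c("neutral", "negative", "positive")[1 + i %% 3]
    sp <- random_spec(mode)
    v <- equilibrium(sp)$v_star
    if (v <= 0) next
    route <- -diffusion_c(sp, v) / (2 * drift_deriv(sp, v) * v)
    f <- fano_equilibrium(sp)
    d <- f$decomposition
    expect_equal((d$protein_term + d$mrna_term + d$gene_term) /
                   d$feedback_denominator,
                 route, tolerance = 1e-10)
    expect_true(all(c(d$mrna_term, d$gene_term) >= 0))
    expect_gt(d$feedback_denominator, 0)
  }
})

test_that("matched-model variance ratios follow the off-state occupancy", {
  sp <- spec_high_mean()
  vc <- variance_comparison(sp)
  expect_equal(vc$q, 1 / 6)
  expect_equal(vc$var_ratio_negative, 6 / 7)
  expect_equal(vc$var_ratio_positive, 6 / 5)
  # consistent with the Fano triplet (means are equal by matching)
  m <- matched_specs(sp)
  f0 <- fano_equilibrium(sp)$fano
  expect_equal(fano_equilibrium(m$negative)$fano / f0, vc$var_ratio_negative)
  expect_equal(fano_equilibrium(m$positive)$fano / f0, vc$var_ratio_positive)
  # q -> 0: feedback irrelevant when the gene is always on
  vc0 <- variance_comparison(spec_high_mean(kappa1_minus = 1e-9))
  expect_equal(vc0$var_ratio_negative, 1, tolerance = 1e-8)
  expect_equal(vc0$var_ratio_positive, 1, tolerance = 1e-8)
})

test_that("time-dependent OU variance has its closed-form limits", {
  # no production: pure exponential decay of the initial variance
  dead <- model_spec("neutral", kappa1_plus = 1, kappa1_minus = 1,
                     kappa2 = 0, nu2 = 1, kappa3 = 0, nu3 = 1)
  ov <- ou_variance(dead, v0 = 0, varU0 = 4, t_grid = seq(0, 5, 0.5))
  expect_equal(ov$var_U, 4 * exp(-2 * ov$t), tolerance = 1e-6)
  # stationary start stays stationary
  sp <- spec_high_mean()
  s_inf <- diffusion_c(sp, 12.5) / (2 * abs(drift_deriv(sp, 12.5)))
  ov2 <- ou_variance(sp, v0 = 12.5, varU0 = s_inf, t_grid = seq(0, 10, 1))
  expect_equal(ov2$var_U, rep(s_inf, nrow(ov2)), tolerance = 1e-6)
  expect_equal(attr(ov2, "stationary"), s_inf)
  # relaxation from zero variance approaches the stationary value
  ov3 <- ou_variance(sp, v0 = 12.5, varU0 = 0, t_grid = c(0, 1, 3, 10))
  expect_equal(ov3$var_U[-1], s_inf * (1 - exp(-2 * ov3$t[-1])),
               tolerance = 1e-6)
})

test_that("predicted transient variance matches simulated ensembles", {
  sp <- spec_high_mean()
  init <- system_state(0, 1, 2, 1250)
  ov <- ou_variance(sp, v0 = 12.5, varU0 = 0, t_grid = c(0, 1, 3, 10))
  for (i in 2:4) {
    tt <- ov$t[i]
    ens <- ensemble_stats(sp, n_reps = 400, seed = 500 + i, T = tt,
                          burn_in = 0, init = init)
    # bootstrap SE of the variance
    expect_lt(abs(ens$var - ov$var_X[i]), 3 * ens$se_var)
  }
})

test_that("the two-species limit drops mRNA noise and nothing else", {
  sp <- model_spec("neutral", kappa1_plus = 10, kappa1_minus = 2,
                   kappa2 = 1, nu2 = 1, kappa3 = 5, nu3 = 1, N = 100)
  fs <- fano_simple(sp)
  expect_equal(fs$fano, 1 + 10 / 144)
  expect_equal(fs$decomposition$mrna_term, 0)
  # kappa3 -> 0: Poisson protein statistics
  tiny <- model_spec("neutral", kappa1_plus = 10, kappa1_minus = 2,
                     kappa2 = 1, nu2 = 1, kappa3 = 1e-8, nu3 = 1)
  expect_equal(fano_simple(tiny)$fano, 1, tolerance = 1e-6)
  set.seed(35)
  for (i in 1:60) {
    mode <- c("neutral", "negative", "positive")[1 + i %% 3]
    sp_i <- random_spec(mode)
    if (equilibrium(sp_i)$v_star <= 0) next
    expect_lt(fano_simple(sp_i)$fano, fano_equilibrium(sp_i)$fano)
  }
})

test_that("noise reports serialize with the documented decomposition fields", {
  f <- fano_equilibrium(spec_high_mean())
  js <- jsonlite::fromJSON(noise_report_json(f))
  expect_named(js$decomposition,
               c("protein_term", "mrna_term", "gene_term",
                 "feedback_denominator"))
  expect_equal(js$fano, f$fano)
})
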