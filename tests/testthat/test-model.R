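test_that("scaled/unscaled parameter views are exact inverses", {
  sp <- spec_high_mean()
  u <- as_unscaled(sp)
  expect_identical(u$lambda1_plus, 1000)   # N * kappa1_plus
  expect_identical(u$lambda1_minus, 200)
  expect_identical(u$lambda2, 300)
  expect_identical(u$mu2, 100)
  expect_identical(u$lambda3, 500)
  expect_identical(u$mu3, 1)               # protein decay is not N-scaled

  neg <- matched_specs(sp)$negative
  expect_identical(as_unscaled(neg)$lambda1_ominus, 0.16)  # unchanged by N

  rt <- from_unscaled(as_unscaled(sp))
  expect_identical(rt$params, sp$params)
  expect_identical(rt$N, sp$N)
  rt_neg <- from_unscaled(as_unscaled(neg))
  expect_identical(rt_neg$params, neg$params)
})

test_that("construction-time validation names the offending field", {
  expect_error(model_spec("neutral", kappa1_plus = -1, kappa1_minus = 2,
                          kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1),
               "kappa1_plus")
  expect_error(model_spec("neutral", kappa1_plus = 1, kappa1_minus = 2,
                          kappa2 = 3, nu2 = 0, kappa3 = 5, nu3 = 1),
               "nu2")
  expect_error(model_spec("negative", kappa1_plus = 1, kappa2 = 3, nu2 = 1,
                          kappa3 = 5, nu3 = 1),
               "kappa1_ominus")
  expect_error(model_spec("neutral", kappa1_plus = 1, kappa1_minus = 2,
                          kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1, M = 1.5),
               "M")
  expect_error(from_unscaled(list(lambda1_plus = 1, lambda1_minus = 1,
                                  lambda2 = 1, mu2 = 1, lambda3 = 1,
                                  mu3 = 1, N = 0.5), mode = "neutral"),
               "N")
  # fields irrelevant to the wiring are dropped
  sp <- model_spec("neutral", kappa1_plus = 1, kappa1_minus = 2,
                   kappa1_ominus = 9, kappa2 = 3, nu2 = 1, kappa3 = 5,
                   nu3 = 1)
  expect_null(sp$params$kappa1_ominus)
})

test_that("propensities follow the feedback wiring and stencils conserve genes", {
  sp <- spec_high_mean()
  expect_equal(propensities(sp, system_state(1, 0, 0, 0)),
               c(1000, 0, 0, 0, 0, 0))
  neg <- matched_specs(sp)$negative
  r <- propensities(neg, system_state(0, 1, 2, 1250))
  expect_equal(r[2], 0.16 * 1250 * 1)   # repression scales with protein count
  pos <- matched_specs(sp)$positive
  expect_equal(propensities(pos, system_state(1, 0, 0, 0)),
               rep(0, 6))               # no protein, all genes off: absorbing
  expect_error(propensities(sp, system_state(0, 0, 0, 0)), "conservation")
})

test_that("fast-subsystem equilibrium moments match the closed forms", {
  sp <- spec_high_mean()
  fe <- fast_equilibrium(sp, v_p = 0)
  expect_equal(fe$E_on, 10 / 12)
  expect_equal(fe$E_R, 3 * 10 / 12)
  neg <- matched_specs(sp)$negative
  fe_neg <- fast_equilibrium(neg, v_p = 12.5)  # kappa1_ominus * v = 2
  expect_equal(fe_neg$E_on, 10 / 12)
  pos <- matched_specs(sp)$positive
  expect_equal(fast_equilibrium(pos, v_p = 0)$E_on, 0)
  dead <- model_spec("neutral", kappa1_plus = 0, kappa1_minus = 0,
                     kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1)
  expect_error(fast_equilibrium(dead, 1), "switching")
})

test_that("fast-subsystem moments agree with protein-clamped simulation", {
  neg <- matched_specs(spec_high_mean())$negative
  init <- system_state(1, 0, 0, 1250)
  on_avg <- r_avg <- numeric(20)
  for (k in seq_len(20)) {
    tr <- simulate_ssa(neg, init = init, T = 30, seed = 400 + k,
                       burn_in = 5, record = FALSE, clamp_protein = TRUE)
    on_avg[k] <- tr$tavg$mean_on
    r_avg[k] <- tr$tavg$mean_r
  }
  fe <- fast_equilibrium(neg, 12.5)
  expect_lt(abs(mean(on_avg) - fe$E_on), 3 * sd(on_avg) / sqrt(20))
  expect_lt(abs(mean(r_avg) - fe$E_R), 3 * sd(r_avg) / sqrt(20))
})

test_that("matched feedback specs share the neutral equilibrium", {
  sp <- spec_high_mean()
  m <- matched_specs(sp)
  expect_equal(m$negative$params$kappa1_ominus, 0.16)
  expect_equal(m$positive$params$kappa1_oplus, 0.8)
  expect_equal(equilibrium(m$negative)$v_star, 12.5, tolerance = 1e-12)
  expect_equal(equilibrium(m$positive)$v_star, 12.5, tolerance = 1e-12)

  sp_b <- spec_low_mean()
  m_b <- matched_specs(sp_b)
  expect_equal(m_b$negative$params$kappa1_ominus, 5 / 3)
  expect_equal(m_b$positive$params$kappa1_oplus, 5)
  expect_equal(equilibrium(m_b$negative)$v_star, 0.6, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    sp_i <- random_spec("neutral")
    v <- equilibrium(sp_i)$v_star
    m_i <- matched_specs(sp_i)
    expect_equal(equilibrium(m_i$negative)$v_star, v, tolerance = 1e-12)
    expect_equal(equilibrium(m_i$positive)$v_star, v, tolerance = 1e-12)
  }
})

test_that("config files round-trip and unknown keys are rejected", {
  sp <- matched_specs(spec_high_mean())$negative
  yml <- tempfile(fileext = ".yaml")
  jsn <- tempfile(fileext = ".json")
  write_model_config(sp, yml)
  write_model_config(sp, jsn)
  expect_equal(read_model_config(yml)$params, sp$params)
  expect_equal(read_model_config(jsn)$params, sp$params)
  expect_equal(read_model_config(yml)$N, sp$N)
  # hand-written YAML with a bare `N` key (parsed as a boolean by YAML 1.1)
  bare <- tempfile(fileext = ".yaml")
  writeLines(c("mode: neutral", "N: 50", "kappa1_plus: 1", "kappa1_minus: 1",
               "kappa2: 1", "nu2: 1", "kappa3: 1", "nu3: 1"), bare)
  expect_equal(read_model_config(bare)$N, 50)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("mode: neutral", "kappa1_plus: 1", "kappa1_minus: 1",
               "kappa2: 1", "nu2: 1", "kappa3: 1", "nu3: 1",
               "burst_size: 7"), bad)
  expect_error(read_model_config(bad), "burst_size")
})
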