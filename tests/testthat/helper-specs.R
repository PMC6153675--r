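# canonical parameter sets used throughout the suite
#
# high-mean configuration: neutral equilibrium N * v_P* = 1250
spec_high_mean <- function(kappa1_minus = 2, kappa1_plus = 10)
  model_spec("neutral", kappa1_plus = kappa1_plus,
             kappa1_minus = kappa1_minus,
             kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1, M = 1, N = 100)

# low-mean configuration: neutral equilibrium N * v_P* = 60
spec_low_mean <- function(kappa1_minus = 1, kappa1_plus = 3)
  model_spec("neutral", kappa1_plus = kappa1_plus,
             kappa1_minus = kappa1_minus,
             kappa2 = 2, nu2 = 0.25, kappa3 = 0.1, nu3 = 1, M = 1, N = 100)

# log-uniform random spec; rates in [1e-2, 1e2]
random_spec <- function(mode) {
  r <- function() 10^stats::runif(1, -2, 2)
  switch(mode,
    neutral = model_spec("neutral", kappa1_plus = r(), kappa1_minus = r(),
                         kappa2 = r(), nu2 = r(), kappa3 = r(), nu3 = r()),
    negative = model_spec("negative", kappa1_plus = r(), kappa1_ominus = r(),
                          kappa2 = r(), nu2 = r(), kappa3 = r(), nu3 = r()),
    positive = {
      # ensure a positive equilibrium exists: kappa1_minus/kappa1_oplus < cap
      k2 <- r(); n2 <- r(); k3 <- r(); n3 <- r(); kop <- r()
      cap <- k2 * k3 / (n2 * n3)
      model_spec("positive", kappa1_oplus = kop,
                 kappa1_minus = stats::runif(1, 0.05, 0.95) * kop * cap,
                 kappa2 = k2, nu2 = n2, kappa3 = k3, nu3 = n3)
    })
}

# time-weighted mean and variance of a trajectory column over [from, to]
time_weighted_stats <- function(traj, column, from, to) {
  d <- traj$data
  t <- c(d$t, traj$T)
  keep_from <- pmax(t[-length(t)], from)
  keep_to <- pmin(t[-1], to)
  w <- pmax(keep_to - keep_from, 0)
  x <- d[[column]]
  m <- sum(w * x) / sum(w)
  list(mean = m, var = sum(w * (x - m)^2) / sum(w))
}
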