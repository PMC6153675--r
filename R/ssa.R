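.mode_int <- function(mode) match(mode, FEEDBACK_MODES) - 1L

# counter-based replicate seed derived from a master seed
rep_seed <- function(seed, k) {
  s <- (as.numeric(seed) + as.numeric(k) * 1000003) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

.unscaled_or_zero <- function(u, field) if (is.null(u[[field]])) 0 else u[[field]]

#' Initial state at the deterministic equilibrium
#'
#' Default starting point for equilibrium ensembles: protein at
#' `round(N v_P*)`, mRNA at the rounded fast-equilibrium mean, and each gene
#' copy active independently with probability `E_on/M`. Draws from the
#' current RNG stream.
#'
#' @param spec a [model_spec()].
#' @param simple logical; for the two-species model the mRNA count is 0.
#' @return a [system_state()].
#' @export
equilibrium_state <- function(spec, simple = FALSE) {
  eq <- equilibrium(spec)
  fe <- fast_equilibrium(spec, eq$v_star)
  x_on <- stats::rbinom(1, spec$M, fe$E_on / spec$M)
  system_state(x_off = spec$M - x_on, x_on = x_on,
               x_r = if (simple) 0 else round(fe$E_R),
               x_p = round(spec$N * eq$v_star))
}

.run_one <- function(spec, init, T, burn_in, record, simple = FALSE,
                     lambda3_eff = NULL, clamp_protein = FALSE) {
  .check_state(spec, init)
  u <- as_unscaled(spec)
  l3 <- if (simple) {
    if (is.null(lambda3_eff)) u$lambda3 * u$lambda2 / u$mu2 else lambda3_eff
  } else u$lambda3
  ssa_run_cpp(.mode_int(spec$mode), simple, clamp_protein,
              .unscaled_or_zero(u, "lambda1_plus"),
              .unscaled_or_zero(u, "lambda1_minus"),
              .unscaled_or_zero(u, "lambda1_ominus"),
              .unscaled_or_zero(u, "lambda1_oplus"),
              if (simple) 0 else u$lambda2, if (simple) 0 else u$mu2,
              l3, u$mu3,
              init$x_off, init$x_on, init$x_r, init$x_p,
              T, burn_in, record)
}

.as_trajectory <- function(raw, spec, seed, T, simple) {
  structure(list(
    data = data.frame(t = raw$t, x_off = raw$x_off, x_on = raw$x_on,
                      x_r = raw$x_r, x_p = raw$x_p),
    final = raw$final, counts = raw$counts, tavg = raw$tavg,
    spec = spec, seed = seed, T = T, absorbed = raw$absorbed,
    simple = simple), class = "trajectory")
}

#' Exact stochastic simulation of the full jump process
#'
#' Direct-method (Gillespie) realization of the continuous-time Markov chain
#' defined by [propensities()]: exponential waiting times at the total
#' propensity, channel chosen proportionally. Statistically exact and fully
#' reproducible given `(spec, init, T, seed)`. When the total propensity hits
#' zero (e.g. the positive-feedback model with no protein and all genes off)
#' the state is frozen up to `T` and the trajectory is flagged `absorbed`.
#'
#' @param spec a [model_spec()].
#' @param init a [system_state()]; default [equilibrium_state()].
#' @param T simulation horizon (`> 0`); default 15 protein lifetimes.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param burn_in start of the window over which time-averages and
#'   per-channel event counts are accumulated.
#' @param record store every jump (`TRUE`) or only endpoint and accumulators.
#' @param clamp_protein freeze the protein count and disable translation and
#'   protein decay (fast-subsystem runs at fixed `x_p`).
#' @return a `trajectory`: jump times and states (`$data`), final state,
#'   event `counts` per channel over `[burn_in, T]`, time-average
#'   accumulators (`$tavg`), and an `absorbed` flag.
#' @export
simulate_ssa <- function(spec, init = NULL, T = 15 / spec$params$nu3,
                         seed = NULL, burn_in = 0, record = TRUE,
                         clamp_protein = FALSE) {
  if (T <= 0) stop("T must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- equilibrium_state(spec)
  raw <- .run_one(spec, init, T, burn_in, record,
                  clamp_protein = clamp_protein)
  if (!record) {
    raw$t <- init$t; raw$x_off <- init$x_off; raw$x_on <- init$x_on
    raw$x_r <- init$x_r; raw$x_p <- init$x_p
  }
  .as_trajectory(raw, spec, seed, T, simple = FALSE)
}

#' Exact simulation of the two-species (gene + protein) model
#'
#' Reduced model without explicit mRNA: gene switching as in the chosen
#' feedback mode, protein produced at `lambda3_eff * x_on` and degraded at
#' `mu3 * x_p`. By default `lambda3_eff = lambda3 * lambda2 / mu2`, so the
#' reduced model carries the same mean protein flux as the full model; this
#' realizes the fast mRNA-turnover limit in which transcript noise
#' disappears.
#'
#' @inheritParams simulate_ssa
#' @param lambda3_eff effective per-active-gene protein production rate
#'   (unscaled); default matches the full model's flux.
#' @return a `trajectory` (the `x_r` column is identically 0).
#' @export
simulate_simple <- function(spec, init = NULL, T = 15 / spec$params$nu3,
                            seed = NULL, burn_in = 0, record = TRUE,
                            lambda3_eff = NULL) {
  if (T <= 0) stop("T must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- equilibrium_state(spec, simple = TRUE)
  raw <- .run_one(spec, init, T, burn_in, record, simple = TRUE,
                  lambda3_eff = lambda3_eff)
  if (!record) {
    raw$t <- init$t; raw$x_off <- init$x_off; raw$x_on <- init$x_on
    raw$x_r <- init$x_r; raw$x_p <- init$x_p
  }
  .as_trajectory(raw, spec, seed, T, simple = TRUE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s feedback%s, %d jumps to T = %g%s\n",
              x$spec$mode, if (x$simple) " (two-species model)" else "",
              nrow(x$data) - 1L, x$T,
              if (x$absorbed) " [absorbed]" else ""))
  invisible(x)
}

#' Monte-Carlo ensemble statistics of the protein count
#'
#' Runs `n_reps` independent replicates and summarizes the protein copy
#' number. Under `scheme = "endpoint"` the statistics are over the `n_reps`
#' values `X_P(T)` (an ensemble of cells observed at one time); under
#' `scheme = "time-average"` each replicate contributes its time-weighted
#' mean and second moment over `[burn_in, T]`, which are then averaged.
#' Replicate seeds are derived from the master seed by a counter, so any
#' single replicate is reproducible in isolation. Standard errors for mean,
#' variance and Fano factor come from a bootstrap over replicates.
#'
#' Absorbed replicates (possible under positive feedback, where extinction
#' at zero protein is permanent) are retained and counted; a warning is
#' emitted when they exceed 1% of the ensemble, since the fluctuation theory
#' describes noise around the positive equilibrium only.
#'
#' @param spec a [model_spec()].
#' @param n_reps number of replicates (`>= 2`).
#' @param seed master integer seed.
#' @param T horizon; default 15 protein lifetimes.
#' @param burn_in start of the averaging window (`scheme = "time-average"`);
#'   default 5 protein lifetimes.
#' @param scheme `"endpoint"` or `"time-average"`.
#' @param init fixed initial [system_state()], or `NULL` to draw
#'   [equilibrium_state()] per replicate.
#' @param simple run the two-species model ([simulate_simple()]).
#' @param lambda3_eff passed to the two-species model.
#' @param n_boot bootstrap resamples for the standard errors.
#' @return an `ensemble_summary`: `mean`, `var`, `fano` (NA when the mean is
#'   0), bootstrap `se_mean`, `se_var`, `se_fano`, `absorbed_fraction`,
#'   per-replicate `values`, plus the sampling metadata.
#' @export
ensemble_stats <- function(spec, n_reps, seed,
                           T = 15 / spec$params$nu3,
                           burn_in = 5 / spec$params$nu3,
                           scheme = c("endpoint", "time-average"),
                           init = NULL, simple = FALSE, lambda3_eff = NULL,
                           n_boot = 200) {
  scheme <- match.arg(scheme)
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (burn_in >= T) stop("burn_in must be < T", call. = FALSE)
  vals <- m2 <- numeric(n_reps)
  absorbed <- logical(n_reps)
  for (k in seq_len(n_reps)) {
    set.seed(rep_seed(seed, k))
    init_k <- if (is.null(init)) equilibrium_state(spec, simple = simple)
              else init
    raw <- .run_one(spec, init_k, T, burn_in, record = FALSE,
                    simple = simple, lambda3_eff = lambda3_eff)
    absorbed[k] <- raw$absorbed
    if (scheme == "endpoint") {
      vals[k] <- raw$final[4]
      m2[k] <- vals[k]^2
    } else {
      vals[k] <- raw$tavg$mean_p
      m2[k] <- raw$tavg$m2_p
    }
  }
  stat <- function(v, s) {
    m <- mean(v)
    va <- mean(s) - m^2
    if (scheme == "endpoint") va <- va * length(v) / (length(v) - 1)
    c(mean = m, var = va, fano = if (m > 0) va / m else NA_real_)
  }
  est <- stat(vals, m2)
  set.seed(rep_seed(seed, n_reps + 1L))
  boot <- replicate(n_boot, {
    idx <- sample.int(n_reps, replace = TRUE)
    stat(vals[idx], m2[idx])
  })
  frac <- mean(absorbed)
  if (frac > 0.01)
    warning(sprintf(
      "%.1f%% of replicates were absorbed; fluctuation theory describes the positive equilibrium only",
      100 * frac), call. = FALSE)
  structure(list(
    n_reps = n_reps, scheme = scheme, T = T, burn_in = burn_in, seed = seed,
    mean = est[["mean"]], var = est[["var"]], fano = est[["fano"]],
    se_mean = stats::sd(boot["mean", ]), se_var = stats::sd(boot["var", ]),
    se_fano = stats::sd(boot["fano", ], na.rm = TRUE),
    absorbed_fraction = frac, values = vals, spec = spec),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d replicates, %s sampling\n",
              x$n_reps, x$scheme))
  cat(sprintf("  mean = %.4g (SE %.3g), var = %.5g (SE %.3g), Fano = %.4g (SE %.3g)\n",
              x$mean, x$se_mean, x$var, x$se_var, x$fano, x$se_fano))
  if (x$absorbed_fraction > 0)
    cat(sprintf("  absorbed fraction = %.3g\n", x$absorbed_fraction))
  invisible(x)
}

#' Export simulation results
#'
#' `write_trajectory_csv()` writes the jump chain as tidy CSV (columns
#' `t, x_off, x_on, x_r, x_p`). `write_ensemble()` writes one CSV row per
#' replicate plus a JSON summary (mean, variance, Fano, standard errors,
#' absorbed fraction, seed and the model configuration).
#'
#' @param traj a `trajectory`.
#' @param path output file path (for `write_ensemble()`, the CSV path; the
#'   JSON summary goes to the same path with extension `.json`).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(traj$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param ens an `ensemble_summary`.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble_summary"))
  utils::write.csv(
    data.frame(replicate = seq_along(ens$values), x_p = ens$values),
    path, row.names = FALSE)
  spec <- ens$spec
  p <- spec$params[!vapply(spec$params, is.null, logical(1))]
  summary <- list(
    mean = ens$mean, var = ens$var, fano = ens$fano,
    se_mean = ens$se_mean, se_var = ens$se_var, se_fano = ens$se_fano,
    absorbed_fraction = ens$absorbed_fraction,
    n_reps = ens$n_reps, scheme = ens$scheme, T = ens$T,
    burn_in = ens$burn_in, seed = ens$seed,
    spec = c(list(mode = spec$mode, M = spec$M, N = spec$N), p))
  jsonlite::write_json(summary, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
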