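#' Matched-model Fano sweep at a fixed protein mean
#'
#' Reproduces the matched-comparison experiment: for each gene deactivation
#' rate `kappa1_minus` in the grid, the activation rate `kappa1_plus` is
#' back-solved so the neutral equilibrium protein mean equals `target_mean`;
#' negative and positive feedback variants are then matched to the same
#' equilibrium ([matched_specs()]). For each of the three wirings the
#' analytic equilibrium Fano factor ([fano_equilibrium()]) is compared with
#' an exact-simulation ensemble estimate.
#'
#' @param kappa1_minus_grid positive deactivation rates to sweep.
#' @param target_mean equilibrium protein count all models share.
#' @param kappa2,nu2,kappa3,nu3 remaining scaled rates.
#' @param M,N gene copy number and system size.
#' @param n_reps replicates per ensemble (`>= 2`).
#' @param seed master seed; each sweep point and mode gets a derived seed.
#' @param scheme,T passed to [ensemble_stats()].
#' @return data.frame with one row per (rate, mode): `kappa1_minus`,
#'   `kappa1_plus`, `mode`, `fano_theory`, `fano_sim`, `fano_sim_se`,
#'   `mean_sim`, `n_reps`, `seed`.
#' @export
sweep_matched_fano <- function(kappa1_minus_grid, target_mean,
                               kappa2, nu2, kappa3, nu3,
                               M = 1L, N = 100, n_reps = 1000, seed = 1,
                               scheme = "endpoint", T = 15 / nu3) {
  if (!length(kappa1_minus_grid) || any(kappa1_minus_grid <= 0))
    stop("kappa1_minus_grid must be a nonempty vector of positive rates",
         call. = FALSE)
  rows <- list()
  point <- 0L
  for (k1m in kappa1_minus_grid) {
    base <- model_spec("neutral", kappa1_plus = 1, kappa1_minus = k1m,
                       kappa2 = kappa2, nu2 = nu2, kappa3 = kappa3,
                       nu3 = nu3, M = M, N = N)
    k1p <- back_solve_kappa1_plus(base, target_mean)
    neutral <- model_spec("neutral", kappa1_plus = k1p, kappa1_minus = k1m,
                          kappa2 = kappa2, nu2 = nu2, kappa3 = kappa3,
                          nu3 = nu3, M = M, N = N)
    triplet <- c(list(neutral = neutral), matched_specs(neutral))
    for (mode in names(triplet)) {
      point <- point + 1L
      sp <- triplet[[mode]]
      seed_i <- rep_seed(seed, point * 100003L)
      ens <- ensemble_stats(sp, n_reps = n_reps, seed = seed_i, T = T,
                            scheme = scheme)
      rows[[point]] <- data.frame(
        kappa1_minus = k1m, kappa1_plus = k1p, mode = mode,
        fano_theory = fano_equilibrium(sp)$fano,
        fano_sim = ens$fano, fano_sim_se = ens$se_fano,
        mean_sim = ens$mean, n_reps = n_reps, seed = seed_i)
    }
  }
  do.call(rbind, rows)
}

#' Repression-strength sweep of the negative-feedback model
#'
#' Sweeps the protein-dependent deactivation constant `lambda1_ominus`
#' (unscaled) at fixed activation rate, tracing the equilibrium mean against
#' the Fano factor. For each point the exact fluctuation-theory value is
#' compared with the linearized approximation ([fano_thattai()]) and an
#' exact-simulation ensemble.
#'
#' @param lambda1_ominus_grid positive unscaled repression constants.
#' @param lambda1_plus,lambda2,mu2,lambda3,mu3 remaining unscaled rates.
#' @param M,N gene copy number and system size.
#' @param n_reps replicates per ensemble.
#' @param seed master seed.
#' @param scheme,T passed to [ensemble_stats()]; `T` defaults to 15 protein
#'   lifetimes.
#' @return data.frame with one row per sweep point: `lambda1_ominus`,
#'   `mean` (`= N v_P*`), `fano_ours`, `fano_thattai`, `fano_sim`,
#'   `fano_sim_se`, `mean_sim`, `n_reps`, `seed`.
#' @export
sweep_feedback_strength <- function(lambda1_ominus_grid, lambda1_plus,
                                    lambda2, mu2, lambda3, mu3,
                                    M = 1L, N = 100, n_reps = 1000, seed = 1,
                                    scheme = "endpoint", T = 15 / mu3) {
  if (!length(lambda1_ominus_grid) || any(lambda1_ominus_grid <= 0))
    stop("lambda1_ominus_grid must be a nonempty vector of positive rates",
         call. = FALSE)
  rows <- list()
  for (i in seq_along(lambda1_ominus_grid)) {
    spec <- from_unscaled(list(
      lambda1_plus = lambda1_plus, lambda1_ominus = lambda1_ominus_grid[i],
      lambda2 = lambda2, mu2 = mu2, lambda3 = lambda3, mu3 = mu3,
      M = M, N = N), mode = "negative")
    seed_i <- rep_seed(seed, i * 100003L)
    ens <- ensemble_stats(spec, n_reps = n_reps, seed = seed_i, T = T,
                          scheme = scheme)
    rows[[i]] <- data.frame(
      lambda1_ominus = lambda1_ominus_grid[i],
      mean = spec$N * equilibrium(spec)$v_star,
      fano_ours = fano_equilibrium(spec)$fano,
      fano_thattai = suppressWarnings(fano_thattai(spec)),
      fano_sim = ens$fano, fano_sim_se = ens$se_fano,
      mean_sim = ens$mean, n_reps = n_reps, seed = seed_i)
  }
  do.call(rbind, rows)
}

#' Plot a sweep result
#'
#' Theory curves with simulation points and 3-SE error bars. For matched
#' sweeps ([sweep_matched_fano()]) the Fano factor is drawn against the
#' deactivation rate, one curve per feedback wiring; for repression sweeps
#' ([sweep_feedback_strength()]) against the equilibrium mean, with the
#' exact and linearized formulas as separate curves. Requires ggplot2.
#'
#' @param results a data.frame from either sweep runner.
#' @return a ggplot object.
#' @export
plot_sweep <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep() requires the ggplot2 package", call. = FALSE)
  if (all(c("kappa1_minus", "mode", "fano_theory") %in% names(results))) {
    ggplot2::ggplot(results, ggplot2::aes(x = kappa1_minus)) +
      ggplot2::geom_line(ggplot2::aes(y = fano_theory, linetype = mode)) +
      ggplot2::geom_pointrange(ggplot2::aes(
        y = fano_sim, ymin = fano_sim - 3 * fano_sim_se,
        ymax = fano_sim + 3 * fano_sim_se, shape = mode)) +
      ggplot2::labs(x = "gene deactivation rate", y = "Fano factor") +
      ggplot2::theme_classic()
  } else if (all(c("mean", "fano_ours", "fano_thattai") %in% names(results))) {
    ggplot2::ggplot(results, ggplot2::aes(x = mean)) +
      ggplot2::geom_line(ggplot2::aes(y = fano_ours, linetype = "exact")) +
      ggplot2::geom_line(ggplot2::aes(y = fano_thattai,
                                      linetype = "linearized")) +
      ggplot2::geom_pointrange(ggplot2::aes(
        y = fano_sim, ymin = fano_sim - 3 * fano_sim_se,
        ymax = fano_sim + 3 * fano_sim_se)) +
      ggplot2::labs(x = "mean protein count", y = "Fano factor",
                    linetype = NULL) +
      ggplot2::theme_classic()
  } else {
    stop("results lack the columns of a known sweep layout", call. = FALSE)
  }
}
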