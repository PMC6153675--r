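#' Langevin diffusion coefficient (averaged fluxes only)
#'
#' The naive Langevin closure keeps only the averaged protein birth and death
#' fluxes, `b(v) = kappa3 * E_R(v) + nu3 * v`. Because gene switching and
#' mRNA turnover are averaged out before the noise is read off, `b`
#' systematically understates the protein fluctuations: `b(v) <= c(v)`, with
#' strict inequality whenever transcription and gene switching are active
#' (see [diffusion_c()]).
#'
#' @param spec a [model_spec()].
#' @param v_p scaled protein level (`>= 0`).
#' @return `b(v_p)`.
#' @export
langevin_b <- function(spec, v_p) {
  spec$params$kappa3 * fast_equilibrium(spec, v_p)$E_R + spec$params$nu3 * v_p
}

#' Full diffusion coefficient of the protein fluctuation process
#'
#' Diffusion coefficient `c(v)` of the limiting Ornstein-Uhlenbeck
#' fluctuation process, accounting for all leading-order noise sources:
#'
#' `c(v) = b(v) + c_R(v) + c_G(v)` with
#'  * `b(v) = kappa3 E_R(v) + nu3 v` -- protein birth-death shot noise,
#'  * `c_R(v) = 2 (kappa3^2/nu2) E_R(v)` -- transcript copy-number
#'    fluctuations filtered through translation,
#'  * `c_G(v) = 2 (kappa2 kappa3/nu2)^2 M a d / (a + d)^3` -- telegraph noise
#'    of the `M` gene copies, with `(a, d)` the per-copy on/off switching
#'    rates at frozen `v` (feedback enters through their `v`-dependence).
#'
#' At the equilibrium this closed form reproduces the classical exact neutral
#' decomposition (Paulsson's formula in the fast-switching scaling) and the
#' printed negative-feedback Fano factor; it is additionally validated
#' against exact simulation in the package tests.
#'
#' @inheritParams langevin_b
#' @return `c(v_p)`.
#' @export
diffusion_c <- function(spec, v_p) {
  p <- spec$params
  E_R <- fast_equilibrium(spec, v_p)$E_R
  r <- gene_switch_rates(spec, v_p)
  a <- r[["on"]]; d <- r[["off"]]
  b <- p$kappa3 * E_R + p$nu3 * v_p
  c_R <- 2 * p$kappa3^2 / p$nu2 * E_R
  c_G <- if (a + d > 0)
    2 * (p$kappa2 * p$kappa3 / p$nu2)^2 * spec$M * a * d / (a + d)^3
  else 0
  b + c_R + c_G
}

.new_noise_report <- function(spec, v_star, F_prime, cc, b, mrna_term,
                              gene_term, denom, model = "full") {
  fano_decomp <- (1 + mrna_term + gene_term) / denom
  fano_route <- -cc / (2 * F_prime * v_star)
  if (abs(fano_decomp - fano_route) > 1e-10 * max(1, abs(fano_route)))
    stop(sprintf(
      "internal inconsistency: decomposition Fano %.12g != -c/(2F'v*) %.12g",
      fano_decomp, fano_route), call. = FALSE)
  structure(list(
    mode = spec$mode, model = model,
    v_star = v_star, F_prime = F_prime, c = cc, b = b,
    fano = fano_decomp,
    decomposition = list(protein_term = 1, mrna_term = mrna_term,
                         gene_term = gene_term,
                         feedback_denominator = denom),
    note = paste("Equilibrium Fano factor from the stationary",
                 "Ornstein-Uhlenbeck fluctuation law; obtained by evaluating",
                 "the long-time limit of the finite-N fluctuation expansion",
                 "(the two limits are exchanged).")),
    class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  d <- x$decomposition
  cat(sprintf("<noise_report> %s feedback (%s model)\n", x$mode, x$model))
  cat(sprintf("  v_P* = %g,  F'(v_P*) = %g,  c(v_P*) = %g,  b(v_P*) = %g\n",
              x$v_star, x$F_prime, x$c, x$b))
  cat(sprintf("  Fano = (1 + %.4g [mRNA] + %.4g [gene]) / %.4g = %.6g\n",
              d$mrna_term, d$gene_term, d$feedback_denominator, x$fano))
  invisible(x)
}

#' Equilibrium Fano factor of the protein count
#'
#' Computes the stationary Fano factor `Var[X_P]/E[X_P]` of the protein copy
#' number from the Ornstein-Uhlenbeck fluctuation law:
#' `Fano = -c(v_P*) / (2 F'(v_P*) v_P*)`. The same number is assembled from
#' its biological decomposition
#' `(1 + mRNA term + gene term) / feedback denominator`, where the unit term
#' is pure protein birth-death (Poisson) noise, the mRNA term equals
#' `kappa3/nu2`, the gene term is the telegraph-noise contribution
#' `c_G(v_P*)/(2 nu3 v_P*)`, and the denominator `-F'(v_P*)/nu3` captures the
#' faster (negative feedback) or slower (positive feedback) relaxation of
#' fluctuations; both routes must agree to 1e-10 relative. For the neutral
#' model the denominator is 1 and the expression reduces to
#' `1 + kappa3/nu2 + kappa1_minus kappa2 kappa3 / (nu2 (kappa1_plus +
#' kappa1_minus)^2)`.
#'
#' @param spec a [model_spec()] with a positive deterministic equilibrium.
#' @return a `noise_report` with fields `v_star`, `F_prime`, `c`, `b`,
#'   `fano`, and `decomposition` (`protein_term`, `mrna_term`, `gene_term`,
#'   `feedback_denominator`).
#' @export
fano_equilibrium <- function(spec) {
  eq <- equilibrium(spec)
  if (eq$degenerate || eq$v_star <= 0)
    stop("no positive equilibrium: Fano factor undefined", call. = FALSE)
  v <- eq$v_star
  p <- spec$params
  Fp <- drift_deriv(spec, v)
  cc <- diffusion_c(spec, v)
  b <- langevin_b(spec, v)
  r <- gene_switch_rates(spec, v)
  a <- r[["on"]]; d <- r[["off"]]
  gene_term <- 2 * (p$kappa2 * p$kappa3 / p$nu2)^2 * spec$M * a * d /
    (a + d)^3 / (2 * p$nu3 * v)
  .new_noise_report(spec, v, Fp, cc, b,
                    mrna_term = p$kappa3 / p$nu2,
                    gene_term = gene_term,
                    denom = -Fp / p$nu3)
}

#' Equilibrium Fano factor in the two-species (no-mRNA) limit
#'
#' In the limit of fast mRNA turnover at fixed transcription/decay ratio
#' (`nu2 = kappa2` both large) the transcript pool tracks the gene state
#' instantaneously and the model reduces to gene + protein. The deterministic
#' equilibrium and the gene telegraph term are unchanged (they depend on the
#' rates only through `kappa2/nu2`); the explicit mRNA noise term
#' `kappa3/nu2` vanishes. For the neutral wiring this yields
#' `1 + kappa1_minus kappa3 (kappa2/nu2) / (kappa1_plus + kappa1_minus)^2`,
#' always below the full-model Fano factor.
#'
#' @inheritParams fano_equilibrium
#' @return a `noise_report` (with `mrna_term = 0`).
#' @export
fano_simple <- function(spec) {
  full <- fano_equilibrium(spec)
  p <- spec$params
  v <- full$v_star
  # diffusion of the reduced model: protein shot noise + gene telegraph noise
  cc <- full$b + (full$decomposition$gene_term) * 2 * p$nu3 * v
  .new_noise_report(spec, v, full$F_prime, cc, full$b,
                    mrna_term = 0,
                    gene_term = full$decomposition$gene_term,
                    denom = full$decomposition$feedback_denominator,
                    model = "simple")
}

#' Matched-model variance ratios
#'
#' For matched models sharing the equilibrium `v_P*` (see [matched_specs()]),
#' the stationary variances obey, with `q = kappa1_minus / (kappa1_minus +
#' kappa1_plus)` the neutral off-state occupancy:
#' `Var_negative / Var_neutral = 1/(1 + q)` and
#' `Var_positive / Var_neutral = 1/(1 - q)`. Negative feedback reduces the
#' variance by at most a factor of 2 (as `q -> 1`), while the increase under
#' positive feedback is unbounded as the gene spends ever more time off.
#'
#' @param neutral a neutral-mode [model_spec()] with positive switching rates.
#' @return list with `q`, `var_ratio_negative`, `var_ratio_positive`,
#'   `reduction_factor` (`= 1 + q`).
#' @export
variance_comparison <- function(neutral) {
  if (neutral$mode != "neutral")
    stop("variance_comparison() expects a neutral-mode spec", call. = FALSE)
  p <- neutral$params
  q <- p$kappa1_minus / (p$kappa1_minus + p$kappa1_plus)
  list(q = q,
       var_ratio_negative = 1 / (1 + q),
       var_ratio_positive = 1 / (1 - q),
       reduction_factor = 1 + q)
}

#' Time-dependent variance of the fluctuation process
#'
#' The fluctuation `U` of the scaled protein level around the deterministic
#' path is a time-inhomogeneous Ornstein-Uhlenbeck process; its variance
#' solves `dS/dt = 2 F'(v_P(t)) S + c(v_P(t))` along the deterministic flow.
#' Solved jointly with the flow by `deSolve::lsoda` (rtol 1e-8). On the
#' original molecule-count scale `Var[X_P](t) = N * Var[U](t)`.
#'
#' @param spec a [model_spec()].
#' @param v0 initial scaled protein level.
#' @param varU0 initial fluctuation variance (`>= 0`).
#' @param t_grid increasing time grid starting at the initial time.
#' @return data.frame with columns `t`, `v_p`, `var_U`, `var_X`
#'   (`= N * var_U`); attribute `stationary` holds the equilibrium value
#'   `c(v*)/(2 |F'(v*)|)` when a positive equilibrium exists.
#' @export
ou_variance <- function(spec, v0, varU0, t_grid) {
  if (varU0 < 0) stop("varU0 must be >= 0", call. = FALSE)
  sol <- deSolve::lsoda(
    y = c(v = v0, S = varU0), times = t_grid,
    func = function(t, y, parms) {
      v <- max(y[[1]], 0)
      list(c(drift(spec, v),
             2 * drift_deriv(spec, v) * y[[2]] + diffusion_c(spec, v)))
    },
    rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("OU variance integration failed; see deSolve diagnostics",
         call. = FALSE)
  out <- data.frame(t = sol[, "time"], v_p = sol[, "v"],
                    var_U = pmax(sol[, "S"], 0))
  out$var_X <- spec$N * out$var_U
  eq <- tryCatch(equilibrium(spec), error = function(e) NULL)
  if (!is.null(eq) && !eq$degenerate && eq$v_star > 0) {
    vs <- eq$v_star
    attr(out, "stationary") <-
      diffusion_c(spec, vs) / (2 * abs(drift_deriv(spec, vs)))
  }
  out
}

#' Serialize a noise report to JSON
#'
#' @param report a `noise_report` from [fano_equilibrium()] or
#'   [fano_simple()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
noise_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "noise_report"))
  x <- unclass(report)
  if (is.null(path))
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
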