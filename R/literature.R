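#' Exact neutral Fano factor (Paulsson)
#'
#' Classical exact Fano factor of the protein count in the unregulated
#' three-stage model, valid without any time-scale separation. With expected
#' life-times `tau1 = 1/(lambda1_minus + lambda1_plus)` (gene-activity
#' changes), `tau2 = 1/mu2` (mRNA) and `tau3 = 1/mu3` (protein):
#'
#' `Fano = 1 + (lambda3/mu3) tau2/(tau2 + tau3)
#'   + (mean lambda1_minus/(M lambda1_plus)) tau1/((tau2 + tau3)(tau1 + tau3))
#'     (tau1 tau2 + tau2 tau3 + tau1 tau3)/(tau1 + tau2)`.
#'
#' In the regime `tau3 >> tau1, tau2` (stable protein, fast gene and mRNA)
#' this reduces to the scaled-limit expression returned by
#' [fano_equilibrium()] for the neutral model.
#'
#' @param u named list of unscaled constants (`lambda1_plus`,
#'   `lambda1_minus`, `mu2`, `lambda3`, `mu3`, optionally `M`), e.g. from
#'   [as_unscaled()] on a neutral spec.
#' @param mean_X_P equilibrium mean protein count (`> 0`).
#' @return the Fano factor.
#' @export
fano_paulsson <- function(u, mean_X_P) {
  if (mean_X_P <= 0) stop("mean_X_P must be > 0", call. = FALSE)
  M <- if (is.null(u$M)) 1 else u$M
  tau1 <- 1 / (u$lambda1_minus + u$lambda1_plus)
  tau2 <- 1 / u$mu2
  tau3 <- 1 / u$mu3
  1 + (u$lambda3 / u$mu3) * tau2 / (tau2 + tau3) +
    (mean_X_P * u$lambda1_minus / (M * u$lambda1_plus)) *
      tau1 / ((tau2 + tau3) * (tau1 + tau3)) *
      (tau1 * tau2 + tau2 * tau3 + tau1 * tau3) / (tau1 + tau2)
}

#' Linearized negative-feedback Fano factor (Thattai-van Oudenaarden)
#'
#' Linearization of the negative-feedback model around a constitutively
#' expressing gene, valid when repression is weak at the operating point
#' (`kappa1_ominus v_P* << kappa1_plus`):
#' `Fano = (1 + kappa3/nu2) (1 - kappa1_ominus v_P* / kappa1_plus)`.
#' Gene-switching noise is absent from the linearized formula, so it
#' systematically understates the exact value from [fano_equilibrium()].
#' A warning is emitted when `kappa1_ominus v_P*/kappa1_plus > 0.2`, where
#' the linearization degrades.
#'
#' @param spec a negative-feedback [model_spec()].
#' @return the linearized Fano factor.
#' @export
fano_thattai <- function(spec) {
  if (spec$mode != "negative")
    stop("fano_thattai() expects a negative-feedback spec", call. = FALSE)
  p <- spec$params
  v <- equilibrium(spec)$v_star
  ratio <- p$kappa1_ominus * v / p$kappa1_plus
  if (ratio > 0.2)
    warning(sprintf(
      "linearization validity: kappa1_ominus * v_P* / kappa1_plus = %.3g > 0.2",
      ratio), call. = FALSE)
  (1 + p$kappa3 / p$nu2) * (1 - ratio)
}

#' Stationary birth-death law of the low-abundance limit (Dessalles et al.)
#'
#' In the scaling where gene switching, transcription and mRNA decay are fast
#' while translation and protein decay are of order one, the protein count
#' under negative feedback converges to a birth-death process with death
#' rates `mu3 n` and birth rates
#' `(lambda3/mu2) lambda2 lambda1_plus / (lambda1_plus + lambda1_ominus n)`.
#' Its stationary law is
#' `pi(n) = (1/Z) prod_{i=0}^{n-1} rho / ((i+1)(i + lambda1_plus/lambda1_ominus))`
#' with `rho = lambda1_plus lambda2 lambda3 / (lambda1_ominus mu2 mu3)`.
#' Products are accumulated in log space; the truncation is grown until the
#' normalized mass at the truncation point is below 1e-12.
#'
#' As `rho -> infinity` the Fano factor of this law tends to 1/2, matching
#' the strong-repression limit of [fano_equilibrium()]; for
#' `lambda1_ominus >> lambda1_plus` the law concentrates on very few
#' molecules and the Fano factor drops below 1/2 (infra-Fano regime,
#' outside the abundant-protein theory).
#'
#' @param lambda1_plus,lambda1_ominus,lambda2,mu2,lambda3,mu3 unscaled rates
#'   (`> 0`).
#' @param n_max cap on the truncation point (default `2^20`); an error is
#'   raised if the tail mass is still above 1e-12 there.
#' @return a `birth_death_law`: list with `n`, `pi`, `rho`, `a`
#'   (`= lambda1_plus/lambda1_ominus`), `mean`, `var`, `fano`, `n_max`.
#' @export
dessalles_stationary <- function(lambda1_plus, lambda1_ominus, lambda2, mu2,
                                 lambda3, mu3, n_max = 2^20) {
  rates <- c(lambda1_plus = lambda1_plus, lambda1_ominus = lambda1_ominus,
             lambda2 = lambda2, mu2 = mu2, lambda3 = lambda3, mu3 = mu3)
  if (any(rates <= 0) || any(!is.finite(rates)))
    stop("all rates must be positive and finite", call. = FALSE)
  rho <- lambda1_plus * lambda2 * lambda3 / (lambda1_ominus * mu2 * mu3)
  a <- lambda1_plus / lambda1_ominus
  n_try <- min(n_max, max(64, ceiling(4 * sqrt(rho) + 10 * sqrt(a) + 50)))
  repeat {
    i <- seq_len(n_try) - 1                     # 0 .. n_try-1
    logw <- c(0, cumsum(log(rho) - log(i + 1) - log(i + a)))
    logZ <- max(logw) + log(sum(exp(logw - max(logw))))
    pi_n <- exp(logw - logZ)
    if (pi_n[length(pi_n)] < 1e-12) break
    if (n_try >= n_max)
      stop(sprintf(
        "tail mass %.2e at truncation %d still above 1e-12; increase n_max",
        pi_n[length(pi_n)], n_try), call. = FALSE)
    n_try <- min(n_max, n_try * 2)
  }
  n <- seq_along(pi_n) - 1
  m <- sum(n * pi_n)
  v <- sum((n - m)^2 * pi_n)
  structure(list(n = n, pi = pi_n, rho = rho, a = a,
                 mean = m, var = v, fano = v / m, n_max = max(n)),
            class = "birth_death_law")
}

#' @export
print.birth_death_law <- function(x, ...) {
  cat(sprintf(
    "<birth_death_law> rho = %g, lambda1_plus/lambda1_ominus = %g\n", x$rho,
    x$a))
  cat(sprintf("  truncation %d, mean = %.4g, var = %.4g, Fano = %.4g\n",
              x$n_max, x$mean, x$var, x$fano))
  invisible(x)
}

#' Classify the noise regime of a stationary birth-death law
#'
#' The abundant-protein fluctuation theory bounds the negative-feedback Fano
#' factor below by 1/2; laws with Fano below that bound (low abundance,
#' strong repression) fall in the infra-Fano regime it cannot reach.
#'
#' @param law a `birth_death_law` from [dessalles_stationary()].
#' @return list with `infra_fano` (logical) and `fano`.
#' @export
regime_classify <- function(law) {
  stopifnot(inherits(law, "birth_death_law"))
  list(infra_fano = law$fano < 0.5, fano = law$fano)
}

#' Export a stationary law to CSV
#'
#' @param law a `birth_death_law`.
#' @param path output file; columns `n, pi_n`.
#' @export
write_law_csv <- function(law, path) {
  utils::write.csv(data.frame(n = law$n, pi_n = law$pi), path,
                   row.names = FALSE)
  invisible(path)
}
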