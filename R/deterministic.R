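#' Averaged drift of the scaled protein concentration
#'
#' In the large-`N` limit the scaled protein level `v_P = X_P / N` follows the
#' autonomous ODE `dv_P/dt = F(v_P)` with
#' `F(v) = kappa3 * E_R(v) - nu3 * v`, where `E_R(v)` is the stationary mean
#' transcript count of the fast gene/mRNA subsystem at frozen protein level
#' `v` (see [fast_equilibrium()]).
#'
#' @param spec a [model_spec()].
#' @param v_p scaled protein level (`>= 0`); vectorized.
#' @return drift value(s) `F(v_p)`.
#' @export
drift <- function(spec, v_p) {
  vapply(v_p, function(v)
    spec$params$kappa3 * fast_equilibrium(spec, v)$E_R - spec$params$nu3 * v,
    numeric(1))
}

#' @rdname drift
#' @details `drift_deriv()` returns the analytic derivative `F'(v_p)`. At the
#'   equilibrium it reduces to `-nu3` (neutral),
#'   `-nu3 * (1 + d/(a + d))` (negative feedback) and
#'   `-nu3 * (1 - d/(a + d))` (positive feedback), with `(a, d)` the per-copy
#'   gene on/off rates at the equilibrium -- feedback changes the relaxation
#'   speed of protein fluctuations.
#' @export
drift_deriv <- function(spec, v_p) {
  p <- spec$params
  MkR <- spec$M * p$kappa2 * p$kappa3 / p$nu2   # kappa3 * E_R = MkR * a/(a+d)
  vapply(v_p, function(v) {
    r <- gene_switch_rates(spec, v)
    a <- r[["on"]]; d <- r[["off"]]
    dEdv <- switch(spec$mode,
      neutral  = 0,
      # a const, d = kominus*v: d/dv [a/(a+d)] = -a*kominus/(a+d)^2
      negative = -a * p$kappa1_ominus / (a + d)^2,
      # a = koplus*v, d const: d/dv [a/(a+d)] = koplus*d/(a+d)^2
      positive = p$kappa1_oplus * d / (a + d)^2)
    MkR * dEdv - p$nu3
  }, numeric(1))
}

#' Deterministic protein equilibrium
#'
#' Solves `F(v_P*) = 0` in closed form per feedback wiring. Neutral:
#' `v_P* = M kappa1_plus kappa2 kappa3 / ((kappa1_plus + kappa1_minus) nu2 nu3)`.
#' Negative feedback: the unique positive root of
#' `v^2 + (kappa1_plus/kappa1_ominus) v - M kappa1_plus kappa2 kappa3 /
#' (kappa1_ominus nu2 nu3) = 0`, evaluated in the cancellation-free quadratic
#' form. Positive feedback: `v_P* = M kappa2 kappa3/(nu2 nu3) -
#' kappa1_minus/kappa1_oplus` on the positive branch; when that expression is
#' not positive only the extinct state `v = 0` remains and the result is
#' flagged `degenerate` (zero is always an equilibrium of the
#' positive-feedback drift).
#'
#' @param spec a [model_spec()].
#' @return list with `v_star`, logical `degenerate`, and the residual
#'   `F(v_star)`.
#' @export
equilibrium <- function(spec) {
  p <- spec$params
  cap <- spec$M * p$kappa2 * p$kappa3 / (p$nu2 * p$nu3)  # sup of kappa3*E_R/nu3
  v <- switch(spec$mode,
    neutral = cap * p$kappa1_plus / (p$kappa1_plus + p$kappa1_minus),
    negative = {
      if (p$kappa1_ominus == 0) {
        # no repression: gene is always on once active -> neutral closed form
        # with kappa1_minus = 0
        cap
      } else {
        # v^2 + b v - c = 0, b = k+/ko-, c = cap * k+ / ko-  (both >= 0)
        b <- p$kappa1_plus / p$kappa1_ominus
        cc <- cap * p$kappa1_plus / p$kappa1_ominus
        # stable positive root: 2c / (b + sqrt(b^2 + 4c))
        if (cc == 0) 0 else 2 * cc / (b + sqrt(b^2 + 4 * cc))
      }
    },
    positive = cap - p$kappa1_minus / p$kappa1_oplus)
  degenerate <- FALSE
  if (spec$mode == "positive" && v <= 0) {
    v <- 0
    degenerate <- TRUE
  }
  res <- if (v > 0 || spec$mode != "positive") drift(spec, v) else 0
  tol <- 1e-10 * max(1, p$nu3 * v)
  if (abs(res) > tol)
    stop(sprintf("equilibrium residual %.3e exceeds tolerance %.3e", res, tol),
         call. = FALSE)
  list(v_star = v, degenerate = degenerate, residual = res)
}

#' Integrate the deterministic protein flow
#'
#' Solves the scalar ODE `dv/dt = F(v)` from `v0` over `t_grid` with a
#' stiff-capable adaptive integrator (`deSolve::lsoda`, rtol 1e-8).
#'
#' @param spec a [model_spec()].
#' @param v0 initial scaled protein level (`>= 0`).
#' @param t_grid strictly increasing times; must start at the initial time.
#' @return data.frame with columns `t` and `v_p`.
#' @export
solve_flow <- function(spec, v0, t_grid) {
  if (v0 < 0) stop("v0 must be >= 0", call. = FALSE)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be increasing", call. = FALSE)
  sol <- deSolve::lsoda(
    y = c(v = v0), times = t_grid,
    func = function(t, y, parms) list(drift(spec, max(y[[1]], 0))),
    rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; see deSolve diagnostics", call. = FALSE)
  data.frame(t = sol[, "time"], v_p = sol[, "v"])
}

#' Back-solve the activation rate for a target protein mean
#'
#' For the neutral model the equilibrium mean protein count is
#' `N v_P* = N M kappa1_plus kappa2 kappa3 / ((kappa1_plus + kappa1_minus)
#' nu2 nu3)`; given the other rates and a target mean this inverts the
#' relation: `kappa1_plus = kappa1_minus * v* / (M kappa2 kappa3/(nu2 nu3) -
#' v*)` with `v* = target / N`. The target must lie strictly below the
#' saturation mean `N M kappa2 kappa3 / (nu2 nu3)` reached when the gene is
#' always on.
#'
#' @param spec a neutral [model_spec()]; its `kappa1_plus` (if any) is
#'   ignored.
#' @param target_mean desired equilibrium protein count (`> 0`, molecules).
#' @return the activation rate `kappa1_plus`.
#' @export
back_solve_kappa1_plus <- function(spec, target_mean) {
  if (spec$mode != "neutral")
    stop("back-solving kappa1_plus requires a neutral spec", call. = FALSE)
  p <- spec$params
  cap <- spec$M * p$kappa2 * p$kappa3 / (p$nu2 * p$nu3)
  v <- target_mean / spec$N
  if (target_mean <= 0 || v >= cap)
    stop(sprintf(
      "target mean must lie in (0, %g): the gene cannot sustain more than %g proteins",
      spec$N * cap, spec$N * cap), call. = FALSE)
  p$kappa1_minus * v / (cap - v)
}
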