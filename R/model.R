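#' @useDynLib fanoreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

FEEDBACK_MODES <- c("neutral", "negative", "positive")

# switching-rate fields that are meaningful for each feedback wiring
.mode_fields <- list(
  neutral  = c("kappa1_plus", "kappa1_minus"),
  negative = c("kappa1_plus", "kappa1_ominus"),
  positive = c("kappa1_oplus", "kappa1_minus")
)

.rate_fields <- c("kappa1_plus", "kappa1_minus", "kappa1_ominus",
                  "kappa1_oplus", "kappa2", "nu2", "kappa3", "nu3")

#' Specify a gene-expression model with optional transcriptional feedback
#'
#' Defines the chemical reaction network of the standard gene-expression
#' model: a gene with `M` copies switching between an inactive and an active
#' state, transcription of mRNA from active copies, translation to protein,
#' and first-order degradation of both transcripts and protein. The protein
#' may feed back on the switching step: under negative feedback it switches
#' active genes off at a protein-dependent rate, under positive feedback it
#' switches inactive genes on at a protein-dependent rate. The regulator acts
#' catalytically -- it is neither consumed nor sequestered by binding.
#'
#' Rates are stored in their scaled form, relative to the system-size
#' parameter `N` (protein abundance is of order `N`, gene and mRNA copies of
#' order 1). The corresponding raw propensity constants are recovered with
#' [as_unscaled()]: `lambda1_plus = N * kappa1_plus`,
#' `lambda1_minus = N * kappa1_minus`, `lambda2 = N * kappa2`,
#' `mu2 = N * nu2`, `lambda3 = N * kappa3`, while the protein-dependent
#' switching constants and the protein decay rate are unscaled
#' (`lambda1_ominus = kappa1_ominus`, `lambda1_oplus = kappa1_oplus`,
#' `mu3 = nu3`).
#'
#' @param mode feedback wiring: `"neutral"`, `"negative"` or `"positive"`.
#' @param kappa1_plus scaled gene activation rate (per time); used by the
#'   neutral and negative models.
#' @param kappa1_minus scaled gene deactivation rate (per time); used by the
#'   neutral and positive models.
#' @param kappa1_ominus protein-dependent deactivation rate (per time per
#'   scaled protein unit); negative feedback only.
#' @param kappa1_oplus protein-dependent activation rate (per time per scaled
#'   protein unit); positive feedback only.
#' @param kappa2,nu2 scaled transcription (per active gene) and mRNA decay
#'   rates; `nu2 > 0`.
#' @param kappa3,nu3 scaled translation (per transcript) and protein decay
#'   rates; `nu3 > 0`.
#' @param M total gene copy number (positive integer).
#' @param N system-size scaling parameter, `>= 1`.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("neutral", kappa1_plus = 10, kappa1_minus = 2,
#'                    kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1, N = 100)
#' equilibrium(spec)
#' @export
model_spec <- function(mode = c("neutral", "negative", "positive"),
                       kappa1_plus = NULL, kappa1_minus = NULL,
                       kappa1_ominus = NULL, kappa1_oplus = NULL,
                       kappa2, nu2, kappa3, nu3, M = 1L, N = 100) {
  mode <- match.arg(mode)
  params <- list(kappa1_plus = kappa1_plus, kappa1_minus = kappa1_minus,
                 kappa1_ominus = kappa1_ominus, kappa1_oplus = kappa1_oplus,
                 kappa2 = kappa2, nu2 = nu2, kappa3 = kappa3, nu3 = nu3)
  needed <- c(.mode_fields[[mode]], "kappa2", "nu2", "kappa3", "nu3")
  for (f in needed) {
    v <- params[[f]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop(sprintf("field '%s' must be a single finite number for mode '%s'",
                   f, mode), call. = FALSE)
    if (v < 0)
      stop(sprintf("field '%s' must be nonnegative (got %g)", f, v),
           call. = FALSE)
  }
  for (f in c("nu2", "nu3"))
    if (params[[f]] <= 0)
      stop(sprintf("field '%s' must be strictly positive", f), call. = FALSE)
  if (length(M) != 1L || !is.numeric(M) || M < 1 || M != round(M))
    stop("field 'M' must be a positive integer", call. = FALSE)
  if (length(N) != 1L || !is.numeric(N) || !is.finite(N) || N < 1)
    stop("field 'N' must be a number >= 1", call. = FALSE)
  # fields irrelevant to the wiring are dropped
  params[setdiff(.rate_fields, needed)] <- list(NULL)
  structure(list(mode = mode, params = params, M = as.integer(M), N = N),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s feedback, M = %d gene copies, N = %g\n",
              x$mode, x$M, x$N))
  p <- x$params[!vapply(x$params, is.null, logical(1))]
  cat("  scaled rates:",
      paste(sprintf("%s = %g", names(p), unlist(p)), collapse = ", "), "\n")
  invisible(x)
}

#' Convert between scaled and unscaled parameterizations
#'
#' The simulator works with raw propensity constants (`lambda`, `mu`); all
#' limit formulas are stated in scaled rates (`kappa`, `nu`). The two views
#' are related through the system size `N` (see [model_spec()]); the mapping
#' is exact and invertible.
#'
#' @param spec a [model_spec()].
#' @return `as_unscaled()`: a named list with `lambda1_plus`, `lambda1_minus`,
#'   `lambda1_ominus`, `lambda1_oplus` (those meaningful for the mode),
#'   `lambda2`, `mu2`, `lambda3`, `mu3`, `M`, `N`, `mode`.
#' @export
as_unscaled <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  p <- spec$params
  N <- spec$N
  u <- list(
    lambda1_plus  = if (!is.null(p$kappa1_plus)) N * p$kappa1_plus,
    lambda1_minus = if (!is.null(p$kappa1_minus)) N * p$kappa1_minus,
    lambda1_ominus = p$kappa1_ominus,
    lambda1_oplus  = p$kappa1_oplus,
    lambda2 = N * p$kappa2, mu2 = N * p$nu2,
    lambda3 = N * p$kappa3, mu3 = p$nu3,
    M = spec$M, N = N, mode = spec$mode)
  u[!vapply(u, is.null, logical(1))]
}

#' @rdname as_unscaled
#' @param u a named list of unscaled constants as returned by `as_unscaled()`
#'   (fields `lambda*`, `mu*`, `M`, `N`).
#' @param mode feedback wiring of the resulting spec; defaults to `u$mode`.
#' @return `from_unscaled()`: the corresponding [model_spec()];
#'   `from_unscaled(as_unscaled(spec))` reproduces `spec` exactly.
#' @export
from_unscaled <- function(u, mode = u$mode) {
  if (is.null(u$N) || u$N < 1) stop("field 'N' must be >= 1", call. = FALSE)
  N <- u$N
  model_spec(mode,
             kappa1_plus  = if (!is.null(u$lambda1_plus)) u$lambda1_plus / N,
             kappa1_minus = if (!is.null(u$lambda1_minus)) u$lambda1_minus / N,
             kappa1_ominus = u$lambda1_ominus,
             kappa1_oplus  = u$lambda1_oplus,
             kappa2 = u$lambda2 / N, nu2 = u$mu2 / N,
             kappa3 = u$lambda3 / N, nu3 = u$mu3,
             M = if (is.null(u$M)) 1L else u$M, N = N)
}

#' System state of the jump process
#'
#' @param x_off,x_on inactive / active gene copies; must sum to the gene copy
#'   number `M` of the spec the state is used with.
#' @param x_r,x_p mRNA and protein counts.
#' @param t time stamp.
#' @return a named list of class `system_state`.
#' @export
system_state <- function(x_off, x_on, x_r, x_p, t = 0) {
  v <- c(x_off = x_off, x_on = x_on, x_r = x_r, x_p = x_p)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("state counts must be nonnegative integers", call. = FALSE)
  structure(list(x_off = as.integer(x_off), x_on = as.integer(x_on),
                 x_r = as.integer(x_r), x_p = as.integer(x_p), t = t),
            class = "system_state")
}

.check_state <- function(spec, state) {
  if (state$x_off + state$x_on != spec$M)
    stop(sprintf("gene conservation violated: x_off + x_on = %d but M = %d",
                 state$x_off + state$x_on, spec$M), call. = FALSE)
}

#' Reaction propensities
#'
#' Evaluates the six reaction-channel propensities in raw (unscaled) units at
#' a given state. Channels are ordered: 1 gene activation, 2 gene
#' deactivation, 3 transcription, 4 mRNA decay, 5 translation, 6 protein
#' decay. Under negative feedback deactivation is `lambda1_ominus * x_p *
#' x_on`; under positive feedback activation is `lambda1_oplus * x_p * x_off`.
#' The state-change stencils are (-1,+1,0,0), (+1,-1,0,0), (0,0,+1,0),
#' (0,0,-1,0), (0,0,0,+1), (0,0,0,-1) on (x_off, x_on, x_r, x_p): switching
#' never changes the protein count.
#'
#' @param spec a [model_spec()].
#' @param state a [system_state()].
#' @return numeric vector of length 6.
#' @export
propensities <- function(spec, state) {
  .check_state(spec, state)
  u <- as_unscaled(spec)
  r1 <- switch(spec$mode,
    neutral  = u$lambda1_plus * state$x_off,
    negative = u$lambda1_plus * state$x_off,
    positive = u$lambda1_oplus * state$x_p * state$x_off)
  r2 <- switch(spec$mode,
    neutral  = u$lambda1_minus * state$x_on,
    negative = u$lambda1_ominus * state$x_p * state$x_on,
    positive = u$lambda1_minus * state$x_on)
  c(r1, r2,
    u$lambda2 * state$x_on, u$mu2 * state$x_r,
    u$lambda3 * state$x_r,  u$mu3 * state$x_p)
}

# Per-gene-copy on/off switching rates of the fast subsystem at frozen
# scaled protein level v_p (scaled units).
gene_switch_rates <- function(spec, v_p) {
  p <- spec$params
  switch(spec$mode,
    neutral  = c(on = p$kappa1_plus, off = p$kappa1_minus),
    negative = c(on = p$kappa1_plus, off = p$kappa1_ominus * v_p),
    positive = c(on = p$kappa1_oplus * v_p, off = p$kappa1_minus))
}

#' Equilibrium moments of the fast gene/mRNA subsystem
#'
#' Gene state and mRNA relax much faster than the protein. Conditional on a
#' frozen scaled protein level `v_p`, the fast subsystem is a linear network
#' whose stationary mean active-gene count is `M a/(a + d)` with per-copy
#' switching rates `(a, d)` determined by the feedback wiring, and whose
#' stationary mean transcript count is `(kappa2/nu2)` per active gene.
#'
#' @param spec a [model_spec()].
#' @param v_p scaled protein level (`>= 0`).
#' @return list with `E_on` (mean active genes, in `[0, M]`) and `E_R`
#'   (mean mRNA count).
#' @export
fast_equilibrium <- function(spec, v_p) {
  if (v_p < 0) stop("v_p must be >= 0", call. = FALSE)
  r <- gene_switch_rates(spec, v_p)
  tot <- r[["on"]] + r[["off"]]
  if (tot == 0)
    stop("all gene switching rates are zero; fast equilibrium undefined",
         call. = FALSE)
  E_on <- spec$M * r[["on"]] / tot
  list(E_on = E_on, E_R = spec$params$kappa2 / spec$params$nu2 * E_on)
}

#' Matched feedback models sharing the neutral equilibrium
#'
#' For a fair noise comparison the feedback strengths are calibrated so that
#' all three wirings share the deterministic protein equilibrium `v_P*` of
#' the neutral model: `kappa1_ominus = kappa1_minus / v_P*` and
#' `kappa1_oplus = kappa1_plus / v_P*`. At the shared equilibrium the gene
#' switching rates -- and hence the full diffusion coefficient -- coincide
#' across the three models; only the relaxation speed differs.
#'
#' @param neutral a neutral-mode [model_spec()] with positive switching rates.
#' @return list with elements `negative` and `positive` ([model_spec()]s).
#' @export
matched_specs <- function(neutral) {
  stopifnot(inherits(neutral, "model_spec"))
  if (neutral$mode != "neutral")
    stop("matched_specs() expects a neutral-mode spec", call. = FALSE)
  v_star <- equilibrium(neutral)$v_star
  if (v_star <= 0)
    stop("neutral equilibrium is zero; matched feedback rates undefined",
         call. = FALSE)
  p <- neutral$params
  list(
    negative = model_spec("negative",
      kappa1_plus = p$kappa1_plus, kappa1_ominus = p$kappa1_minus / v_star,
      kappa2 = p$kappa2, nu2 = p$nu2, kappa3 = p$kappa3, nu3 = p$nu3,
      M = neutral$M, N = neutral$N),
    positive = model_spec("positive",
      kappa1_oplus = p$kappa1_plus / v_star, kappa1_minus = p$kappa1_minus,
      kappa2 = p$kappa2, nu2 = p$nu2, kappa3 = p$kappa3, nu3 = p$nu3,
      M = neutral$M, N = neutral$N))
}

#' Read or write a model configuration file
#'
#' Flat key-value configuration in YAML or JSON with keys exactly
#' `mode, M, N, kappa1_plus, kappa1_minus, kappa1_ominus, kappa1_oplus,
#' kappa2, nu2, kappa3, nu3` (keys irrelevant to the mode may be omitted).
#' Unknown keys are rejected.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return `read_model_config()`: a [model_spec()].
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `N` as a boolean; the only schema key it can
  # swallow that way is the scaling parameter, so map it back
  names(cfg)[names(cfg) %in% c("TRUE", "FALSE")] <- "N"
  allowed <- c("mode", "M", "N", .rate_fields)
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$mode)) stop("config key 'mode' is required", call. = FALSE)
  args <- cfg[setdiff(names(cfg), "mode")]
  do.call(model_spec, c(list(mode = cfg$mode), args))
}

#' @rdname read_model_config
#' @param spec a [model_spec()] to serialize.
#' @export
write_model_config <- function(spec, path) {
  p <- spec$params[!vapply(spec$params, is.null, logical(1))]
  cfg <- c(list(mode = spec$mode, M = spec$M, N = spec$N), p)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}
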