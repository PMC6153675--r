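---
title: "Quantifying intrinsic noise in autoregulated gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrinsic noise in autoregulated gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanoreg)
```

## The model

`fanoreg` works with the standard three-stage model of gene expression. A
gene with $M$ copies switches between an inactive (*off*) and an active
(*on*) state; active copies are transcribed into mRNA ($R$), transcripts are
translated into protein ($P$), and both molecules are degraded at constant
per-molecule rates. Six reaction channels result: activation, deactivation,
transcription, mRNA decay, translation, protein decay.

Autoregulation acts at the switching step and the regulator is catalytic —
it is not consumed by binding:

* **neutral**: activation at rate $\kappa_1^+$ per inactive copy,
  deactivation at $\kappa_1^-$ per active copy;
* **negative feedback**: deactivation is protein-dependent,
  $\kappa_1^\ominus v_P$ per active copy;
* **positive feedback**: activation is protein-dependent,
  $\kappa_1^\oplus v_P$ per inactive copy.

Protein is abundant while gene and mRNA copies are few. The package encodes
this with a system-size parameter $N$: the protein count is
$X_P = N v_P = O(N)$, gene and mRNA counts are $O(1)$, and gene switching
and mRNA turnover run at rates of order $N$ — a time-scale separation under
which the fast species reach quasi-stationarity between protein events.
Rates are stored in scaled form ($\kappa$'s and $\nu$'s, all $O(1)$); the
simulator uses the raw propensity constants
$\lambda_1^\pm = N\kappa_1^\pm$, $\lambda_2 = N\kappa_2$,
$\mu_2 = N\nu_2$, $\lambda_3 = N\kappa_3$, while
$\lambda_1^\ominus = \kappa_1^\ominus$, $\lambda_1^\oplus = \kappa_1^\oplus$
and $\mu_3 = \nu_3$ are not rescaled.

## Deterministic limit

Averaging the fast subsystem at frozen protein level $v$ gives the mean
active-gene count $\mathbb{E}_\pi[V_{on}](v) = M a(v)/(a(v)+d(v))$, with
$(a, d)$ the per-copy on/off rates of the active wiring, and the mean
transcript count $\mathbb{E}_\pi[V_R] = (\kappa_2/\nu_2)\,
\mathbb{E}_\pi[V_{on}]$. As $N \to \infty$ the scaled protein level follows

$$\dot v_P = F(v_P) = \kappa_3\,\mathbb{E}_\pi[V_R](v_P) - \nu_3 v_P .$$

`equilibrium()` solves $F(v_P^*) = 0$ in closed form: a linear equation for
the neutral model, the positive root of
$v^2 + (\kappa_1^+/\kappa_1^\ominus)v - M\kappa_1^+\kappa_2\kappa_3/
(\kappa_1^\ominus\nu_2\nu_3) = 0$ under negative feedback (evaluated as
$2c/(b+\sqrt{b^2+4c})$, which stays accurate as
$\kappa_1^\ominus \to 0$ where the textbook root formula cancels
catastrophically), and
$v_P^* = M\kappa_2\kappa_3/(\nu_2\nu_3) - \kappa_1^-/\kappa_1^\oplus$ under
positive feedback. The positive-feedback drift always has a second
equilibrium at $v = 0$; when the positive branch does not exist the result
carries a `degenerate` flag rather than silently reporting extinction,
because the fluctuation expansion below is built around the positive branch
and has nothing to say about the extinct state. Every root is gated by a
residual check $|F(v_P^*)| \le 10^{-10}\max(1, \nu_3 v_P^*)$.

## Fluctuation theory

A naive Langevin closure adds noise $\sqrt{b(v)}\,dW$ with
$b(v) = \kappa_3\mathbb{E}_\pi[V_R] + \nu_3 v$ — the averaged birth and
death fluxes of the protein itself. Averaging first and adding noise second
discards the fluctuations *of the averaged species*, so $b$ understates the
noise whenever the gene switches or transcripts are finite-lived
(`langevin_b()` is kept as a comparator and the package asserts
$b(v_P^*) < c(v_P^*)$ throughout).

The correct central-limit description of
$U = \sqrt{N}(V_P^N - v_P)$ is an Ornstein–Uhlenbeck process
$dU = F'(v_P)U\,dt + \sqrt{c(v_P)}\,dW$ whose diffusion coefficient
collects all three leading-order noise sources:

$$c(v) \;=\; \underbrace{\kappa_3\mathbb{E}_\pi[V_R] + \nu_3
v}_{\text{protein birth–death}}
\;+\; \underbrace{\tfrac{2\kappa_3^2}{\nu_2}\,
\mathbb{E}_\pi[V_R]}_{\text{mRNA turnover}}
\;+\; \underbrace{2\Big(\tfrac{\kappa_2\kappa_3}{\nu_2}\Big)^{2}
\frac{M\,a(v)\,d(v)}{(a(v)+d(v))^{3}}}_{\text{gene telegraph}} .$$

At the equilibrium, the stationary OU variance gives the Fano factor of the
protein *count* (dimensionless, no factor of $N$):

$$\frac{\mathbb{V}[X_P]}{\mathbb{E}[X_P]} \approx
-\frac{c(v_P^*)}{2F'(v_P^*)\,v_P^*}
= \frac{1 + \kappa_3/\nu_2 + \text{gene term}}{-F'(v_P^*)/\nu_3}.$$

`fano_equilibrium()` computes the number through **both** routes and fails
if they disagree beyond $10^{-10}$ relative — a deliberate internal
cross-check, since the additive decomposition (protein $=1$, mRNA
$=\kappa_3/\nu_2$, gene telegraph, feedback denominator
$-F'(v_P^*)/\nu_3$) is the biologically interpretable form while
$-c/(2F'v^*)$ is the form the OU theory delivers. The closed form of $c$
was additionally required, before being trusted, to reproduce two
independent anchors: the exact neutral-model decomposition of Paulsson in
the fast-gene/fast-mRNA regime (`fano_paulsson()`), and the fully explicit
repressed-model expression

$$\frac{\mathbb{V}[X_P]}{\mathbb{E}[X_P]} =
\left(\frac{\kappa_1^\ominus v_P^*\,\kappa_2\kappa_3}
{(\kappa_1^+ + \kappa_1^\ominus v_P^*)^2\,\nu_2} +
\frac{\kappa_3}{\nu_2} + 1\right)
\Big/\left(1 + \frac{\kappa_1^\ominus v_P^*}
{\kappa_1^\ominus v_P^* + \kappa_1^+}\right),$$

which the test suite re-evaluates independently for hundreds of random
parameter sets; exact stochastic simulation provides the third, external
anchor.

```{r fano}
neutral <- model_spec("neutral", kappa1_plus = 10, kappa1_minus = 2,
                      kappa2 = 3, nu2 = 1, kappa3 = 5, nu3 = 1, N = 100)
fano_equilibrium(neutral)
```

## Matched comparison of feedback variants

Comparing wirings is only fair at equal protein abundance.
`matched_specs()` sets $\kappa_1^\ominus = \kappa_1^-/v_P^*$ and
$\kappa_1^\oplus = \kappa_1^+/v_P^*$, which makes all three models share
$v_P^*$ — and, because the switching rates then coincide at the
equilibrium, the same $c(v_P^*)$. Only the relaxation speed $F'(v_P^*)$
differs, so with $q = \kappa_1^-/(\kappa_1^- + \kappa_1^+)$ the neutral
off-state occupancy,

$$\frac{\mathbb{V}_\ominus}{\mathbb{V}_\varnothing} = \frac{1}{1+q},
\qquad
\frac{\mathbb{V}_\oplus}{\mathbb{V}_\varnothing} = \frac{1}{1-q}.$$

Negative feedback reduces the variance by at most a factor of 2 (attained
as the gene is off almost always, $q \to 1$), while positive feedback can
amplify noise without bound. The same denominator also bounds the repressed
Fano factor below by $1/2$ — values below that (the infra-Fano regime)
require protein scarcity, outside this scaling, and are reached instead by
the low-abundance birth–death law implemented in `dessalles_stationary()`.

```{r matched}
m <- matched_specs(neutral)
c(neutral = fano_equilibrium(neutral)$fano,
  negative = fano_equilibrium(m$negative)$fano,
  positive = fano_equilibrium(m$positive)$fano)
variance_comparison(neutral)[c("q", "var_ratio_negative", "var_ratio_positive")]
```

## The exact simulator as ground truth

Because every analytic object in the package is an $N \to \infty$ limit,
the package carries its own ground truth: a direct-method Gillespie
simulator of the full jump process (compiled, using R's RNG stream so that
`set.seed()` reproduces trajectories bit-for-bit). `ensemble_stats()`
summarizes replicate ensembles with bootstrap standard errors, and every
closed form above is required in the tests to sit within 3 standard errors
of its simulated counterpart at $N = 100$.

Simulation choices, made once:

* **Initial condition** for equilibrium ensembles: protein at
  $\mathrm{round}(Nv_P^*)$, mRNA at its rounded fast-equilibrium mean, each
  gene copy on with probability $\mathbb{E}_\pi[V_{on}]/M$ — starting at
  the deterministic equilibrium minimizes burn-in.
* **Horizon** $T = 15/\nu_3$ with endpoint sampling: ten-plus protein
  lifetimes relax the slowest mode (rate $|F'(v_P^*)| \ge \nu_3(1-q)$ is
  slowest under positive feedback, which is why a generous horizon is the
  default). Time-average sampling over $[5/\nu_3, T]$ is available, and the
  tests require the two schemes to agree within error.
* **Seeds**: one master seed; replicate $k$ uses a counter-derived seed, so
  any replicate can be rerun alone.
* **Absorption**: positive-feedback trajectories that reach zero protein
  with all genes off are frozen, retained in the ensemble, counted, and a
  warning fires above 1% absorbed — the OU theory describes fluctuation
  around the positive equilibrium only.

The two-species reduction (`simulate_simple()`, `fano_simple()`) removes
the mRNA stage while preserving the protein flux
($\lambda_3^{\mathrm{eff}} = \lambda_3\lambda_2/\mu_2$). It realizes the
fast-mRNA-turnover limit $\nu_2 = \kappa_2 \to \infty$: the deterministic
equilibrium and the gene telegraph term are untouched (both depend on the
mRNA stage only through $\kappa_2/\nu_2$), the explicit mRNA term
$\kappa_3/\nu_2$ vanishes, and the two-species Fano factor is strictly
smaller than the full model's.

## Reference formulas

Three classical results are implemented for comparison, not as the
package's own machinery:

* `fano_paulsson()` — the exact unregulated Fano factor in raw rates, with
  no time-scale assumptions; it converges to the package's neutral formula
  as the protein becomes long-lived relative to gene and mRNA.
* `fano_thattai()` — the linearization of weak repression,
  $(1+\kappa_3/\nu_2)(1-\kappa_1^\ominus v_P^*/\kappa_1^+)$. It carries no
  gene-switching noise and distorts the feedback correction, so it
  systematically *underestimates* the exact value; the package warns when
  $\kappa_1^\ominus v_P^*/\kappa_1^+ > 0.2$ (the asymptotic validity
  condition is only stated as $\ll 1$; 0.2 is this package's practical
  threshold).
* `dessalles_stationary()` — the stationary birth–death law of the
  low-abundance scaling under repression,
  $\pi(n) \propto \prod_{i<n} \rho/\big((i+1)(i+\lambda_1^+/
  \lambda_1^\ominus)\big)$ with
  $\rho = \lambda_1^+\lambda_2\lambda_3/(\lambda_1^\ominus\mu_2\mu_3)$.
  Probabilities are accumulated in log space (the raw products overflow
  quickly) and the truncation grows adaptively until the mass at the cut is
  below $10^{-12}$. For $\rho \to \infty$ its Fano factor approaches $1/2$,
  meeting the fluctuation theory from the other side of the abundance
  divide; for $\lambda_1^\ominus \gg \lambda_1^+$ it drops below $1/2$
  (infra-Fano), which the abundant-protein theory cannot reach —
  `regime_classify()` makes that distinction explicit.

## What the built-in experiments do and do not show

`sweep_matched_fano()` varies the deactivation rate at a fixed target mean
(back-solving $\kappa_1^+$ each time) and compares the analytic Fano
triplet with simulated ensembles; `sweep_feedback_strength()` varies the
repression constant at fixed activation and traces mean against Fano
factor, with the linearized comparator alongside. Default grids reproduce
the package's two canonical operating points (protein means 1250 and 60 at
$N = 100$).

The generator emulates *intrinsic* noise only: a single cell with fixed
rate constants. It does not emulate extrinsic rate fluctuations, cell
growth and division, replication of the gene copy, or translational
autoregulation. Agreement of theory and simulation here therefore validates
the mathematics of this reaction network, not the completeness of the
network as a description of any particular organism.

Problem sizes used by the shipped tests and the acceptance script — 1000
replicates per ensemble for the headline means and sweep gates (the
reduced smoke paths use 2–400), $10^4$-point grids for the factor-2 bound,
$10^5$ random parameter sets for the Fano lower bound — were chosen as the
sizes at which the Monte-Carlo standard errors are small enough for the
3-SE gates to be informative.

## Known limitations

* The gene-telegraph term of $c(v)$ scales linearly in $M$ (independent
  switching of identical copies). All validation uses $M = 1$; the
  $M$-linear choice is untested against simulation for $M > 1$.
* The equilibrium Fano factor exchanges the long-time and large-$N$ limits;
  this is recorded in each `noise_report` as an approximation note.
* The refined expansion in which mRNA is slow and abundant (and
  cross-terms between transcript and protein fluctuations appear) is not
  implemented; in the regimes covered here protein lifetimes dominate and
  the standard formula is the better fit.
* Under positive feedback the theory is silent on extinction; the package
  surfaces absorption as data (flags, counts, warnings) and leaves the
  interpretation to the user.
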