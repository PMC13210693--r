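---
title: "Methods: residual-error coding, FOCE-I, and diagnostic residuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual-error coding, FOCE-I, and diagnostic residuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model, the nine `$ERROR`-block coding variants, the
estimation algorithm, and the numerical choices made in `ruvdiag`. It is a
methods reference; the README shows the worked example.

## 1. The problem

In NONMEM-style `$ERROR` blocks the observation equation

```
Y = IPRED + W*EPS(1)
```

plays two roles at once. The distribution of `Y` implies the residual variance
that enters the likelihood, while the variable `W` is also (by convention,
`IWRES = (DV - IPRED)/W`) the scale used to weight individual residuals. The
two can be coded inconsistently: the likelihood may be identical across two
codings while `W` — and hence IWRES — differs. `ruvdiag` implements nine coding
variants, an estimator, and the full set of diagnostic residuals so that this
artifact can be produced, measured, and compared cleanly.

Each coding object therefore carries two separate functions:

* `variance_fn(ipred, params)` — the residual variance `v` implied by `Y`,
  used everywhere the likelihood is needed (estimation, WRES, CWRESI);
* `w_fn(ipred, params)` — the diagnostic scale `W`, used **only** for
  `IWRES = IRES / W`.

For the *normalized* codings `W^2 == v` identically. The non-normalized
variants (`W = 1` for additive, `W = IPRED` for proportional) omit the
estimated variance component from `W`; that omission is the artifact under
study. The registry (`error_codings()`):

| id | structure | parameters | W |
|---|---|---|---|
| `ADD.1` | additive | `SIGMA(1,1)` (variance) | `sqrt(SIGMA(1,1))` |
| `ADD.2` | additive | `SIGMA(1,1)` (variance) | `1` |
| `ADD.3` | additive | `THETA(4)` (SD), `$SIGMA 1 FIX` | `THETA(4)` |
| `PROP.1` | proportional | `SIGMA(1,1)` | `IPRED*sqrt(SIGMA(1,1))` |
| `PROP.2` | proportional | `SIGMA(1,1)` | `IPRED` |
| `PROP.3` | proportional | `THETA(4)`, `$SIGMA 1 FIX` | `IPRED*THETA(4)` |
| `COMB_VAR1` | combined | `SIGMA(1,1)`, `SIGMA(2,2)` (two EPS) | `sqrt(IPRED^2*S11 + S22)` |
| `COMB_VAR3` | combined | `THETA(4)`, `THETA(5)`, `$SIGMA 1 FIX` | `sqrt(IPRED^2*T4^2 + T5^2)` |
| `COMB_SD` | combined | `THETA(4)`, `THETA(5)`, `$SIGMA 1 FIX` | `T4*IPRED + T5` |

`COMB_VAR1` and `COMB_VAR3` parameterize the same variance model (variance
scale vs SD scale), so their fits coincide. `COMB_SD` uses a *linear-in-IPRED
standard deviation*; since `(a+b)^2 >= a^2+b^2`, it overstates the combined SD
everywhere except `IPRED = 0`, most severely at low concentrations — which is
where its IWRES diverges from the variance-based codings.

## 2. Structural and statistical model

One-compartment, first-order absorption, single oral dose, parameterized as
apparent clearance `CL/F`, apparent volume `V/F`, and absorption rate `KA`:

$$C(t) = \frac{D\,k_a}{V (k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right),
  \qquad k_e = CL/V.$$

Between-subject variability is log-normal on CL and V
(`CL_i = TVCL e^{\eta_{1i}}`, `V_i = TVV e^{\eta_{2i}}`), with a diagonal
`Omega = diag(omega2_cl, omega2_v)`. KA is fixed during estimation.

Numerical choices:

* The closed form is evaluated as
  `C = (D ka / V) e^{-ka t} \, t \, \mathrm{expm1}(u)/u` with
  `u = (ka - ke) t`, which is exact and passes smoothly through the flip-flop
  point `ka = ke` (limit `t`), avoiding catastrophic cancellation.
* The sensitivities `dC/d\eta` used by the linearization are analytic. The
  kernel `g(u) = (\mathrm{expm1}(u) - u e^u)/u^2` is replaced by its series
  `-(1/2 + u/3 + u^2/8 + u^3/30)` for `|u| < 10^{-4}`.

## 3. The simulated study

`sim_protocol()` defaults encode the study conditions: 500 subjects, one
100 mg dose, 12 samples at 0.25–24 h, `TVCL = 5` L/h, `TVV = 50` L,
`KA = 1` /h, `omega2 = 0.09` on both CL and V, and per error structure:
additive SD 0.5 mg/L; proportional CV 20%; combined CV 15% + additive SD
0.5 mg/L (two independent noise terms). Simulated concentrations below
0.001 mg/L are truncated to that floor (`apply_floor()`), and the count of
affected records is reported.

Reproducibility: a single RNG stream is seeded once per dataset
(`withr::local_seed`) with a fixed draw order — both `eta` columns first, then
the noise terms in subject-major order. An identical protocol object always
reproduces the identical dataset. (A per-subject sub-stream scheme would give
the same contract with more machinery; the single stream was chosen
deliberately.)

Scope and realism limits of the generator: single dose, a common sampling grid
for all subjects, no covariates, no BSV on KA, uncorrelated `eta`, and plain
truncation (not the censored-likelihood treatment a real below-limit-of-
quantification analysis would use). The truncation matters: clipping negative
pre-floor values thins the lower tail of the residual distribution exactly
where the additive error dominates, which biases additive/combined residual
variance estimates downward and proportional components upward (see §7).

## 4. Estimation: FOCE with interaction

The estimator is first-order conditional estimation with interaction.

**Inner problem.** Per subject, the empirical Bayes (MAP) `eta` minimizes
$$q_i(\eta) = \sum_j \left[\log v_{ij}(\eta) +
  \frac{(y_{ij}-f_{ij}(\eta))^2}{v_{ij}(\eta)}\right] + \eta^\top\Omega^{-1}\eta,$$
with `v` evaluated at the conditional prediction (the “interaction”). It is
solved for all subjects simultaneously by a damped Fisher-scoring Newton
iteration on subject-contiguous long vectors (`rowsum()` reductions):

* per-observation curvature weight `2/v + (v'/v)^2` (mean-model plus
  variance-model information), giving a symmetric positive-definite 2×2
  Hessian solved in closed form;
* a two-point line search (full and half Newton step) followed by up to 20
  backtracking halvings; the half step damps the sign-oscillation a scoring
  direction can produce when true curvature exceeds the scoring approximation;
* an active-subset mask so converged subjects cost nothing; subjects for which
  no improving step exists are frozen at their current value;
* gradient tolerance `1e-8`, at most 100 iterations;
* warm starts: each subject restarts from the better of the carried-over
  `eta` and the prior mode `0`, so a stale warm start can never trap the
  solver in a bad basin.

**Outer problem.** The objective is the standard FOCE-I approximation to
`-2 log L` (the `n log 2pi` constant excluded, following the OFV convention —
only OFV differences are ever interpreted):
$$\mathrm{OFV} = \sum_i \left[\log\det V_i + r_i^\top V_i^{-1} r_i\right],
  \qquad V_i = J_i \Omega J_i^\top + \mathrm{diag}(v_{ij}(\hat\eta_i)),$$
with `r_i = y_i - f_i(\hat\eta_i) + J_i \hat\eta_i`. The determinant and
quadratic form use the matrix determinant lemma and Woodbury identity, so only
`k×k` (`k <= 2`) systems are formed, vectorized across subjects.

All parameters are log-transformed (positivity by construction) and minimized
by BFGS (`stats::optim`, `reltol 1e-10`, finite-difference step `1e-5`),
followed by up to two Newton polishing steps on a central finite-difference
gradient (step `1e-5`) and Hessian (step `1e-4`) of the objective with a
frozen warm-start cache. The gradient step is deliberately coarse: below
`~1e-5` the inner-solve tolerance (`1e-8` in the objective) dominates the
difference quotient. Standard errors come from the inverse of half the OFV
Hessian on the log scale, delta-methoded back (`se = estimate * se_log`);
convergence requires `optim` code 0 and a final gradient below 0.1.

## 5. Diagnostic residuals

With `f` the model prediction, `J` the eta-Jacobian, and `v` the coding's
variance function:

* **Individual (conditional):** `IPRED = f(etahat)`, `IRES = DV - IPRED`,
  `IWRES = IRES / W(IPRED)` — the only place `W` enters.
* **Population (first order):** `PRED = f(0)`, `RES = DV - PRED`,
  `WRES_i = L_0^{-1}(y_i - PRED_i)` with
  `V_0 = J(0)\,\Omega\,J(0)^\top + diag(v(PRED))`.
* **Conditional with interaction:**
  `CWRESI_i = L^{-1}(y_i - E_i)`, `E = f(etahat) - J(etahat)\,etahat`, with
  `V` evaluated at the conditional predictions.

`L` is the lower-triangular Cholesky factor of `V` (forward substitution).
Per-observation values of whitened residuals depend on this decorrelation
convention; summary statistics (SD, correlations across runs computed with the
same convention) do not.

`epsilon_shrinkage()` is `1 - SD(IWRES)`: shrinkage of the empirical Bayes
etas compresses IWRES towards zero, so even a correctly normalized IWRES has
SD slightly below 1.

Because `nm_diagnostics()` accepts any parameter point (not only a fitted
optimum), the pure effect of a `W` redefinition can be isolated by holding the
parameters fixed and swapping the coding: WRES and CWRESI are then *identical*
between codings that share a variance function, while IWRES rescales by
exactly the omitted factor.

## 6. Comparisons and the study orchestrator

`compare_runs()` aligns two diagnostics tables on `(ID, TIME)` and summarizes
the per-observation IWRES ratio (mean, SD, range), Pearson correlations of
IWRES/WRES/CWRESI, maximum absolute WRES/CWRESI differences, the
back-calculated implicit scaling factor `IRES/IWRES` of the second run, and
the count of extreme ratios. Conventions fixed here:

* ratios with reference `|IWRES| < 1e-12` are excluded and counted
  (`n_ratio_excluded`) — a 0/0 guard the source material leaves unspecified;
* the extreme threshold is `|ratio| > 5`.

`run_study()` simulates the three datasets (seeds `seed`, `seed+1`,
`seed+2`), fits all nine codings from truth-inflated initial estimates
(default ×1.2; variance-scale slots are inflated by the square so all codings
start at the same SD-scale point), and assembles per-run estimates (panel A),
residual summary statistics (panel B), eight pairwise comparisons — each
coding against the normalized reference of its group (`ADD.1`, `PROP.1`,
`COMB_VAR1`), plus `COMB_SD` vs `COMB_VAR3` and the cross-model `ADD.2` vs
`PROP.1` overlay — and figure-ready data series. A failed fit is logged and
skipped; the study continues. `write_study()` emits everything as CSV plus a
run log.

## 7. Problem sizes and known limitations

Default problem sizes are the package's own choice: the full protocol
(500 subjects × 12 samples) runs each fit in roughly 40–60 s on one CPU;
the test suite uses 10–100 subjects for unit properties and the full 500 for
end-to-end checks.

Known limitations, deliberate and observed:

* **Truncation bias.** With the 0.001 mg/L floor, residual-error components
  are not recovered at their generating values: the additive SD estimates low
  (≈0.47 vs 0.5) and the combined model trades additive for proportional
  error (CV estimates high). This is a property of estimating untruncated
  likelihoods on truncated data, not of the optimizer: an exact
  adaptive-Gauss-Hermite marginal MLE on the same data lands on essentially
  the same values, and the empirical residual variance of the simulated data
  matches the model variance only where truncation is rare.
* **FOCE is an approximation.** The linearization is exact for linear models
  (the test suite exploits this with a random-intercept oracle) but
  approximate here; estimates can differ slightly from exact-likelihood
  implementations, and `ΔOFV` across non-nested parameterizations is not a
  fit criterion.
* **No covariance step extras**: standard errors are asymptotic, from the OFV
  Hessian only (no sandwich estimator).
* KA is fixed, `Omega` is diagonal, and only single-dose, one-compartment
  designs are generated.
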