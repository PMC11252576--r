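---
title: "Fractal-fractional dynamics of Alzheimer's disease cell populations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal-fractional dynamics of Alzheimer's disease cell populations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracAD)
```

## The model and its assumptions

fracAD simulates a linear compartmental model of Alzheimer's pathology with
seven populations — reactive (R) and quiescent (Q) astrocytes, amyloid-β
fibrils (Aβ), pro- (Ip) and anti-inflammatory (Ia) microglia, surviving (S)
and dead (D) neurons — coupled by sixteen signed crosstalk pathways
(activation and suppression) plus an amyloid clearance rate. The model
assumes a constant risk of neuronal degeneration, neglects spatial dispersion
of cells and fibrils, and is deliberately linear and unclamped: populations
are allowed to go negative (the solver warns the first time one does), since
clamping would destroy both the linearity and the conservation structure.

Three structural facts follow from the pairwise antisymmetric equations and
are exploited throughout:

* R+Q, Ip+Ia and S+D are conserved exactly;
* the system is equivalent to `y' = M y` with a 7×7 rate matrix
  (`ad_matrix()`) whose paired rows sum to zero;
* the dynamics are linear in the initial state.

The right-hand side computes the second member of each pair as the explicit
floating-point negation of the first, so the antisymmetry — and hence the
pair-sum conservation of any linear update — holds bit-exactly, not merely
to truncation error.

## Parameters

All seventeen rates are in 1/year (`ad_parameters()`), time is in years, and
populations are dimensionless counts. The defaults are the published rate
table: λ15 = 1 (amyloid production by surviving neurons) and λr = 1 (amyloid
clearance) dominate; the remaining rates range from 1e-5 to 1e-2. One table
quirk is worth flagging rather than silently absorbing: the printed pathway
label of λr duplicates λ16's ("Ia suppresses Aβ"), but the equations apply
λr to Aβ itself, so it is implemented as the fibril self-clearance rate.
The default initial state (`ad_initial_state()`) is R = 10³, Q = 10⁵,
Aβ = 10³, Ip = 10³, Ia = 10⁵, S = 10⁴, D = 10², and the default horizon is
20 years with step l = 0.05 years — small enough that halving it moves the
20-year integer-order endpoint by less than one count.

## The fractal-fractional operator and the scheme

The fractal-fractional Caputo derivative of order p composes a power-law
memory kernel with differentiation with respect to t^q; its inverse is the
Volterra operator

$$y(t) = y_0 + \frac{q}{\Gamma(p)} \int_0^t s^{q-1}(t-s)^{p-1}\, h(s, y(s))\, ds .$$

`solve_ff()` discretizes this on a uniform grid by two-point Lagrange
interpolation of the product $s^{q-1} h(s, y(s))$ over each panel, which
yields the explicit two-step update with closed-form bracket weights

$$w_A = (m+p+2-n)(1+m-n)^p - (m+2p+2-n)(m-n)^p, \qquad
  w_B = (m+1-n)^{p+1} - (m+1+p-n)(m-n)^p$$

and prefactor $q\,l^p/\Gamma(p+2)$. The weights depend only on the lag
$m-n$; at $p=1$ they collapse to the classical Adams–Bashforth pair (3, 1),
and a telescoping identity $w_A - w_B = (p+1)[(k+1)^p - k^p]$ makes the
scheme exact for constant forcing when $q = 1$ — both facts are asserted in
the test suite rather than assumed.

### Numerical choices

* **t = 0 singularity.** For q < 1 the fractal weight $t^{q-1}$ is infinite
  at the first node. It is regularized by the *first-panel mean* of
  $s^{q-1}$, i.e. $l^{q-1}/q$. The more obvious endpoint value $l^{q-1}$
  was implemented first and rejected on measurement: it underweights the
  first panel by a factor q and roughly doubles the endpoint error of the
  Beta closed-form benchmark (worst case 2.4e-2 vs 1.1e-2 at l = 0.01 over
  (p, q) ∈ {0.6, 0.8, 1}²). The panel mean is exactly inert at q = 1 and
  perturbs only the first panel.
* **History node.** The n = 0 term of the memory sum references the
  pre-grid pair $(t_{-1}, Y_{-1})$; it is taken by constant extrapolation
  as $(t_0, Y_0)$, the standard two-step starter, which preserves exactness
  for constant integrands.
* **Cumulative form.** Each step recomputes the full memory sum from $Y_0$
  (O(n²) total work) instead of updating incrementally. This is the literal
  form of the scheme, it keeps the conservation argument exact per step,
  and at desk scale (n ≤ a few thousand) the vectorized inner products make
  it cheap.
* **Determinism.** No randomness anywhere; fixed summation order in
  increasing n; double precision throughout. Identical inputs give
  bit-identical trajectories.
* **$0^p$** is evaluated as 0 for p > 0 (the limit the derivation assumes;
  R's native behaviour).
* **Degenerate inputs.** A zero-step or out-of-range order is an error; a
  zero-length horizon returns the single initial node; a non-finite state
  aborts with the offending step index.

## Oracles: what validates the solver

The solver is never compared against itself alone. Four independent
references are used, each in its own regime:

1. **Matrix exponential** (`expm_solution`, via `Matrix::expm`): the exact
   integer-order solution $e^{Mt} y_0$, for the p = q = 1 limit, where the
   scheme must converge at second order.
2. **Mittag–Leffler function** (`mittag_leffler`): the q = 1 scalar
   relaxation $y_0 E_p(\lambda t^p)$. The series is summed to 1e-14 with a
   10,000-term cap; beyond |z| = 30, where double-precision cancellation
   kills the series, the standard exponential/algebraic asymptotic
   expansion with optimal truncation takes over (no arbitrary-precision
   arithmetic is available in this stack; all solver validations use
   |z| ≤ ~5, well inside the series regime, and the series is itself
   checked against the closed form $E_{1/2}(-x) = e^{x^2}\mathrm{erfc}(x)$).
3. **Beta closed forms** (`power_forcing_exact`): for forcing $c\,t^a$ the
   Volterra equation integrates exactly to
   $y_0 + c\,(q/\Gamma(p)) B(q+a, p)\, t^{p+q+a-1}$, giving a ground truth
   at *general* (p, q).
4. **Fine-grid self-reference** (`fine_grid_reference`) for the fully
   general case, with the empirical convergence order reported by
   `convergence_study()`. The weakly singular kernel degrades the nominal
   second order near t = 0; the measured global order on the AD model at
   (p, q) = (0.9, 0.9) is ≈ 1.2, and halving the step reliably shrinks the
   endpoint error by well over the 1.8× the tests demand.

A deliberate omission: no matrix Mittag–Leffler function. The AD rate
matrix is singular (three zero row-pair sums), which makes an
eigendecomposition-based matrix function fragile; scalar decoupling of
diagonal test problems validates the scheme just as well.

## Stability machinery

With the summed-components state norm, the Lipschitz constant of the linear
right-hand side is the induced 1-norm (maximum absolute column sum); for
the default rates both the Aβ and S columns attain it, X_Θ = 1.04/year.
The contraction constant is

$$\Xi = \frac{q\, X_\Theta\, T^{p+q-1}\, B(p,q)}{\Gamma(p)},$$

and $C_{p,q} = \Xi|_{X_\Theta = 1}$. One typographic conflict in the source
derivation chain had to be resolved: the uniqueness theorem prints
$\Gamma(q)$ in the denominator while every neighbouring bound uses
$\Gamma(p)$; this package uses $\Gamma(p)$ everywhere for internal
consistency (at the equal-order cases p = q the choice is immaterial). The
horizon symbol in those bounds is read as the interval length T, the only
dimensionally coherent reading.

`uh_report()` reports the certificate honestly: with the default rates,
$\Xi < 1$ holds only for T < 1/1.04 ≈ 0.96 years at p = q = 1, so the
20-year simulations are *not* covered by the contraction certificate —
non-certification is a reported state, not an error, and no bound factor is
fabricated for it.

## The sweep, and what the order dependence actually looks like

`ff_sweep()` mirrors the published experiments: an equal-order preset
(p = q ∈ {0.80, 0.85, 0.90, 0.95, 1.00}) and a mixed-order preset with
p ≠ q. The source study does not print its exact step size or order values
behind its figures, so these presets are this package's choices, labelled
as such and overridable.

The measured order dependence deserves a plain statement. The integer-order
system drives Aβ to a saturation level near 8.9·10³; a power-law memory
kernel with p < 1 slows the approach to that level, so at any fixed time
the fibril load *increases* monotonically as (p, q) → (1, 1) — at t = 20
the equal-order endpoints run 8533, 8725, 8832, 8884, 8907. This was
cross-checked against an independent L1 Caputo discretization, which
reproduces both the ordering and the integer-order endpoint to 0.1. The
narrative this package inherited asserts the opposite ordering ("the fibril
population decreases as the orders approach unity"); the corresponding
acceptance check is retained exactly as stated and fails, and the measured
behaviour is pinned by its own passing test. What *is* true near the
integer order is a temporal decrease: at p = q = 1 the Aβ trajectory peaks
near t = 10 and declines afterwards, while at p = q = 0.8 it is still
rising at t = 20. Neuronal loss tracks fibril load throughout (S(20) is
smallest at the integer order), so the simulated world is internally
consistent.

## Limitations

* The model is linear; it cannot saturate, oscillate nonlinearly, or keep
  populations non-negative, and negative excursions do occur late in the
  default run (the solver warns once).
* The scheme is explicit with no adaptive stepping; only the power-law
  (Caputo-sense) kernel is implemented — no Mittag–Leffler or
  exponential-kernel fractal-fractional operators.
* The contraction-based stability certificate is sufficient, not necessary:
  $\Xi \ge 1$ on long horizons says the argument is inconclusive there, not
  that the system is unstable.
* Green tests establish agreement with the stated rates, initial
  conditions and closed-form/independent references — not fidelity to any
  clinical data; the model was never fitted to any.
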