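---
title: "Homotopy decomposition series for the 1-D Keller-Segel system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homotopy decomposition series for the 1-D Keller-Segel system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmks)
```

## The model

The one-dimensional Keller-Segel system couples the density $u(x,t)$ of
chemotactic cells (classically, slime-mold amoebae) to the concentration
$\rho(x,t)$ of the chemoattractant they secrete and follow:

$$
u_t = a\,u_{xx} - \partial_x\!\bigl(u\,\partial_x \chi(\rho)\bigr), \qquad
\rho_t = b\,\rho_{xx} + c\,u - d\,\rho,
$$

on a bounded interval with zero-flux Neumann boundaries
($u_x = \rho_x = 0$ at both endpoints) and initial data $u(x,0) = u_0(x)$,
$\rho(x,0) = \rho_0(x)$.  Here $a, b$ are diffusivities, $c$ is the rate at
which cells produce the chemical and $d$ its decay rate; the sensitivity
function $\chi(\rho)$ encodes how strongly cells respond to the chemical
gradient.  The package supports $\chi = 1$ (no chemotaxis: the cell equation
decouples into pure diffusion), $\chi = \rho$, $\chi = \rho^2$, and — through
the fully general He-polynomial path only — arbitrary smooth $\chi$.

## The homotopy decomposition recursion

The method inverts the time derivative with the Abel-kernel operator
$\mathcal{I}^m g = \tfrac{1}{(m-1)!}\int_0^t (t-\tau)^{m-1} g(x,\tau)\,
d\tau$ (the single-integral form of $m$-fold integration), embeds the
solution in a power series of a homotopy parameter $p \in (0,1]$,
$U = \sum_n p^n U_n$, expands the nonlinearity in He polynomials

$$
H_n(U_0,\dots,U_n) = \frac{1}{n!}\,\frac{\partial^n}{\partial p^n}
N\Bigl(\sum_j p^j U_j\Bigr)\Big|_{p=0},
$$

and matches powers of $p$.  The order-0 term is the time-Taylor polynomial
of the initial data (for first-order-in-time problems, simply $u_0(x)$);
the order-$n$ term is $\mathcal{I}^m$ applied to
$L(U_{n-1}) + H_{n-1} + [n{=}1]\,f$.  Although the defining sum for the
nonlinear term is sometimes written starting at $n = 1$, $H_0$ is defined
and required: the recursion must start the nonlinear ladder at order 0 to
reproduce every worked term, and that is what the package does.

For the Keller-Segel system the chemical equation is linear, so its
recursion is simply
$\rho_n = \int_0^t\! \bigl(b\,\rho_{n-1,xx} + c\,u_{n-1} - d\,\rho_{n-1}\bigr)\,d\tau$;
the chemotactic term in the cell equation is bilinear ($\chi = \rho$) or
trilinear ($\chi = \rho^2$) in the fields, and its He polynomials reduce to
discrete (for $\rho^2$: double) convolutions over term orders.  The package
implements both that convolution path and the defining $p$-extraction
(`he_polynomial_bruteforce()`), keeps them as mutually checking routes in
the test suite, and additionally ships `he_polynomial_quoted()`, a
`stats::D()`-based construction that handles non-polynomial sensitivities
(e.g. $\log\rho$, $\rho/(\rho+1)$) at the price of returning raw R
expressions suitable for numeric work only.

## Two sign conventions, on purpose

Expanding the divergence-form chemotactic term gives
$-\partial_x(u\,\chi'(\rho)\,\rho_x) = -u_x \chi' \rho_x - u\,(\chi'\rho_x)_x$,
with both summands negative.  The worked examples this package reproduces
expand it with mixed signs instead (for $\chi=\rho$:
$-u_x\rho_x + u\,\rho_{xx}$).  Both conventions are implemented:

* `sign_variant = "as_printed"` (default) reproduces the published series
  terms exactly and is what `verify_fixtures()` checks;
* `sign_variant = "conservative"` is the self-consistent divergence form,
  and is the only variant the finite-difference reference solver accepts,
  because only a divergence-form flux conserves mass under zero-flux
  boundaries.

The two coincide when $\chi$ is constant.  For the exponential-data
linear-sensitivity example the as-printed chemotactic contribution cancels
order by order, which is what makes its cell series sum in closed form to
$u = m\,e^{at - x}$.

## The fixture library and its known discrepancies

`printed_terms()` ships the published terms of the three worked examples as
expression strings; `verify_fixtures()` regenerates each term and compares
symbolically.  Three fixtures of the quadratic-sensitivity example are
internally inconsistent with the example's own recursion and are stored
with `status = "discrepant"`:

* the order-1 cell term is printed with $\cos^2 x$ where the recursion's
  integrand yields $\sin^2 x$; the symbolic difference is
  $2 m n^2 t \sin x \cos 2x$;
* the order-2 cell term inherits that problem (it even contains an
  order-$t$ monomial, though every order-2 term must vanish like $t^2$);
* the order-2 chemical term is reproduced exactly by the recursion seeded
  with the *published* order-1 cell term, except for a single monomial
  printed ambiguously; under the reading $c\,m\,n^2$ the term is exact,
  under the literal $c\,n\,m^2$ it differs by
  $\tfrac12 c\,m\,n\,(m-n)\,t^2 \sin x$.

The report marks these `known_discrepancy` and carries the symbolic
difference; it never silently passes or fails them, and it records both
candidate order-1 integrands (mixed-sign and divergence-form).  No attempt
is made to "fix" the published terms.

## The symbolic kernel

No computer-algebra system is required: the package carries its own
canonical expression class, closed under exactly the operations the
recursion needs.  Every expression is a sum of monomials

$$
q \cdot \prod_i s_i^{k_i} \cdot e^{e_1 x + e_2 x^2} \cdot
\sin^{\sigma}\!x \cdot \cos^{\gamma}\!x,
$$

with $q$ an exact rational, $s_i$ arbitrary symbols (the parameters
$a,b,c,d$, the amplitudes $m,n$, the variables $x,t$, the embedding
parameter $p$), and integer powers.  This class is closed under addition,
multiplication, differentiation in any symbol (with $x$ driving the
exponential and trigonometric factors) and the Abel-kernel time integral
(a monomial $t^k$ maps to $k!/(m+k)!\,t^{m+k}$), which is all the recursion
ever does — every published term lies inside it.  Canonicalisation expands
products, reduces $\sin^2 x \to 1 - \cos^2 x$ so that at most one sine
power survives per monomial, merges like monomials and orders them
deterministically; equality is decided by canonicalising the difference,
with a random-point numeric fallback (relative tolerance $10^{-10}$,
verdict labelled `"numeric"`) for inputs outside the class, and an
ambiguity error when two expressions share no symbols and no evaluation
ranges are declared.  Multiple-angle arguments ($\sin kx$, $\cos kx$ for
integer $k$) are expanded into the $\sin x,\cos x$ power basis at parse
time, which is how the published $\cos 2x$ terms are compared.

Rational coefficients are kept exact with numerator and denominator stored
as integers below $2^{53}$, reduced by gcd at every operation; an operation
that would overflow that window degrades the affected coefficient to a
double.  In practice this happens only past series order $\sim 19$, where
$n!$ denominators outgrow the window — orders used exclusively for numeric
partial-sum work, never for symbolic fixture comparison.  Because the
canonical ordering is deterministic, serialising a series to JSON
(`series_to_json()`) and re-loading it reproduces bit-identical numeric
evaluations.

## Numeric evaluation and validity diagnostics

`hdm_evaluate()` sums terms pointwise on a grid.  The truncated series is
asymptotic in $t$: no validity radius is claimed anywhere in the sources,
so instead of inventing one the package flags, per grid point, where
$|{\rm term}_N| > |{\rm term}_{N-1}|$ — the point has left the regime where
successive terms shrink.  This matters in practice: for the decoupled
Gaussian example with $b = 3$, the chemical series violates the heuristic
already at $t = 0.1$ (term ratio $\approx 4bt > 1$), while the cell series
($4at = 0.2$) is still well inside its regime.  Default grids mirror the
published figure slices ($x$ across the domain at $t = 5$; $t \in [0,5]$
at a fixed $x$).

`convergence_report()` tabulates partial-sum increments per order, and
`series_limit()` sums a pointwise series to a prescribed increment
threshold.  For the exponential-data example the cell terms are
$m e^{-x} (at)^n/n!$, so at $x = 2.5$, $t = 5$ with $m = 120$, $a = 0.5$
the increments decay factorially and the partial sums converge to the
closed-form value $m e^{at-x} = 120$; the default threshold $10^{-9}$ is
reached at order 20 with $|S - 120| < 10^{-6}$.

## The finite-difference reference solver

`fd_solve()` is an independent oracle: second-order central differences on
a node grid including both endpoints, all transport written as fluxes at
midpoints with zero boundary fluxes (so the trapezoidal cell mass is
conserved to integrator accuracy when reaction terms vanish), the
chemotactic flux evaluated from face-averaged fields, and stiff time
integration by banded-Jacobian LSODA with interleaved state ordering.
Integrator failure (chemotactic blow-up) returns the snapshots reached,
flagged, rather than erroring.

The published examples pose Gaussian, exponential and sinusoidal initial
data without stating an interval, while the boundary-value problem lives on
a bounded one; the solver therefore truncates to wide intervals where the
data decay to negligible size ($[-10, 10]$ for Gaussians, $[0, 20]$ for
$e^{-x}$, $[-\pi, \pi]$ for $\sin x$) and accepts the residual boundary
perturbation as part of the reported error budget (for $e^{-x}$ and
$\sin x$ the data are not Neumann-compatible at the boundary, so a small
boundary layer forms immediately; it is part of what the error report
measures).

`compare_series_fd()` reports, per field, absolute differences scaled by
the field's maximum reference magnitude over the compared grid.  A sup-norm
normalisation is deliberate: pointwise relative error is ill-posed in
Gaussian tails where both solutions sit at $10^{-40}$.  Oracle comparisons
are restricted to short horizons (default $t \le 0.1$) as a package
decision — a truncation-order-4 asymptotic series cannot be expected to
track $t = 5$ dynamics, and the point of the comparison is to validate the
recursion, not the large-time series.  For the decoupled Gaussian example
at $N = 4$, 401 points on $[-10,10]$, $t \le 0.1$, the cell field agrees
with the oracle to a few times $10^{-5}$ in this norm (dominated by the
$O(\Delta x^2)$ spatial error); the chemical field is excluded from that
bound because its series is already outside its validity regime there, as
the divergence heuristic reports.

## Numerical and design choices worth knowing

* **Initial-data convention.**  For time order $m$ the scheme fixes the
  $(m-1)$-th time derivative at $t = 0$ to zero, so a field carries $m - 1$
  initial functions ($1$ for $m = 1$); supplying all $m$ Taylor
  coefficients is also accepted.  This convention is unusual for $m \ge 2$
  initial-value problems and is irrelevant to Keller-Segel ($m = 1$); it is
  implemented as specified, not generalised.
* **Forcing** enters at order 1 only (it carries no power of $p$).
* **Linearity spot-check.**  `general_problem()` verifies additivity of the
  supplied linear operator on three random polynomial fields.
* **Parameter validation.**  $a, b > 0$ strictly; $c, d \ge 0$, with zero
  admitted for degenerate diagnostic configurations (the mass-conservation
  check needs $c = d = 0$; the cell mass is conserved regardless, but the
  chemical field's balance is only conservative then).
* **Truncation default** is $N = 4$, matching the depth of the worked
  examples; anything the symbolic integration can reach is allowed
  (performance, not correctness, is the practical bound — order 30 for the
  closed-form limit check runs in well under a minute).
* **Randomised checks.**  All randomised property tests run under a fixed
  seed (20140708) for reproducibility; `symbolic_equal()`'s numeric
  fallback draws from declared per-symbol ranges, defaulting to
  $[0.3, 1.7]$.
* **Problem sizes in the shipped tests** were chosen to exercise each claim
  at the scale its sources state (fixture orders 1-4; order 30 for the
  limit check; 401-point oracle grids with 51/101-point pairs for the
  convergence-order check).

## What the worked examples do and do not show

Everything symbolic here is exact reproduction, not approximation, so
"passing" means the recursion and the publication agree term for term.  The
numeric comparisons, by contrast, validate the *recursion* at short times
on smooth decaying data; they say nothing about large-time behaviour of
truncated series (flagged divergent well before $t = 5$ for the stiffer
parameter sets), about blow-up phenomena (out of scope), or about the
as-printed mixed-sign variants as PDE models (they are not divergence-form
and are excluded from the oracle on purpose).  Convergence proofs and error
bounds beyond these empirical diagnostics are out of scope, as are
fractional-order and higher-dimensional extensions.
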