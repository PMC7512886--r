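---
title: "Methods: chaos diagnostics for the forced love model"
author: "lovechaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaos diagnostics for the forced love model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`lovechaos` studies the planar system

$$
\frac{dR}{dt} = aR + bJ(1-|J|) + y(t), \qquad
\frac{dJ}{dt} = cR(1-|R|) + dJ + f(t),
$$

where $R$ and $J$ are the signed love/hate levels of two partners,
$a,d$ are self-feeling coefficients, $b,c$ cross-response
coefficients, and $y, f$ are external "advice" inputs. The saturating
terms $x(1-|x|)$ bound the response to extreme feelings; they make the
system piecewise smooth, with kinks only in second derivatives along
$R=0$ and $J=0$ (the field itself is Lipschitz, so a non-stiff
explicit integrator is appropriate and no event handling is needed).

The forcing is sinusoidal advice,

$$ y(t) = A\sin(\omega\pi t) + B, $$

applied by default to Romeo's equation only ($f \equiv 0$); routing it
to Juliet or to both is supported as an extension. **Convention
warning:** $\omega$ is the coefficient of $\pi t$, so the forcing
period is $2/\omega$, not $2\pi/\omega$. All period-based settings
(transients, strobes, renormalization) are expressed in this period.
$A+B$ and $-A+B$ are the positive and negative advice magnitudes;
three presets fix the balance studied throughout: `P_eq_N`
($5\sin\pi t$), `P_gt_N` ($6\sin\pi t + 1$), `P_lt_N`
($6\sin\pi t - 1$).

For the linearization $[[a,b],[c,d]]$ the origin is a saddle iff
$ad < bc$ (negative determinant). `classify_fixed_point()` reports
this dichotomy *alongside* the full spectral class, because "not a
saddle" implies stability only when the trace $a+d$ is also negative.
That holds throughout the region studied here ($b=-2, c=1, d=1$,
$a < -2$, where the saddle condition reduces to exactly $a < -2$),
but not for general coefficients, so both labels are exposed rather
than guessing which one a user means.

## Integration

`integrate_love()` uses classical fixed-step RK4. A fixed step was a
deliberate choice over adaptive solvers:

* the forcing period $2/\omega$ is required to be an exact integer
  multiple of `dt`, so stroboscopic samples fall on grid points with
  no interpolation;
* runs are bit-reproducible, which the test suite asserts literally.

Defaults: `dt = 0.001` (2000 steps per period at $\omega = 1$;
step-halving shows the expected 4th-order error decay on smooth
windows), 500 transient periods discarded, 200 periods recorded,
initial state $(0.1, 0.1)$. The long transient matters near
period-doubling points, where settling onto the doubled branch is
slow; at two dimensions it is cheap (the stepper is compiled). An
overflow guard (default $10^6$) aborts with an error naming the
failing step; the model is bounded in every regime studied, so
hitting the guard indicates a mis-set parameter rather than genuine
model behavior.

When advice is balanced ($B = 0$) the field obeys the odd symmetry
$F(t + T/2, -x) = -F(t, x)$, and RK4 commutes with this flip exactly;
the suite checks the implied trajectory equivariance at tolerance
1e-9 (floating-point evaluation of the shifted sine prevents exact
bitwise agreement).

## Period detection

A period-$n$ orbit of the forced system yields $n$ distinct points in
the stroboscopic section. `detect_period()` makes this operational:

* single-linkage clustering (via `stats::hclust`) at radius
  `rel_tol` $\times$ the section diameter, with the diameter floored
  at 1e-9 so that a numerically-degenerate period-1 section (spread
  ~1e-13) still clusters as one point. A *relative* radius is used
  because attractor scale differs across scenarios;
* the strobe sequence must visit the $n$ clusters in a fixed cyclic
  order, with at least two full cycles recorded. This distinguishes
  genuine period-$n$ orbits from quasiperiodic loops whose points
  happen to fall into clusters;
* if the cyclic test passes but the cluster count changes as
  `rel_tol` varies over $[5\times10^{-4}, 5\times10^{-3}]$, the
  detection is reported as unresolved rather than silently picking a
  count.

The stroboscopic construction (rather than a crossing-based section)
is the natural choice for a periodically forced system, and the
period-$n$ point counts it produces match the qualitative cascade
this model is known for.

## Power spectra

`power_spectrum()` computes a mean-removed, Hann-windowed
periodogram via `stats::fft`; peaks are local maxima above 1% of the
global maximum, merged within one frequency bin. These are
conventional estimation choices; no claim of optimality is made. The
spectrum is treated as *corroborating* evidence (a period-$n$ orbit
of a period-$T$ forcing shows subharmonic lines at multiples of
$1/(nT)$); the strobe-based period is authoritative.

## Maximal Lyapunov exponent

`max_lyapunov()` implements the Benettin single-exponent method: the
state and a unit tangent vector are co-integrated with the same RK4
stepping, the tangent evolving under the variational equation with
Jacobian

$$ \begin{pmatrix} a & b(1-2|J|) \\ c(1-2|R|) & d \end{pmatrix}. $$

The derivative of $x(1-|x|)$ is $1-2|x|$ everywhere, including $x=0$
where the one-sided limits agree — only the second derivative is
kinked, so the tangent dynamics are well defined without event
handling. The additive forcing has no state derivative and enters
only through the base trajectory. The tangent is renormalized once
per forcing period (stretch factors stay well inside floating-point
range at these exponents; halving the interval changes settled
estimates by far less than the convergence tolerance, which the suite
checks). The initial tangent is fixed at $(1,0)$ for determinism; a
run at $(0,1)$ agrees within 0.01.

The estimate is validated against an independent closed-form oracle:
with zero forcing the origin is invariant, so a run started exactly
there exercises the constant coefficient matrix, and the estimate
must match its largest eigenvalue real part within 0.01 over 2000
time units — checked for randomly generated matrices with distinct
real eigenvalues and for a complex-pair case.

A dead zone of $\pm 0.01$ per unit time separates the verdicts:
`classify_attractor()` calls an orbit periodic only with a detected
period *and* $\lambda < -0.01$, chaotic only with an aperiodic strobe
*and* $\lambda > +0.01$, and otherwise reports `unresolved` (near
bifurcation points $\lambda \approx 0$ and no honest verdict exists).

### Scroll count

For chaotic verdicts the number of attractor lobes is reported as
descriptive metadata. The statistic is built on the balanced-advice
symmetry: a double scroll is an attractor invariant under the
half-period flip $(R,J,t)\to(-R,-J,t+T/2)$ — the operation that glues
two lobes together — while a single-scroll band breaks it. We
measure the *symmetry defect*, the distance between the strobe
centroid at phase 0 and the negated centroid at phase $T/2$, relative
to the section spread, and label 2 scrolls below 0.5. A sign-based
test on strobed $R$ was rejected: the single-scroll band itself
straddles $R=0$, so sign fractions misclassify it. For $B \neq 0$
the flip is only an approximate symmetry and the label is
correspondingly approximate; it never feeds into the
periodic/chaotic verdict.

## Bifurcation sweeps

`sweep_bifurcation()` walks an ascending grid of $a$ (default: 400
uniform points on $[-6, -2.01]$, inside the saddle region), seeding
each grid point with the previous final state (`continuation = TRUE`,
standard bifurcation-diagram practice; it shortens transients and
follows the attractor branch). Sweep defaults use 200 transient + 100
recorded periods per point and a 400-period exponent accumulation —
continuation keeps the state near the attractor, so these are
shorter than standalone-run defaults. The suite verifies that
continuation does not change labels at the five reference points
(no hysteresis detected there). Strobed $R$ is the plotted ordinate
(switchable to $J$). A diverging point is recorded as missing, not
fatal. `doubling_points()` reads $n \to 2n$ transitions (and entries
into the aperiodic regime) off consecutive grid intervals.

## Reference regimes and what the tests show

With $b=-2, c=1, d=1$ under balanced advice, the converged dynamics
reproduce the period-doubling route: period 1 at $a=-5.41$, a 1→2
transition near $a \approx -3.62$, a 2→4 transition bracketed in
$(-3.46, -3.45)$, chaos onset near $-3.40$, a single-scroll
(Rössler-type) band at $-3.201$ and a double scroll at $-2.561$, with
periodic windows inside the chaotic range. One point deserves
emphasis: $a = -3.451$ lies on the **period-4** side of the 2→4
doubling. This is robust in our runs across step sizes from 0.05 down
to 0.00025, a forward-Euler cross-check, and dozens of initial
conditions (no coexisting period-2 attractor was found); immediately
past the doubling the four strobe points form two pairs that merge
visually under short transients, which we suspect explains period-2
readings of this parameter elsewhere. The acceptance suite therefore
contains one deliberately failing expectation at this value; the
computed count is reported as-is rather than tuned.

The three advice balances produce genuinely different bifurcation
structure; the suite asserts that at least one grid value of $a$
receives different period labels across scenarios.

## Synthetic fixtures

`make_fixtures()` generates seeded inputs for testing the diagnostics
in isolation: cyclic cluster sequences (with and without jitter) for
period detection, uniform random points as an aperiodic control, and
random $2\times2$ matrices with distinct real eigenvalues carrying
their closed-form largest eigenvalue as the Lyapunov oracle. These
exercise the *detectors*, not the model: passing them shows the
clustering, cyclic-order and tangent-propagation machinery is
correct, and says nothing about real affective data — the model
itself is a stylized metaphor, and no empirical fitting to human
relationship data is attempted or implied.

## Degenerate inputs and edge cases

* `dt` not dividing the forcing period, phases off the step grid,
  fewer than 32 strobe points, non-uniform spectral input, unknown
  configuration keys: all rejected with specific errors.
* $ad = bc$ classifies as `degenerate` (boundary of the saddle
  region).
* The origin's basin of attraction under zero forcing can be small
  (the coefficient matrix is non-normal, so small states can grow
  transiently before decaying); convergence tests use initial states
  well inside the basin.

## Known limitations

* Only the maximal Lyapunov exponent is computed (no full spectrum,
  no Kaplan–Yorke dimension), and no correlation-dimension or 0-1
  chaos test is provided; period detection plus $\lambda$ suffice for
  the regime claims made here.
* Time-delay variants and non-sinusoidal advice (Fourier series,
  Gaussian, fuzzy-membership shapes) are out of scope.
* The scroll count is descriptive and approximate for $B \neq 0$.
* Fixed-step RK4 is not suited to stiff extensions of the model.
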