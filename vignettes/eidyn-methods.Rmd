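---
title: "Methods: mean-field theory and chaos diagnostics for noisy E-I random networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean-field theory and chaos diagnostics for noisy E-I random networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`eidyn` studies a recurrent rate network with an excitatory population of
size $N_E$ and an inhibitory population of size $N_I$ ($N = N_E + N_I$),
driven by additive white noise:

$$
\dot x_{Ki} = -x_{Ki} + \sum_{j=1}^{N_E} J_{Ki,Ej}\,\phi(x_{Ej})
 + \sum_{j=1}^{N_I} J_{Ki,Ij}\,\phi(x_{Ij}) + \sigma\,\xi_{Ki}(t),
\qquad K \in \{E, I\},
$$

with unit leak time constant, transfer function $\phi$ (arctangent by
default), and independent unit white noises $\xi_{Ki}$. Time is measured in
units of the leak time constant and all parameters are dimensionless.

The couplings carry two kinds of structure. Within a population, the two
weights of every reciprocal pair $(J_{ij}, J_{ji})$ are *jointly* Gaussian
with mean $m_{KK}/N_K$, variance $g^2/N$ and correlation $\eta_K$; between
populations every weight is independent with mean $m_{KL}/N_L$ (sender $L$)
and variance $g^2/N$. The gain $g$ scales all coupling fluctuations and is
the bifurcation parameter for both linear instability and chaos; $\eta_K$
interpolates between symmetric ($\eta_K = 1$), independent ($0$) and
antisymmetric ($-1$) reciprocal wiring. The signs of the mean couplings
encode the excitatory/inhibitory identity; no sign clipping of individual
weights is applied (`sample_coupling()` documents the exact construction,
including the exactly degenerate $|\eta_K| = 1$ cases and the convention
that self-couplings are drawn independently from the block marginal and
excluded from pair-correlation estimates, since the pair construction only
constrains $i \neq j$).

The shipped presets (`ei_preset()`) encode the parameter sets used in the
worked analyses; the baseline set is $N_E = 1500$, $N_I = 1000$,
$m_{EE} = 1$, $m_{IE} = 0.75$, $m_{EI} = -0.25$, $m_{II} = -0.5$,
$g = 1.4$, $\sigma = 0.8$, $\eta_E = 1/3$, $\eta_I = 1/2$ — chosen so that
$N_E \eta_E = N_I \eta_I = 500$, the balance that synchronizes the two
populations' autocorrelation structure (below).

## Mean-field reduction

For large $N$ the recurrent drive onto a neuron of population $K$ behaves
as a stationary Gaussian process $\gamma_K(t)$ plus the mean drive, giving
the reduced two-dimensional dynamics

$$
\dot x_K = -x_K + \gamma_K(t) + \sigma \xi_K(t)
 + m_{KE}\langle\phi(x_E)\rangle + m_{KI}\langle\phi(x_I)\rangle ,
$$

with effective-noise correlations (implemented in `gamma_kernel()`)

$$
\langle\gamma_E(t)\gamma_E(t')\rangle = \frac{g^2}{N}\Big[
 N_E(1+\eta_E)\,\langle\phi_E\phi_E'\rangle + N_I\,\langle\phi_I\phi_I'\rangle
\Big],
$$

and the $I$ row carrying $(1+\eta_I)$ on the inhibitory term. The
correlation $\langle\phi(x(t))\phi(x(t+\tau))\rangle$ of a stationary
Gaussian state with variance $c_{K0}$, lag covariance $C_K(\tau)$ and mean
$\mu_K$ is a two-dimensional Gaussian expectation, written
$f_\phi(C_K, c_{K0})$ and computed by `gaussian_pair_expectation()`.

**Quadrature.** The bivariate expectation is reduced by conditioning,
$z_2 = (C/c_0) z_1 + \sqrt{c_0 - C^2/c_0}\, w$, and evaluated with tensor
Gauss-Hermite quadrature (64 nodes per axis), which is spectrally accurate
for the smooth arctangent families. The rectified transfer
$\max(\arctan x, 0)$ has a kink, on which Gauss-Hermite converges too
slowly for the 1e-5 consistency checks, so all its expectations are
rewritten as integrals of the smooth arctangent branch over the truncated
domain and evaluated with Gauss-Legendre rules (48 nodes per axis, window
$\pm 8.5$ standard deviations); degenerate limits ($c_0 \to 0$,
$|C| \to c_0$) are collapsed analytically to single integrals. With this
split, Price's theorem
$\partial f_\Phi / \partial C = f_\phi$, $\partial f_\phi / \partial C =
f_{\phi'}$ holds to better than 1e-5 by finite differences for every
transfer family, which is the property the potential/power bookkeeping
relies on.

## Stationary self-consistency

The stationary structure of the reduced theory is six scalars: the means
$\langle x_E\rangle, \langle x_I\rangle$, the variances $c_{E0}, c_{I0}$,
and the long-lag limits $c_{E\infty}, c_{I\infty}$. They satisfy
simultaneously:

1. the mean equations
   $\langle x_K\rangle = m_{KE}\langle\phi(x_E)\rangle +
    m_{KI}\langle\phi(x_I)\rangle$;
2. the energy balance $\sigma^4/8 + V_K(c_{E0}, c_{I0}) =
   V_K(c_{E\infty}, c_{I\infty})$, where $V_K$ is the Newtonian potential
   of the lag dynamics (`potentials()`), built from the pair expectation of
   the antiderivative of the shifted transfer so that its $C$-derivative
   reproduces $f_\phi$;
3. the dissipation conditions $W_K(c_{E\infty}, c_{I\infty}) = 0$, where
   $W_K$ is minus the total $C$-directional derivative of $V_K$
   (`powers()`).

The white noise enters as the initial kinetic energy $\sigma^4/8$ of the
lag dynamics, equivalently the slope jump $C_K'(0^+) = -\sigma^2/2$; the
delta term is implemented exactly as this boundary condition, never as a
discretized spike. We take the decaying branch (negative initial slope):
the growing branch is unbounded and unphysical for an autocorrelation.

`solve_self_consistency()` solves the system with a damped Newton
iteration (numerical Jacobian, step-halving line search) on
$(c_{E0}, c_{I0})$, initialized at the decoupled value $\sigma^2/2$, with
inner solves for the means (exactly zero for odd transfers) and for the
long-lag limits at each candidate variance pair; for large gains a
fixed-point preconditioner derived from rewriting the energy balance as
$c_{K0} \leftarrow \sqrt{2\,\mathrm{RHS}(c_{K0})}$ supplies the warm
start. For odd transfers $C = 0$ solves the dissipation condition exactly,
so $c_{K\infty} = 0$ on that branch. At $\sigma = 0$ the trivial solution
$c_{K0} = 0$ always exists and the solver additionally searches for a
chaotic branch using the residual rescaled by $|c_0|^2$ (the trivial root
is a double root, and the rescaling removes it); when a nonzero root
exists it is returned and the trivial root is recorded in `alt_roots`.
Residual tolerances are 1e-10 (internal) with convergence declared below
1e-8 on all three equation groups. The solution was cross-validated
against an independent functional fixed point (Green-function convolution
of the linear filter against the self-consistent kernel), which agrees on
$c_0$ to 5e-5 at the baseline preset.

`integrate_autocorrelation()` then integrates the second-order lag
dynamics $\ddot C_K = W_K$ with `deSolve::lsodar` at tight tolerances
(rtol 1e-11). Two numerical points deserve mention. First, the lag
dynamics are a saddle: the solution that decays toward $c_{K\infty}$ is
dynamically unstable, so integration is stopped by a root function the
moment a curve escapes $[-c_{K0}, c_{K0}]$; by default that is an error,
and callers that only need the valid initial segment (the linearized-field
solver, plotting) request truncation. Second, trial steps of the solver
may probe marginally outside the admissible covariance domain; the
right-hand side clamps $C$ into $[-c_0, c_0]$, while genuine escapes are
still caught by the root function. Energy conservation
($\tfrac12 \dot C_K^2 + V_K$ constant, `energy_residual()`) holds along
the synchronized solutions to 1e-6 with derivatives taken by central
differences on a 2e-3 grid; note that the conservation law is exact only
when the two populations share one curve — with unbalanced correlations
the cross-potential terms exchange energy between the two lag equations,
and correspondingly no bounded solution from the stationary boundary data
need exist (the baseline anti-correlated preset escapes near lag 2.5; the
package treats this as expected behavior, not failure).

### Synchronization conditions

`check_synchronization_conditions()` evaluates the three sufficient
conditions for the two populations to share one autocorrelation function:
(i) $\eta_E = \eta_I = 0$; (ii) odd transfer and
$N_E\eta_E = N_I\eta_I$; (iii) equal stationary means with
$N_E\eta_E = N_I\eta_I$. Under any of them the package's solver returns
$C_E \equiv C_I$ to 1e-8 and the linearized-field solver returns
$G_E \equiv G_I$ to the same tolerance.

## Chaos diagnostics

Three routes to the chaos transition are implemented and cross-checked.

**Replica simulation** (`estimate_mle()`). Two copies of the network share
the same coupling matrix and the same noise path and differ only by a
per-neuron offset of magnitude $\varepsilon = 10^{-8}$ (random signs), so
the squared population distances $d_K(t)$ start at $\varepsilon^2$
exactly. The maximal Lyapunov exponent is half the log-slope of $d_K(t)$.
The fit uses all points after the alignment transient (default 5 time
units) and below a saturation cap ($10^{-3}$), in a single least-squares
fit; a best-window scan was considered and rejected because the single fit
uses strictly more data and has lower variance near the transition, where
the slope is close to zero (fits there are flagged via a low
R-squared rather than discarded). A lower cutoff at $d = 10^{-27}$ keeps
the fit above the double-precision cancellation floor: with states of
order one, replica differences below $\sim 10^{-15}$ per neuron are pure
rounding noise and flatten the measured slope (this is visible as
$\lambda \approx -0.93$ instead of $-1$ at $g = 0$ if the cutoff is
omitted). A Benettin variant renormalizes the separation back to
$\varepsilon$ every 2 time units and averages per-interval log expansions,
for use deep in the chaotic regime where the direct fit would saturate.
Protocol defaults: burn-in 20 before forking, pair horizon 60, Euler-
Maruyama step 0.01 (additive noise; the scheme's $O(\sqrt{dt})$ noise
scaling is exact here, and halving the step moves stationary variance
estimates by less than their sampling error), divergence guard at
$|x| > 10^6$.

One point the replica protocol makes unavoidable: the linearized
difference dynamics couple the two populations, so both population
distances asymptotically grow at the single leading rate, and the fitted
exponents of E and I agree to $\sim 10^{-3}$ at every gain. Separate
per-population transition gains are therefore not resolvable by this
protocol at these sizes — the measured common crossing for the
anti-correlated preset (reduced sizes $N_E = 600$, $N_I = 400$, five-gain
grid, three seeds) lands near $g \approx 1.9$, between the two values read
off per population in transient fits at full size. The same locking holds
in the mean-field field equations below, whose kernels couple $G_E$ and
$G_I$ with positive weights.

**Linearized cross-correlation field** (`evolve_G()`). Writing the replica
cross-correlation as $C_K^{12}(t, t') = C_K(t - t') + \epsilon G_K(t,t')$,
the deviation field obeys

$$
(\partial_{t'} + 1)(\partial_t + 1) G_K = \frac{g^2}{N}\Big[
 N_E(1 + \delta_{KE}\eta_E) f_{\phi'}(C_E(t - t'), c_{E0})\, G_E +
 N_I(1 + \delta_{KI}\eta_I) f_{\phi'}(C_I(t - t'), c_{I0})\, G_I\Big],
$$

and $d_K(t) \propto G_K(t, t)$, so the mean-field exponent is half the
asymptotic diagonal rate (`meanfield_mle()`). The field is evolved on a
uniform lattice (default extent 20, step 0.05) from a unit impulse with
free-decay data on the axes, using the cell update
$G_{i+1,j+1} = e^{-h}(G_{i,j+1} + G_{i+1,j}) - e^{-2h} G_{i,j} + h^2
\mathrm{RHS}_{i,j}$, which treats the two first-order contraction factors
exactly over a cell (the homogeneous solution $e^{-t-t'}$ is reproduced to
machine precision, hence the exact $-2$ diagonal rate and $\lambda = -1$
at $g = 0$). Rows are rescaled on the fly with a log-scale accumulator so
strongly chaotic parameters do not overflow. The kernel needs
$C_K(\tau)$ out to the lattice extent; beyond the valid (possibly
truncated) curve it is padded with $c_{K\infty}$, which is the correct
long-lag limit of the kernel argument.

**Critical-gain condition** (`critical_g()`). At the transition the
stationary theory yields the implicit condition
$c_{K0} = g_c^2 (1 + N_K\eta_K/N)\, f_\phi(c_{K0}, c_{K0})$, with
$c_{K0}$ itself recomputed at every candidate gain. It is solved by
bracketed root-finding; on the noise-free trivial branch the exact
small-variance limit $1 = g_c^2 (1 + N_K\eta_K/N)\,\phi'(\mu_K)^2$ is used
instead, giving $g_c = 1$ for the unit-slope arctangent with independent
couplings and $g_c = 1/\sqrt{1 + r}$ when the correlation load is $r$. The
condition is derived under the synchronization conditions; outside them it
is computed per population but flagged advisory, and for strongly
anti-correlated populations it can lack a root altogether (the
excitatory condition at the $\eta_E = -1$ preset stays positive for all
gains scanned) — `allow_partial = TRUE` then returns `NA` for that
population instead of erroring. A `variant = "phi_prime"` switch solves
the same condition with the derivative pair expectation (the kernel that
actually drives the field equations) for sensitivity analysis; the printed
form is the default. The qualitative facts — noise raises the critical
gain, reciprocal correlation lowers it, steeper transfer slope lowers
it — are all reproduced by this route and tested.

## Linear stability

`network_jacobian()` builds $-I + J\,\mathrm{diag}(\phi'(x))$ along a
reference state and `spectral_abscissa()` takes the maximum real
eigenvalue part (dense eigensolve; at $N = 2500$ a values-only
nonsymmetric solve takes a few seconds). `stability_sweep()` samples a
fresh coupling matrix per gain, integrates the noisy network through a
50-unit burn-in, evaluates the Jacobian at several stationary snapshots
(default 3, one time unit apart), and interpolates the zero crossing of
the snapshot-averaged abscissa. Snapshots of the noisy trajectory are the
default reference because with noise the states spend time where
$\phi' < \phi'(0)$, which is what places the instability threshold above
the noise-free value; the deterministic fixed point is available via
`reference = "origin"`. Averaging the abscissa over snapshots (rather
than averaging the Jacobian) is the default because the abscissa is the
quantity with the stability interpretation; both are easily obtained from
the returned per-snapshot table. Between the stability threshold and the
chaos transition lies the band where the network is linearly unstable yet
non-chaotic; its existence at the anti-correlated preset is asserted by
the test suite.

## Problem sizes and what the tests do (and do not) show

The test suite and the reproduction script use: full size
($N_E = 1500, N_I = 1000$) for everything spectral and for the mean-field
theory (which is size-independent in cost), and reduced sizes
($N_E = 600, N_I = 400$, preserving $N_E/N_I$ and $N_K\eta_K$ balance
where relevant) with horizons of 60-150 time units and 3 seeds for the
replica sweeps. These sizes resolve the transitions to about $\pm 0.05$
in gain.

Two quantitative limitations are documented rather than hidden. First,
the saddle-point reduction is quantitative sub-critically — simulated
stationary variances match $c_{K0}$ to 1% at $g = 0.6$ and 9% at
$g = 1.0$ — but at the baseline gain $g = 1.4$, which sits essentially at
the noisy chaos transition (mean-field $\lambda = -0.008$), finite-size
fluctuations inflate the simulated variance by ~30% at both
$N = 1000$ and $N = 2500$; consistency tests therefore assert the match in
the sub-critical regime. Second, as noted above, per-population Lyapunov
exponents measured from shared-noise replicas lock to a common rate; the
per-population transition values quoted for the anti-correlated preset
should be read as transient-fit readings, and the package's crossing
estimates land between them. The synthetic conditions emulate stationary
noise-driven dynamics only: no spiking, delays, sparse connectivity, or
sign-constrained (Dale-clipped) weights, so passing tests say nothing
about those features of real circuits.
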