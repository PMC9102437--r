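---
title: "Modelling apoptosis regulation in memory plasma cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling apoptosis regulation in memory plasma cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptosim)
```

## The biological question

Memory plasma cells are not intrinsically long-lived: they persist only
while their bone-marrow niche supplies survival signals. In vitro, two
signals suffice to extend their lifespan from under a day to nearly a
week — the cytokine APRIL (signalling through NF-kB) and direct contact
to stromal cells (the ST2 line, signalling through PI3K). `apoptosim`
implements a mechanistic model of how these inputs act on the intrinsic
apoptosis machinery, and the statistical layer needed to confront the
model with flow-cytometric protein measurements and population survival
curves.

## The mass-action network

The state comprises six free species — BIM, NOXA (pro-apoptotic),
BCL-2, MCL-1 (anti-apoptotic), BAX and its activated form BAX\* — and
five 1:1 complexes. Each free protein P is produced at a
condition-dependent rate and decays at a first-order rate $d_P$ taken
from published protein half-lives. Anti-apoptotic proteins bind their
partners reversibly:

$$\frac{d[C_{AB}]}{dt} = k^+ [A][B] - k^+ K_d^{AB} [C_{AB}] - d_{C}\,[C_{AB}],$$

with the dissociation rate written as $k^+ K_d$ so that the binding
equilibrium is controlled by the annotated dissociation constants.
BAX interconverts with BAX\* at first-order rates $k_1$ (activation)
and $k_2$ (deactivation); both BAX forms are produced/decay like the
other proteins, and only BAX\* is bound by MCL-1 and BCL-2.

**Topology.** The five binding pairs are MCL-1:BIM, MCL-1:NOXA,
BCL-2:BIM, MCL-1:BAX\*, BCL-2:BAX\*, with the dissociation constants
$K_{d,3}\dots K_{d,7}$ assigned in that order — the smallest constant
(2 nM) to the strongest reported interaction, MCL-1:BIM, and NOXA
binding only MCL-1. The assignment is a reconstruction from the
qualitative interaction literature; `pc_topology()` accepts any other
pair set and Kd mapping, so alternative wirings are one line away.

**Units.** The annotated table prints the association rate as
0.17 "µM d⁻¹" and the BAX (de)activation rates as 43.2 and 8.64
"µM d⁻¹". Dimensionally, a bimolecular association needs
concentration⁻¹ time⁻¹ and first-order steps need time⁻¹. We resolve
this as: $k_1, k_2$ in d⁻¹ (normalising by a 1 µM reference
concentration), and $k^+$ in **nM⁻¹ d⁻¹** — the same concentration
scale on which every dissociation constant is printed. The nM reading
matters: it makes the dissociation rates $k^+K_d$ (0.3–12 d⁻¹)
comparable to the decay rates, so competitive binding genuinely
shapes the steady state. On a µM⁻¹ reading the binding fluxes would be
three orders of magnitude slower than decay, complex occupancy would be
negligible, and the network would lose all condition dependence of
BAX\* — contradicting both the observed ST2-driven rise in activated
BAX and the measured half-life contrast, which the nM reading
reproduces directly (see below).

**Condition modifiers.** With ST2 contact, production of MCL-1, BCL-2,
BIM and NOXA is multiplied by factors $s_P \in (0,1]$ (measured
downregulation); with APRIL, BCL-2 production is multiplied by
$(1 + a_{BCL2})$, an upregulation. BAX production is
condition-independent. Under graded (Hill) regulation the ST2 factor
interpolates between 1 and $s_P$ proportionally to $f(\mathrm{ST2})$.

**Complex decay.** The annotated source does not specify how complexes
are cleared. We let each complex decay at the *faster* partner's rate —
the conservative choice that keeps complexes from becoming permanent
sinks for short-lived proteins; `complex_decay = "none"` switches this
off. This choice mainly affects how strongly MCL-1 complexes drain
their partners (MCL-1 turns over in ~1 h).

**BAX activation** is first-order from BAX with first-order reversal.
BIM-catalysed activation is biologically plausible but the annotation
provides no catalytic constant, so it is not modelled.

## Solvers

Trajectories use `deSolve::ode` (lsoda; rtol 1e-8, atol 1e-10).
Steady states use a damped Newton iteration with finite-difference
Jacobian, started from the decoupled production/decay balance
($g_P/d_P$), with long-time ODE relaxation as fallback. Convergence is
declared when each equation's residual falls below 1e-9 times that
equation's gross rate magnitude — a relative criterion that remains
meaningful in the fast-binding regime where individual fluxes are
enormous. An independent rapid-equilibrium solver
(`equilibrium_complexes()`, damped fixed-point iteration on the free
concentrations with exact mass conservation) provides an oracle: as
$k^+ \to \infty$ at fixed $K_d$, the mass-action steady-state complexes
converge to the rapid-equilibrium solution, and the test suite verifies
this on random parameter draws.

## The death-rate law

The population death rate is

$$\lambda = \gamma\left(\frac{[\mathrm{BAX}^*]^3}{K_{BAX}^3 +
[\mathrm{BAX}^*]^3} + \frac{\kappa}{1 + \alpha f(\mathrm{APRIL})}\right)
\frac{1}{1 + \beta f(\mathrm{ST2})}$$

with BAX\* in nM at the interface ($K_{BAX} = 200$ nM; concentrations
are µM internally). The Hill term is the core BAX-driven route; the
$\kappa$ term is ER-stress-driven caspase-12 activity, suppressed by
APRIL ($\alpha = 10$, fixed); the trailing factor is ST2's inhibition
of the executioner caspases 3/7. With $\kappa = \beta = 0$ the law
collapses exactly to the core Hill form. The printed form of the
extended law writes the Hill argument as BAX, but the core law and all
figure annotations use activated BAX; we use BAX\* in both, which keeps
the two laws nested.

Survival is $N(t) = 100\,e^{-\int_0^t \lambda(s)\,ds}$, integrated
jointly with the network ODEs (`mode = "trajectory"`) or, since cells
arriving from an intact niche start at the Medium steady state and
relax within a day or two, frozen at the condition's own steady state
(`mode = "steady"`, single-exponential). Both agree when the network
starts in steady state; the trajectory mode is the default for
simulation, the steady shortcut is used inside fitting loops where the
data are themselves single-exponential.

At the packaged annotated parameters the model gives (steady mode)
half-lives of `r paste(round(model_half_lives(annotated_parameters()$kinetic,
annotated_parameters()$death, mode = "steady"), 2), collapse = ", ")`
days for Medium, APRIL, ST2 and APRIL+ST2 — under one day without
signals, over six days with both, bracketing the reported contrast.

## Fitting

`fit_apoptosis_model()` minimises
$\chi^2 = \sum_i ((y_i - f(x_i))/\sigma_i)^2$ with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`). Data enter as:

* **Protein targets.** Measurements are normalized per protein to the
  Medium geometric mean, then summarised either as pro/anti pair
  ratios (BIM/MCL-1, NOXA/MCL-1, BIM/BCL-2; bootstrap sd) or as
  normalized per-protein abundances (replicate sd). Model predictions
  are the corresponding steady-state *total* abundances (free plus
  complexed — antibody staining cannot distinguish binding state).
  Medium-condition targets are identically 1 on both sides and are
  excluded.
* **Survival targets.** Per condition and time point, the replicate
  mean with the replicate sd as $\sigma$.

All uncertainties are floored at 1% of the signal to avoid infinite
weights. Default bounds keep $s_* \in (0, 1.5]$ and the death
parameters non-negative. Finite-difference steps use `epsfcn = 1e-8`:
the residuals carry ~1e-9 numerical noise from the inner steady-state
solves, and the Levenberg–Marquardt default (machine epsilon) would
make the Jacobian noise-dominated. A seeded multistart option guards
against local minima; on noise-free self-consistency data the fit
returns to the generating truth from starting values displaced by
±40%.

**Identifiability.** The ST2 factors and the death parameters are
strongly identified by the default synthetic designs. The APRIL effect
$a_{BCL2} = 0.11$ is a deliberately small effect: with six replicates
at 5% geometric noise, the standard error of the relevant normalized
abundances is itself ~3%, so the best achievable relative precision on
$a_{BCL2}$ is of order 20% — users should not over-interpret its point
estimate from small designs.

## Submodel selection

`enumerate_submodels()` builds the full model plus five reductions:
removing APRIL's caspase-12 inhibition ($\alpha = 0$), all APRIL inputs
($\alpha = 0, a_{BCL2} = 0$), ST2's caspase-3/7 inhibition
($\beta = 0$), both caspase regulations, or the caspase module entirely
($\kappa = \beta = 0$, the core law). The registry follows the
narrative description of the reduced topologies; the exact panel
composition is configurable. Each submodel is refit from scratch
(parameters fixed at zero leave the free set, so $k$ is consistent),
and `rank_models()` reports $-\Delta\mathrm{AIC}$ relative to the worst
model using $\mathrm{AIC} = 2k + N\ln(\chi^2/N)$, flagging differences
above 2 from the best model as significant. AIC differences are only
meaningful between fits to identical data; the ranking warns when $N$
differs.

## Perturbation scans

`perturbation_scan()` multiplies or divides a parameter by 2, 5 or 10
and reports log2 fold changes of the population half-life and of
steady-state BAX\* under a reference condition (default APRIL+ST2, the
full-survival culture). The signalling-level targets are
reconstructions: "NF-kB" jointly scales every APRIL-driven effect
($a_{BCL2}$, $\alpha$); "PI3K" jointly scales every ST2-driven effect —
$\beta$ linearly, and the production factors on the log scale
($s_P \mapsto s_P^{fold}$) so they remain valid fractions. Under the
default reconstruction, caspase-3/7-branch perturbations show the
strongest single-parameter effects, and NF-kB knockdown shortens the
half-life more than PI3K knockdown; these qualitative statements are
asserted in the test suite but are contingent on the topology and the
branch mapping — if you rewire either, re-derive them rather than
assuming they transfer.

## Synthetic data

The generators emulate the *statistical shape* of the two measurement
types, not the instruments:

* `make_protein_dataset()` draws lognormal replicates around the
  model's steady-state totals (geometric means are the natural summary
  for fluorescence intensities; default geometric sd 0.15, typical of
  normalized flow-cytometry replicates; n = 6 replicates).
* `make_survival_dataset()` draws exponential decays at
  condition-specific half-lives (defaults 0.7, 1.5, 1.5, 6.5 days,
  respecting the observed under-one-day / over-six-day bounds) with
  additive Gaussian noise (sd 5 percentage points) clipped to
  [0, 100], on days 0–5 (the practical culture window; co-cultures
  overgrow after ~5 days) with 12 replicates.

Both are deterministic under a seed and attach their generating truth
as metadata. What they do **not** emulate: single-cell heterogeneity,
instrument drift and spectral spillover, replicate-level batch
correlation, non-exponential late-time survival. Passing recovery
tests on these generators therefore demonstrates estimator
correctness under the assumed noise model, not robustness to real
cytometry artefacts.

Clipping at 0 interacts with estimation: fast decays reach the floor
within the sampling window, and on the log scale clipped values must
be dropped, biasing the default log-linear estimator upward for
half-lives well under a day. The linear-space `method = "nls"`
estimator retains those points and is unbiased under additive noise;
use it when curves visibly hit the floor.

## Problem sizes and numerical settings

The shipped test suite exercises: steady-state/ODE agreement and
non-negativity on dozens of random parameter draws; the
rapid-equilibrium oracle on 50 random instances in the fast-binding
limit (relative error below 1e-4); joint parameter recovery on 20
seeded datasets at the default design; and submodel selection on 25
seeded datasets, where the full model ranks first and all reductions
are rejected by wide AIC margins. These sizes were chosen to give
stable pass/fail behaviour at desk scale; larger replications only
sharpen the same conclusions.

## Known limitations

* The network wiring, Kd assignment, complex-decay rule and the
  signalling-branch mappings are reconstructions with documented
  defaults, not measured facts; all are configurable.
* BAK is not modelled separately from BAX, and caspases enter
  algebraically rather than as dynamical species.
* The model describes population-average concentrations; it cannot
  reproduce single-cell apoptosis switching.
* $a_{BCL2}$ is weakly identified at realistic noise (see above).
* In-vivo lifespans (years) are outside the model's domain; the
  culture system it describes holds for days.
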