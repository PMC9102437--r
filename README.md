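# apoptosim

Mechanistic modelling of apoptosis regulation in bone-marrow memory
plasma cells.

Memory plasma cells secrete protective (and sometimes pathogenic)
antibodies for years, but only while their survival niche supplies two
signals: the soluble cytokine APRIL and direct contact to mesenchymal
stromal cells (modelled after the ST2 line). Removed from the niche,
the cells die within a day; with both signals they persist for many
days in culture. `apoptosim` implements a quantitative model of how
these two inputs control the intrinsic apoptosis machinery, for
immunologists and systems biologists who want to simulate, fit and
interrogate that network.

## The model

**BCL-2 family network.** Pro-apoptotic BIM and NOXA, anti-apoptotic
BCL-2 and MCL-1, and the effector BAX (with activated form BAX\*) obey
mass-action kinetics: condition-dependent production, first-order
decay, reversible 1:1 complex formation between anti-apoptotic proteins
and their partners (five pairs, each with a literature dissociation
constant), and first-order BAX activation/deactivation. ST2 contact
scales production of MCL-1, BCL-2, BIM and NOXA by factors `s_P < 1`;
APRIL scales BCL-2 production by `(1 + a_BCL2)`.

**Death-rate law.** The population death rate couples to activated BAX
through a Hill term, extended by algebraic caspase regulation:

    lambda = gamma * ( [BAX*]^3 / (K_BAX^3 + [BAX*]^3)
                       + kappa / (1 + alpha * f(APRIL)) )
             * 1 / (1 + beta * f(ST2))

where `kappa` is the relative caspase-12 effect (suppressed by
APRIL/NF-kB with strength `alpha`) and `beta` the maximal inhibition of
caspase 3/7 by ST2/PI3K; `f` is a Boolean presence indicator (a graded
Hill mode is available). Survival follows
`N(t) = 100 * exp(-integral of lambda)`.

On top of the simulator the package provides chi-square
Levenberg–Marquardt fitting of production and death parameters to
protein-abundance and survival data (jointly or separately), AIC
ranking of reduced network topologies, fold-change perturbation scans
(including NF-kB- and PI3K-branch knockdowns), exponential half-life
statistics with bootstrap uncertainties, and seeded synthetic-data
generators for both measurement types.

## Worked example

```r
library(apoptosim)

fx <- annotated_parameters()      # packaged literature/best-fit values

# steady-state activated BAX (nM) per condition
sapply(default_conditions(), function(cc)
  round(steady_state(fx$kinetic, cc)[["BAXa"]] * 1000, 1))
#>    Medium     APRIL       ST2 APRIL+ST2
#>     117.6     106.8     239.3     225.5

# model-implied population half-lives (days)
round(model_half_lives(fx$kinetic, fx$death, mode = "steady"), 2)
#>    Medium     APRIL       ST2 APRIL+ST2
#>      0.83      5.48      2.44      7.83
```

Stromal contact alone *raises* activated BAX (117.6 to 239.3 nM, a
pro-apoptotic push through the binding network), yet cells still live
longer under ST2 because of direct caspase-3/7 inhibition — the
non-additive signal integration the model exists to capture. Without
any survival signal the population halves in under a day; with both
signals the half-life exceeds six days.

Fitting synthetic data back to the generating truth:

```r
pd <- make_protein_dataset(fx$kinetic, noise_cv = 0.05, seed = 1)
sv <- make_survival_dataset(model_half_lives(fx$kinetic, fx$death, mode = "steady"),
                            n_replicates = 12, noise_sd = 5, seed = 2)
fit <- fit_joint(pd, sv)
fit
#> apoptosis model fit
#>   data: protein survival (N = 33)
#>   chi2 = 9.4885, k = 8, AIC = -25.13, converged: TRUE
#>   estimates:
#>  a_BCL2  s_MCL1  s_BCL2   s_BIM  s_NOXA   gamma   kappa    beta
#> 0.12735 0.42155 0.60770 0.54230 0.43079 0.45454 1.61082 2.45850
```

Submodel selection (`fit_submodels()` + `rank_models()`) reproduces the
finding that every reduced topology — dropping APRIL's caspase-12
inhibition, ST2's caspase-3/7 inhibition, or the caspase module
entirely — is decisively rejected by AIC on data the full model
generated.

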