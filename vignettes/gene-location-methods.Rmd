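---
title: "Methods: modeling the chromosomal versus plasmid-borne location of bacterial genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling the chromosomal versus plasmid-borne location of bacterial genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidfate)
```

## The question and the model

Bacterial genes can sit on the chromosome or on a conjugative plasmid, and
some functions — antibiotic resistance prominently — are over-represented on
plasmids even though plasmids are occasionally lost at cell division. This
package implements a competition model that makes the selective forces on
gene *location* explicit, using antibiotic resistance as the worked example.

Each cell has a chromosome that is resistant (R) or sensitive (S) and
carries at most one plasmid, which is itself resistant, sensitive, or
absent. That yields six cell types, always ordered
`r paste(CELL_TYPES, collapse = ", ")` (chromosome letter first; `0` = no
plasmid). Densities `N` evolve by:

* replication at rate $\lambda$, discounted multiplicatively by the cost of
  resistance ($1-c_R$ per gene copy) and of plasmid carriage ($1-c_P$); a
  dually resistant RR cell pays $(1-c_R)^2$ but gains **no** extra
  protection,
* density-dependent death $\gamma T$, with $T$ the total density,
* antibiotic-associated death $A$ for the two fully susceptible types
  (S0, SS),
* plasmid transmission at rate $\beta$ from any plasmid bearer to any
  plasmid-free cell (carriage of one plasmid excludes the other), and
* segregation loss: a fraction $s$ of replications of a plasmid bearer
  produces a plasmid-free daughter of the same chromosomal type.

`plasmid_rhs()` implements these equations; the derivative of each type has
the form
$N_\bullet[(1-s)\lambda_\bullet - \gamma T - A_\bullet] + \text{infection} +
\text{segregation influx}$. Summing the six equations shows segregation
terms cancel pairwise — plasmid loss moves cells between classes without
creating or destroying them — which the test suite checks as an algebraic
identity.

The default parameter values (`plasmid_params()`: $\lambda=1$, $\gamma=1$,
$A=1$, $c_R=0.05$, $c_P=0.075$, $\beta=0.2$, $s=0.005$) are a reference
parameterisation chosen to display the full range of outcomes, not a fit to
any particular organism; time and density units are arbitrary.

## Equilibria and evolutionary stability

Competitive exclusion rules out coexistence of sensitive and resistant
variants of the same replicon, and dual resistance (a dual cost with no dual
benefit) rules out RR cells at equilibrium. The candidate equilibria are
therefore boundary states: the sensitive population with or without the
(sensitive) plasmid, chromosomal resistance with or without the sensitive
plasmid, and plasmid-borne resistance (S0 hosts plus SR cells). Because the
exclusion argument is verbal rather than a theorem, `attractor_scan()`
integrates from random initial conditions and flags any attractor that
matches none of the candidates; none has ever appeared.

Single-type equilibria are immediate: $N_{S0}^*=(\lambda-A)/\gamma$
(existing only when $A<\lambda$) and $N_{R0}^*=(1-c_R)\lambda/\gamma$. Each
two-type equilibrium (plasmid-free host $X_0$ plus plasmid bearer $X_P$)
collapses analytically: setting the $X_P$ equation to zero gives
$\gamma T=(1-s)\lambda_P - A_P + \beta X_0$, hence
$X_P = a + bX_0$ with $a=((1-s)\lambda_P - A_P)/\gamma$,
$b=(\beta-\gamma)/\gamma$, and substituting into the $X_0$ equation leaves
the quadratic

$$-\frac{\beta^2}{\gamma}X_0^2 +
\left[\lambda_0 - A_0 - (\beta+\gamma)a + s\lambda_P b\right]X_0 +
s\lambda_P a = 0,$$

solved in closed form with the admissible root (both components strictly
positive) selected. Every reported equilibrium is verified to satisfy the
full model with residual below $10^{-10}$.

Evolutionary stability is then assessed in the **full** six-dimensional
model: `stability()` evaluates the analytic Jacobian (`plasmid_jacobian()`,
validated against central finite differences to relative error $<10^{-6}$)
and demands that all six eigenvalues have negative real part. No tolerance
for "negative" is stated in the source analyses, so we adopt an absolute
guard of $10^{-9}$ on the real part; a spectrum within $10^{-9}$ of zero is
reported as *marginal* and counted as neither stable nor unstable. Marginal
spectra arise structurally, not just numerically: with the second-copy cost
removed, the RR direction at the chromosomal equilibrium has growth rate
exactly zero.

`classify_regime()` combines verdicts into *bistable* (both a chromosomal
equilibrium and the plasmid-borne equilibrium stable), *chromosomal_only*,
*plasmid_only*, or *no_resistance*; `phase_sweep()` maps these over any two
parameters. At the reference point the system is bistable — both gene
locations are evolutionarily stable, and whichever establishes first
excludes the other. At a boundary equilibrium the Jacobian block of the
absent types decouples, so `invasion_eigenvalue()` reports the growth rate
of a rare invader restricted to the types it can dynamically reach (the
closure of the nonzero entries of that block); the forward-integration
`invasion_test()` provides an independent check, and the two are required to
agree on randomized parameter draws.

One structural finding deserves note: high antibiotic pressure alone does
*not* destabilise plasmid-borne resistance at the reference costs. Invading
chromosomally resistant cells are immediately parasitized by the resident
resistant plasmid ($\beta X_P^*$ flux into costly RR), and the stability of
the plasmid-borne equilibrium persists as $A\to\infty$; the
chromosomal-only regime instead occupies a narrow band of very cheap
resistance genes ($c_R \lesssim 0.01$ at the default $\beta$, $c_P$). The
transmission/plasmid-cost plane behaves as expected: plasmid-involving
regimes require $\beta$ above a threshold that rises with $c_P$.

## Numerical dynamics and basins of attraction

`integrate_model()` uses the adaptive stiff lsoda family (deSolve), with the
nominal horizon of $10^7$ time units standing in for "integrate to
equilibrium". Because adaptive steps make most of that horizon unnecessary,
integration stops early once $\|\dot N\|_\infty < 10^{-14}$ (a root-finding
stop). The stop threshold is tied to the reporting threshold: final
densities below $10^{-10}$ are rounded to zero (only at the end, never
mid-integration), and the slowest decay rates near the equilibria of
interest are of order $10^{-3}$–$10^{-4}$, so a decaying type has reached
$\sim 10^{-14}/10^{-4} = 10^{-10}$ or less by the time the stop fires. At a
looser stop ($10^{-13}$) borderline cells misreport a still-decaying type as
present; the chosen value leaves a safety factor and outcomes are verified
to be invariant to halving the solver tolerances. Tiny negative excursions
are clipped at the end (with a warning if they exceed $10^{-6}$ in
magnitude).

`classify_outcome()` reads the rounded zero pattern: *plasmid_borne* when
resistant plasmids persist without chromosomal resistance, *chromosomal*
for the reverse, *sensitive*/*extinct* when no resistance survives, and
*mixed* otherwise (never observed under the default assumptions).

`basin_map()` reconstructs the initial-condition experiment: a sensitive
subpopulation of density 1 split between S0 and SS by the frequency $x$,
plus a resistant subpopulation of density 1 split by the plasmid-borne
frequency $y$ — with the chromosomally resistant founders carrying the
sensitive plasmid (panel A) or not (panel B). The default grid is
$41\times41$; the acceptance checks use $21\times21$, and outcomes are
pointwise deterministic so resolution only affects smoothness. The maps
show a single monotone boundary per row and column (positive
frequency-dependent selection) and panel A's plasmid-borne region nested
inside panel B's.

## Structural variants

`variant_config()` exposes the sensitivity-analysis knobs; with every knob
at its default the variant reproduces the core derivative bitwise, because
both share one implementation. Where the original sensitivity analyses are
described only verbally, the following concrete forms were chosen:

* **Gene flow (transposition)** — within-cell relocation of the gene
  between replicons, SR $\leftrightarrow$ RS at equal per-cell rate. This
  is the minimal flow that lets the excluded form persist at low frequency;
  copy-type mechanisms involving RR would need additional assumptions and
  the rate is a free knob, so either convention can be emulated.
* **Fluctuating antibiotic pressure** — a square wave (period, duty
  fraction, on/off levels), integrated piecewise segment-by-segment so the
  solver never steps across a discontinuity. Persistence of each resistance
  form is assessed by simulation from its constant-pressure equilibrium
  (autonomous stability analysis does not apply).
* **Dual-resistance knobs** — the cost of the second gene copy is a free
  parameter (default $c_R$, recovering $(1-c_R)^2$), and
  `single_copy_protection` $<1$ leaves residual antibiotic mortality
  $(1-\pi)A$ for single and $(1-\pi)^2A$ for dual resistance.
* **Independent segregation loss** — plasmid loss as a standalone
  per-capita rate $s\lambda$ decoupled from replication; it matches the
  replication-coupled default up to terms of order $s\times$cost.
* **Growth-slowing antibiotic** — susceptible replication multiplied by
  $1-A/\lambda$ (clamped at zero), calibrated so the susceptible-alone
  equilibrium density equals the death-rate formulation whenever
  $A<\lambda$.
* **Costs as death** — each type's fitness deficit charged as added death
  while all types replicate at $\lambda$.

Stability analysis of a variant starts from the core equilibrium, refines
it into the variant's own equilibrium by damped Newton on the equilibrium's
support (a no-op for the dual-resistance knobs, which leave RR-free
equilibria fixed), and uses a central-finite-difference Jacobian. A small
residual outside the support — the transposition leak out of an equilibrium
that excludes one form — is tolerated, since the true equilibrium is then an
$O(\tau)$ perturbation of the reported one.

The immigration model (`plasmid_rhs_migration()`) adds a constant influx
$\mu$ of chromosomally sensitive cells, a fraction `f_imm` of which carry
the sensitive plasmid; there is no emigration term. A niche-scale influx of
*plasmid-free* sensitive cells is pure fuel for plasmid-borne resistance
(chromosomal resistance cannot infect immigrants), so the overall maps are
more plasmid-favourable at higher $\mu$; what grows with $\mu$ is the
*contrast* between plasmid-free and plasmid-carrying immigrants.

## The multispecies acquisition model

`run_realization()` simulates $n$ species, each starting without the gene
(S) and absorbing permanently into chromosomal (RC) or plasmid-borne (RP)
resistance — absorption encodes the priority effect established by the ODE
analysis. The per-species acquisition hazards are
$m + cN_{RC} + ctN_{RP}$ (to RC) and $pN_{RP} + ptN_{RC}$ (to RP), with $m$
the de-novo mutation rate, $c$ and $p$ the interspecies transfer rates and
$t$ the frequency of the low-frequency form maintained by
plasmid–chromosome gene flow. The source description is phrased as
per-timestep probabilities without a stated timestep; we implement the
model as a continuous-time Markov chain with those expressions as hazards,
resolving each event by competing exponentials — free of timestep artifacts
and of simultaneous-event tie-breaking, and equal to the discrete scheme in
the small-rate limit that all the reference rates occupy. A discrete-time
Bernoulli mode with explicit `dt` is provided and cross-checked against the
CTMC. Ensembles (`ms_ensemble()`, default 1000 realizations) report the
mean proportion of RP species with a normal-approximation 95% CI
($\pm1.96\,\mathrm{SE}$; the CI method of the original is unstated). The
two-species case has the exact solution
$P(\text{RP second}) = pt/(pt+m+c)$, used as an analytic oracle. Because
both RP hazards vanish while no species is resistant, the first acquisition
is always chromosomal, capping the RP proportion at $(n-1)/n$.

## What the scenarios emulate, and what they do not

`builtin_scenarios()` encodes the study designs (regime sweeps, both basin
panels, the immigration experiment at $\mu\in\{10^{-1},10^{-2}\}$, and the
multispecies sweep at $m=10^{-6}$, $c=10^{-5}$, $t=10^{-1}$); these
parameter grids and initial-condition recipes *are* the data of this
analysis — there is no external dataset. Passing tests therefore
demonstrate internal correctness and the claimed qualitative structure of
the model, not agreement with any experimental system: the model omits
demographic stochasticity, spatial structure, multi-copy plasmids and
plasmid co-infection (the relaxation of single-plasmid exclusion is not
implemented here, and `variant_config()` deliberately has no knob for it),
and compensatory evolution.

Problem sizes used by the automated checks — $21\times21$ basin and
migration grids, $7\times7$ variant sweeps, 20 randomized
invasion-agreement points, 1000-realization ensembles — are the package's
chosen desk-scale defaults; all are configurable upward.

## Reproducibility

All stochastic components (random parameter draws, multispecies ensembles,
attractor scans) run under explicit seeds; sweep and scenario outputs are
tidy CSV plus JSON metadata recording parameters, tolerances, seeds and the
package version. `scripts/acceptance.R --seed <int> --out <path>` recomputes
the headline quantities end-to-end from an installed copy of the package.
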