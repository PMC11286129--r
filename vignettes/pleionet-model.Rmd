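---
title: "The pleionet model: coevolution of pleiotropic signalling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pleionet model: coevolution of pleiotropic signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleionet)
```

## The question the model addresses

Immune genes are disproportionately pleiotropic: the same signalling module
often drives both defence and an unrelated life-history trait such as
development. Because immunity is under rapid antagonistic coevolution while
development is under purifying selection, sharing components looks like a
liability — yet pleiotropy persists across taxa. `pleionet` implements an
agent-based model built to probe when a shared downstream module (a
*pleiotropic effector*) is favoured over two independent effectors, and why.

Hosts are pairs of small signed regulatory networks — one immune, one
developmental — that must (a) track a pulsed developmental input and
(b) suppress a replicating parasite that hijacks immune signalling. The two
architectures differ only in their effector layer:

* **independent**: each network has its own detector, three signalling
  proteins and an effector (10 proteins);
* **shared**: the two networks share a single effector (9 proteins).

Both architectures may also evolve regulatory edges *between* the two
networks ("upstream pleiotropy"), which the analysis module reports
separately from the built-in "downstream" sharing of the effector.

## Activation dynamics

Each protein has unit total concentration split into an active fraction
$P_i^*$ and an implicit inactive fraction $1 - P_i^*$; only active protein
regulates. Per unit time-step,

$$\Delta P_i^* = (1 - P_i^*)\sum_j k_{i,j} P_j^*
  \;-\; P_i^*\sum_j I_{i,j} P_j^* \;-\; c\,N_i,$$

where $k_{i,j} \ge 0$ are upregulatory coefficients, $I_{i,j} \ge 0$ the
magnitudes of downregulatory ones, $c = 0.01$ is the protein-use
coefficient and $N_i$ the number of interactions leaving protein $i$ — an
activity cost: regulating more targets consumes more active protein.

Integration is forward Euler with $\Delta t = 1$ and clamping of every
state to $[0,1]$ after each step. The time grain of the model *is* the
unit step (all windows — 5 equilibration steps, a 150-step life, a 50-step
developmental window — are counted in it), so a finer or adaptive solver
would change the model rather than merely its accuracy; the clamped unit
step is the model definition here, not an approximation choice.

**Resource cap.** Resources limit the creation of new active protein. If
the positive deltas of a step sum to more than the cap (0.1 when scarce,
1.0 when plentiful), all positive deltas are scaled proportionally so
their sum equals the cap; negative deltas are untouched. The parasite's
replication delta is included under the same cap: an infection competes
with the host's own signalling for the activation budget. Under the
*alternating* condition the cap switches each generation — scarce on even
generations (starting at generation 0), plentiful on odd. The schedule's
grain is a genuinely open point; per-generation alternation is the
choice here because the cap is a property of the environment a host lives
its whole life in, and it gives each architecture equal exposure to both
regimes over any two generations.

Two implementations of these dynamics coexist deliberately: a pure-R
vectorized path (`regulatory_deltas()`, `apply_resource_cap()`,
`step_state()`) used for exposition and unit-level work, and a compiled
kernel that runs whole life trajectories for the population loops. The
test suite holds both equal to a third, naive per-edge scalar
re-implementation to $10^{-12}$.

## A host's life

1. **Equilibration** — all proteins start at $P^* = 0.5$ and the dynamics
   run 5 steps with no input, letting the evolved network settle.
2. **Development** — for 50 of the 150 life steps the host receives the
   pulsed input $\mathrm{sig}(t) = \sin(x(t)/2) + 0.5$ on the 50-point
   grid $x \in [0, 8\pi]$ (four pulses, mimicking periodic developmental
   programmes such as segmentation). The signal acts as an external node
   with a fixed $+1$ link to the developmental detector; it is an input,
   not a concentration, so it is never clamped and may leave $[0,1]$. The
   source rendering of the formula is ambiguous between $\sin(x/2)+0.5$
   and $\sin(x)/2+0.5$; the half-angle reading is the default because the
   same rendering demonstrably drops division slashes elsewhere, and the
   half-amplitude variant is exposed as `dev_signal_variant` so the choice
   is inspectable rather than buried.
3. **Infection** — each generation every parasite infects one distinct
   host (50% prevalence at default sizes). The parasite joins the immune
   network as an extra node: $+1$ onto the immune detector, an evolved
   coefficient onto its target signalling protein (target index resolved
   modulo the host's immune signalling roster, so any parasite can infect
   any host), and $+0.8$ onto itself (replication). The host's immune (or
   sole shared) effector gains a $-1$ link onto the parasite, and that
   link counts toward the effector's outgoing-interaction cost while the
   infection lasts. Under *synchronous* signalling the infection step is
   drawn uniformly inside the developmental window; under *asynchronous*,
   uniformly inside the 50 steps after it. The reversed order
   (`signal_order = "development-last"`) places the developmental window
   on steps 101–150; its asynchronous infection window is the first 50
   signal-free steps, mirroring the development-first case. The inoculum
   abundance is 0.5 — the parasite is "a new protein in the network" and
   0.5 is the initialization value of every protein; the model states no
   other value.
4. **Fitness** — $W = e^{-(\mathrm{Imm.Eff.Area} + \mathrm{Par.Area} +
   \mathrm{Dev.Cost})}$, with the immune effector area the lifespan-mean
   of immune effector activity (constitutive immunity is costly), the
   parasite area the infection-duration-mean of parasite abundance, and
   the developmental cost $(1 - \mathrm{Corr}(\mathrm{sig}, \mathrm{out}))
   + \mathrm{mean}|\mathrm{sig} - \mathrm{out}|$ over the developmental
   window. A flat effector output makes the Pearson correlation
   undefined; it is taken as 0 because a flat output carries no
   tracking information — it neither matches nor opposes the signal.
   Parasite fitness is the parasite area itself, a proxy for
   transmission.

## The generation cycle

Up to 30% of each population dies per generation. Hosts whose parasite
area exceeded 0.9 die first; a uniform subset is released back if they
exceed the cap. Remaining host deaths come from one randomized pass over
the survivors, each dying with probability $1 - W_i/W_{\max}$. The model
statement — death "inversely proportional to relative fitness" — admits
several forms; this one needs no normalizing constant, guarantees the
fittest survivor always survives its visit, and caps naturally at one
visit per host. Parasite death is strictly rank-based: the least-fit 30%
die, ties resolved in input order.

Surviving hosts reproduce with probability proportional to fitness until
the population is restored (500 independent; the merged size doubles to
1000 in competition). Offspring copy the parent exactly or, at rate
$5\times10^{-3}$, carry exactly one mutation: add an edge (0.25; any
ordered protein pair, cross-network allowed, detector–effector forbidden,
self-loops only on signalling proteins), delete an edge (0.25), redraw a
coefficient on $[-1,1]$ (0.30), delete a signalling protein (0.10), or
duplicate one with all incoming, outgoing and self edges (0.10).
Detectors and effectors are never deleted or duplicated, and each network
keeps at least one signalling protein. Infeasible events are no-ops
rather than resampled, keeping the printed event probabilities exact
without rejection loops. Whether hosts may evolve self-loops is not
stated by the model's description; they are permitted on signalling
proteins (the parasite's self-regulation is the precedent) and forbidden
on detectors and effectors.

Parasites reproduce in fitness order, most fit first, each earning 1, 2
or 3 offspring as its abundance falls in $[0, 1/3]$, $(1/3, 2/3]$ or
$(2/3, 1]$ — the printed bins (0–0.33 / 0.34–0.66 / >0.66) read as a
partition of the continuous unit interval — cycling through the ranking
until the population is replenished. Offspring mutate at $10^{-2}$:
retarget (index redrawn on 0–7, resolved per host by modulo) or redraw
the coefficient.

## Competition

A competitive simulation burns in a shared and an independent population
(250 hosts, 125 parasites each) in isolation for 250, 500 or 1000
generations, then merges them: 500 hosts and 250 parasites in one pool,
one fitness-weighted reproduction market, offspring inheriting their
parent's architecture, host target 1000 from the first reproduction.
The model description merges "their respective parasite populations"
without saying whether prevalence is topped back up; here the merged pool
is left as is, so prevalence halves to 25% during competition — the
conservative reading, and the same for both architectures. Competition
ends at extinction of one architecture or after 1000 generations (a
draw). Draws are excluded from win-percentage numerators and kept in
denominators.

## Analyses

**Knockout robustness.** The host is infected with a *non-disrupting*
parasite — detector, replication and effector links intact but no target
link — so the immune response is provoked without interference. Each
signalling protein (immune and developmental alike; the constraint that a
network keep one signalling protein binds mutation, not measurement) is
removed in turn and the life re-run with infection fixed at the midpoint
of the infection window, so intact/knockout differences reflect structure
rather than timing noise. The score is the mean absolute difference in
immune effector activity over the 150 life steps; the summary is the mean
over knockouts, with the per-knockout distribution also returned.

**Network features.** Connectivity divides realized within-network edges
by the count of valid ordered same-network pairs under the model's edge
rules — detector–effector pairs excluded, self-loops on signalling
proteins only, the shared effector a member of both networks (both
founder rosters have exactly 42 valid pairs; the denominator is
recomputed from the evolved roster). Reported network size subtracts one
from independent hosts to offset their 10-versus-9 founder advantage.
Upstream pleiotropy is any edge joining the two networks' proteins,
excluding edges incident to a shared effector (those are the downstream
kind).

**Regression.** `fit_quasibinomial()` models the final shared fraction of
competition endpoints on synchrony, resources and burn-in length via
`stats::glm(family = quasibinomial())` — logit link, dispersion from the
Pearson chi-square over residual degrees of freedom, standard errors
scaled by its square root. Asynchronous and scarce are the reference
levels; burn-in enters in units of 250 generations. The test suite
cross-checks the dispersion scaling against a manually rescaled ordinary
binomial fit.

**Geometric mean fitness** is `exp(mean(log(w)))`, the variance-penalizing
mean used to compare populations whose arithmetic means overstate their
long-run growth.

## Reproducibility and problem sizes

All randomness flows through R's global RNG; every driver takes a seed,
and `run_campaign()` derives and records a per-row seed from its master
seed so any replicate is reproducible in isolation (base R has a single
global stream, so recorded derived seeds stand in for per-component
substreams). Identical seeds give bit-identical genotypes, trajectories
and histories.

The package's own checks run at sizes chosen to exercise every mechanism
while staying desk-scale: full 500/250 populations for 20 generations for
the generation-mechanics checks, and ten-plus competitive replicates at
50+50 hosts / 25+25 parasites with 200 burn-in generations and a 300
generation competition cap for the qualitative reproduction of the
shared-effector advantage under synchronous, scarce conditions. Ensemble
results over hundreds of 1000-generation simulations are the model's
native scale; the scaled-down setting preserves the prevalence and
death-cap structure exactly and the burn-in:competition ratio
approximately.

## What the model does and does not emulate

Within its scope, founder genotypes are random wirings (each valid
connection present with probability 0.5, coefficients uniform on
$[-1,1]$), so early generations are dominated by selection on standing
variation — as intended, the founders being "genomes" seeding the run.
The model omits, by design: spatial structure, diploid genetics and
recombination, multiple concurrent infections, within-life parasite
mutation, stage-structured trait expression, and unequal trait
contributions to fitness. Passing tests therefore show the mechanisms are
implemented faithfully and that the pleiotropy results emerge from them
at reduced scale — not that any particular biological system is
quantitatively described.

## Numerical notes

* States are clamped to $[0,1]$ after every step; the cap guarantees the
  positive-delta sum never exceeds the limit to within $10^{-12}$.
* Genotype equality for modal-genotype counting is structural and exact
  (architecture, roster, edge list, full-precision coefficients);
  serialization writes coefficients at 17 significant digits so genotypes
  round-trip bit-exactly through text.
* Modal-genotype and parasite-death ties break by first occurrence /
  stable input order, making runs reproducible independent of sort
  internals.
* Degenerate regression designs (a single level of a predictor) drop the
  constant term rather than fitting a singular model; non-convergence is
  warned about, not silently returned.
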