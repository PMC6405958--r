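---
title: "Organization-oriented coarse-graining of reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organization-oriented coarse-graining of reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorg)
```

chemorg analyses chemical reaction networks through the lens of *chemical
organization theory*: instead of following every concentration, it asks
which *sets of species* can persist together, and coarse-grains both the
static network and its stochastic dynamics to the level of those sets.
The bundled model hierarchy describes the mitotic spindle assembly
checkpoint (SAC) — the mechanism by which a single unattached kinetochore
blocks anaphase — at four levels of detail, from a 14-species biochemical
network down to a four-state model of individual kinetochores.

## The static theory

A reaction network is a pair of a species set $\mathcal{M}$ and a reaction
set $\mathcal{R}$; each reaction $r$ has reactant and product multisets and
a mass-action rate constant $\lambda_r$.  The stoichiometric matrix
$N = (n_{i,r})$ holds net productions.  For a species set
$A \subseteq \mathcal{M}$:

* $\mathcal{R}_A$ is the set of reactions whose reactants all lie in $A$
  (the reactions that can *fire* in $A$; an inflow with empty left-hand
  side fires everywhere);
* $\mathrm{dp}(A)$ is the union of product sets over $\mathcal{R}_A$
  (*direct production*);
* $A$ is **closed** when $\mathrm{dp}(A) \subseteq A$; every $B$ has a
  unique smallest closed superset $G_{CL}(B)$, reached by iterating
  $B_{i+1} = B_i \cup \mathrm{dp}(B_i)$;
* $A$ is **self-maintaining** when a flux vector $v$ exists with
  $v_r > 0$ for $r \in \mathcal{R}_A$, $v_r = 0$ otherwise, and
  $N v \ge 0$ on the relevant rows — i.e. the fireable reactions can run
  at strictly positive rates without any member species decaying.

A closed and self-maintaining set is an **organization**.  Organizations
matter dynamically: the species sets with strictly positive concentrations
at fixed points (and many other limit sets) of the mass-action ODE system
are organizations, for *any* choice of kinetic constants.  The Hasse
diagram of organizations under inclusion is therefore a rate-free map of
where the dynamics can settle.

### Numerical choices

Strict positivity is encoded as $v_r \ge 1$; the system is homogeneous, so
feasibility is scale-invariant.  Substituting $w = v - 1 \ge 0$ turns the
test into a standard-form LP feasibility problem solved with a Big-M
simplex (`pracma::linprog`); any witness is re-verified against
$Nv \ge -10^{-9}$ before being accepted, and $10^{-9}$ is the global
feasibility tolerance.  For a closed set all species rows are enforced
(species outside a closed $A$ have no fireable consumer); for a non-closed
set the rows are restricted to the members of $A$.

`generate_self_maintaining()` needs a removal order, which the theory
leaves open.  We iterate an LP that maximises the minimum net production
over the current set (fluxes $\ge 1$ on fireable reactions, the objective
capped at 1 so it is bounded) and remove *every* species with negative net
production at the optimum, recomputing fireable reactions until nothing is
removed.  This is deterministic and removes provably unmaintainable
species in batches.  `generate_organization()` alternates closure and
self-maintaining generation to a joint fixed point: in *consistent*
networks one pass $G_{SM}(G_{CL}(B))$ suffices, but the self-maintaining
set of a closed set need not be closed in general, so the result records
whether more than one pass was needed (`consistent_pass`).

`enumerate_organizations()` finds all closed sets first — an exhaustive
sweep over the $2^{|\mathcal{M}|}$ subset lattice up to 14 species
(bitmask-vectorised), and closure-driven exploration from the closure of
the empty set upward beyond that; both strategies are tested to agree —
and then LP-tests each closed set.  Output order is always size, then
lexicographic by sorted member names, so results are byte-stable.  Cover
edges are the transitive reduction of inclusion.

"Interesting" organizations are selected by a boolean species-presence
predicate (grammar: `OR` over `AND` over atoms and parentheses).  The
bundled presets require a kinetochore in some form plus the regulatory
machinery in some form; e.g. for the coarsest model,
`(KinA OR KinU) AND (Activator OR Inhibitor)`.

```{r}
m3 <- sac_model("model3")
m3
lat <- enumerate_organizations(m3)
tidy(lat)
length(filter_interesting(lat, sac_predicate("model3")))
```

## The stochastic layer: discrete organizations

With finitely many molecules the static picture is too coarse: both too
few and too many molecules can block reactions.  `build_ctmc()` constructs
the continuous-time Markov chain over all count vectors with total at most
$N_{\max}$, with mass-action rates
$\lambda_r \prod_{s \in \mathrm{LHS}(r)} q(s)$ (falling factorials where a
coefficient exceeds one); transitions that would exceed the cap are
absent.  State order is lexicographic in the counts, so state ids are
reproducible.

The chain is decomposed into strongly connected components (via igraph).
A **bottom** SCC (BSCC) has no outgoing transition; a component is
**good** when every reaction whose reactants all appear in the component's
species footprint $\varphi(T)$ labels at least one internal transition
(any internal transition of an SCC lies on a cycle, so this captures
"contains a cycle of the firing").  **Discrete organizations** are
extracted as:

* the footprint of *every* BSCC — any BSCC state is an internal generator
  of its footprint, because reachability closure and the return-sequence
  condition hold trivially inside a bottom component.  Note this is
  deliberately *not* filtered by static closedness: with inflow reactions
  the cap can truncate firings so that a BSCC footprint is not closed in
  the static sense, yet it is still a discrete organization in the
  reachability sense;
* plus the footprint of every good non-bottom SCC whose footprint *is*
  statically closed (for a closed footprint, reachable states cannot
  introduce new species, so the reachability closure equals the
  footprint).

For the coarsest SAC model this reproduces the static lattice exactly:

```{r}
mc <- build_ctmc(m3, N_max = 5)
mc
discrete_organizations(mc)$species
```

Expected leaving times of a state block solve the first-passage linear
system on the embedded jump chain.  The exit *probability* is solved
first; a state is reported as `Inf` when it falls below $1 - 10^{-9}$,
which avoids solving a singular expected-time system for blocks that are
never left.  `block_transition_probabilities()` assembles the
organization-level coarse-grained chain: blocks are the non-empty
present-species classes ($\le 2^{|\mathcal{M}|}$), and for each block the
probability that each other block is the first one entered.  The entry
distribution over a block's states is uniform by default — an explicit
approximation knob, since nothing in the construction dictates it — with
an entry-rate-weighted alternative (`entry = "entry"`).  Outgoing rows sum
to one within $10^{-9}$ for non-absorbing blocks.

`is_internal_generator()` is a literal-definition oracle used by the test
suite, not by the pipeline: a bounded breadth-first search over composed
firing sequences (budget $4 N_{\max} |\mathcal{R}_q|$; exceeding it raises
an error rather than answering).  It implements the sequence semantics as
stated; whether Parikh-vector semantics would be equivalent is left open,
so the oracle does not assume it.

## Exact trajectory simulation

`ssa_simulate()` is a direct-method stochastic simulation algorithm (no
cap, no tau-leaping — exactness matters more than speed at these sizes).
Trajectories carry their seed, so runs are reproducible byte for byte.
For the coarsest SAC model, the kinetochore count and the
activator-plus-inhibitor count are conserved along every path, and every
trajectory with unattached kinetochores is eventually absorbed in the
state where all kinetochores are attached and all inhibitor has relaxed —
the dynamic realisation of the single interesting organization
`{Activator, KinA}`:

```{r}
traj <- ssa_simulate(m3, c(KinU = 10, Activator = 50), t_max = 1e5, seed = 1)
traj
```

The fixture rate constants (attachment 0.01, inhibition 1.0, relaxation
0.1 per time unit; nominal binding/unbinding rates in the larger models)
are chosen to display the checkpoint switching shape; all organization
results are independent of them, and they can be edited in the `.rn`
files.

## The four-state kinetochore model

The finest spatial question — must the "wait" signal be global? — is
studied with a deliberately minimal model: each of $n = 92$ kinetochores
is a node on a $10 \times 10$ plane (or an explicit graph) with states
*unattached* → *attached* → *about-to-exit* → *exit*.  Updates are
synchronous, reading neighbor states from the pre-step configuration:
attachment with probability 0.005 per step, attached → about-to-exit with
probability $p$, and a node in about-to-exit moves irreversibly to exit
exactly when all of its neighbors (Euclidean distance $\le$ radius; self
excluded) are in about-to-exit or exit, falling back to attached
otherwise.  The all-neighbors condition over an empty neighborhood is
vacuously true — isolated nodes may exit — which is precisely what makes
small radii fail.  A trial *fails* when an exited node coexists with an
unattached one; it *succeeds* when all nodes exit; hitting the step cap
without failure is reported as a timeout and counted as success (with
$p = 0$ no trial can fail, and with a complete neighborhood no node can
exit early, so the estimate is 1 in both regimes — the timeout count is
reported alongside).  Success estimates carry Wilson 95% score intervals.

```{r}
params <- lattice_params(n = 92, p_exit = 0.5, radius = 20, max_steps = 500)
success_probability(params, trials = 20, seed = 1)
```

With a complete neighborhood the failure predicate is *unreachable* — the
test suite verifies this exhaustively over all $4^n$ configurations for
$n \le 4$ and by seeded trials at $n = 92$ — whereas small radii with
fast exit fail with high probability: checkpoint reliability requires the
wait signal to be global.  An exact oracle
(`exact_success_probability()`) enumerates the full synchronous chain for
$n \le 3$ and anchors the Monte-Carlo estimator within three standard
errors.

## Spatial organizations

At the compartment level, space is a graph of well-stirred compartments
coupled by diffusion; each compartment holds one kinetochore (so `KinU`
and `KinA` are mutually exclusive within a compartment).  The *spatial
organization* of a compartment is the organization generated by the union
of species in its hop-distance-$r$ neighborhood, including itself —
an upper bound on the compartment's fate at the timescale implicitly set
by the neighborhood radius.  Radius is measured in hops because the
compartment layout is a graph; geometric space belongs to the kinetochore
module.  The generation network defaults to the short-timescale coarsest
model, matching the transition-phase setting.  No quantitative rule links
diffusion rates to the radius; the radius is an interpretation parameter.

```{r}
spatial_organization_map(sac_compartment_fixture(), sac_model("model3b"),
                         radius = 1)[, c("compartment",
                                         "neighborhood_species",
                                         "organization_species")]
```

Compartments 3 and 4 hold identical species but map to different
organizations — locality in the species pattern does not determine local
fate; the neighborhood does.

## The bundled model hierarchy

Six fixture networks ship as editable `.rn` files: the coarsest model
(`model3`: 4 species, 3 reactions), the reduced model (`model2`: 7
species, 9 reactions, with the APC/C lumped into
Promotor/Promotor_A/Promotor_I classes), and the full model (`model1`: 14
species, 21 reactions, covering the Mad2 template mechanism, mitotic
checkpoint complex assembly and APC/C regulation), each with a
pro-metaphase variant (`model1b`/`model2b`/`model3b`) obtained by removing
kinetochore attachment (plus, for `model1b`, the slow O-Mad2 decay) via a
removal manifest.

The coarsest network is specified exactly.  The two larger reaction lists
are *reconstructions* from published network diagrams, and their
validation is by organization structure: the long/short organization
counts (16/64 for the full model, 8/16 for the reduced model) and the
interesting-organization counts under the bundled predicates are the
arbiter, and the acceptance suite asserts them.  For the reduced model the
reconstruction also reproduces the published membership of all three
interesting short-timescale organizations.  For the full model the counts
pin down less of the chemistry: the reconstruction reproduces 16/64 and
the uniqueness of the interesting long-timescale organization, but the
membership of that organization ({KinA, Cdc20, BubR1:Bub3,
Cdc20:BubR1:Bub3} here) and the short-timescale interesting count are not
uniquely determined by the counts and should not be over-interpreted.
Mass consistency of every reaction (each complex's composition is
conserved) was imposed throughout, which is what makes counts this
constraining.

What these fixtures do *not* emulate: three-dimensional particle
diffusion, reactor geometry, realistic copy numbers of the full proteome,
and measured kinetic constants.  Passing tests therefore certify the
organization-level structure and the qualitative switching dynamics, not
quantitative time courses of real cells.

## Problem sizes and limitations

The test suite and the acceptance script run the full-model enumeration
over all $2^{14}$ subsets with LP checks (seconds to a minute), CTMCs at
$N_{\max} \le 10$ (1001 states for four species), stochastic trajectories
up to 92 kinetochores with 1000 activator molecules, and 200 seeded
four-state trials of 92 nodes with a step cap of 2000 (attachment
completes in roughly 1500 steps at rate 0.005, and with a complete
neighborhood longer horizons only add timeout steps).  Known limitations:
state-space construction is dense in the number of states (guarded at
$2 \times 10^6$); the coarse chain's entry distribution is an
approximation; exact four-state enumeration is limited to $n \le 3$;
and organization enumeration above ~20 species would require the
exploratory strategy plus problem-specific pruning.
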