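---
title: "Modeling host-plasmid communities on coupled ecological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling host-plasmid communities on coupled ecological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`plasmidnets` simulates a community of bacterial host populations and
conjugative plasmids as an exact stochastic (Gillespie) jump process. The
state is the integer abundance table $H_{i,p}$ over subpopulations: all
individuals of host $i$ carrying exactly the binary plasmid profile $p$
(element $\alpha$ of $p$ is 1 iff plasmid $\alpha$ is present; one copy per
cell; with $n_b$ hosts and $n_p$ plasmids there are at most
$n_b \cdot 2^{n_p}$ subpopulations). Two fixed binary networks constrain
the dynamics:

* the **infection network** $I$ (hosts × plasmids): $I_{i\alpha} = 1$ iff
  plasmid $\alpha$ can conjugate into host $i$;
* the **compatibility network** $P$ (plasmids × plasmids, symmetric, zero
  diagonal): $P_{\alpha\beta} = 1$ iff $\alpha$ and $\beta$ can stably
  co-reside in one cell. Plasmids are self-incompatible.

A profile is *feasible* for a host iff every carried plasmid can infect the
host and every carried pair is compatible. Five event channels act on
subpopulations, with per-capita rates

* death $\mu_{i,p} = \mu_i$;
* growth $\eta_{i,p} = \eta_i \prod_{\alpha \mid p_\alpha = 1}
  (1 - c_\alpha)$ — plasmid costs are multiplicative, i.e. a slight
  positive epistasis relative to additive costs;
* segregation $\omega_{i,p} = e_i \eta_{i,p}$: a division in which the
  daughter loses *all* plasmids, so the host's plasmid-free subpopulation
  gains one individual and the parent subpopulation is unchanged;
* competition $\xi_{i,p} = \eta_{i,p} \sum_j b_{ij} H_j / K$, a direct
  mortality term under a community-wide carrying capacity $K$, with
  $b_{ij} = 1 + a_{ij}$ off-diagonal and $b_{ii} = 1$ — all hosts draw on
  one shared resource pool;
* infection $\phi_{i,p} = \gamma_i \sum_{(k,q) \in L(p)} H_{k,q}$, where
  $L(p)$ is the donor profile's recipient list; $\phi = 0$ for plasmid-free
  profiles. $\gamma$ is donor-host-specific and profile-independent.

Channel totals are abundance-weighted sums and the usual exact-SSA loop
applies: exponential waiting time $\Delta t = X/R$ with $X \sim$ Exp(1),
channel choice proportional to channel totals, actor choice proportional
to per-capita rate × abundance. A conjugation event picks a donor by its
infection rate, a recipient by abundance within the donor's list, and a
transconjugant from the normalized column of the **propensity tensor**:
transferring the set $s \subseteq p \setminus q$ (non-empty, all able to
infect the recipient host, union $q \cup s$ feasible) has raw weight
$1/2^{\nu-1}$ with $\nu = |s|$, and each (donor profile, recipient) column
is normalized to one. The recipient loses one individual, the
transconjugant gains one, the donor is untouched. Because all four
transfer conditions involve the recipient's host but not the donor's, the
tensor and the recipient lists are indexed by donor *profile* only — this
is what makes the incremental bookkeeping below cheap.

## What the default parameters mean

`trait_params()` defaults describe the uniform theoretical community of
three hosts and four plasmids: growth $\eta = 1\,h^{-1}$, death
$\mu = 0.12\,h^{-1}$, conjugation encounter rate
$\gamma = 10^{-5}\,(\text{cell}\cdot h)^{-1}$, segregation error
$e = 10^{-8}$, plasmid cost $c = 0.3$ (a 30% growth-rate reduction per
carried plasmid), $K = 20000$ cells, interspecific competition
$a_{ij} = 0.01$. Uniform traits mean hosts and plasmids differ only in
their network position, so any asymmetry in outcomes is attributable to
structure. The canonical motifs (`build_infection_network()`,
`build_compatibility_network()`) are the 3 × 4 full/nested/modular
infection structures and 4-plasmid full/modular/hub compatibility
structures; `factorial_design()` crosses them into the nine coded cells.
The canonical initial condition is 2000 plasmid-free individuals per host
plus 10 individuals of every reachable mono-plasmidic subpopulation, so
every plasmid is established in each focal host before transfer begins.
The theoretical horizon is 20000 h with snapshots every 5 h.

Two degrees of freedom are fixed by package choice where the motif family
leaves them open: the intermediate row of the nested motif is the strict
stair-step $H_2 = \{P_1, P_2, P_3\}$ (the generalist and specialist rows
are fixed by the motif definition), and the modular motif uses
$H_1 = \{P_1, P_2\}$, $H_2 = \{P_2, P_3\}$ (bridge), $H_3 = \{P_3, P_4\}$.
Outcomes are invariant under consistent relabelings; the modular motif
maps onto itself under the reversal $H_1 \leftrightarrow H_3$,
$P_1 \leftrightarrow P_4$, $P_2 \leftrightarrow P_3$.

## The scaled desk preset

Replicating the full design (300 replicates × 20000 h × 9 cells at
$K = 20000$) is a batch-compute job. For interactive work and for the
package's own test suite, `preset_params("scaled")` transports the system
to $K = 2000$. Unimolecular rates carry over unchanged, but the
bimolecular conjugation rate is scaled inversely with system size
($\gamma = 10^{-4}$), the standard system-size transport of a mass-action
pair rate: the per-capita infection force $\gamma N$ — and with it the
plasmid invasion threshold — is preserved. Without this scaling every
plasmid at $K = 2000$ sits *below* its invasion threshold
($\gamma N \approx 0.017\,h^{-1}$ against a net per-capita loss of
$\approx 0.036\,h^{-1}$) and the community trivially sheds all plasmids.
Initial conditions scale alongside to 200 plasmid-free per host; the
mono-plasmidic inoculum is kept at 10 (rather than scaled to 1) so that
every mono-plasmidic subpopulation is reliably established, preserving the
design intent that each plasmid already exists in its focal hosts.

At this scale the package's checks run the following problem sizes, chosen
once: 100 replicates run to single-survivor absorption for the host-
symmetry check under full/full; 50 replicates to 1500 h for hub-plasmid
fixation under full-I/hub-P; 100 replicates to 1500 h for bridge-host
extinction under modular-I/full-P; 30 replicates for nested-I dominance;
12 replicates per cell for the cost × structure comparison. 1500 h is the
point by which, at $K = 2000$, the conjugation flux has absorbed the
plasmid-free and mono-plasmidic subpopulations of surviving hosts into
multi-plasmid compositions. Because extinction and fixation outcomes at
this scale are absorbing-state or symmetry driven, they are robust to the
reduced capacity; quantities that are *not* scale-free (e.g. the ≈ 0.4
two-host coexistence probability at 20000 h under modular I, which is
drift-limited and therefore contracts with $K$) are checked only
qualitatively (non-zero, and exceeding the full-network control).

## Metrics

`relative_host_abundance()`, `plasmid_prevalence()`, `host_composition()`
(per-replicate within-host profile proportions averaged over replicates in
which the host survived, hosts surviving in more than 5 replicates only),
and `coexistence_probability()` (fraction of replicates with at least — or
exactly — $k$ extant hosts per recorded time) mirror the standard
community summaries for this kind of experiment. "Survived" means positive
abundance at the final recorded snapshot; standard errors are across
replicates. `classify_coexistence()` distinguishes stable coexistence
(≥ 2 hosts at the end) from transient-only coexistence.

## Numerical design

The event loop is compiled (Rcpp) and maintains channel totals
incrementally: an event changes at most two cells, and each cell change
touches only the per-host aggregates and the recipient-sums of the donor
profiles whose lists contain that cell (a precomputed reverse adjacency).
Abundance-valued aggregates are exact integers in doubles; the
floating-point aggregates (realized-growth sums) are refreshed from
scratch every $2^{22}$ events to bound drift. The package tests replay the
engine's event log against a full R-side recomputation of all channel
totals at every step, so the incremental path is proven equivalent to
recomputation. Sampling uses linear cascades over at most
$\max(n_b, 2^{n_p})$ weights with a last-positive-weight fallback against
floating-point cascade rounding.

Randomness comes from R's own RNG stream (`unif_rand`/`exp_rand` under
`set.seed()`), so runs are reproducible across platforms for a fixed R
RNG kind. Replicate seeds are spawned from an ensemble base seed by one
`sample.int()` draw per replicate; experiment cells spawn their own base
seeds the same way.

Snapshots record the state *after* the first event at or past each grid
multiple (the alternative — pre-event state — differs by one event and is
immaterial at the recording resolution); the final state is always
recorded. Termination occurs at the horizon, at community collapse, or —
optionally — at single-host absorption, which is exact for
survival-frequency analyses because host count can never recover.

Degenerate inputs are handled explicitly: a zero total rate is an
absorbing state and terminates the run; infeasible initial states are
rejected at configuration time; the plasmid-free profile has zero
segregation and infection rates (the formal segregation event of a
plasmid-free cell would be indistinguishable from growth; its rate,
$e_i \eta_i \approx 10^{-8}$, is folded to zero rather than into growth).

## The mean-field companion and what validation shows

`meanfield_derivatives()`/`integrate_meanfield()` provide the
deterministic expectation of the jump process: the same per-capita rates,
with conjugation as mass action
$\gamma_j H_{j,p_d} H_{k,q}$ split over transconjugants by the normalized
tensor column. In the single-host plasmid-free limit this reduces to
logistic-type growth with equilibrium $H^* = K(1 - \mu/\eta)$ (17600 at
the table parameters — an algebraic check in the tests). The stochastic
engine is validated against it in the near-equilibrium regime of a
1-host/1-plasmid system, where the mean-field flow is the expectation of
the process to leading order: ensemble means of 200 replicates match
within Monte-Carlo error at every recorded time. Far from equilibrium
(growth from a small inoculum) the deterministic limit acquires a genuine
finite-size lag relative to the mean of the stochastic process, so
agreement there is not a valid engine test and is not asserted. The
propensity tensor has an independent brute-force oracle
(`brute_force_tensor()`, a naive scan of all profile triples against the
four transfer conditions) that must and does agree entry-by-entry on all
nine canonical cells.

## The empirical scenario

`make_empirical_config()` encodes a 3-host × 2-plasmid laboratory-style
community (*P. fluorescens* SBW25, *P. putida* KT2440, *E. coli* MG1655
with plasmids pQBR57 and pKJK5): a modular infection network with the
*P. putida* host as the bridge, a full compatibility network, $K = 10^5$,
each host starting at $3.3 \times 10^3$ split half plasmid-free and half
across its carriable plasmids, over a 240 h (10-day) horizon. Trait values
are *synthetic placeholders* honoring the published orderings — growth
$H_1 \le H_2 < H_3$, conjugation $H_1 = H_2 < H_3$, costs $P_1 < P_2$,
competitive effects $H_1 < H_2 < H_3$ — and are overridable once measured
values are available. The conjugation placeholder is set so the infection
force $\gamma K \approx 0.02$–$0.04\,h^{-1}$: strong enough for plasmids
to spread, weak enough that prevalence does not saturate within 240 h —
at saturating force both plasmids reach prevalence 1 under a full
infection network and the structure contrast (which plasmid leads) cannot
be expressed. The placeholder scales with $1/K$ so the scenario can be run
at reduced capacity.

## What the simulations emulate — and what they do not

The generator reproduces the study conditions: uniform traits (theoretical
part), small fixed network motifs, well-mixed populations, single-copy
plasmids, purely costly carriage, fixed networks. It does not emulate
spatial structure, multi-copy plasmids and partial segregation, beneficial
accessory genes, evolving networks, or larger empirical network sizes —
so passing tests speak to the model's internal consistency and to the
structure-driven mechanisms above, not to quantitative prediction for any
real community.

## Limitations

Runtime grows with $K$ (total event rate) and with $n_b 2^{n_p}$ (tensor
and list construction); the exact SSA is not accelerated by tau-leaping
or parallelism beyond independent replicates. Trajectory storage is
plain-text CSV (a two-table relational layout readable by any tabular
tool); binary formats are out of scope. The closed-form prevalence
results available for uniform traits are not reproduced symbolically; the
mean-field system is the package's deterministic reference instead.
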