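---
title: "Methods: the coevonet host-parasite network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coevonet host-parasite network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevonet)
```

## The model

`coevonet` simulates antagonistic coevolution between two populations of
gene regulatory networks — a *host* and a *parasite* — in which the parasite
is rewarded for mimicking the host's phenotype and the host for escaping the
mimicry. Because each population's fitness landscape is generated by the
other population, the selective environment is an emergent property of the
simulation rather than an externally imposed target.

### Genotype-to-phenotype map

A genotype is an $N \times N$ real matrix $W$; $w_{ij}$ is the regulatory
effect of gene $j$'s product on gene $i$'s cis-regulatory region (positive =
activation, negative = repression, zero = no interaction). Expression states
$S(t) \in [0,1]^N$ evolve synchronously:

$$S(t+1) = \sigma\!\big(W\,(2S(t) - 1)\big), \qquad
  \sigma(x) = \frac{1}{1 + e^{-a x}}.$$

The regulatory input is *centered at the basal expression point* 0.5. This
is a deliberate reading of the model family's dynamics: because
$\sigma(-x) = 1 - \sigma(x)$, the centered map guarantees that whenever
$S^\*$ is a steady state of $W$, its inversion $1 - S^\*$ is too. That twin-
attractor symmetry is the structural backbone of the whole phenomenon the
package studies — populations alternating between a phenotype and its
inversion. Under the uncentered alternative $\sigma(WS(t))$, switched-off
genes stop contributing to regulation altogether; we verified empirically
that "switch this gene off" mutations then generically produce period-2
limit cycles, the inverted state is usually not an attractor, and neither
alternation nor mutational sensitivity can evolve at the standard
parameters. Genes whose $W$-row is entirely zero have no inputs and sit at
the basal level $\sigma(0) = 0.5$ exactly; they are excluded from inversion
tests.

Development (`develop()`) iterates the map from a fixed random binary
initial state $S(0)$ and declares a steady state when the largest per-gene
change stays below `conv_tol` ($10^{-4}$) for `conv_window` (10) consecutive
steps, within `max_steps` (100). Limit cycles therefore never converge;
non-developing genotypes are non-viable (zero fitness). The sigmoid gain
defaults to $a = 20$, making converged non-basal expression effectively
binary; the gain is exposed in `dynamics_params()` and all quantitative
plateau values quoted below were measured under this default.

### Selection

Each generation both species update synchronously from the other species'
*pre-update* generation. Every candidate is scored against a freshly drawn
random opponent:

$$f_{\text{parasite}} = e^{-D/\alpha}, \qquad
  f_{\text{host}} = e^{-(1-D)/\alpha},$$

where $D$ is the phenotype distance and $\alpha$ the selection strength
(smaller = stronger). The two functions are mirror images intersecting at
$D = 1/2$. The default distance is the *mean squared difference*
$D = \sum_i (x_i - y_i)^2 / N$, the form the model family prints; the
root-mean-square variant is available via `fitness_distance = "rms"`. The
choice matters: under the default ("msd") form, inter-founder distances are
about 0.5 and worst-case survival probabilities about $e^{-5}$, which makes
plain viability selection feasible; under the rms form the same quantities
reach $e^{-7}$ to $e^{-10}$ and a fixed-size population of threshold
survivors cannot be filled.

Two selection schemes are implemented:

* `selection = "proportional"` (default): Wright-Fisher sampling — each
  current individual is scored once per generation, parents of the $M$
  offspring slots are drawn with probability proportional to fitness, and
  offspring are only filtered for developmental viability.
* `selection = "threshold"`: a candidate offspring survives iff its fitness
  exceeds a fresh $U(0,1)$ draw; parents are drawn uniformly and candidates
  are generated until $M$ survive (viability selection, the survival rule
  the model family states explicitly for its split-selection variant). The
  attempt budget (`max_attempt_factor * M`) must accommodate the losing
  species' mean survival of order $e^{-1/\alpha}$.

Both schemes produce the same qualitative phenomenology (alternating
phenotypes, emergent distributed sensitivity, rising robustness and
diversity), and they bracket the reference's quantitative plateaus: in
matched 3-replicate, 1,500-generation runs the threshold rule gave a
steady-state sensitivity plateau of $\approx 0.13$ and a host
sign-diversity plateau of $\approx 0.66$, while proportional sampling gave
$\approx 0.09$ and $\approx 0.33$–$0.36$ — the latter pair matching the
reference plateaus ($\approx 0.08$; $\approx 0.45$). The proportional
scheme is therefore the default; the comparison is reproducible by flipping
the config switch.

### Reproduction and mutation

Reproduction is clonal by default; sexual reproduction draws two distinct
parents and inherits each $W$ row from one of them with probability 1/2
(row = cis-regulatory region, free recombination among loci). Mutation
draws a Poisson number of events per offspring; each event picks a uniform
random matrix element: a zero element gains a fresh $N(0,1)$ weight with
probability $\rho$ (addition), a nonzero element is zeroed with probability
$\phi$ (deletion) and otherwise redrawn from $N(0,1)$ (modification). With
$\rho = \phi = 0.025$ the expected density change
$\mu(\rho(1-c) - \phi c)/N^2$ vanishes at density $c = 0.5$, the founder
density.

The mutation-rate parameter `mu` (default 0.1) is interpreted as the rate
*per gene*, so the genotype-level event count is Poisson($\mu N$) — one
expected event per genotype per generation at the defaults. We adopted the
per-gene reading after three independent consistency checks of the
per-genotype alternative failed: (i) with Poisson(0.1) events per genotype
the density recurrence's own relaxation time is $N^2/(\mu(\rho+\phi)) =
20{,}000$ generations, so an off-equilibrium population provably cannot
re-equilibrate on the few-thousand-generation horizon the protocol uses;
(ii) genotypes carrying 3–4 simultaneous new mutations would occur at rate
$\sim 10^{-6}$ and could not produce measurable lineage statistics; and
(iii) empirically, populations under the per-genotype rate cannot even
track a fixed target phenotype ($D$ stalls at 3–5 mismatched genes
indefinitely), and no alternation, sensitivity or diversity emerges in
1,500 generations. Under the per-gene reading all of these behave as the
model family describes.

### Measurements

**Sensitivity score.** A virtual mutation replaces one interaction
$w_{ij}$ by a value $l$ drawn from $N(0, \sigma^2)$, evaluated on a regular
grid $l \in \{-L, -L+\delta, \dots, L\}$ (defaults $L=3$, $\delta=0.02$,
$\sigma=1$; 301 points carrying $\approx 99.73\%$ of the Gaussian mass).
The phenotype is *inverted* when the $L_1$ distance over non-basal genes
exceeds $p_{\text{flip}}(N - N_b)$ with $p_{\text{flip}} = 0.9$;

$$SS_{ij} = \sum_l \delta \, f(l) \, k(l)$$

with $f$ the Gaussian density and $k(l)$ the inversion indicator, and the
genotype-level $SS$ is the mean over all $N^2$ interactions. "Unchanged"
phenotypes are those within `same_tol` $\cdot (N - N_b)$ in the same $L_1$
sense (`same_tol = 0.1`, the complement of $p_{\text{flip}}$); mutational
robustness is the Gaussian-weighted fraction
unchanged / (unchanged + partially-changed), with non-viable mutants
counted as changed and inversions excluded. Non-viable mutants score
$k(l) = 0$ for $SS$.

**Environmental robustness** develops each genotype from 500 perturbed
copies of $S(0)$ (per-gene flip probability `rate`), averaging the mean
absolute phenotype distance to the unperturbed phenotype, excluding
inversions and non-converging runs.

**Diversity** maps each genotype to its sign matrix and counts distinct
patterns as a fraction of the population. **Lability** compares the
sensitive-interaction set ($SS_{ij} > 0$) of an individual with that of its
closest same-phenotype ancestor per lag bucket, with a size-preserving
random-relocation null; the spread of sensitivity among the sensitive
interactions is compared against a string-cutting (Dirichlet) null.
**Modularity** uses the partition-quality score
$Q(C) = \sum_i [|E(C_i)|/l - (\sum_{v \in C_i} \deg(v)/2l)^2]$ on the
undirected, self-loop-free interaction graph, maximized by deterministic
greedy agglomeration plus single-vertex relocation (exhaustive search
verifies the optimizer in the tests for $n \le 8$).

**Alternation detection** looks for the signature of the alternating
strategy: *rapid* inversions of the binarized modal phenotype (most genes
flipping within at most `flip_window` = 5 generations), repeated at least
`min_cycles` = 3 times in both species, each departing from a plateau
consistent with the previous inversion's endpoint. Gradual phenotype
turnover — which also flips genes, but never most of them within a short
window — is deliberately not counted. The detector works from the
population-mean expression, so a population that splits into two stable
phenotype clusters of similar size reads as indeterminate (near 0.5) and is
not scored as alternating; this polymorphic regime does occur in a minority
of runs and is reported as such.

## Model variants

* **Split selection** (`split_fitness()`): half the genes are scored
  against the founder phenotype (stabilizing), half against the antagonist
  (coevolutionary), with the scale factor $\zeta$ (1 continuous, 4 discrete)
  and survival requiring both components to beat independent $U(0,1)$
  draws. The stabilizing component is printed in the source model as
  $1 - e^{-d/\alpha}$, which rewards *large* distance from the stabilizing
  target and yields zero fitness at the optimum; the package defaults to
  the self-consistent $e^{-d/\alpha}$ and keeps the printed form behind
  `stabilizing_form = "printed"` as a documented suspected typo.
* **Environmental-perturbation fitness** (`espinosa_fitness()`):
  $f = 1 - e^{-3\gamma}$, $\gamma = \sum_i (1 - D_i/D_{\max})^5 / 400$ over
  400 perturbed initial states (per-gene flip rate $0.15/N$), $D_i$ the
  Hamming distance of the binarized perturbed phenotype to the target;
  non-converging runs contribute $D_{\max}$ (default $N$, configurable).
* **Discrete dynamics** (`discrete_develop()`): states in $\{-1,+1\}^N$,
  $s_i(t+1) = \mathrm{sign}(\sum_j w_{ij} s_j(t))$ with $\mathrm{sign}(0) =
  +1$ fixed for determinism; fixed points converge, limit cycles (detected
  exactly — the state space is finite) do not.
* **Modularly varying goals** (`run_mvg()`): a single population with 4
  clamped input genes and 6 regulatory genes (one the output) evolves
  toward alternating boolean goals $G_1 = (X \oplus Y) \lor (Z \oplus W)$
  and $G_2 = (X \oplus Y) \land (Z \oplus W)$, switching every 50
  generations; fitness is the fraction of the 16 input patterns mapped
  correctly. An interaction is *MVG-sensitive* when some grid mutation
  makes the network match the alternate goal in more than 12 of 16
  mappings. Because the sigmoid has no intrinsic threshold, logic gates
  obtain their bias from a self-locked always-ON gene; the perfect-$G_1$
  fixture builds each XOR from a NAND/OR pair and reads the output through
  a single linear threshold that is exact on the reachable gate states.
  Two control regimes replace the logic goals with alternating phenotype
  targets (half- or fully-inverted founder phenotype) under stabilizing
  selection, scoring sensitivity with the standard inversion criterion.

## Study conditions and problem sizes

The generator defaults *are* the standard study conditions: $N = 10$,
$M = 200$ per species, $\mu = 0.1$ per gene, $\alpha = 0.1$, founder density
$c = 0.5$, $\rho = \phi = 0.025$, asexual reproduction, fixed $S(0)$ per
population. Under these conditions, scaled-down replicate runs of 1,500
generations show: a monotone rise of mean $SS$ from $\approx 0$ to a
plateau of roughly 0.09; mutational robustness dipping and then climbing to
$\approx 0.7$–$0.8$; host sign-diversity plateauing around 0.33–0.36; and
rapid phenotype alternation in both species within the first tens of
generations. The packaged protocols use 3 replicates of
800–1,500 generations with sensitivity sampled on 20 individuals every
50–100 generations — sizes chosen so a complete analysis runs on a desk
machine in minutes while the plateaus are already unambiguous.

One reference behaviour did not reproduce: in the source model the
alternating strategy fails to evolve for $\alpha$ above roughly 0.15,
whereas in this implementation alternation (with declining inversion
frequency) persists well beyond $\alpha = 0.3$ under every combination of
selection scheme, distance convention, founder density and sigmoid gain we
tested. The selection mechanics of the reference are not specified at the
level of detail needed to reconstruct what suppresses alternation there;
the package reports its own critical $\alpha$ honestly from an extended
grid rather than asserting the reference value.

## What the synthetic data do and do not show

All inputs are generated internally (random founders, random binary initial
states); there is no external data. The model emulates regulatory evolution
under idealized conditions: fixed population sizes, non-overlapping
generations, a constant developmental environment, equal gene counts in
both species, and mutation restricted to single-element weight changes.
Passing tests therefore demonstrate the *internal* consistency of the
implementation and the emergence of the modeled phenomena under those
idealizations — not that real host-parasite systems behave quantitatively
like the model. Degenerate inputs are handled by convention and tested:
all-basal networks develop to uniform 0.5 and have zero sensitivity and
robustness 1; empty sensitive sets compare with Jaccard index 1; the
one-block partition has modularity exactly 0; `x = 1` string cutting has
SD 0.

## Numerical choices

Convergence uses the $L_\infty$ step change with a 10-step confirmation
window, so slowly contracting states are accepted while period-2 cycles are
rejected regardless of phase. The mutation grid includes $l = 0$
(deletion-like) with its ordinary Gaussian weight. Gene relabeling permutes
all per-interaction scores consistently; all stochastic components run
through R's single seeded RNG stream (including the compiled code, which
uses the R RNG), so a seed fixes every result bit-exactly. Ties in the
greedy modularity optimizer are broken toward the lowest cluster indices,
making it deterministic without randomization.
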