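---
title: "Probabilistic contour integration with afield: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic contour integration with afield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(afield)
library(dplyr)
```

## The problem

Human observers can spot a chain of curvilinearly aligned Gabor elements
hidden among randomly oriented distractors, even when the local density of
elements carries no information about where the chain is. `afield` implements
a complete probabilistic account of this ability:

1. a **generative model** in which contours are sampled from a Markov chain
   whose transition density is an *association field* (AF);
2. **stimulus construction** that hides generated contours among distractors
   with matched nearest-neighbour distance statistics, so that only relative
   edge alignment distinguishes the target hemifield;
3. an **observer** that inverts the generative model, accumulating per-edge
   starting-edge likelihoods by iterated matrix multiplication and making
   two-alternative forced-choice (2-AFC) decisions;
4. **decision statistics** that quantify how strongly two response patterns
   agree beyond what their accuracies predict (a mid-p excess-correlation
   statistic with an exact combinatorial null); and
5. a **grid search** for the fixed-parameter observer that best reproduces a
   reference set of decisions, subject to reaching the reference performance.

Everything can be exercised end to end on synthetic data: a panel of noisy
synthetic observers stands in for human subjects.

## The generative model

An *edge* is an element at position $(x, y)$ (degrees of visual angle, DVA,
screen-centred) with a full-circle direction $\theta \in [0, 2\pi)$.
Directions, not orientations: a contour travels along its edges, and keeping
the full circle prevents the creation process from reversing by 180° between
steps.

A contour of length $L$ starts with an edge placed uniformly at random with
uniform direction; each subsequent edge is drawn from the AF conditioned on
its predecessor. By translation, rotation, and reversal symmetry the AF
reduces to a density over three pair coordinates: the distance $d$, the
viewing angle $\phi$ (the angle under which an observer sitting on the first
edge and looking along its direction sees the second), and the direction
difference $\Delta\theta$.

The density factorizes into a radial and an angular part,
$$ A_{\text{full}}(d, \phi, \Delta\theta) \;=\; R(d)\, A(\phi, \Delta\theta), $$
with

* $R(d) \propto e^{-d/\lambda}$, a truncated exponential with spatial
  constant $\lambda$ (DVA);
* $A(\phi, \Delta\theta) = V\!\left(\phi - \tfrac{\Delta\theta}{2};\,
  \sigma_1/2\right) V\!\left(\Delta\theta;\, \sigma_2\right)$, a product of
  von Mises factors $V(x;\sigma) = \exp(\kappa \cos x)/(2\pi I_0(\kappa))$
  with $\kappa = 1/\sigma^2$.

The first factor concentrates placements around the *co-circular*
configuration $\Delta\theta = 2\phi$ (two edges tangent to a common circle).
We measure the deviation in the viewing angle, $\phi - \Delta\theta/2$, at
angular scale $\sigma_1/2$, which is equivalent to penalizing the
direction-space deviation $\Delta\theta - 2\phi$ at scale $\sigma_1$ for
small deviations but — crucially — is single-moded in $\phi$: a density
written directly on $\Delta\theta - 2\phi$ is $\pi$-periodic in $\phi$ and
would assign the *backward* placement ($\phi = \pi$, same direction) the same
density as the forward one, so generated contours would fold back on
themselves and the directionality predictions below would vanish. The second
factor penalizes the direction change itself, which at fixed distance is
proportional to the curvature of the connecting arc. Both principles —
decay with deviation from co-circularity at scale $\sigma_1$, decay with
curvature at scale $\sigma_2$ — are retained exactly.

With this parametrization $\int\!\!\int A \,d\phi\, d\Delta\theta = 1$
analytically, and sampling is exact (inverse-CDF for $d$, von Mises draws for
$\Delta\theta$ and the co-circularity deviation), so the sampler and the
density can be tested against each other by goodness of fit.

```{r af-sections}
p <- af_params(sigma_align = 0.28, sigma_curv = 0.56, lambda_radial = 2.4)
plot_af_sections(p)
```

**Overlap repair.** Strongly curved contours can fold so that two
non-consecutive edges would collide when rendered as finite-width Gabors. The
repair permutes the sequence of relative steps $(d, \phi, \Delta\theta)$ and
rebuilds the contour from the same starting edge until the separation
constraint holds; the multiset of consecutive-pair configurations — the
pairwise statistics that define the ensemble — is conserved exactly.

## Hiding contours among distractors

A stimulus consists of two hemifields split at $x = 0$; the contour lies in
one of them. Background edges start on a jittered grid at the condition's
spacing, take Brownian steps (standard deviation $0.1\times$ the spacing)
under a hard minimum-separation constraint, and relax to a steady state
(judged by the Kolmogorov–Smirnov distance between the background
nearest-neighbour distributions of successive sweeps). An outer loop then
replaces the contour's step lengths with draws matched to the *measured*
background nearest-neighbour (NN) distribution and repeats until the three NN
distributions — background–background (bb), background–contour (bc),
contour–contour (cc) — are statistically indistinguishable at the available
sample size.

Three implementation details matter and are our own choices, since no
constants are prescribed for this procedure:

* **Which distance is matched.** We match first-nearest-neighbour distances;
  the matched statistic is exactly what a density-based strategy could
  exploit.
* **The quantile map.** An interior contour edge's NN distance is the
  minimum of its two flanking steps. Interior steps are therefore drawn at
  the max-of-two-uniforms quantile of the background NN distribution
  ($u \mapsto 1-(1-u)^2$), which makes the minimum of two adjacent draws
  marginally follow the background distribution; the two end steps, which
  *are* their edges' NN distances, are drawn from it directly.
* **Border correction.** Background edges near the field boundary have
  inflated NN distances (fewer neighbours); the bb sample therefore excludes
  the outermost half-spacing band (minus-sampling), mirroring the interior
  placement of the contour.

Removed background edges are replaced at random admissible positions so that
neither hemifield ends up sparser. A *decoy path* — a mirrored copy of the
final matched contour's positions with uniformly random directions — is
placed on the opposite hemifield, so even higher-order positional statistics
carry no cue. A *mask* shares every position with its stimulus but has all
directions redrawn.

Two checks quantify success: the pooled KS statistics between the three NN
distributions stay below 0.1 at ensemble scale, and a classifier using only
local density (guessing the more crowded hemifield) performs at chance.

```{r stimulus, fig.height=4.5}
spec <- ensemble_spec(p, L = 6, n_stimuli = 2, field_width = 20,
                      field_height = 16, spacing = 2.4, ensemble_id = "demo")
st <- build_ensemble(spec, seed = 7)
plot_stimulus(st)
```

## The observer

Given the $N$ edges of one hemifield, the link matrix
$Q_{ij} = A_{\text{full}}(e_i \to e_j)$ collects all pairwise link densities
(zero diagonal). Per-edge salience weights
$$ w_i = 1 - a\,(\varepsilon_i/\varepsilon_{\max})^{\gamma} $$
attenuate evidence with eccentricity $\varepsilon_i$ (distance from
fixation); $a = 0$ gives the translation-invariant observer, and $\gamma$
sets the concavity of the fall-off. The default
$\varepsilon_{\max} = 16.66$ DVA is the maximum eccentricity of the default
field (whose corners lie at 16.64 DVA).

Starting-edge likelihoods accumulate by the weighted matrix iteration
$$ b^{(0)} = w, \qquad b^{(n)} = W\,Q\,b^{(n-1)}, $$
with $W = \mathrm{diag}(w)$; $b^{(n)}_i$ sums, over all $n$-step paths
starting at edge $i$ (consecutive edges distinct), the product of link
densities and salience weights. Detecting contours of $L$ edges takes
$L - 1$ iterations, and with $w \equiv 1$ the weighted recursion reduces
exactly to the unweighted one. An independent brute-force oracle enumerates
the same path sum explicitly on small instances; the two agree to $10^{-10}$
relative error. (Path sums with *all-distinct* edges differ from the matrix
recursion from $L = 3$ on — the recursion only excludes immediate returns —
so the recursion is taken as the defining object, consistent with computing
the likelihoods "by matrix multiplication".)

For the 2-AFC decision, each hemifield's summed likelihood is normalized by
its number of ordered edge configurations,
$M_X = N_X (N_X - 1)\cdots(N_X - n)$, and the observer responds with the
larger side; exact ties fall to a seeded coin flip. Configuration-independent
prior factors cancel in the comparison, and with equal hemifield counts the
normalization itself cancels.

**Iterations as time.** Assuming link signals propagate at a constant speed
$v$, one iteration bridges the mean element distance $\bar d$ in time
$\bar d / v$; an exposure duration (SOA, stimulus-onset asynchrony) of $t$ ms
then corresponds to $\mathrm{round}(t v / \bar d)$ iterations, clamped to
$[1, L-1]$. The default $v$ = 13.9 DVA per 200 ms (the approximate contour
extent of the default design) maps the longest exposure, 200 ms, to the full
$L - 1$ iterations in every condition.

**Directionality.** Contour creation is directed, and the observer inherits
that: likelihood propagates along the chain, so at the final iteration the
largest per-edge likelihood sits at an *end* element of the contour.
Symmetrizing the link matrix (averaging over flips of either edge's
direction by $\pi$) produces the classical undirected coupling, and the peak
moves to *interior* elements — a qualitative, experimentally testable
signature that separates the two coupling schemes:

```{r dynamics, fig.height=3.5}
mod <- observer_model(p)
dyn <- symmetrize_af_dynamics(st, mod, "unidirectional")
autoplot(dyn)
```

## Decision statistics

For observers $a$ and $b$ answering the same $S$ stimuli of one condition
with $n_a$ and $n_b$ correct responses, the number $k$ of identical responses
under the assumption that errors fall on stimuli at random has an exact null:
the both-correct overlap $m$ is hypergeometric, and since a 2-AFC response is
identical exactly when both are right or both are wrong,
$k = S - n_a - n_b + 2m$ (so $k$ has fixed parity). The excess-correlation
statistic is the mid-p tail probability
$$ \Phi = P(k' < k_{\text{obs}}) + \tfrac12 P(k' = k_{\text{obs}}), $$
whose null expectation is *exactly* $1/2$ for any $(S, n_a, n_b)$ — the
continuity correction makes the calibration exact, including the degenerate
single-atom cases $n_a \in \{0, S\}$ (where $\Phi = 1/2$ identically; such
conditions are included, not skipped). $\Phi > 1/2$ means two response
patterns agree more often than their accuracies can explain, i.e. they share
stimulus-specific structure.

Supporting machinery: the performance score $P$ (fraction of conditions
where a model's correct count reaches the mean reference count, ties
counting as reached); leave-one-out *prototype observers* (stimulus-wise
majority votes of the remaining panel, ties broken by a seeded coin flip),
whose excess correlation with the held-out observer benchmarks what a
noise-free model can reach; and a permutation threshold obtained by
shuffling each observer's correctness pattern within conditions, which
preserves every per-condition accuracy exactly while destroying
stimulus-locked agreement.

```{r phi}
tidy(null_pmf(4, 3, 2))
phi_pair(3, null_pmf(4, 3, 2))
```

## Synthetic observers

The synthetic panel shares one base observer model (the shared,
stimulus-dependent difficulty) and adds independent symmetric lapse noise:
each observer's base response flips with probability $\eta \in [0, 0.5]$.
This is the simplest mechanism that reproduces the qualitative structure of
a human panel — above-chance pairwise $\Phi$ driven by shared difficulty,
degraded by independent noise; $\eta = 0.5$ gives pure noise and $\Phi = 1/2$.
An optional softmax mode draws responses from a logistic function of the
log likelihood ratio for graded difficulty sensitivity. The default
$\eta = 0.15$ produces panel accuracies and pairwise excess correlations in
the range typical of trained psychophysical observers on this task.

## The model search

Candidate observers vary $(\sigma_1, \sigma_2, a, \gamma)$; the radial scale
$\lambda$ is not a search dimension — it is fixed per condition to the
condition's spacing (for generation) or supplied globally. Every candidate is
run once over all stimuli at full iteration depth; from that single pass both
criteria are computed: $P$ against the reference panel and the model–panel
excess correlation $\Phi_{MH}$. Candidates with $P < 0.5$ (out-detected by
the reference in most conditions) are inadmissible — the qualitative
exclusion "performance inferior to the reference" needs a numeric cut, and
half the conditions is our choice, configurable via `perf_cutoff`. Among
admissible candidates the largest $\Phi_{MH}$ wins; if nothing is admissible
the best candidate is still reported, flagged.

In parameter-recovery experiments on synthetic panels, the angular scales
dominate identifiability: $\Phi_{MH}$ is sharply peaked along
$(\sigma_1, \sigma_2)$ but shallow along $(a, \gamma)$, because eccentricity
weighting only flips decisions whose likelihood margins are already small.
Recovering $(a, \gamma)$ therefore needs hard conditions (strong jitter,
full-field eccentricity range); even then expect one-grid-step uncertainty.

## Default experiment design

Six AF jitter pairs $(\sigma_1, \sigma_2)$ — (4°, 8°), (8°, 8°), (8°, 16°),
(16°, 16°), (16°, 32°), (32°, 32°) — crossed with seven contour lengths
$L \in \{4, 5, 6, 7, 8, 10, 12\}$ give 42 ensembles of 48 stimuli each
(2016 per session), with targets balanced 24/24 across hemifields. Total
contour extent is held at 14.4 DVA, so the mean inter-edge distance
$14.4/L$ spans 1.2–3.6 DVA; each ensemble's generating radial scale equals
its spacing. The field is $26.6 \times 20$ DVA around fixation; SOAs are
$\{20, 30, 60, 100, 200\}$ ms. The jitter values and the length grid are
package defaults chosen to span straight/aligned through curved/jittered
conditions at the published design scale; they are reconstructions, not
published values, as are the radial constant and the Gabor sizes in DVA.

## Numerical choices and degenerate inputs

* Von Mises densities use exponentially scaled Bessel functions, so
  $\sigma$ down to $10^{-3}$ rad is safe; sampling uses the Best–Fisher
  rejection algorithm (exact at any concentration).
* Coincident edge positions make the viewing angle undefined and raise a
  degenerate-geometry error naming the pair.
* Contour sampling resamples steps that leave the field (reflection would
  bias the angular statistics). A contour that wanders into a corner facing
  outward could stall; after a per-edge proposal budget the whole contour is
  restarted rather than forcing degenerate tiny steps.
* Brownian relaxation uses parallel proposals with conflict rejection; the
  steady-state check compares successive bb NN distributions (KS < 0.02 over
  five consecutive sweeps) under a sweep cap of 25.
* Exact likelihood ties in the 2-AFC rule and majority-vote ties in
  prototypes are broken by seeded coin flips, keeping every pipeline
  deterministic under a master seed.
* Eccentricities beyond $\varepsilon_{\max}$ are clamped with a warning.

## What the synthetic tests do and do not show

The test suite validates the machinery at reduced problem sizes chosen for a
laptop-class budget: the distance-matching checks pool 20 default-grid
ensembles of 10 stimuli; the matched-observer comparison uses 2000 trials at
$L = 5$ on a $22 \times 16$ DVA field; parameter recovery uses 10 hard
ensembles of 48 stimuli on a $4 \times 4 \times 3 \times 3$ grid; the
directionality contrast uses 100 small ensembles. The synthetic panel
emulates shared stimulus difficulty plus independent lapses — it does not
emulate sequential effects, criterion drift, attention lapses correlated in
time, or eccentricity-dependent human noise, so passing tests demonstrate
the correctness and calibration of the machinery, not that the flip-noise
panel is a quantitative model of human observers.

Known limitations: the matched-parameter optimality holds over the AF
jitter-parameter family. Distance matching deliberately replaces the
generator's radial step statistics with the background's, so after matching
an observer with a shorter radial scale than the generator's can edge out
the nominally matched one — the optimality comparison is therefore run on
raw (unmatched) generative ensembles, where the inversion argument applies.
The exact forms in the source literature for the angular kernel could not be
recovered; the forms here implement the stated principles and symmetries and
are validated against their own sampler and oracles.
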