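---
title: "Measuring category distributions with discrete MCMC with people: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring category distributions with discrete MCMC with people}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcmcp)
```

## The model

A category is modeled as a subjective probability distribution p(x | c)
over a discrete stimulus set: the probability that item x would be offered
as an exemplar of category c. The measurement device is a Markov chain
whose states are items and whose acceptance step is a two-alternative
forced choice. On each trial the responder sees the chain's current item x
and a proposed item x′ and picks the better category member. Under the
exponentiated Luce (ratio) rule the proposal is chosen with probability

$$P(x' ; x \mid c) = \frac{p(x'|c)^{\gamma}}{p(x'|c)^{\gamma} + p(x|c)^{\gamma}},$$

which is the Barker acceptance function for the target
$p(\cdot|c)^{\gamma}$ (renormalized). If the proposal distribution
q(x′; x) is symmetric, the chain satisfies detailed balance with respect
to that target, so post-burn-in visit frequencies estimate it. Three
consequences shape the package:

* **γ lives on the responder, not the engine.** The chain never needs to
  know γ; a more deterministic responder (γ > 1) simply yields a sharpened
  estimate $p^\gamma$. Orderings of items are preserved for any γ > 0, so
  "which items are most typical" is identified even when γ is not.
  `luce_chooser()` carries γ; `exponentiate_target()` produces the matching
  reference distribution for simulation checks.
* **Everything hinges on proposal symmetry.** That is why proposals come
  from random walks on *degree-regular* graphs (next section), and why
  `proposal_distribution()` exists: it enumerates the exact proposal matrix
  Q on small graphs so symmetry can be asserted to numerical precision
  rather than assumed.
* **The chooser is an interface.** Anything that returns one of two offered
  items is a valid acceptance oracle: the simulated Luce chooser, or a
  replay of a recorded human session (`replay_chooser()`), which reproduces
  the original chain trajectory exactly.

## Proposal graphs by maximum-weight b-matching

Choosing each item's b most similar neighbors does not give a valid
proposal support: neighborhood is not symmetric and degrees vary, which
breaks q(x′; x) = q(x; x′). Instead the graph solves

$$\max_G \sum_{i<j} G_{ij} S_{ij} \quad \text{s.t.} \quad \sum_j G_{ij} = b,\; G_{ii}=0,\; G_{ij}=G_{ji},$$

a maximum-weight b-matching on the similarity matrix S. The constraint is
read per node — every item has exactly b neighbors — which is what the
symmetry argument needs.

Two solvers are provided:

* `bmatch_exact()` — branch-and-bound over edges in lexicographic order
  with per-node top-k suffix bounds. It is deliberately capped (default
  n ≤ 12): its role is to be a trustworthy oracle for tests, not to scale.
  Among equal-weight optima it returns the lexicographically smallest edge
  set (include-first depth-first search with strict-improvement
  incumbents), so results are deterministic even on tied weights.
* `bmatch_message_passing()` — synchronous max-product updates
  $m_{i\to j} \leftarrow S_{ij} - \text{b-th max}_{k \ne j}(S_{ik} + m_{k\to i})$
  with damping (default 0.5), a seeded tie-breaking jitter of magnitude
  1e-12, and extraction by mutual top-b selection. Convergence is declared
  when messages settle below `tol` *or* the extracted edge set is stable
  across several successive checks; messages often keep drifting by tiny
  amounts long after the selection has locked in.

**Feasibility as a certificate.** Max-product is provably exact on this
problem only when the LP relaxation is tight; on a small fraction of dense
instances (odd-cycle frustration) it settles on a fixed point whose mutual
selection drops an edge, leaving some nodes at degree b − 1. In every such
case the failure is visible in the output itself — the graph is not
b-regular — and the attached degree report says so. The package's
equivalence test exploits this: across a fixed range of seeded instances,
every *feasible* (exactly b-regular) message-passing output must equal the
exact optimum, and feasible outputs must be the large majority.
Degree-deficient outputs are kept rather than repaired: experiments of
this design are routinely run on graphs with residual degree variation,
and the walk operates on each node's actual neighbor set.

A maximal matching need not be connected. `largest_connected_component()`
extracts the component chains run on (ties go to the component containing
the smallest item index), and `validate_graph()` reports symmetry, zero
diagonal, connectivity, regularity and aperiodicity. With any positive
uniform-jump probability the proposal support is all items, so
irreducibility and aperiodicity hold regardless of graph quality; without
a jump, aperiodicity is equivalent to the graph being non-bipartite
(checked by 2-coloring).

## Proposals

`proposal_spec()` configures the walk:

* `kind = "uniform_neighbor"` — one uniform step to a neighbor; on a
  b-regular graph the base proposal matrix is A/b, symmetric by
  construction.
* `kind = "geometric_walk"` — a step count k ~ Geometric(`geom_param`)
  on {1, 2, ...}, then k uniform-neighbor steps. Support starts at 1
  because a 0-step walk would propose the current item and waste a trial.
  The endpoint may still equal the start (the walk can return); the engine
  re-draws such proposals. `geom_param = 0.5` is the conventional setting;
  `geom_param = 1` degenerates to a single step.
* `jump_prob` — probability of proposing an item uniformly at random
  (default 0.10, the conventional value). The jump branch is drawn first;
  it may land on the current item, in which case the engine re-draws.

`proposal_distribution()` enumerates Q exactly, truncating the geometric
series at a stated length and reporting the untracked mass
$(1-p)^{T}$ (flagged when above 1e-6). On regular graphs both kinds give
max |Q − Qᵀ| at numerical zero; on irregular (approximate-matching) graphs
the walk uses actual neighbor sets and the resulting mild asymmetry is
accepted and measurable through the same enumeration.

## The session engine

`session_config()` mirrors the standard in-lab session: several chains per
category, `trials_per_chain` (default 100) chain trials each, `n_practice`
(default 12) practice trials first, `n_catch` (default 40) catch trials
inserted at seeded random positions among the post-practice slots, chains
interleaved round-robin. Practice and catch trials never advance any
chain; a test asserts this by replaying chain continuity from the log.
Each chain starts at a seeded uniform-random item unless `init_states` is
given; `link_sessions()` starts each chain at the previous session's final
state, which is how 100-trial sessions accumulate into 1,000-trial chains
across ten participants.

Catch trials pair an item of very high target probability with one of very
low probability (`make_catch_trials()` samples from the top and bottom
20% pools), and record the correct answer. `catch_exclusion()` passes a
session iff at least `catch_pass_threshold` catch answers are correct. The
default threshold is the conventional 27 of 40; `binomial_catch_threshold()`
computes the exact binomial-tail value, which at α = .01 is 28 — the
conventional value is one trial more lenient than the exact tail, and both
are reported rather than silently reconciled.

Randomness is strictly partitioned: the session seed drives initialization,
proposal draws, trial ordering and left/right display; each simulated
chooser owns a private RNG stream seeded at construction. The partition is
what makes replay exact — a replayed session consumes the engine stream
identically while taking choices from the log.

Degenerate inputs are errors, not silent defaults: an empty session
configuration, a chain started outside the graph, both choice strengths
zero, burn-in swallowing every trial, catch thresholds without catch
trials.

## Estimation and diagnostics

`empirical_distribution()` normalizes post-burn-in chain-trial counts over
a caller-supplied item universe. The default counting mode is per-trial
chosen items; a "states" mode is nominally distinct but coincides because
the state after a trial *is* the chosen item — only chain trials count in
either mode. Burn-in is per chain. The default burn-in is 0 because the
averaging diagnostics conventionally use all trials; recovery tests pass
an explicit burn-in instead.

`sliding_cumulative_average()` evaluates windowed means of chosen items'
features at 40 log-spaced trial counts (all trials up to t when
t < window; default window 50). `within_between_convergence()` computes
cumulative histograms per chain and averages pairwise L1 distances within
and between categories; a converging design shows the within curve
dropping below the between curve. `l1_histogram_distance()` is the plain
L1 metric (2 for disjoint normalized histograms), and `total_variation()`
is half of it — the recovery metric. `category_frequency()` and
`top_k_items()` are normalized choice proportions by tag and
count-ranked items (ties by ascending id).

For image stimuli, `color_histogram()` buckets pixels into 11 basic colors
by nearest-prototype matching in RGB against fixed documented anchors — a
deliberate simplification of published basic-color boundaries, adequate
for similarity computation, not colorimetry. `combine_similarities()`
rescales each descriptor's off-diagonal entries to unit variance before
summing, so descriptors on different scales contribute comparably; the
diagonal is excluded because matching ignores it, and a zero-variance
input is an error naming the offending matrix.

## Synthetic study conditions

The fixture generator exists so that every claim is testable without any
external dataset. `make_stimuli()` draws standard-normal features
(default d = 2); `make_target_distribution()` places isotropic Gaussian
kernels at chosen mode centers — the kernel family is a package choice
(real categories are elicited, not specified), picked for smooth,
controllable multimodality; `perturb_similarity()` adds symmetric Gaussian
noise scaled by `noise_level` times the off-diagonal standard deviation of
S, making the level unit-free, with the diagonal untouched.

The recovery studies use these fixed conditions:

* **Stationary recovery (γ = 1) and exponent recovery (γ = 2):** 50 items
  on a 1-d feature line, bimodal target (modes at the 25th and 75th
  feature quantiles, kernel width 0.3), a 6-regular ring over the feature
  ordering (the similarity-optimal b-regular graph on a line, used because
  the exact solver does not reach n = 50), uniform-neighbor proposals with
  a 10% jump, 20 linked sessions of 1,000 chain trials (20,000 total),
  burn-in 2,000, three seeds. Total variation to the (γ-adjusted) target
  is required to be below 0.05 per seed.
* **Noise robustness:** the full pipeline (2-d features, message-passing
  matching at b = 6, largest component) at a fixed budget of 5,000 trials,
  noise levels {0, 1, 4}, ten seeds; mean TV must be non-decreasing in the
  noise level within one Monte-Carlo standard error of the paired
  difference. Two-dimensional features are used here because near-colinear
  1-d geometry makes the noise-free matching prone to disconnection, which
  confounds the comparison with component-size effects.
* **Acceptance-rate check:** an 8-item fixture run long enough that
  frequently offered ordered pairs (≥ 2,000 offers) have empirical move
  rates within 0.02 of the Luce closed form.

These sizes are the package's own choices balancing statistical resolution
against run time; they are stated here so the reported numbers are
interpretable.

What the generator does *not* emulate: realistic feature statistics of
faces, words or photographs (features are isotropic Gaussian); perceptual
similarity structure (similarity is exact negated distance plus controlled
noise); and human behavior beyond the exponentiated Luce rule — no lapses,
learning, response-time effects or left/right biases. Passing tests
therefore certify the machinery (graph construction, symmetry, acceptance
dynamics, estimators), not that any particular human population behaves
like the simulated chooser.

## Known limitations

* Feature extraction for real modalities (Gabor/PCA pipelines, local
  image descriptors, semantic embeddings) is out of scope; users supply
  feature matrices or precomputed similarity matrices.
* The exact matcher is exponential and capped at small n by design; at
  scale only the message-passing solver applies, with the feasibility
  caveat above.
* Geometric-walk proposals on irregular graphs are only approximately
  symmetric; the package measures the asymmetry (via exact enumeration on
  small graphs) but does not correct it.
* Inferential statistics over human participants (tests between groups,
  effect sizes) are not provided; the package stops at distribution
  estimates and convergence diagnostics.
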