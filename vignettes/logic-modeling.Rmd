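---
title: "Training logic models of signaling networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training logic models of signaling networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lognet)
```

## The modeling problem

Protein signaling networks process extracellular cues (growth factors,
cytokines, drugs) into changes in the phosphorylation state of downstream
proteins. Databases and literature describe which proteins *can* interact,
but not which interactions are functional in a given cell type under a given
condition. `lognet` addresses this gap by training logic models: a *prior
knowledge network* (PKN) — a signed directed graph of candidate
interactions — is confronted with a perturbation dataset in which
combinations of stimuli and small-molecule inhibitors are applied and a
panel of phosphoproteins is measured. The trained model is the sub-network
of the prior knowledge that best explains the measurements, penalized for
size so that unsupported interactions are dropped.

## Input formats and normalization

Networks are read from SIF text files (`source sign target`); datasets from
MIDAS CSV files (`TR:` cue columns, paired `DA:`/`DV:` time/value columns
per readout, one row per condition/time). Inhibitor cues are recognized by
the conventional `i` suffix on the `TR:` column name, with an explicit
override map for dialects that name the drug rather than its target.
Duplicate condition/time cells are an error by default — silent averaging
hides plate-layout mistakes — and can be averaged explicitly with
`merge_duplicates = TRUE`.

Raw intensities are mapped to the unit interval before modeling
(`normalize_midas()`): a fold change relative to the within-condition
baseline (the earliest time in the file) is squashed through a Hill curve
(`k = 2`, `EC50 = 0.5` by default, both configurable), then multiplied by a
penalty — the ratio of the raw value to the per-readout maximum, capped at
one — that down-weights signals close to the assay background. Readouts
expected to decrease are handled by a `decrease` (or direction-agnostic
`two_sided`) fold-change mode, since a single convention cannot serve both
phospho-activation and degradation readouts. The data is deliberately *not*
discretized: an intermediate normalized value (say 0.5) penalizes either
Boolean prediction equally and mildly, so uncertain measurements carry less
weight than clear on/off calls.

## From prior knowledge to a trainable scaffold

Three preprocessing steps turn the PKN into the search space:

1. **Pruning** (`cut_unreachable()`): species that no cue can influence, or
   from which no measured species can be reached, are uninformative for
   training and are removed (never a designated — stimulated, inhibited or
   measured — node).
2. **Compression** (`compress_network()`): an undesignated species with a
   single input or a single output is spliced out, rewiring each
   input/output pair into a direct edge whose sign is the product of the two
   signs. A removal that would create a self-loop or contradict an existing
   edge is skipped, so feedback structure is preserved (this is why the
   IkB node survives in the example below). Compression shrinks the search
   space without changing the input–output logic.
3. **Expansion** (`expand_gates()`): each remaining target with *d* inputs
   contributes *d* single-input gates plus one AND gate per input
   combination up to `max_and_arity` (default 2 — pairwise gates follow the
   standard convention, and each extra arity multiplies the search space).
   OR logic is implicit: co-selecting several gates with the same target
   ORs them, so for two inputs the three hyperedges span all four logic
   options. Gates are ordered deterministically (byte-wise lexicographic,
   locale-independent) so a saved bitstring means the same model on any
   machine.

## The objective

A candidate model is a bitstring *P* over the scaffold gates. Its score is

$$\theta(P) = \theta_f(P) + \alpha\,\theta_s(P),$$

where the fit term \(\theta_f\) is the mean squared deviation between the
simulated state of each measured species and the normalized measurement
over all matched (condition, readout, time) cells — missing cells are
excluded from both numerator and denominator — and the size term
\(\theta_s\) is the number of selected gate inputs divided by the total
input count of the scaffold, so the empty model scores 0 and the full
scaffold 1. The weight \(\alpha\) is a required analysis choice, not a
package default: it is the squared-error cost at which one extra gate input
is worth keeping and should reflect the measurement noise (with noisy data
and few readouts, values around 0.1 are reasonable; the simulated study in
the tests uses 0.005 because its planted effects are of order 0.05–0.1 on
a 192-point dataset). A species that oscillates under synchronous updating
never reaches a steady state; every data point matched to it is charged
`na_penalty` (default 1.0, a maximal mismatch).

## Simulation semantics

The Boolean engine (`simulate_steady()`) updates all nodes synchronously:
a node's next state is the OR over its selected gates of the AND over each
gate's literals (a negative-sign input enters as NOT). Stimulus nodes are
clamped to their treatment value, inhibited nodes to 0 — a drug is modeled
as a full block — and a node with no selected incoming gate holds its
value, which makes the empty model well defined. Iteration stops at a
fixpoint or after `ceiling(1.2 * n_nodes)` steps (enough for any acyclic
cascade, with headroom; configurable). On non-convergence the residual
attractor is traversed until the state recurs, and every node that varies
along it is reported as unresolved: a single-step probe would miss
oscillating nodes that happen to pause at the probe's phase.

## Search

Training minimizes θ by a seeded genetic algorithm over bitstrings
(`ga_optimize()`): binary tournament selection, uniform crossover, per-bit
mutation at `mutation / n_bits` (so `mutation` is the expected number of
flips per chromosome), elitism, and early stopping after `stall`
generations without improvement. The empty and full models are injected
into the initial population so both reference scores are always explored.
Every evaluated bitstring is archived exactly once; the reported *family*
is every evaluated model within a user tolerance of the best score, and
per-gate selection frequencies over that family express which interactions
the data actually pins down — many near-optimal models typically coexist,
and a frequency table is more honest than a single winner.
`exhaustive_optimize()` certifies optima by enumeration for scaffolds up to
20 free gates; the test suite uses it as the ground-truth oracle for the GA.

## The five formalisms

**Boolean, one steady state.** Measurements at one characteristic time are
assumed to reflect a logical fixpoint. Fast and scalable; blind to
transients, oscillations and partial activation.

**Boolean, two pseudo-steady states** (`train_two_steps()`). Data at an
early and a late time are treated as two fixpoints arising from mechanisms
on different time scales (fast post-translational signaling versus slow,
expression-mediated feedback). Step one trains an ordinary model at the
early time. Step two searches only the gates absent from that model,
scored at the late time: each candidate late gate is evaluated on the
early steady state and *locks* its target to the resulting value (OR
across several late gates on one node). Locking is what makes slow
negative feedback representable at all — co-selecting the feedback in a
flat model just oscillates. Two interpretation choices are worth stating:
the locked value is the late gate's output at the early fixpoint, held
constant thereafter; and locks override stimulus clamps (receptor
desensitization can switch off a stimulated receptor) but never inhibitor
clamps (the drug is still present). The late search space is the
complement of the single best early model, so late results inherit the
early model's degeneracy; inspect the early family before reading too much
into late frequencies.

**Discrete time** (`train_dt()`). Full time courses are fit by the same
synchronous simulator, recorded step by step, with one extra trainable
parameter: the time-scale factor δ (data-time units per update step). The
prediction at data time *t* is the state after `round(t / δ)` steps —
nearest step, not interpolation, because Boolean trajectories are step
functions — and time 0 is scored against step 0. δ is searched jointly
with the topology as a binary-encoded index into a log-spaced grid
(default 20 values), which keeps the whole chromosome binary and reuses
the GA unchanged. Oscillations and transients become representable: a
negative feedback loop of length *L* yields a period-2*L* square wave
whose real period δ·2·*L* the search aligns with the data.

**Constrained fuzzy logic** (`train_fuzzy()`). Node states become
continuous in [0,1]; each gate input passes through a transfer function
from a small menu — normalized Hill curves
\(f(x) = g\,x^{n}(1+K^{n})/(x^{n}+K^{n})\) plus the identity — with AND =
min and OR = max, iterated to a fixed point (tolerance 1e-4; an
unspecified numerical knob fixed here at a value far below the data
scale). Full gain (g = 1) makes every transfer agree with Boolean logic at
0/1 inputs. The gain axis of the menu (g in {0.25, 0.5, 0.75, 1}) is the
load-bearing choice: with binary cues, any full-gain model maps Boolean
states to Boolean states — that is exactly what the normalization
guarantees — so the simulation never leaves the Boolean cube and partial
activation would be unfittable. A capped gain represents an interaction
that saturates below full activation of its target, which is how the menu's
reference formalism captures graded responses. After the discrete GA,
`refine_and_reduce()` locally tunes the selected (n, K, g) triples
(never worsening θ) and then greedily drops gates or simplifies transfers
to identity when the score worsens by less than `reduction_threshold`
(default 1e-4 absolute — a change an order of magnitude below the fixpoint
tolerance cannot be meaningful).

**Logic-based ODEs** (`fit_ode()`). Each dynamic species follows
\(\dot x_i = (\bar B_i(x) - x_i)/\tau_i\), where \(\bar B_i\) is the
multilinear (Boolean-cube) interpolation of the node's Boolean update
function evaluated on Hill-transformed inputs — the normalized "HillCube"
construction: OR of two inputs becomes \(w_1 + w_2 - w_1 w_2\), AND
becomes \(w_1 w_2\), and Boolean vertices are reproduced exactly. This
composition is smooth, which the stiff integrator (`deSolve::lsoda`)
requires; min/max composition is not. Transfer parameters are per
(target, input) edge — a node appearing in several gates of the same
target is transformed once, which keeps the parameterization identifiable —
and each dynamic node has a time constant τ in data-time units. The flow
cannot leave [0,1]: at \(x_i = 0\), \(\dot x_i = \bar B_i \ge 0\), at
\(x_i = 1\), \(\dot x_i = \bar B_i - 1 \le 0\). The topology is fixed
(train it first with a discrete formalism); parameters are fitted by a
bound-constrained global optimizer minimizing the mean squared deviation
over all matched cells, with K and τ searched on a log scale (bounds
n in [1,10], K in [0.01,1], τ in [0.01, 10 × max time]). The built-in
optimizer is a compact differential evolution (`de_optim()`,
rand/1/bin, F = 0.7, CR = 0.9), seeded and deterministic; any function
with the same `(fn, lower, upper, seed) -> list(par, value)` signature can
replace it.

## The simulated study

`toy_pkn()` and `toy_data()` generate the package's reference problem: a
10-node network of the canonical EGF and TNFa pathways with three planted
dynamic behaviors — a transient ERK peak caused by slow negative feedback
from ERK onto SOS-1, a damped NFkB oscillation from the NFkB→IkB⊣NFkB
loop, and a partial (≈0.5) p38 activation only under co-stimulation,
because p38 needs both branches and integrates them slowly. Data are
produced by integrating a ground-truth logic ODE model on the *full*
network under the four cue combinations, sampling every 2 time units over
[0, 30], and adding truncated Gaussian noise (sd 0.01 — a few percent of
the dynamic range, on the optimistic end for phosphoproteomics but
appropriate for a reference problem whose purpose is contrasting
formalisms, not stress-testing robustness).

The kinetic constants are fixed design choices, placed so that each
behavior is visible in the sampling window: the ERK read-back is gentle
(n = 2, K = 0.2) so the feedback loop settles at a low interior
equilibrium after a mid-window peak rather than oscillating indefinitely;
the NFkB/IkB loop uses near-step transfers (n = 24) with a fast activator
and slow inhibitor, giving a pronounced overshoot and damped ringing — a
two-species loop of this form is always eventually damped (its
linearization has real part \(-\tfrac12(1/\tau_1 + 1/\tau_2)\) regardless
of gain), which is worth knowing when judging what "oscillation" means
here; and p38 integrates both branches with τ = 8 through gentle
transfers, reaching about half-maximum at the end of the window.

What the generator does *not* emulate: biological replicates and
heteroscedastic noise, missing values, antibody cross-reactivity,
unmeasured off-network crosstalk, and partial drug inhibition. Passing
tests on this study therefore demonstrate that each formalism recovers the
structure it is designed to see under favorable data, not that it is
robust to real-data pathologies.

On this study the five formalisms reproduce the expected contrast: the
one-time Boolean fit selects the EGF→ras→ERK cascade but not the ERK
feedback (which would oscillate and be penalized); the two-time-scale fit
adds exactly the AND-gated feedback at the late step; the discrete-time
fit selects the NFkB/IkB loop because the square-wave oscillation, scaled
by δ, tracks the overshoot and ringing; the fuzzy fit captures the partial
p38 through a gain-capped transfer; and the ODE fit reproduces all three
behaviors at once. The acceptance script (`scripts/acceptance.R`)
recomputes all of this from scratch.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small instances — scaffolds
of 3–12 gates for oracle comparisons (exhaustive enumeration is the
ground truth there), the 11-gate toy scaffold for the formalism contrast,
and single-edge models for parameter-recovery checks — sizes at which
exact oracles exist and a full run completes in minutes. GA settings for
these studies (population 30–40, a few hundred generations, expected 1.5
bit flips per chromosome, stall 40–60) were chosen as the smallest
configuration that reliably reaches the certified optimum on the oracle
problems; real analyses on hundred-gate scaffolds should scale population
and stall up, not down. Ties in scores are resolved toward whichever model
was evaluated first (archives are insertion-ordered); gate order, and
hence bitstring meaning, is locale-independent by construction.

## Known limitations

- Boolean modes model inhibition as a full block; partial drug efficacy
  needs the fuzzy or ODE formalisms.
- The two-time-scale step conditions on a single best early model; its
  output should be read together with the early family's frequencies.
- The discrete-time formalism shares one δ across all reactions, so two
  oscillators with incommensurate periods cannot both be fit exactly.
- The fuzzy fixed-point iteration can fail to converge for steep transfer
  loops; such models are penalized like oscillating Boolean ones rather
  than solved by relaxation.
- ODE training fixes the topology; structure search in ODE mode is out of
  scope.
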