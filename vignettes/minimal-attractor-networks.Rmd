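---
title: "Minimal connectivity of attractor-supporting Hopfield networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal connectivity of attractor-supporting Hopfield networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopnet)
```

## The model

`hopnet` treats a homeostatic biological network — gene regulation,
metabolism, immune signalling — as a Hopfield-type recurrent net of $N$
two-state nodes. The state $x \in \{-1,+1\}^N$ marks each node quiescent
($-1$) or active ($+1$). All nodes update synchronously under the
threshold rule

$$x_i[n+1] = \begin{cases} +1 & \text{if } \sum_j w_{ij}\, x_j[n] \ge 0,\\
-1 & \text{otherwise,}\end{cases}$$

where $w_{ij}$ is the strength of the directed link from node $j$ into
node $i$. A designated attractor pattern $s$ is stored by the Hebbian
outer-product (dyad) rule $T = s s^\top$, i.e. $T_{ij} = s_i s_j$,
diagonal included. $T$ is symmetric and rank 1 with single nonzero
eigenvalue $N$ and eigenvector $s$; for any state, $Tx$ is either the
zero vector or a multiple of $s$, so the fully connected net funnels
essentially every state to $s$ or its complement $-s$ in one step.

Assumptions worth keeping in mind:

* **Synchronous updates.** The recurrence defines $x[n+1]$ from $x[n]$
  wholesale. Limit cycles of period $>1$, which pruning can create once
  the symmetric Hopfield structure is broken, only arise under synchronous
  updating; no asynchronous mode is implemented.
* **Ties resolve to $+1$.** An input sum of exactly zero activates the
  node. One consequence is that a node with no surviving incoming links is
  pinned at $+1$ forever; this interacts with the retention criterion
  below.
* **Complement identification.** For symmetric $\pm1$-pattern weights the
  negation $-s$ of a stored pattern is automatically a fixed point and
  captures roughly half of all random starts. Convergence to $-s$ is
  therefore counted as reaching the designated attractor, and retention
  results record which sign each probe reached.
* **Self-links** are created by the dyad rule ($w_{ii} = 1$) and are
  prunable like any other link.

## The retention criterion

A network *retains* its designated attractor when

1. **existence**: $s$ and $-s$ are both fixed points, and
2. **global stability**: every one of `nStarts` fresh uniform random
   initial states converges, within `maxIters` synchronous updates, to a
   fixed point equal to $s$ or $-s$. Trajectories that enter a limit
   cycle of period up to `maxPeriod`, stop at any other fixed point, or
   fail to converge defeat retention.

The existence half is not redundant decoration. With ties resolving to
$+1$, an accept/reject pruning loop driven by probe convergence alone
drifts into a regime where random probes no longer sample the shrinking
basin of $-s$; from then on the loop will happily strip *every* incoming
link from each node with $s_i = +1$ (such nodes pin to $+1$, which $s$
cannot distinguish from genuine support), silently destroying the
complement attractor and collapsing the "minimal" net to roughly the
number of $-1$ nodes, about $N/2$ links. Demanding that the attractor
pair keep existing — the natural meaning of probing for the *continued
existence and global stability* of the attractor once complements are
identified — forbids that degenerate shortcut, and structurally forces
every node to keep at least one incoming link, so a minimal net always
has at least $N$ links. The dual-attractor test applies the same
standard to all four states $\pm s, \pm r$.

Probe states are drawn fresh at every retention test. A fixed probe panel
would let the pruning loop overfit the minimal net to those particular
starts.

## Pruning protocols

**Bulk pruning** (`bulkPrune()`) removes a uniformly random subset of
links so that exactly `round(targetLinksPerNode * N)` remain (default 10
per node), then verifies retention, resampling the removal set on failure
(rarely needed; a random cut this shallow almost never kills the
attractor, though it can occasionally isolate a node).

**Sequential pruning** (`sequentialPrune()`) removes one uniformly chosen
remaining link at a time. An accepted removal persists; a rejected one is
reinstated and marked ineligible. Eligibility resets whenever any other
link is removed, because that removal may change which links are
dispensable; a run terminates when every remaining link has been tried
and rejected since the last acceptance. Termination is guaranteed (links
strictly decrease between resets, and each reset's round is finite), and
the endpoint is *minimal* in the operational sense that deleting any
single remaining link fails the retention test. Whether a previously
rejected link may be retried later was left open in the protocol this
reimplements; resetting eligibility after each acceptance is the choice
made here, since a removal elsewhere genuinely changes the test.

**Mass elimination** (`massEliminationSurvival()`) is the robustness
counterpoint: it deletes a large random fraction of the full net's links
in one stroke and reports the fraction of independent trials in which
retention survives. Minimal nets are one-link-fragile; the full net
typically shrugs off 95% deletion.

**Dual grafting and pruning.** A second pattern $r$ with $r \cdot s = 0$
exactly (requiring even $N$; the generator picks the $N/2$ agreement
positions uniformly at random) is grafted onto the minimal skeleton
$T^{*}$ by `buildDualMatrix()`: protected entries — the nonzero entries
of $T^{*}$ — keep their skeleton values, every other entry takes the
two-pattern Hebbian value $s_i s_j + r_i r_j \in \{-2, 0, 2\}$. The
construction is verified ( $\pm s$, $\pm r$ all fixed) before use.
`dualSequentialPrune()` then removes added links only, in two phases:

1. **dual phase** — a removal is kept only if the four-state retention
   test passes; the phase ends at the *dual-minimal* net, when every
   remaining added link has been tried and rejected;
2. **single phase** — eligibility resets and pruning continues under the
   single-attractor criterion for $s$, so the trace spans the full
   connectivity range; the step index of the transition and the
   links-per-node value at which $r$ first stops being a fixed point are
   recorded.

The two-phase design follows from removals being permanent only after the
combined test: a removal that breaks $r$ while dual-viable removals
remain is reinstated, not accepted, so the second attractor's death is
observed at the dual-minimal density rather than at the first link that
happens to break it (an alternative reading that places the loss
noticeably higher on the connectivity axis).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nNodes` | 200 | network size $N$ (50–400 in the study design; dual experiments need even $N$) |
| `nStarts` | 100 single / 200 dual | random probe states per retention test |
| `maxIters` | 500 | synchronous updates per probe before declaring nonconvergence |
| `maxPeriod` | 4 | longest limit-cycle period screened for |
| `bulkTarget` | 10 single / 15 dual | links per node after bulk pruning |
| `snapshotEvery` | 25 | accepted removals between saved edge-list snapshots |
| `binWidth`, `lpnRange` | 0.25, [1, 10] | links-per-node grid for cross-$N$ curve comparison |

The probe counts reflect the two experiments' designs (100 starts for
single-attractor pruning, 200 for the dual experiment); both are
configurable and recorded in each run's `meta.json`. The 500-step cap and
period-4 screen are part of the study conditions, not tuning knobs: a
probe that needs longer, or cycles longer, counts against retention.

## Randomness and reproducibility

Every experiment runner expands one master seed into named per-stage
child seeds (`deriveSeeds()`): the master seed initialises R's global
stream once and one integer child seed is drawn per stage in a fixed
order (attractor, partner, bulk, prune, probes, trials). Each stage then
reseeds the stream, so stages are independently reproducible and a run is
bit-for-bit determined by `(nNodes, seed, parameters)`. Derived seeds are
written into `meta.json`.

## Numerical choices

* States and weights are small integers; all comparisons (fixed points,
  cycle detection) are exact equality, never tolerance-based.
* Recurrence detection compares the new state against the previous
  `maxPeriod` states, recognising exactly periods 1–4; `iterations`
  counts the update steps until the recurring state was first *reached*
  (a start already at a fixed point reports 0).
* The batched evolution core (Rcpp/Armadillo) multiplies in sparse form —
  pruning spends nearly all its time on matrices with about $N$ of $N^2$
  entries nonzero — and a retention test aborts as soon as one probe
  finishes anywhere other than a designated fixed point.
* Exhaustive enumeration refuses $N$ above a configurable limit
  (default 20) since it visits all $2^N$ states; cycle identities are
  canonicalised by rotating the orbit to its lexicographically smallest
  state.
* Degree convention: a node's degree counts nonzero entries in its row
  plus its column with a self-link counted once, matching endpoint
  counting in the degree histograms.

## What the generator emulates — and what it does not

All inputs are generated internally: uniform $\pm1$ attractor patterns,
exactly orthogonal partners (constructive, never approximate; odd $N$ is
refused), and uniform $\pm1$ probe states. This emulates an idealised
environment whose perturbations are uniform over state space. Real
perturbation distributions have central tendencies set by the organism's
environment; real nodes saturate smoothly (e.g. Michaelis–Menten
kinetics) rather than stepping; and real networks are not built from a
stored pattern. Passing tests therefore show that the *pruning logic and
dynamics* behave as designed under the stated idealisation — they do not
show that any particular biological network sits at the measured
connectivity thresholds.

## Problem sizes used by the tests

The packaged test suite runs three $N=50$ pruning runs, ten $N=100$ runs
(degree statistics and the $\ln N$ collapse), one $N=100$ dual run, and
exhaustive-enumeration cross-checks at $N \le 12$; `scripts/acceptance.R`
recomputes the headline quantities at $N=200$. These sizes keep a full
check of every property to about a minute of computation while leaving
the $N$-scaling visible; all quantities they compute are defined for any
even $N$.

## Known limitations

* Only two stored patterns are supported; attractor clusters and larger
  pattern sets are out of scope.
* The pruning is greedy and random: $T^{*}$ is minimal against single
  deletions, not the globally smallest attractor-supporting subgraph.
* The dual-matrix construction keeps skeleton entries and uses the plain
  two-pattern Hebbian value elsewhere; with it, the second attractor's
  capture fraction in our traces declines steadily under pruning rather
  than collapsing abruptly at any particular density, so statements about
  *where* capture becomes negligible depend on the probe count used.
* Retention is a Monte-Carlo test: a tiny surviving alien basin can
  escape `nStarts` probes. The exhaustive oracle bounds this risk only at
  small $N$.
* Nonconvergent probes and long cycles are indistinguishable by design:
  anything not recurring within the period screen by the iteration cap
  counts as nonconvergent.
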