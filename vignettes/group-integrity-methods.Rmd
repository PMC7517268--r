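---
title: "Quantifying group integrity in small fish schools with integrated information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying group integrity in small fish schools with integrated information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolphi)
```

## The problem

Small groups of schooling fish (2-6 individuals) coordinate through local
interactions - staying near a neighbour, keeping a neighbour in the visual
field, turning in response to others.  A long-standing question is how
*integrated* such a group is: to what extent is the school an irreducible
causal unit rather than a collection of independent or merely feed-forward
coupled individuals?  schoolphi implements an analysis pipeline that answers
this with integrated information theory (IIT 3.0): binarize trajectories
into collective states, estimate the Markovian transition structure of
those states, and measure, per collective state, how much the system's
cause-effect structure is destroyed by the least damaging unidirectional
partition of the group.

## The model, stage by stage

### 1. From trajectories to collective states

A trajectory is a uniform 120-fps time series of 2-D positions (mm).  At a
chosen timescale of `dt_frames` frames the trajectory is strided
(`X[seq(1, T, by = dt_frames)]`), then each coordinate is smoothed with a
centred, unweighted 3-point moving average (ends truncated).  Velocities
are one-step differences on the resampled time base.

Each individual then gets one bit per time step, under one of two settings:

* **local** (bottom-up, Boids-like): the conjunction (AND) of
  - *distance*: some neighbour strictly closer than `xi_D` (mm);
  - *visual field*: some neighbour within the field of total width
    `xi_VF` (rad) around the velocity vector;
  - *turning*: own turning rate at least `xi_TR` (rad/step).
* **global** (top-down, mean-field-like): the conjunction of
  - *alignment*: heading within `Xi_AD` (rad) of the mean group direction
    (inclusive);
  - *centre of mass*: position within `Xi_CM` (mm) of the centroid
    (inclusive).

The AND is essential: an individual is "ON" exactly when it is in a
Boids-style interaction state (near enough, seeing someone, and turning),
or - globally - when it is behaving like a group member with respect to
the mean field.

Comparison conventions follow the defining formulas exactly: distance and
visual field are strict `<`, turning is `>=`, both global conditions are
`<=`.  Zero-velocity samples have no heading; their visual-field and
turning bits are set to 0 and counted (`n_zero_velocity` attribute).

Two conventions in the visual-field bit were genuinely open and are
exposed as flags:

* `vf_half_angle` (default `TRUE`): the literal formula compares the
  angle (which lives in `[0, pi]`) against `xi_VF` directly, which would
  make every width above `pi` equivalent to a complete field - yet
  distinct behaviour is attributed to widths of `1.6*pi`-`1.9*pi`.  We
  therefore read `xi_VF` as the *total* field width and compare against
  `xi_VF / 2`; at `xi_VF = 2*pi` the comparison is inclusive so a
  neighbour exactly astern is seen.  The literal reading remains available.
* `view_toward_neighbour` (default `TRUE`): the literal formula uses the
  self-minus-neighbour vector, which points *away* from the neighbour and
  describes a rear-facing field; the default uses the vector toward the
  neighbour.  The flag restores the literal formula.
* `smooth_first` (default `FALSE`): whether smoothing precedes striding.
  The slicing notation in the source suggests stride-first, which is the
  default.

The local sequence starts at the third resampled sample (the turning bit
needs the previous step's velocity as well), the global sequence at the
second.

### 2. From collective states to a TPM

The `2^N x N` state-by-node TPM is the maximum-likelihood per-node ON
frequency conditional on the previous collective state - the conditional
independence assumption of the downstream IIT machinery.  States never
observed as predecessors are filled with 0.5 per node, the same
maximum-entropy convention the IIT input distribution uses; add-one
smoothing is available behind `fill = "laplace"`.  No smoothing is applied
to observed rows by default: the intended sequences are of order 10^5
steps, and the synthetic tests control length explicitly.  A consequence
worth knowing: a *degenerate* sequence (e.g. everyone always ON at extreme
thresholds) produces a TPM whose one observed row is deterministic while
all other rows are 0.5, and that filled TPM retains joint structure - its
never-visited states can carry non-zero Phi.  The degeneracy shows in the
occupancy (a point mass), not necessarily in the unweighted mean Phi.

### 3. Integrated information per collective state

The IIT 3.0 engine is self-contained and exact for binary networks of up
to 6 nodes:

* **Repertoires.**  The effect repertoire of a mechanism over a purview
  clamps the mechanism, replaces all other inputs by independent
  maximum-entropy noise, and factorises over purview nodes.  The cause
  repertoire is the Bayesian inversion of the forward dynamics under a
  uniform prior on past states, computed per mechanism node, combined
  multiplicatively and renormalised; an unreachable mechanism state makes
  it undefined and the mechanism contributes `phi_cause = 0`.
* **Distances.**  All repertoire comparisons are exact earth mover's
  distances with the Hamming ground metric; conceptual structures are
  compared with the phi-weighted transport ("extended EMD") in concept
  space where each concept's cause and effect repertoires are expanded
  over the full subsystem state space and destroyed concepts move to the
  null concept (the unconstrained repertoires).
* **Small phi / concepts.**  Mechanism-level partitions are the standard
  IIT 3.0 bipartitions of the (mechanism, purview) pair into two
  non-degenerate parts.  phi^max is maximised over all `2^k - 1` purviews
  per direction; a concept exists iff `min(phi_cause, phi_effect) > 0`.
* **Big Phi.**  Phi is the minimum over unidirectional system cuts
  (connections from one part into the other replaced by noise) of the
  extended EMD between the intact and cut conceptual structures.  The
  `cut_one` approximation evaluates the `2N` cuts that sever one node's
  incoming or outgoing edges; `exhaustive` evaluates all `2^N - 2`
  bipartitions.  For `N <= 3` the two sets coincide; for larger `N`,
  cut-one can only overestimate.
* **Main complex.**  The node subset (size >= 2) with the greatest Phi;
  nodes outside a candidate subsystem are background conditions frozen at
  their current state.  All reported surfaces use the main complex by
  default (`scope = "main_complex"`), with `"full_system"` available - the
  source analyses name both, so results carry the scope in their metadata.

Numerical choices: `|phi| < 1e-10` is treated as zero (suppresses
floating-point ghost concepts); purview ties prefer the larger purview,
then the lexicographically smallest node list; cut ties keep the first cut
in enumeration order (per node: incoming before outgoing).  These rules
make every result bit-reproducible.

The transport solver is an exact successive-shortest-paths algorithm
implemented in C++ (no LP dependency); it is validated in the test suite
against frozen values from an independent linear-programming oracle
(`scipy.optimize.linprog` on the transport LP).

### 4. Derived statistics

* `phi_per_state()` - one Phi (with its MIP cut) per collective state.
* `mean_phi()` / `variance_phi()` - *unweighted* mean and *population*
  variance over all `2^N` states (not occupancy-weighted; the divisor is
  `2^N`).  The Fano factor is `var / mean`, undefined at zero mean and
  reported as missing; undefined cells are excluded (and counted) in the
  Phi-Fano correlation.
* `phi_surface()` - the grid machinery: encode, estimate, Phi for every
  threshold cell; `normalize_surface()` scales by the maximum cell
  (optionally within a region such as `xi_VF < pi`);
  `weighted_mean_position()` is the mean of cell coordinates weighted by
  `mean_phi` over cells above a fraction (default half) of the maximum;
  `top_k_mean()` (default k = 20) supports the local-versus-global peak
  comparison `local_global_difference()`, positive when the mean-field
  (global) reference underestimates the locally generated integrity.
* Leadership: `single_off_index()` finds states with exactly one OFF
  individual; `positional_leader()` is the argmax of position projected
  on the unit mean-velocity direction (ties to the lowest index;
  undefined and dropped from rates when the mean velocity vanishes);
  `pl_match_rate()` is `100 * |{t : OFF(t) = PL(t)}| / |{t : OFF(t) > 0}|`;
  `mip_cut_match_rate()` is the share of single-OFF timesteps whose
  state's MIP cut isolates exactly the OFF individual (either direction;
  cuts are computed once per state).  For `N = 2` the only bipartition
  separates the two fish, so this rate is structurally 100% whenever an
  event exists.  `cohesion_rate()` is the percentage of timesteps with
  all pairwise distances `<=` 400 mm (700 mm reported alongside).

## The synthetic world

No trajectory data are deposited with the analysis this package
operationalises, so the generators state a synthetic world chosen once to
match the reported regime: a 3 x 3 m arena, 120 fps, cruising speeds
around 250 mm/s (the observed band is roughly 150-350 mm/s), cohesive
groups whose pairwise distances stay within 400 mm nearly always.

* `boids_school()` - cohesion / alignment / separation steering with
  per-frame heading noise (default sd 0.08 rad) and soft wall repulsion.
* `leader_follower_chain()` - fish 1 walks persistently, fish k chases
  fish k-1; guarantees a persistent positional leader for testing the
  leadership statistics.
* `independent_walkers()` - the null model: persistent random walks, no
  interaction, dispersed initialisation; encoded sequences estimate to
  near node-independent TPMs and Phi near 0.
* `random_markov_tpm()` - the abstract null: every conditional
  ON-probability i.i.d. uniform on `[0, 1]`.

What a green test on this world does establish: the pipeline's operations
are correct on inputs with the assumed statistical structure, and the
engine agrees with exhaustive brute force.  What it does not establish:
any empirical claim about real fish - the generators do not reproduce
species-specific kinematics, pairwise interaction laws fitted to data,
tank-wall boundary behaviour, or tracking noise.

## Known limitations

* The engine is exact but exponential: practical up to ~6 nodes
  (state-of-the-art for IIT 3.0 generally).
* Only IIT 3.0 conventions are implemented; no self-loop network variants
  are exposed by the pipeline (the underlying engine accepts any
  state-by-node TPM).
* Heading is velocity-based; body posture is out of scope, as is 3-D.
* The behavioural labels (chasing, fission-fusion, leadership,
  interactive) are interpretive; the pipeline reports the underlying
  quantities and attaches labels only behind an opt-in heuristic flag.

## A worked example

```{r example, eval = FALSE}
cfg  <- generator_config(n_fish = 3, n_steps = 20000, seed = 1)
traj <- leader_follower_chain(cfg)
rep_ <- match_report(traj, local_thresholds(400, 1.2 * pi, 0.001),
                     dt_frames = 10)
print(rep_)
```

See the README for the printed output of this exact call and how to run
the acceptance report (`scripts/acceptance.R`).
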