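---
title: "Ring-attractor agents and allocentric flocking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-attractor agents and allocentric flocking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringflock)
```

# The scientific problem

Classical models of collective motion endow agents with explicit behavioral
rules — align with neighbors, repel at short range, attract at long range.
`ringflock` implements a different premise: each agent carries a small
recurrent neural circuit, a **ring attractor**, of the kind animals from
fruit flies to mammals use to encode bearings, and its movement decisions
are whatever that circuit produces.  Conspecifics are nothing more than
sensory inputs on each other's rings.  The package exists to study when
collective motion *emerges* from this closed sensory-motor loop, and in
particular how the answer depends on whether bearings are encoded
**egocentrically** (relative to the agent's own heading, so the neural
frame rotates with the body) or **allocentrically** (anchored to the world,
e.g. to distant visual cues, so the frame does not rotate as the agent
turns).

Agents live on a two-dimensional square torus of side `L` (periodic
boundaries, minimum-image distances and bearings).  Each agent's ring has
`Ns` neurons; neuron `i` has a receptive field and a motor contribution
both centered on the angle `2*pi*(i-1)/Ns` measured from the zero of the
agent's current reference frame.

# The two network back-ends

## Spin-system formulation

Neurons are binary spins `s_i` in `{-1, +1}` with circulant
modified-cosine connectivity

    J_ij = cos(pi * (d(alpha_i, alpha_j) / pi)^nu),

where `d` is circular distance on `[0, pi]` and `nu` shapes the balance of
local excitation and long-range inhibition (`nu = 1` is a plain cosine;
`nu < 1` is more locally excitatory).  The energy of a configuration is

    H = -[ (1/Ns) * sum_{i != j} J_ij s_i s_j + sum_i (h_i - h_b) s_i ],

with `h_i` the sensory field and `h_b` a global inhibition constant.
Dynamics are single-spin stochastic updates: a uniformly random neuron is
proposed per attempt; the flip is accepted with certainty if the energy
difference is non-positive and with probability `exp(-beta * dH)`
otherwise.  `beta` is the inverse noise (inverse temperature).  Between
movement steps the network performs `T0 * Ns` attempts; the chain's
stationary law is the Boltzmann distribution, which the test suite checks
against exact enumeration on small rings.

Sensory input is a normalized Gaussian per source,

    h_i = sum_s A_s / sqrt(2*pi*sigma^2) * exp(-d(center_i, theta_s)^2 / (2*sigma^2)),

and the motor readout averages the unit vectors of the active spins,
`v = (v0/Ns) * sum_{s_i = +1} (cos c_i, sin c_i)`.

## Neural-field formulation

The same ring geometry carries real membrane potentials evolved by an
Euler-discretized Amari-type equation,

    u_i <- u_i + dt * ( -u_i + (1/Ns) * sum_j J_ij tanh(beta u_j) - h_b + h_i ),

with `tanh(beta u)` the output nonlinearity; here `beta` is the output
slope and plays the inverse-noise role (the dynamics themselves are
deterministic — all stochasticity comes from the random initial potentials
and, under the switching policy, from frame choice).  The sensory Gaussian
in this formulation is *unnormalized* (`h_i = A * exp(-d^2/(2*sigma^2))`);
the two back-ends deliberately keep their own printed conventions rather
than sharing one.  The readout rectifies: only positive activities
contribute, `v = (v0/Ns) * sum_i max(0, tanh(beta u_i)) (cos c_i, sin c_i)`.
A third back-end (`field_heading_only`) moves at constant speed `v0` and
uses the ring only to choose the heading through the summed rectified
components.

# Reference frames and switching

The frame enters solely through the receptive-field centers
`c_i = origin + 2*pi*(i-1)/Ns`:

* **ego** — `origin` is the agent's current heading, re-set every step, so
  a bump that sits at ring deviation `alpha` makes the agent turn by
  `alpha` per step: a frozen bump yields a circular orbit of radius
  `step_length / (2 sin(alpha/2))` (≈ `v0/alpha` for small `alpha`).
* **allo** — `origin` is a world-anchored constant; a frozen bump yields a
  straight path.  Which world direction an agent calls zero is pure neuron
  indexing and does not affect the dynamics; anchors default to the world
  +x axis, with per-agent random anchors available.
* **switch** — each agent each step is egocentric with probability `omega`,
  allocentric otherwise.  On a mode change the new frame's origin is the
  agent's heading from the end of the previous step, and the ring state is
  circularly shifted by `round(delta * Ns / (2*pi))` indices
  (`delta` = outgoing origin − incoming origin) so the world direction
  encoded by the bump survives the switch to within one neuron.  This
  continuous re-anchoring is what keeps a switching agent from losing its
  sense of direction.

`omega = 0` and `omega = 1` take the pure-frame code paths exactly — they
consume no switching randomness, so such runs are bit-identical to `allo`
and `ego` runs at the same seed (this is tested).

# Social coupling and targets

Every agent is a sensory source on every other agent's ring.  The control
parameter is the *total* social attraction `h_t_s`; each conspecific
contributes amplitude `h_t_s / N`, which makes phase diagrams comparable
across population sizes.  Variants: a short-range repulsion step (amplitude
`h_rep < 0` below a collision radius), and an exponential distance decay
with characteristic length `zeta * L`.  Environmental targets are extra
sources, static or performing a per-axis `±v_t` random walk (position
increments by default; a velocity-walk flag integrates the increments
instead, since the convention is ambiguous).  Coincident pairs have no
defined bearing and are skipped for that step.

# The synchronous step

Per step: (1) frame modes are sampled and re-anchoring applied (switch
policy only); (2) positions are frozen and every agent's sensory field is
composed in its own frame; (3) all networks update (spin: `T0 * Ns`
attempts; field: one Euler step); (4) velocities are read out; (5) all
agents move synchronously by `v` (one movement step per simulation step in
both back-ends — see *Numerical choices*); (6) headings follow the
velocity, and are retained when the readout is silent; (7) targets advance.

# Order metrics

* **Global order (GO)** — norm of the population-mean unit velocity
  (polarization); zero-speed agents contribute the zero vector.
* **Local order (LO)** — for each agent, the norm of the summed unit
  velocities over its `k + 1` topologically nearest agents (self included,
  minimum-image distances, `k = 5` by default), averaged and divided by
  `k + 1` so a fully aligned population scores 1.  Ties in the k-th
  distance break by smaller agent index (relevant only for lattice
  fixtures; ties are measure-zero in simulation).
* **Mean pair distance** — `sum_{i != j} d_ij / (N (N-1))` on the torus.
* **Decision time** — first passage of the agent-target distance below a
  threshold (5 distance units by default), censored if never reached.
* **Mean target distance** — post-burn-in time average of the agent-target
  distance, reported as `d / L`.

All metrics are recomputable from the emitted trajectory CSV alone, and the
suite verifies the round trip.

# Parameters, defaults, and why

| Parameter | Spin default | Field default | Meaning |
|---|---|---|---|
| `Ns` | 100 | 100 | neurons per ring |
| `beta` | 400 | 1000 | inverse noise (temperature / tanh slope) |
| `nu` | 1 | 0.5 | connectivity exponent |
| `v0` | 10 | 0.05 | speed constant (distance per step) |
| `sigma` | `2*pi/Ns` | 0.4 | receptive-field width (rad) |
| `h_b` | 0 | 0 | global inhibition |
| `L` | 1000 | 1000 | arena side |
| `T0` | 10 | — | equilibration sweeps per movement step |
| `dt` | — | 0.3 | Euler step of the neural update |
| `u0` | — | 0.01 | initial-potential half-width |

These are the base conditions of the simulation study the package
reproduces.  Two parameters deserve comment because the study protocol
does not pin them down:

* **`T0`** exists "for the network to equilibrate" between moves.  Ten
  sweeps suffice at `Ns = 100`, where the collective phenomenology is
  insensitive to it.  Equilibration time grows quickly with ring size,
  however: bump migration is edge diffusion, roughly quadratic in `Ns`.
  The target-seeking protocols (which use larger rings, see below)
  therefore raise `T0` to 100; with an under-equilibrated ring the bump
  cannot track the target bearing and capture fails for mechanical rather
  than scientific reasons.
* **`u0`** only breaks the symmetry of the `u = 0` fixed point; results do
  not depend on its scale as long as it is small.

# Numerical choices

* **Acceptance at `dH = 0`**: flips with exactly zero cost are accepted
  with probability one, the continuity limit of `exp(-beta dH)`.  This
  matters for the zero-recurrence control, where every flip costs zero.
* **Self-pairs** are excluded from the double sum of the energy; with
  binary spins the `i = j` term is a state-independent constant, and
  excluding it keeps the cached-field energy difference exact (tested to
  `1e-9` against full re-evaluation).  The cache costs `O(1)` per attempt
  and `O(Ns)` per accepted flip; attempts whose acceptance probability is
  below `exp(-40)` are rejected outright.
* **Angular distances** in receptive fields and connectivity use circular
  distance on `[0, pi]`; only this reading preserves ring symmetry for
  `nu != 1`.
* **Half-open wrapping**: coordinates live in `[0, L)`; minimum-image
  components lie in `(-L/2, L/2]` with ties at exactly `L/2` resolved to
  `+L/2`.  Angle zero is the world +x axis, counterclockwise positive.
* **Movement scale**: both back-ends move agents by `v` once per
  simulation step; `dt` scales only the neural relaxation within the step.
  Scaling the displacement by `dt` as well would merely stretch the
  field-model's spatial kinetics by `1/dt` (~3.3x), putting the documented
  collective regimes outside the step counts at which they are known to
  occur; with unit movement steps the field model reproduces them at those
  step counts.
* **Spin initialization** is i.i.d. uniform `±1`; network state persists
  across movement steps (resetting would destroy bump continuity).
* **RNG**: a single R random stream seeded once per run drives everything
  in a fixed order (initialization, then per step: mode sampling where
  genuine, spin updates in agent order, target steps).  The compiled spin
  kernel draws from the same stream, so `seed` alone reproduces any run
  bit-for-bit.  Recording options consume no randomness and cannot perturb
  the dynamics.  Sweep cells derive their seeds deterministically from the
  base seed.
* **Configuration files** are JSON (primary) or YAML; unknown keys are
  rejected and every field is range-checked with the offending name in the
  error.

# What the test conditions show — and what they do not

The package's acceptance-style tests run the study conditions at reduced
scale, chosen once as protocol:

* Spin collective contrast: `N = 20`, `beta = 400`, `h_t_s = 0.1`, 6000
  steps, 5 seeds (the full-scale study uses `N = 80` and 10000+ steps).
* Field collective contrast: `N = 20` in `L = 500` — the same density as
  80 agents in `L = 1000`, since the phase structure is density-independent
  — at `beta = 100` and `h_t_s = 0.24`, 25000 steps, averaging the final
  fifth.  At very large slope (`beta = 1000`) pure-allocentric flocks are
  themselves unstable and globally disordered, so the contrast is measured
  in the collective-motion band.
* Zero-recurrence control: `N = 5` in `L = 100`.  With the synapses
  removed, each agent relaxes to its rectified input; when many sources
  surround an agent on the torus their motor contributions nearly cancel,
  so coalescence time explodes with `N`.  Five agents coalesce to a single
  point with terminal speeds below 2% of `v0` within 50000 steps,
  preserving the control's substance — feed-forward agents collapse into a
  slow aggregate instead of flocking.
* Target seeking: `Ns = 200`, `T0 = 100`, threshold 5 units,
  `h0 = 0.0025`.  Capture requires the sensory peak
  `h0/sqrt(2*pi*sigma^2)` to exceed the bump-edge flip barrier `4/Ns`
  (with `sigma = 2*pi/Ns` both scale with `Ns`; the crossover is near
  `Ns = 160`, which is why the full-scale protocol uses a 400-neuron
  ring and why a 100-neuron ring cannot do this task at this amplitude).
  Decision time is compared between just-above-critical (`beta = 1.5`;
  the mean-field critical point of the plain-cosine ring is `beta = 1`)
  and ordered (`beta = 4`) regimes, 20 runs each, capped at 5000 steps.

The generator emulates the in-silico study design: point agents, global
visibility, a single shared receptive width, no body collisions (unless the
repulsion variant is enabled), no sensory latency, and no synaptic delay.
Passing tests therefore demonstrate properties of the model, not of any
animal data; the qualitative claims (allocentric encoding enables collective
motion, egocentric encoding yields aggregation, switching preserves
continuity) are exactly the model-level statements being reproduced.

# Known limitations

* Two-dimensional space only; reflective/absorbing boundaries and 3-D are
  out of scope.
* Per-agent heterogeneity is limited to the frame policy.
* The spin kernel's rejection shortcut (skip below `exp(-40)`) makes the
  chain statistically indistinguishable from the exact rule but not
  bit-identical to a naive implementation that always draws a uniform.
* Field-model collective timescales are long near phase boundaries; the
  reduced-scale runs above were sized for stationary windows, and shorter
  runs can under-estimate global order.
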