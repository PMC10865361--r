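---
title: "Methods: trajectory analysis of self-assembled coiled-coil fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of self-assembled coiled-coil fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The system and the problem

`ccfibril` analyses molecular-dynamics trajectories of peptide hydrogels
built from alpha-helical coiled-coil dimers. The peptide monomer is a
26-residue heptad-repeat sequence (LKKELAA repeated, ending in LKKEL) whose
leucines form the hydrophobic zipper of a parallel dimer; lysines and the
N-terminus are protonated, glutamates and the C-terminus deprotonated, so a
dimer carries a net charge of +8 and dimers associate end-to-end through
ammonium--carboxylate salt bridges into transient fibril chains. An optional
N-terminal aminobenzoic-acid chromophore contributes an additional
protonated amino group that can take over the N-terminal salt-bridge role.

Four questions drive the analysis stages: how stiff are the fibrils
(persistence length), how are dimers connected over time (assembly graph and
its kinetics), how does the fibril perturb nearby water (radial density and
local self-diffusion), and what do simple closed-form models say about the
macroscopic gel (mesh size, water retention, counterions). Because
cluster-scale MD trajectories are not shipped with the package, a
synthetic-data module generates every input with known ground truth; all
tests and the acceptance script run against those generators.

## Virtual bead chain and persistence length

A discretisation along the peptide backbone would measure the flexibility of
one helix, not of the fibril. Instead one bead is placed per
leucine--leucine zipper pair at the midpoint of the two leucine C-alpha
atoms, which puts the beads on the coiled-coil core axis; the 26-residue
monomer has leucines at sequence positions 1, 5, 8, 12, 15, 19, 22 and 26,
so a dimer contributes $N = 8$ beads. Leucine positions are found by
scanning the sequence rather than hard-coded, so a chromophore group (which
contains no leucine) shifts nothing and contributes no bead. Midpoints are
computed after minimum-image unwrapping of the monomer pair relative to its
first zipper atom, so chains are never split across the periodic box.

Local orientations are the normalised bond vectors
$\vec e_j = (\vec b_{j+1}-\vec b_j)/\lVert\vec b_{j+1}-\vec b_j\rVert$, and
the orientation correlation at bead separation $k$ is the pooled average
$\langle \vec e_j\cdot\vec e_{j+k}\rangle$ over start indices, chains and
frames. For a worm-like chain this decays exponentially with contour
separation $s = k\,\Delta l$:

$$\langle \vec e(l)\cdot\vec e(l+s)\rangle = e^{-s/L_P}.$$

The direct route — integrating the correlation along the contour — is
bounded above by the chain length $(N-1)\Delta l$ and therefore
systematically unphysical for short stiff chains (a 3.8 nm eight-bead chain
can never report more than 3.8 nm); `naive_persistence_sum()` implements it
purely as the foil, and a regression test checks that the exponential fit
escapes the bound on stiff synthetic data.

Estimator choices, all deliberate:

* **Weighted log-linear fit with zero intercept.** The correlation is
  exactly 1 at $s=0$, so the intercept is fixed; weights are the per-$k$
  sample counts. This is deterministic and convex, unlike nonlinear least
  squares.
* **Positive-correlation threshold $\varepsilon_{\mathrm{pos}} = 0.05$.**
  Separations whose mean correlation is at or below 0.05 are excluded:
  their logarithm is dominated by sampling noise (and undefined at or below
  zero).
* **Empirical spacing.** $\Delta l$ defaults to the measured mean bead
  spacing of the data, because spacing fluctuates in MD.
* **Divergence flag.** A fitted slope indistinguishable from zero at
  floating precision (above $-10^{-12}$) is reported as a divergent
  $L_P = \infty$, the signature of a rigid chain, rather than a meaningless
  huge number.
* **Fit uncertainty** comes from the weighted-least-squares covariance; no
  bootstrap by default.

At trajectory level, chains come either from a fixed dimer ordering or from
the per-frame assembly graph; correlations are pooled per chain-length
class (dimers per chain). Classes with fewer than 2000 nearest-neighbour
vector pairs are excluded by default, as are chains longer than seven
coiled coils, which are sampled too erratically to fit; both filters are
arguments. Beads of consecutive dimers are concatenated in graph order, and
each dimer's bead run is flipped when that brings its terminal bead closer
to the junction — the N-terminus of one dimer meets the C-terminus of the
next. How to order beads across a strongly kinked junction is genuinely
open; this nearest-junction convention is ours and is documented rather
than hidden.

## Salt bridges and the assembly graph

A contact counts as a salt bridge when any hydrogen of an ammonium group
(backbone N-terminus `H1-H3`, lysine `HZ1-HZ3`, or the chromophore amino
hydrogens, whose residue and atom names are configurable) is within
0.35 nm — minimum image — of either oxygen of a carboxylate group
(glutamate `OE1/OE2`, C-terminal `OC1/OC2/OXT`). A *dimer--dimer
interaction* is stricter: a bridge between one dimer's {N-terminal amino
group, K2, K3} and another dimer's {C-terminus, E25}. When several bridges
link the same group pair or dimer pair simultaneously, the pair is counted
once per frame (interactions are per pair, not per bridge).

Oligomer chains are connected components of the interaction graph
(via igraph):

* a simple path is a linear chain, reported length = dimer count;
* a component containing a cycle is a circular fibril, flagged and reported
  **one element longer** than its dimer count (the ring closure is an extra
  chain element);
* isolated dimers are unbound;
* branched components (a dimer with three or more partners) have no
  published convention; they are reported as one chain ordered along the
  longest simple path, flagged `branched`, with a warning. This preserves
  the partition invariant — every dimer belongs to exactly one chain or is
  unbound — without inventing a split rule.

Size distributions are *chain-weighted*: each chain contributes one count at
its reported length per frame, which makes the probability mass at size 1
equal the unbound fraction of chains. Unbound-dimer time series are
non-overlapping block averages (1 ns blocks typical) with mean and standard
deviation across replica simulations.

Interaction lifetimes are maximal runs of continuous presence; a run's
duration counts all frames from first to last present frame times the frame
interval, and runs separated by at most `gap_tolerance` absent frames are
merged (default 0 — strict — since no tolerance is canonical). Runs touching
a window edge are flagged censored; a run spanning the entire window is
excluded from the cumulative distribution's numerator, so the CDF reaches 1
only if every interaction breaks within the window.

The N-terminal contact table classifies, per frame and per N-terminal amino
group, bridges to a carboxylate in (a) the same helix (typically E4), (b)
the partner helix of the same coiled coil, (c) a different coiled coil;
frames with no bridge count as solvent-exposed. The flags are
non-exclusive — one group can simultaneously bridge two partners — so the
four percentages can sum to slightly more than 100; replica mean and
standard deviation are reported.

## Water density and local self-diffusion

Fine-interval trajectories store coordinates (every 10 fs), not velocities,
so velocities are reconstructed by central differences
$v(t) = [x(t+\delta t)-x(t-\delta t)]/2\delta t$ with the two-step
displacement taken minimum-image — a particle crossing the periodic
boundary keeps a continuous velocity — accurate to $O(\delta t^2)$.

The velocity autocorrelation function is computed with the Wiener--Khinchin
theorem: the VACF is the real part of the inverse FFT of the FFT multiplied
by its complex conjugate. Two details matter numerically. Each series is
zero-padded to at least twice its length, so the autocorrelation is linear
rather than circular; and lag $k$ is normalised by its actual number of
origins $N-k$ (unbiased), which a direct $O(N^2)$ reference implementation
verifies to $10^{-10}$ relative in the tests. The self-diffusion
coefficient follows from the Green--Kubo relation

$$D = \int_0^{\tau_{\max}} \langle v(0)\,v(\tau)\rangle\, d\tau,$$

by trapezoidal integration, per Cartesian component (the VACF is already
per component, so no 1/3 factor). The water VACF levels off to zero within
roughly 0.8 ps, so the default cutoff $\tau_{\max} = 2$ ps is already in
the converged regime; it is configurable. Internally $D$ is in nm²/ps and
reported in cm²/s with the exact factor
$1\,\text{nm}^2/\text{ps} = 10^{-2}\,\text{cm}^2/\text{s}$, unit-tested
against the hand computation. The Einstein (mean-square-displacement) slope
estimator is included as the independent cross-check; it cannot be made
local in space — the particle wanders away from its initial position —
which is exactly why the local analysis uses Green--Kubo.

The fibril axis is the segment from the first to the last bead of the bead
chain. Radial coordinates are taken from the minimum-image displacement to
the axis *midpoint* (anchoring at an endpoint would wrap the axial range of
an axis spanning most of the box), waters are restricted axially to between
the end planes, and shell densities divide mean per-frame counts by exact
annulus volumes $\pi(r_{i+1}^2-r_i^2)h$ — with that choice the profile
integrates to the mean in-range water count identically.

For the local diffusion profile the stream is cut into non-overlapping
windows (default 5 ps, at least $2\tau_{\max}$); each water is assigned to
the radial bin of its centre of mass *at the window start*, frozen for the
window — justified because structural rearrangement of the hydration shell
(tens of ps) is slow compared to the VACF decay (under 1 ps) — and bin
results are averaged over windows weighted by occupancy. Empty bins are
reported missing, never zero.

## Gel calculators

Closed-form and exact, with feasibility checks:

* **Mesh size.** Assuming each mesh of the network stores one $k_BT$ of
  elastic energy, the plateau modulus gives
  $\xi = (k_B T/G_0)^{1/3}$. Since a true plateau may not exist, the caller
  chooses the frequency at which $G_0$ is read, and $\xi$ is an upper
  estimate. $k_B$ is the SI-exact constant; temperatures are accepted in K
  or °C because rheology is done at 37 °C while simulations run at 300 K.
* **Loss tangent** $\tan\delta = G''/G'$, vectorised over frequency sweeps.
* **Water retention.** Each dimer plus hydration shell is a cylinder
  $V_{cc} = \pi r^2 h$; the bulk-water fraction of a box with $n$ dimers is
  $1 - n V_{cc}/V_{box}$. Cylinder overlap is deliberately ignored (the
  bound-water estimate is an upper bound), matching the standard
  back-of-envelope arithmetic.
* **Counterions**: dimer count times the magnitude of the net charge
  (+8 per dimer at neutral pH).

## The synthetic generators — what they emulate, what they do not

Every generator is deterministic under a fixed seed and returns its ground
truth; `write_fixture()` writes GRO + mapping + a JSON sidecar.

* **Worm-like chains.** Successive bond directions follow a
  von Mises--Fisher-type polar law about the previous bond, with the
  concentration $\kappa$ solved from
  $\coth\kappa - 1/\kappa = e^{-\Delta l/L_P}$, so the stationary mean
  cosine is exact, not approximate. This emulates equilibrium fibril
  *shapes*; it has no dynamics and no excluded volume.
* **Ornstein--Uhlenbeck velocities.** Exact discretisation
  $v_{t+1} = e^{-\gamma\delta t} v_t + s\sqrt{1-e^{-2\gamma\delta t}}\,\xi$,
  started stationary, with analytic VACF $s^2 e^{-\gamma\tau}$ and
  $D = s^2/\gamma$. A guard requires $\gamma\,\delta t < 0.1$. Positions
  accumulate by trapezoidal integration. This emulates thermal velocity
  relaxation but not hydrodynamic backflow or the oscillatory short-time
  VACF of real water, so estimator accuracy — not water realism — is what
  the tests certify.
* **Planted assemblies.** Minimal pseudo-monomers carry only the atoms the
  contact analyses inspect (N-terminal ammonium, K2/K3 side-chain ammonium,
  E4/E25 carboxylates, C-terminal carboxylate) at their true residue
  indices, placed on a lattice with all unrelated groups at least 0.6 nm
  apart; each planted link is one H--O pair at 0.30 nm, optionally routed
  across the periodic boundary, optionally toggled per frame for kinetics.
  With `with_beads = TRUE` every monomer also gets its eight zipper
  C-alphas, laid out so each planted oligomer's bead chain is itself a
  worm-like chain — this is what lets the persistence stage run end-to-end
  on assembly-graph output. The box is enlarged so no fibril approaches
  half the box length, keeping minimum-image unwrapping unambiguous.
* **Two-state kinetics.** Markov on/off series with mean on-time
  $1/k_{\mathrm{off}}$; note the discrete-time observation inflates the
  continuous mean by about $\delta t/2$ relative, so fixtures keep
  $k_{\mathrm{off}}\,\delta t \le 0.05$.
* **Solvated cylinders.** Single-site pseudo-waters placed as an
  inhomogeneous Poisson field (thinning against the radial density
  profile), then evolved with OU velocities whose per-particle diffusivity
  is fixed from the profile at the *initial* radius. Particles therefore
  carry their $D$ with them as they drift; bins within one mixing length
  $\sqrt{2D\,t}$ of a planted discontinuity are transitional, and tests
  assert plateaus outside that band.

## Problem sizes, tolerances and degenerate inputs

The test suite runs at sizes chosen to keep the statistical error of each
check several times smaller than its asserted tolerance: worm-like-chain
recovery uses 10,000 eight-bead chains at $\Delta l = 0.54$ nm (within 10%
of truth for $L_P \in \{5, 10, 50\}$ nm, with convergence checked on
replicate-averaged errors across a 64-fold sample-size range);
the Green--Kubo check uses $10^6$ steps times 100 OU component series at
$\gamma = 5$ ps⁻¹ (within 5% of $s^2/\gamma$, and against the MSD oracle);
assembly recovery uses 50 seeded random topologies plus one branched case;
lifetime statistics use about $10^4$ completed events; hydration profiles
use a 6 × 6 × 4 nm box at 30 waters/nm³ for 16–32 ps of 10 fs frames.
Degenerate inputs fail loudly and specifically: zero atoms, duplicated atom
ids, triclinic boxes, coincident consecutive beads, missing zipper
leucines, missing donors or acceptors, windows shorter than $2\tau_{\max}$,
$\tau_{\max}$ beyond the data, infeasible cylinder packings, and unknown
config keys are all errors, not warnings.

## Known limitations

* Dimer labeling in the input is convention-dependent: GRO carries no chain
  records, so monomers are inferred from residue-number restarts and dimers
  default to consecutive pairing, overridable by a two-column mapping file.
  Any consistent labeling works.
* Trajectories are read as multi-frame GRO text (or DCD via bio3d when
  available); compressed XTC is not parsed — fixtures are generated in code,
  so the text route is the reference path.
* The branched-component convention and the bead-concatenation flip rule
  are package choices where no published rule exists; both are flagged in
  the output rather than silent.
* The generators certify estimator correctness, not force-field realism:
  passing tests say the code recovers known ground truth, not that any
  particular peptide behaves like the fixtures.
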