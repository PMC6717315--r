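---
title: "Predicting chromatin domains from nucleosome positions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chromatin domains from nucleosome positions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Budding-yeast chromosomes are organized into chromosomal interaction
domains (CIDs) of roughly 0.5--10 kbp (4--50 nucleosomes), visible in
nucleosome-resolution MicroC contact maps.  `nucdomains` implements a
predictive pipeline built on a deliberately minimal physical premise: the
only biological input is the 1D positions of nucleosomes along the
genome.  A chromatin fiber is modelled as a bead-spring heteropolymer,
sampled by Langevin dynamics, and observed through a stochastic
cross-linking model that mimics the MicroC protocol.  Domain boundaries
emerge where unusually long linkers (nucleosome-depleted regions, NDRs)
interrupt the otherwise dense chain of nucleosomes.

The pipeline is:

1. nucleosome positions (`read_positions()` or the synthetic generators),
2. chain topology (`build_chain()`),
3. conformational ensemble (`run_dynamics()`),
4. simulated contact map (`generate_map()`),
5. insulation profile and boundary calls (`insulation_profile()`,
   `call_boundaries()`), plus structural analytics (`rg_vs_length()`,
   `local_rg_profile()`, `reads_vs_separation()`, `linker_stats()`).

## The polymer model

Reduced units: length $\sigma = 2.5$ nm, energy $k_BT = 1$, bead mass
$m = 1$, time $\tau$ (nominally 80 microseconds).

* **DNA** is a chain of $1\sigma$ beads, one per ~8 bp, joined by stiff
  harmonic springs $U = \tfrac{1}{2} k (r - r_0)^2$ with
  $k = 200\,k_BT/\sigma^2$.
* **Bending** is a Kratky--Porod potential $U = K(1 + \cos\theta)$ on
  DNA--DNA--DNA triplets with $K = 20\,k_BT$.  For the discrete chain this
  gives $\langle\cos\phi\rangle = \coth K - 1/K \approx 0.95$ between
  successive tangents, i.e. a persistence length
  $l_p = -b/\ln\langle\cos\phi\rangle \approx 19.5\sigma \approx 49$ nm,
  the canonical 50 nm for DNA.  The package verifies this behaviourally
  (`estimate_persistence_length()`), not by quoting the constant.
* **Nucleosomes** (histone core plus the full 147-bp wrap) are single
  $4\sigma$ (10 nm) spheres.  A DNA--nucleosome--DNA junction carries no
  bending triplet: it is a freely rotating joint.  No orientational
  entry/exit constraint is imposed.
* **Excluded volume** is a purely repulsive WCA potential with additive
  contact distances ($1\sigma$, $2.5\sigma$, $4\sigma$); directly bonded
  pairs are excluded so a straight chain at rest lengths is force-free.
  Optionally, a cut-shifted Lennard-Jones attraction of depth `eps_n`
  between nucleosome centers models histone-tail-mediated stickiness
  (default 0: the reference model has excluded volume only).
* **Topology rules**: a linker of $\ell$ bp becomes
  `round(l/8)` DNA beads (half-up).  Linkers under 4 bp -- about a
  quarter of all yeast linkers -- therefore produce a direct
  nucleosome--nucleosome bond at $4\sigma$, which is legal and common.
  Flanking DNA outside the terminal nucleosomes is retained.

## Sampling

`run_dynamics()` integrates the Langevin equation with the BAOAB
splitting.  At $\gamma = 0$ the scheme reduces exactly to velocity
Verlet, which is how the energy-conservation check is run.  Thermostat
noise is uniform with matched variance (as in common MD practice);
velocities are initialized from the Maxwell--Boltzmann distribution.  The
integrator was validated against exact ideal-chain statistics: the
bend-angle distribution and the tangent-correlation law
$C(s) = \langle\cos\phi\rangle^s$ are reproduced to well under 1% at the
default $dt = 0.01\tau$.

Initial conformations (`init_conformation()`) are grown as self-avoiding
walks whose bend angles are drawn from the exact Kratky--Porod Boltzmann
distribution (uniform directions at free nucleosome joints).  Starting
from equilibrium *local* statistics matters: the slow collective modes
of a several-hundred-bead fiber relax on $10^4$--$10^5\,\tau$, far beyond
any desk-scale run, so an initialization with wrong tangent statistics
would bias every structural observable.

Two protocol choices deserve explanation:

* **Replicas over marathon runs.** Independent replicas are independent
  draws from the initial-conformation distribution, so ensemble averages
  converge with replica count even when single-trajectory decorrelation
  is slow.  The desk-scale default is 10 replicas; the persistence-length
  protocol uses 100 short replicas of a 100-bead chain.
* **Reduced friction for structural targets.** Equilibrium averages do
  not depend on the friction $\gamma$, but relaxation times scale
  roughly as $\gamma$ in the overdamped regime.  The fiber-scale
  protocols therefore run at $\gamma = 0.2$--$0.25/\tau$ rather than the
  default $2/\tau$, an order-of-magnitude speedup of the slow
  excluded-volume swelling of 200--400-bead fibers that makes the
  difference between converged and unconverged radius-of-gyration
  statistics.  Temperature control (equipartition) is unaffected.

Problem sizes used by the shipped analyses: a 100-bead bare-DNA chain
(persistence length, bare-window compaction); a 100-nucleosome regular
fiber, ~400 beads, 10 replicas of $12\,000\tau$ (size scaling); ten
irregular/regular pairs at 60 nucleosomes, ~240 beads (compaction
comparison).  These are the package's desk-scale study conditions; the
full production protocol ($5\times10^4\tau$, snapshots every $250\tau$,
20 replicas, 2000 configurations) is available via
`sim_config(protocol = "full")`.

## The observation model

Two nucleosomes and a snapshot are drawn uniformly at random; the pair is
accepted as a read with probability
$p(r) = 1/(1 + e^{(r - l_c)/w})$, a logistic function of their 3D
distance $r$.  The cross-linker length scale $l_c$ is the distance at
which $p = 1/2$; the softness $w$ defaults to 2.5 nm (one DNA bead).
Draws repeat until the requested read total is accepted, so read depth is
conserved exactly and simulated maps can be depth-matched to experiments.
Presets `lc_preset("microc")` (11.25 nm) and `lc_preset("microc-xl")`
(26.25 nm) correspond to the short- and long-cross-linker protocols.
Increasing $l_c$ lifts long-range reads and flattens the reads-versus-
separation curve, which is why apparent $P(s)$ exponents depend on the
experimental protocol; `lc_sweep()` reproduces this trend across the
7.5--60 nm grid.

`bin_map()` produces conventional base-pair-binned maps, optionally
including linker-DNA beads in the pair draws and normalizing by per-bin
occupancy products, to confirm that domains are not an artifact of
nucleosome-only observation.

## Domain analysis

The insulation value at nucleosome $i$ is the mean read count between the
`window` nucleosomes to its left and the `window` to its right (default
window 6, matching the 4--50-nucleosome domain scale).  Boundaries are
local insulation minima with topographic prominence above a threshold
(default: 10% of the profile range), thinned strongest-first to a minimum
spacing (default 4).  Boundary strength is the prominence.  Matching of
predicted against reference boundaries is greedy, nearest-first and
one-to-one, with the field's "within 1 nucleosome" tolerance.  The
Monte-Carlo null p-value redraws boundary sets uniformly (via an exact
gap-transform that preserves the predicted set's minimum separation) and
is validated against exhaustive enumeration on small maps.  These
algorithmic choices (prominence caller, greedy matching) are the
package's own: acceptance rests on planted-ground-truth recovery, not on
reproducing any particular external caller.

## Structural analytics

`rg_vs_length()` computes sliding-window radii of gyration with
prefix-sum accumulation ($O(n)$ per window length per snapshot) and fits
$R_g \sim L^\alpha$ on the log-log scale.  `local_rg_profile()` uses a
fixed window (default $L = 11$ beads) and normalizes by
$\lambda = \sqrt{N_d + 4 N_n}$, the square root of the window contour
length in $\sigma$ ($N_d$, $N_n$: DNA and nucleosome bead counts).  The
quantity named $\lambda$ is dimensionally the square root of a length;
we adopt this reading because it is the only one that makes
$R_g/\lambda$ a sensible dimensionless compaction measure and reproduces
the bare-DNA reference value (~0.9 for an 11-bead window: between the
rigid-rod limit 0.95 and the flexible continuous-chain limit 0.83).

`linker_stats()` classifies linkers by midpoint into gene bodies
(genes >= 1 kbp), strand-aware 500-bp upstream windows, nongenic
regions, activity classes, and boundary linkers, reporting histograms,
means, and short/medium/long fractions (<=3, 4--49, 50--200 bp) among
linkers <= 200 bp -- longer linkers are treated as unmappable-region
artifacts and excluded from all summaries.

## The synthetic generator

`default_linker_spec()` is a three-component mixture calibrated to the
published genome-wide summary statistics: probability 0.25 uniform on
1--3 bp (crowded, sub-nucleosomal linkers), 0.63 on a discretized
lognormal over 4--49 bp with mode 16 bp, and 0.12 uniform on 50--200 bp
(NDR-like linkers); the lognormal width is solved so the overall mean is
28.7 bp.  The generator emulates the multimodality, the short-linker
mass, the NDR mass, and the mean of real yeast linker data.  It does
**not** emulate: the detailed shape of the NDR tail (real NDR lengths
decay with length; the uniform component overweights 150--200-bp
linkers), positional coupling between linkers (phasing off NDRs),
sequence-directed positioning, or cell-to-cell variability.  Passing
tests on synthetic fibers therefore demonstrates correctness of the
machinery under these stated statistics, not fidelity to every property
of MNase-derived position sets.

One measurable consequence: in the irregular-versus-regular compaction
comparison, fibers built from this spec come out approximately the same
size as bead-matched regular fibers (the published comparison on real
position sets reports the irregular fiber ~10% smaller).  The uniform
50--200-bp component plants 16--25-bead persistent DNA rods that inflate
the irregular fiber's radius of gyration; with a decaying NDR tail the
irregular fiber loses that extra stiffness.  We keep the calibrated
mixture as the package's fixed study condition and report the comparison
as computed.

`generate_planted_domain_map()` provides ground-truth contact maps (a
block model with a specified within/between ratio) for validating the
boundary caller; `generate_toy_genes()` plants non-overlapping >= 1-kbp
genes for the context statistics.

## Numerical choices and degenerate inputs

* Linker discretization is round-half-up; `round(2/8) = 0` DNA beads is
  legal (direct nucleosome--nucleosome bond).
* Pair forces exclude only directly bonded pairs; coincident beads raise
  an error (singular repulsion) rather than returning infinities.
* Neighbor lists use a Verlet skin with displacement-triggered rebuilds;
  per-step pair evaluation is $O(n)$ for the default cutoffs.
* The tangent-correlation fit weights each separation by the inverse
  sampling variance of its log-correlation, estimated from per-replica
  scatter; without this the noisy large-$s$ tail dominates the fit.
* The power-law fitter aggregates zero-count separations into log-spaced
  bins before fitting (log of zero is otherwise undefined); fits with
  fewer than 3 positive points are errors.
* Insulation values are NA within `window` of the map edges; boundary
  calling operates on the defined range only.  Plateau minima are
  reported at their leftmost point.
* All randomness flows from one explicit integer seed per operation; the
  R global RNG state is saved and restored, and the C++ integrator uses
  its own xoshiro256++ stream, so identical seeds give bit-identical
  ensembles on a given platform.

## Known limitations

* Whole-fiber radii of gyration of 400-bead fibers have intrinsic
  replica-to-replica spreads of ~15% and mixing times beyond desk scale;
  quantities built on window averages (scaling exponents, local
  compaction) converge far better and are preferred throughout.
* The model omits wrapped-DNA geometry, entry/exit angle constraints,
  twist rigidity, hydrodynamics, and nucleosome repositioning dynamics.
* Experimental-map ingestion assumes nucleosome-indexed input; base-pair
  indexed data must be mapped to nucleosomes upstream.
* The trajectory container is in-memory with plain-text export
  (extended XYZ, TSV); there is no binary trajectory format.
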