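# nucdomains

Predicting chromatin interaction domains in budding yeast from
one-dimensional nucleosome positions, by coarse-grained polymer
simulation.

## What it does, and for whom

Nucleosome-resolution contact maps (MicroC) show that yeast chromosomes
are partitioned into chromosomal interaction domains (CIDs) of about
0.5–10 kbp. `nucdomains` is for chromatin biologists and biophysicists
who want to test how much of that 3D organization is already encoded in
the 1D nucleosome landscape: it takes only a set of nucleosome positions
(measured, e.g. MNase-seq-derived, or synthetic) and predicts the
contact map and its domain boundaries.

The physical model is deliberately minimal. A chromatin fiber is a
bead-spring heteropolymer: linker DNA is a chain of 2.5-nm beads (~8 bp
each) with harmonic bonds and a Kratky–Porod bending potential
U = K(1 + cos θ) calibrated so the DNA persistence length is
l_p = 50 nm; each nucleosome (histones plus wrapped DNA) is a single
10-nm sphere joined to its linkers by freely rotating joints; the only
interaction is excluded volume (optionally, a short-range
nucleosome–nucleosome attraction of depth ε_n). Conformations are
sampled by Langevin dynamics (BAOAB, implicit-solvent thermostat,
reduced units σ = 2.5 nm, k_BT = 1, τ ≈ 80 µs). A simulated MicroC map
is produced by a stochastic cross-linking model: random nucleosome pairs
from random snapshots are accepted as reads with probability
p(r) = 1/(1 + exp((r − l_c)/w)), where l_c is the cross-linker length
scale (presets: 11.25 nm MicroC-like, 26.25 nm MicroC XL-like). Domain
boundaries are minima of the insulation signal — the mean contact count
across a nucleosome within a sliding window — called by topographic
prominence.

Alongside the pipeline, the package provides the analyses used to
characterize such fibers: reads-versus-separation curves with power-law
fits P(s) ~ s^(−α), radius-of-gyration scaling R_g ~ L^α, local
compaction profiles R_g/λ with λ = sqrt(N_d + 4 N_n), linker-length
statistics by genomic context, boundary matching with Monte-Carlo null
p-values, and a synthetic generator for the multimodal yeast
linker-length distribution (25% at 1–3 bp, broad mode near 16 bp, 12% at
50–200 bp, mean 28.7 bp).

## Worked example

Synthetic 10-kbp region → fiber → ensemble → simulated MicroC →
boundaries:

```r
library(nucdomains)

spec <- default_linker_spec()
pos <- generate_positions(spec, region_length = 10000, seed = 11)
pos
#> <nuc_positions> synthetic: 59 nucleosomes in 10000 bp (footprint 147 bp)
#>   linkers: mean 21.3 bp, range [1, 176]

chain <- build_chain(pos)
chain
#> <bead_chain> synthetic: 223 beads (59 NUC, 164 DNA), 222 bonds, 84 bends

cfg <- sim_config(equil_time = 500, run_time = 2000, snapshot_every = 50,
                  n_replicas = 5L)
ens <- run_dynamics(chain, cfg, seed = 1)

map <- generate_map(ens, lc = lc_preset("microc"), n_reads = 5e4, seed = 2)
map
#> <contact_map> 59 x 59 nucleosomes, 50000 reads (simulated, lc = 11.25 nm)

prof <- insulation_profile(map, window = 4)
bounds <- call_boundaries(prof, min_separation = 4)
bounds$positions
#>  [1]  6 13 17 22 26 31 35 39 46 50

linker_stats(pos, boundaries = bounds)
#> <linker_stats>
#>   all           n=   58  mean  21.3 bp  [1-3] 0.31  [4-49] 0.64  [50-200] 0.05
#>   boundary      n=   10  mean  53.6 bp  [1-3] 0.00  [4-49] 0.80  [50-200] 0.20
```

The map's 50,000 reads are exactly the requested depth (read totals are
conserved, so simulated maps can be depth-matched to experiments). The
called boundaries fall preferentially at long linkers: boundary linkers
average 53.6 bp against 21.3 bp for all linkers in this region — the
package's restatement, on synthetic data, of the observation that domain
boundaries coincide with nucleosome-depleted regions.

A YAML-driven end-to-end run (positions → chain → dynamics → map →
insulation → boundary BED, plus a JSON manifest with seeds and
checksums) is available as `pipeline_run("config.yaml")`.

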