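# ccfibril

Trajectory analysis of self-assembling coiled-coil peptide fibrils, for
people studying peptide hydrogels with molecular dynamics: how stiff the
fibrils are, how the coiled-coil dimers connect and reconnect, how the
fibril perturbs its hydration water, and what the simple macroscopic gel
models predict.

The peptides are 26-residue heptad-repeat helices (LKKELAA-type) that pair
into leucine-zipper coiled-coil dimers of net charge +8; dimers associate
end-to-end through ammonium–carboxylate salt bridges into transient fibril
chains. The package implements four analysis stages over such trajectories,
plus a synthetic-data module that generates every input with known ground
truth so the whole pipeline is testable without running MD:

* **Bead chain & persistence length** — one virtual bead per
  leucine–leucine zipper pair (midpoint of the two Cα atoms); orientation
  correlations ⟨e(l)·e(l+s)⟩ fitted to exp(−s/L_P) by a weighted
  log-linear fit with zero intercept. The naive contour-integral estimator
  is bounded by the chain length and kept only as the foil.
* **Assembly graph** — salt bridges (any ammonium H within 0.35 nm of
  either carboxylate O, minimum image), dimer–dimer interactions
  (N-terminus/K2/K3 to C-terminus/E25), oligomer chains as connected
  components with circular fibrils reported one element longer than their
  dimer count, size distributions, unbound-dimer kinetics, residence-time
  distributions, and the N-terminal contact classification table.
* **Hydration** — velocities by central differences from finely spaced
  positions, VACF via the Wiener–Khinchin theorem (zero-padded FFT,
  unbiased N−k normalisation), self-diffusion from the Green–Kubo integral
  D = ∫₀^τmax ⟨v(0)v(τ)⟩dτ per component, and radially resolved water
  density and D(r) around the fibril axis.
* **Gel calculators** — mesh size ξ = (k_BT/G₀)^{1/3} from the plateau
  modulus, loss tangent G″/G′, cylindrical solvation-shell bulk-water
  fraction 1 − n·πr²h/V_box, and counterion bookkeeping.

## Worked example

Water retention and mesh size of a coiled-coil hydrogel, and a
persistence-length recovery on synthetic worm-like chains:

```r
library(ccfibril)

# 32 dimers in a 20 nm box (4 wt %); shell cylinder r = 2.4 nm, h = 4.0 nm
bulk_water_fraction(r = 2.4, h = 4.0, n_cc = 32, v_box = 8000)
#> $fraction
#> [1] 0.7104708
#> $v_cc
#> [1] 72.38229

mesh_size(G0 = 25.7, temperature = 37, unit = "C")
#> [1] 55.02677

counterion_count(32, charge_per_dimer = 8)
#> [1] 256

# recover a planted 10 nm persistence length from 10,000 eight-bead chains
ens <- generate_wlc_ensemble(l_p = 10, n_beads = 8, dl = 0.54,
                             n_chains = 10000, seed = 20240911)
cur <- orientation_correlation(lapply(ens$chains, chain_orientations),
                               spacing = 0.54)
fit_persistence_length(cur)
#> persistence_estimate: L_P = 10.043 nm (se 0.026), 6 separations, 210000 samples
```

So at 4 wt % only 71% of the water is bulk (each dimer's 72.4 nm³ shell
cylinder binds the rest), a 25.7 Pa plateau modulus at 37 °C corresponds to
a ~55 nm network mesh, and the exponential-decay fit recovers the planted
stiffness to 0.4% — even though each chain is only 3.8 nm long, far shorter
than its persistence length.

The numbered scripts under `analysis/` run each stage as a small narrative
study (gel calculators, worm-like-chain persistence recovery, planted
assembly graph and kinetics, hydration profiles) and write their tables
under `results/`:

```sh
Rscript analysis/01_gel_calculators.R
Rscript analysis/02_wlc_persistence.R
Rscript analysis/03_assembly_graph.R
Rscript analysis/04_hydration.R
```

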