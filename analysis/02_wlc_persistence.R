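#!/usr/bin/env Rscript
# Persistence-length estimation validated on worm-like-chain ensembles with
# known stiffness.
#
# Finding: the zero-intercept weighted log-linear fit of the orientation
# correlation recovers the planted persistence length within a few percent
# for L_P between 5 and 50 nm from 10,000 eight-bead chains at the 0.54 nm
# bead spacing of a coiled-coil zipper, while the naive contour-integral
# estimator saturates at the 3.78 nm chain length for stiff chains -- the
# reason the exponential fit is the estimator of record.

library(ccfibril)
dir.create("results", showWarnings = FALSE)
seed <- 20240901
dl <- 0.54

rows <- do.call(rbind, lapply(c(5, 10, 50), function(l_p) {
  ens <- generate_wlc_ensemble(l_p, n_beads = 8, dl = dl, n_chains = 10000,
                               seed = seed + l_p)
  cur <- orientation_correlation(lapply(ens$chains, chain_orientations),
                                 spacing = dl)
  est <- fit_persistence_length(cur)
  data.frame(l_p_true_nm = l_p, l_p_fit_nm = est$L_P, stderr_nm = est$stderr,
             naive_sum_nm = naive_persistence_sum(cur),
             chain_length_nm = 7 * dl, n_chains = 10000)
}))
print(rows, digits = 4)
write_stage_csv(rows, "results/persistence_recovery.csv", "persistence",
                list(dl = dl, n_beads = 8, seed = seed))

# correlation curve of the L_P = 10 nm ensemble, for plotting
ens <- generate_wlc_ensemble(10, 8, dl, 10000, seed = seed + 10)
cur <- orientation_correlation(lapply(ens$chains, chain_orientations),
                               spacing = dl)
write_stage_csv(as.data.frame(cur), "results/persistence_curve_lp10.csv",
                "persistence", list(l_p = 10, seed = seed + 10))
message("wrote results/persistence_recovery.csv, results/persistence_curve_lp10.csv")
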