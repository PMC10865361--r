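#!/usr/bin/env Rscript
# Salt-bridge assembly-graph analysis on a planted 32-dimer fixture, plus
# residence-time statistics on two-state interaction kinetics.
#
# Finding: oligomer chains, circular fibrils (reported one element longer
# than their dimer count) and unbound dimers are recovered exactly from the
# planted ammonium-carboxylate contacts; on Markov on/off kinetics with a
# 200 ps mean on-time the residence-time analysis reproduces the mean within
# statistical error and the cumulative distribution stays below 1 whenever
# an interaction survives the whole window.

library(ccfibril)
dir.create("results", showWarnings = FALSE)
seed <- 73

topo <- random_topology(32, seed = seed)
pa <- generate_planted_assembly(topo, 32, n_frames = 5, seed = seed)
dir.create("results/fixtures", showWarnings = FALSE)
paths <- write_fixture(pa, "results/fixtures", "assembly32")
out <- run_pipeline(list(stage = "assembly", trajectory = paths$trajectory,
                         dimer_map = paths$dimer_map,
                         out_dir = "results/assembly32"))
chains <- read_stage_csv(out$chains)
message("recovered ", nrow(chains) / 5, " oligomer chains per frame (",
        sum(chains$circular) / 5, " circular); outputs under results/assembly32/")

sizes <- read_stage_csv(out$sizes)
print(sizes)

# residence-time analysis on planted two-state kinetics
kin <- generate_interaction_kinetics(k_on = 0.005, k_off = 0.005,
                                     n_pairs = 150, n_frames = 3000, dt = 10,
                                     seed = seed)
res <- interaction_lifetimes(kin$presence, dt = kin$dt)
lt <- res$lifetimes
ok <- !lt$censored_left & !lt$censored_right
message(sprintf("mean residence time %.1f ps over %d events (truth %.0f ps)",
                mean(lt$duration[ok]), sum(ok), kin$truth$mean_on_time))
write_stage_csv(res$cdf, "results/lifetime_cdf.csv", "assembly",
                list(k_on = 0.005, k_off = 0.005, dt = 10, seed = seed))

# Table-style classification of N-terminal amino-group contacts on a
# planted 50/30/20 category mixture
mix <- c(same_helix = 0.5, same_cc = 0.3, different_cc = 0.2, solvent = 0)
pam <- generate_contact_fixture(n_dimers = 5, n_frames = 40, mixture = mix,
                                seed = seed)
tab <- classify_n_terminal_contacts(pam$stream, pam$system)
print(tab)
write_stage_csv(tab, "results/contact_classification.csv", "assembly",
                list(mixture = paste(mix, collapse = "/"), seed = seed))
message("wrote results/lifetime_cdf.csv, results/contact_classification.csv")
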