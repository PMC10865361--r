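# Helper: a 2-dimer system with one donor H and one acceptor O placed at an
# exact separation, optionally across the periodic boundary.
planted_pair_frame <- function(distance, wrap = FALSE) {
  topo <- list(list(type = "chain", dimers = 1:2))
  pa <- generate_planted_assembly(topo, 2, link_distance = distance,
                                  wrap_link = if (wrap) 1 else NULL, seed = 2)
  pa
}

test_that("salt-bridge detection applies the 0.35 nm cutoff, minimum image", {
  near <- planted_pair_frame(0.34)
  br <- detect_salt_bridges(near$stream$frames[[1]], near$system)
  expect_equal(nrow(br), 1)
  expect_equal(br$distance, 0.34, tolerance = 1e-9)

  far <- planted_pair_frame(0.36)
  br2 <- detect_salt_bridges(far$stream$frames[[1]], far$system)
  expect_equal(nrow(br2), 0)

  wrapped <- planted_pair_frame(0.30, wrap = TRUE)
  fr <- wrapped$stream$frames[[1]]
  br3 <- detect_salt_bridges(fr, wrapped$system)
  expect_equal(nrow(br3), 1)
  # the naive (unwrapped) distance is nearly a box length; the 27-image
  # brute force confirms the wrapped distance
  h <- fr$positions[wrapped$links$h_row[1], ]
  o <- fr$positions[wrapped$links$o_row[1], ]
  expect_gt(sqrt(sum((h - o)^2)), fr$cell[1] / 2)
  expect_equal(brute_min_image(h, o, fr$cell), 0.30, tolerance = 1e-9)
  expect_equal(br3$distance, 0.30, tolerance = 1e-9)
})

test_that("salt-bridge detection agrees with an all-pairs brute-force scan", {
  topo <- random_topology(8, seed = 31)
  pa <- generate_planted_assembly(topo, 8, seed = 31)
  fr <- pa$stream$frames[[1]]
  br <- detect_salt_bridges(fr, pa$system)
  # brute force: scan every H x O pair over 27 images
  a <- pa$system$atoms
  crit <- salt_bridge_criteria()
  hs <- which((a$resid == 1 & grepl("^H[123]$", a$name)) |
                (a$resname == "LYS" & grepl("^HZ[123]$", a$name)))
  os <- which((a$resname == "GLU" & grepl("^OE[12]$", a$name)) |
                grepl("^OC[12]$", a$name))
  found <- 0
  for (h in hs) for (o in os) {
    if (brute_min_image(fr$positions[h, ], fr$positions[o, ], fr$cell) <= crit$cutoff) {
      found <- found + 1
    }
  }
  expect_equal(nrow(br), found)  # planted links are single H-O pairs
  expect_equal(nrow(br), nrow(pa$links))
})

test_that("dimer interactions require the N-terminal/K2/K3 to C-terminal/E25 pattern", {
  mk <- function(donor_group, acceptor_group, d1 = 1, d2 = 2) {
    data.frame(donor_monomer = 1, donor_dimer = d1, donor_resid = 2,
               donor_group = donor_group, acceptor_monomer = 3,
               acceptor_dimer = d2, acceptor_resid = 25,
               acceptor_group = acceptor_group, distance = 0.3)
  }
  expect_equal(nrow(dimer_interactions(mk("K2", "E25"))), 1)
  expect_equal(unname(dimer_interactions(mk("NTER", "CTER"))[1, ]), c(1, 2))
  # K9 is not a qualifying donor; E4 is not a qualifying acceptor
  expect_equal(nrow(dimer_interactions(mk("K9", "E25"))), 0)
  expect_equal(nrow(dimer_interactions(mk("NTER", "E4"))), 0)
  # intradimer bridges never qualify
  expect_equal(nrow(dimer_interactions(mk("K2", "E25", d1 = 1, d2 = 1))), 0)
  expect_equal(nrow(dimer_interactions(empty_bridge_table())), 0)
})

test_that("chains, rings and singletons are identified with the +1 ring convention", {
  pairs <- rbind(c(1, 2), c(2, 3))
  res <- identify_chains(pairs, 1:4)
  expect_equal(length(res$chains), 1)
  ch <- res$chains[[1]]
  expect_true(identical(ch$dimers, c(1L, 2L, 3L)) ||
                identical(ch$dimers, c(3L, 2L, 1L)))
  expect_false(ch$circular)
  expect_equal(ch$length, 3)
  expect_equal(res$unbound, 4)

  ring <- identify_chains(rbind(c(1, 2), c(2, 3), c(3, 1)), 1:3)
  expect_true(ring$chains[[1]]$circular)
  expect_equal(ring$chains[[1]]$length, 4)  # one element longer than its dimers
  expect_equal(sort(ring$chains[[1]]$dimers), 1:3)
})

test_that("50 random planted topologies are recovered exactly from coordinates", {
  for (seed in 1:50) {
    n <- sample(4:14, 1)
    topo <- random_topology(n, seed = seed)
    pa <- generate_planted_assembly(topo, n, seed = seed)
    fc <- frame_chains(pa$stream$frames[[1]], pa$system)
    expect_equal(sort(fc$unbound), sort(as.integer(pa$truth$singletons)))
    got <- lapply(fc$chains, function(ch) sort(ch$dimers))
    want <- lapply(pa$truth$chains, function(cp) sort(as.integer(cp$dimers)))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    for (ch in fc$chains) {
      planted <- Filter(function(cp) setequal(cp$dimers, ch$dimers),
                        pa$truth$chains)[[1]]
      expect_equal(ch$circular, planted$type == "ring")
      expect_equal(ch$length,
                   length(planted$dimers) + as.integer(planted$type == "ring"))
      # linear chains recovered in planted order (possibly reversed)
      if (planted$type == "chain") {
        expect_true(identical(ch$dimers, as.integer(planted$dimers)) ||
                      identical(ch$dimers, rev(as.integer(planted$dimers))))
      }
    }
    # partition invariant: chains + unbound cover every dimer once
    all_ids <- c(unlist(lapply(fc$chains, `[[`, "dimers")), fc$unbound)
    expect_equal(sort(all_ids), 1:n)
  }
})

test_that("branched components stay one chain, flagged, with a warning", {
  pairs <- rbind(c(1, 2), c(2, 3), c(2, 4))
  expect_warning(res <- identify_chains(pairs, 1:5), "branched")
  expect_equal(length(res$chains), 1)
  expect_true(res$chains[[1]]$branched)
  expect_equal(sort(res$chains[[1]]$dimers), 1:4)
  expect_equal(res$unbound, 5)
  # result invariant under dimer relabeling (sizes preserved)
  perm <- c(3, 1, 4, 2, 5)
  pairs2 <- cbind(perm[pairs[, 1]], perm[pairs[, 2]])
  expect_warning(res2 <- identify_chains(pairs2, 1:5))
  expect_equal(sort(vapply(res2$chains, `[[`, integer(1), "length")),
               sort(vapply(res$chains, `[[`, integer(1), "length")))
})

test_that("size distribution is chain-weighted with replica statistics", {
  topo <- list(list(type = "chain", dimers = 1:3),
               list(type = "singleton", dimers = 4))
  pa <- generate_planted_assembly(topo, 4, n_frames = 3)
  tl <- assembly_timeline(pa$stream, pa$system)
  hist <- oligomer_size_distribution(list(tl, tl))
  expect_equal(hist$mean_prob[hist$size == 1], 0.5)
  expect_equal(hist$mean_prob[hist$size == 3], 0.5)
  expect_equal(hist$sd_prob, c(0, 0))  # identical replicas
})

test_that("unbound-dimer series is block averaged over replicas", {
  topo <- list(list(type = "singleton", dimers = 1),
               list(type = "singleton", dimers = 2))
  pa <- generate_planted_assembly(topo, 2, n_frames = 6)
  tl <- assembly_timeline(pa$stream, pa$system)
  ts <- unbound_dimer_timeseries(list(tl, tl), block = 40)  # 2 frames/block
  expect_equal(ts$mean_unbound, rep(2, 3))
  expect_equal(ts$sd_unbound, rep(0, 3))
  expect_error(unbound_dimer_timeseries(list(tl), block = 10),
               "below the frame interval")

  # alternating 0/4 with 2-frame blocks averages to 2
  topo4 <- list(list(type = "chain", dimers = 1:2),
                list(type = "chain", dimers = 3:4))
  sched <- matrix(rep(c(FALSE, TRUE), 3), nrow = 2, ncol = 6, byrow = TRUE)
  pa4 <- generate_planted_assembly(topo4, 4, n_frames = 6, schedule = sched)
  tl4 <- assembly_timeline(pa4$stream, pa4$system)
  counts <- vapply(tl4, function(fc) length(fc$unbound), numeric(1))
  expect_equal(counts, rep(c(4, 0), 3))
  ts4 <- unbound_dimer_timeseries(list(tl4), block = 40)
  expect_equal(ts4$mean_unbound, rep(2, 3))
})

test_that("interaction lifetimes follow the run and gap-tolerance semantics", {
  p <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- interaction_lifetimes(p, dt = 20)
  expect_equal(res$lifetimes$duration, 60)
  expect_true(res$lifetimes$censored_left)
  expect_false(res$lifetimes$censored_right)

  p2 <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  strict <- interaction_lifetimes(p2, dt = 20, gap_tolerance = 0)
  expect_equal(strict$lifetimes$duration, c(20, 20))
  merged <- interaction_lifetimes(p2, dt = 20, gap_tolerance = 1)
  expect_equal(merged$lifetimes$duration, 60)  # gap frame counts into the run

  # a run surviving the whole window caps the cumulative distribution below 1
  full <- interaction_lifetimes(rbind(rep(TRUE, 5), c(FALSE, TRUE, TRUE, FALSE, FALSE)),
                                dt = 1)
  expect_lt(max(full$cdf$cumulative), 1)
})

test_that("two-state kinetics fixtures recover the mean on-time", {
  kin <- generate_interaction_kinetics(k_on = 0.005, k_off = 0.005,
                                       n_pairs = 60, n_frames = 2000,
                                       dt = 10, seed = 12)
  res <- interaction_lifetimes(kin$presence, dt = kin$dt)
  lt <- res$lifetimes
  ok <- !lt$censored_left & !lt$censored_right
  expect_gt(sum(ok), 1000)
  expect_equal(mean(lt$duration[ok]), kin$truth$mean_on_time, tolerance = 0.1)
})

test_that("N-terminal contact classification recovers planted categories", {
  # all bridges to E4 of the same helix -> 100% same_helix, 0% solvent
  pa <- generate_contact_fixture(n_dimers = 3, n_frames = 4,
                                 mixture = c(same_helix = 1, same_cc = 0,
                                             different_cc = 0, solvent = 0),
                                 seed = 1)
  tab <- classify_n_terminal_contacts(pa$stream, pa$system)
  expect_equal(tab$mean[tab$category == "same_helix"], 100)
  expect_equal(tab$mean[tab$category == "solvent"], 0)

  # no bridges anywhere -> 100% solvent
  pa0 <- generate_contact_fixture(3, 4, mixture = c(same_helix = 0, same_cc = 0,
                                                    different_cc = 0, solvent = 1),
                                  seed = 2)
  tab0 <- classify_n_terminal_contacts(pa0$stream, pa0$system)
  expect_equal(tab0$mean[tab0$category == "solvent"], 100)
  expect_equal(sum(tab0$mean[tab0$category != "solvent"]), 0)

  # planted 50/30/20 mixture recovered exactly
  mix <- c(same_helix = 0.5, same_cc = 0.3, different_cc = 0.2, solvent = 0)
  pam <- generate_contact_fixture(n_dimers = 4, n_frames = 25, mixture = mix,
                                  seed = 3)
  tabm <- classify_n_terminal_contacts(pam$stream, pam$system)
  got <- stats::setNames(tabm$mean, tabm$category)
  expect_equal(got[names(pam$truth$planted_pct)], pam$truth$planted_pct,
               tolerance = 1e-9)
})
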