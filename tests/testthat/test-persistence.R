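test_that("orientation correlation pools dot products over chains and frames", {
  # perfectly straight chains: correlation 1 at every separation
  straight <- generate_wlc_ensemble(Inf, 8, 0.5, 5, seed = 1)
  cur <- orientation_correlation(lapply(straight$chains, chain_orientations),
                                 spacing = 0.5)
  expect_equal(cur$correlation, rep(1, nrow(cur)), tolerance = 1e-12)
  expect_equal(cur$correlation[cur$k == 0], 1)
  expect_true(all(diff(cur$count) <= 0))

  # ensemble of 2-vector sets with perpendicular members: 0 at k = 1
  sets <- replicate(4, {
    structure(rbind(c(0, 0, 1), c(1, 0, 0)), class = c("orientation_set", "matrix"))
  }, simplify = FALSE)
  cur2 <- orientation_correlation(sets)
  expect_equal(cur2$correlation[cur2$k == 1], 0)

  # O(N^2) double-loop oracle on random chains
  set.seed(21)
  ens <- generate_wlc_ensemble(5, 10, 0.5, 10, seed = 21)
  sets <- lapply(ens$chains, chain_orientations)
  cur3 <- orientation_correlation(sets, spacing = 0.5)
  for (k in c(1, 3, 6)) {
    acc <- c()
    for (e in sets) {
      for (j in seq_len(nrow(e) - k)) acc <- c(acc, sum(e[j, ] * e[j + k, ]))
    }
    row <- cur3[cur3$k == k, ]
    expect_equal(row$correlation, mean(acc), tolerance = 1e-12)
    expect_equal(row$count, length(acc))
  }
})

test_that("the exponential fit inverts an exact curve to machine precision", {
  s <- seq(0, 3.5, 0.5)
  curve <- data.frame(k = 0:7, separation = s, correlation = exp(-s / 10),
                      count = rep(100, 8))
  est <- fit_persistence_length(curve)
  expect_equal(est$L_P, 10, tolerance = 1e-12)
  expect_false(est$divergent)

  flat <- data.frame(k = 0:5, separation = 0:5, correlation = rep(1, 6),
                     count = rep(10, 6))
  expect_true(fit_persistence_length(flat)$divergent)
  dead <- data.frame(k = 0:2, separation = 0:2, correlation = c(1, 0.01, 0.001),
                     count = c(5, 5, 5))
  expect_error(fit_persistence_length(dead), "fit failed")
})

test_that("estimates are invariant under chain reversal", {
  ens <- generate_wlc_ensemble(8, 12, 0.5, 20, seed = 5)
  sets <- lapply(ens$chains, chain_orientations)
  sets_rev <- lapply(ens$chains, function(ch) {
    chain_orientations(new_bead_chain(ch$beads[rev(seq_len(nrow(ch$beads))), ]))
  })
  c1 <- orientation_correlation(sets, spacing = 0.5)
  c2 <- orientation_correlation(sets_rev, spacing = 0.5)
  expect_equal(c1$correlation, c2$correlation, tolerance = 1e-12)
  expect_equal(fit_persistence_length(c1)$L_P, fit_persistence_length(c2)$L_P,
               tolerance = 1e-12)
})

test_that("worm-like-chain recovery converges to generator truth", {
  l_p <- 10; dl <- 0.54
  errs <- vapply(c(100, 1000, 10000), function(n) {
    ens <- generate_wlc_ensemble(l_p, 8, dl, n, seed = 42)
    cur <- orientation_correlation(lapply(ens$chains, chain_orientations),
                                   spacing = dl)
    abs(fit_persistence_length(cur)$L_P - l_p)
  }, numeric(1))
  expect_lt(errs[3] / l_p, 0.1)
  expect_true(all(diff(errs) < 0))  # error shrinks with sample size
})

test_that("the naive direct estimator is bounded by chain length, the fit is not", {
  # stiff chains much longer than their contour: L_total = 7 * 0.54 = 3.78 nm
  l_p <- 50; dl <- 0.54
  ens <- generate_wlc_ensemble(l_p, 8, dl, 3000, seed = 13)
  cur <- orientation_correlation(lapply(ens$chains, chain_orientations),
                                 spacing = dl)
  l_total <- 7 * dl
  expect_lte(naive_persistence_sum(cur), l_total)
  est <- fit_persistence_length(cur)
  expect_gt(est$L_P, l_total)          # exponential fit escapes the bound
  expect_lt(abs(est$L_P - l_p) / l_p, 0.25)
})

test_that("trajectory-level estimation filters chain-length classes", {
  # mixed chain lengths 3..10 dimers
  topo <- list()
  nxt <- 1
  for (n in 3:10) {
    topo[[length(topo) + 1]] <- list(type = "chain", dimers = nxt:(nxt + n - 1))
    nxt <- nxt + n
  }
  expect_true(setequal(unlist(lapply(topo, `[[`, "dimers")), seq_len(sum(3:10))))
  pa <- generate_planted_assembly(topo, sum(3:10), n_frames = 2,
                                  with_beads = TRUE, bead_l_p = 15, seed = 77)
  res <- persistence_from_trajectory(pa$stream, pa$system, source = "assembly",
                                     min_points = 1, max_cc = 7)
  classes <- as.integer(names(res$estimates))
  expect_true(all(classes <= 7))
  expect_true(all(3:7 %in% classes))
  expect_false(any(classes > 7))
})

test_that("straight rigid fibrils give a divergent persistence flag", {
  topo <- list(list(type = "chain", dimers = 1:4))
  pa <- generate_planted_assembly(topo, 4, n_frames = 2, with_beads = TRUE,
                                  bead_l_p = Inf, seed = 3)
  res <- persistence_from_trajectory(pa$stream, pa$system, source = "assembly",
                                     min_points = 1, max_cc = Inf)
  expect_true(all(vapply(res$estimates, `[[`, logical(1), "divergent")))
  expect_error(persistence_from_trajectory(pa$stream, pa$system,
                                           source = "assembly",
                                           min_points = 1e6),
               "no chain-length class")
})
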