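test_that("bead positions are leucine-CA midpoints and the zipper has 8 beads", {
  dim <- make_ideal_dimer(offset = c(1, 0, 0))
  bc <- build_bead_chain(dim$frame, dim$system, 1)
  expect_equal(nrow(bc$beads), 8)  # leucines of LKKELAA x3 + LKKEL
  # midpoint: x halfway between the two helices
  expect_equal(unique(round(bc$beads[, 1], 9)), 5.5)
  # identical helices -> beads coincide with the CA trace
  dim0 <- make_ideal_dimer(offset = c(0, 0, 0))
  bc0 <- build_bead_chain(dim0$frame, dim0$system, 1)
  ca1 <- dim0$frame$positions[dim0$system$atoms$monomer == 1 &
                                dim0$system$atoms$resname == "LEU", ]
  expect_equal(unname(bc0$beads), unname(ca1), tolerance = 1e-12)
  # straight dimer: beads equally spaced within each heptad pattern
  expect_true(all(diff(bc$beads[, 3]) > 0))
})

test_that("leucine positions come from the sequence, so a chromophore shifts nothing", {
  dim <- make_ideal_dimer()
  # prepend a chromophore pseudo-residue (no leucine, no CA bead)
  extra <- data.frame(name = c("N1", "HN1"), resid = 1, resname = "ABA",
                      monomer = 1)
  atoms <- rbind(extra, dim$system$atoms[, c("name", "resid", "resname", "monomer")])
  atoms$id <- seq_len(nrow(atoms))
  sys2 <- molecular_system(atoms)
  fr2 <- frame(rbind(matrix(c(5, 4.5, 4.5, 5, 4.4, 4.4), 2, 3),
                     dim$frame$positions), dim$frame$cell)
  bc <- build_bead_chain(fr2, sys2, 1)
  expect_equal(nrow(bc$beads), 8)
})

test_that("missing zipper leucines raise a topology error naming the dimer", {
  atoms <- data.frame(name = "CA", resid = 1:4, resname = "ALA",
                      monomer = rep(1:2, each = 2), id = 1:4)
  sys <- molecular_system(atoms)
  fr <- frame(matrix(runif(12), 4, 3), c(10, 10, 10))
  expect_error(build_bead_chain(fr, sys, 1), "leucine")
})

test_that("orientation vectors are normalised finite differences", {
  beads <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(0, 0, 3))
  e <- chain_orientations(new_bead_chain(beads))
  expect_equal(unname(unclass(e)), matrix(rep(c(0, 0, 1), each = 3), 3, 3),
               tolerance = 1e-12)
  right <- new_bead_chain(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  er <- chain_orientations(right)
  expect_equal(sum(er[1, ] * er[2, ]), 0, tolerance = 1e-12)
  set.seed(2)
  beads <- matrix(cumsum(rnorm(30)), 10, 3)
  e <- chain_orientations(new_bead_chain(beads))
  d <- diff(beads)
  expect_equal(unclass(e), d / sqrt(rowSums(d^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(e^2)), rep(1, 9), tolerance = 1e-9)
})

test_that("the coiled-coil axis is the normalised first-to-last bead vector", {
  straight <- new_bead_chain(cbind(0, 0, seq(0, 3, 0.5)))
  ax <- coiled_coil_axis(straight)
  expect_equal(ax$direction, c(0, 0, 1))
  # helix around z: direction still z regardless of phase
  for (phase in c(0, 1, 2)) {
    t <- seq(0, 4 * pi, length.out = 20)
    helix <- new_bead_chain(cbind(cos(t + phase), sin(t + phase),
                                  seq(0, 4, length.out = 20)))
    expect_equal(coiled_coil_axis(helix)$direction, c(0, 0, 1), tolerance = 1e-9)
  }
  set.seed(3)
  beads <- matrix(cumsum(rnorm(24)), 8, 3)
  ax <- coiled_coil_axis(new_bead_chain(beads))
  v <- beads[8, ] - beads[1, ]
  expect_equal(ax$direction, v / sqrt(sum(v^2)), tolerance = 1e-12)
  expect_error(coiled_coil_axis(new_bead_chain(rbind(c(0, 0, 0), c(1, 0, 0),
                                                     c(0, 0, 0)))),
               "degenerate")
})

test_that("orientations are translation invariant and rotation covariant", {
  set.seed(8)
  ens <- generate_wlc_ensemble(10, 8, 0.5, 1, seed = 8)
  beads <- ens$chains[[1]]$beads
  e0 <- unclass(chain_orientations(new_bead_chain(beads)))
  e_shift <- unclass(chain_orientations(new_bead_chain(sweep(beads, 2, c(3, -2, 7), "+"))))
  expect_equal(e0, e_shift, tolerance = 1e-12)
  R <- random_rotation()
  e_rot <- unclass(chain_orientations(new_bead_chain(beads %*% t(R))))
  expect_equal(e_rot, e0 %*% t(R), tolerance = 1e-10)
})

test_that("a chain split across the periodic box is unwrapped before midpoints", {
  dim <- make_ideal_dimer(origin = c(5, 5, 18.5))  # helix crosses z = 20
  pos <- dim$frame$positions
  pos[, 3] <- pos[, 3] %% 20
  fr <- frame(pos, c(20, 20, 20))
  bc <- build_bead_chain(fr, dim$system, 1)
  seps <- sqrt(rowSums(diff(bc$beads)^2))
  expect_lt(max(seps), 1.0)  # no box-length jump between beads
})

test_that("oligomer bead chains concatenate dimers head to tail", {
  set.seed(9)
  ens <- generate_wlc_ensemble(20, 16, 0.5, 1, seed = 9)
  beads <- ens$chains[[1]]$beads
  sf <- make_system_from_beads(beads)
  bc <- build_bead_chain(sf$frame, sf$system, c(1, 2))
  expect_equal(nrow(bc$beads), 16)
  expect_equal(unname(bc$beads), unname(beads), tolerance = 1e-9)
})
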