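# Synthetic fixtures with known ground truth: worm-like bead chains,
# Ornstein-Uhlenbeck velocity processes, planted salt-bridge assemblies,
# two-state interaction kinetics, and solvated-cylinder particle fields.
# Every generator is deterministic under a fixed seed and returns its
# ground-truth parameters alongside the data.

#' Solve the worm-like-chain concentration parameter
#'
#' For bond directions drawn from a von Mises-Fisher-type polar law with
#' concentration `kappa` about the previous direction, the stationary mean
#' cosine between consecutive bonds is `coth(kappa) - 1/kappa`. This solves
#' for the `kappa` whose mean cosine equals `exp(-dl / L_P)`.
#'
#' @param mean_cos target mean cosine in (0, 1).
#' @return concentration parameter kappa.
#' @export
wlc_kappa <- function(mean_cos) {
  stopifnot(mean_cos > 0, mean_cos < 1)
  f <- function(k) 1 / tanh(k) - 1 / k - mean_cos
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}

# Sample cos(theta) from the vMF polar law, numerically stable for large kappa
sample_vmf_cos <- function(n, kappa) {
  u <- stats::runif(n)
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

rotate_about <- function(dir, cos_t, phi) {
  # unit vector at polar angle acos(cos_t), azimuth phi, relative to dir
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  # orthonormal frame around dir
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * dir) * dir
  u <- u / sqrt(sum(u^2))
  w <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  cos_t * dir + sin_t * (cos(phi) * u + sin(phi) * w)
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

#' Generate an ensemble of worm-like bead chains
#'
#' Successive bond directions follow a first-order Markov chain on the
#' sphere with `E[e_j . e_{j+1}] = exp(-dl / L_P)`, so the orientation
#' correlation decays as `exp(-k dl / L_P)` -- the discrete worm-like chain.
#' `l_p = Inf` yields perfectly straight chains.
#'
#' @param l_p persistence length in nm (> 0 or `Inf`).
#' @param n_beads beads per chain (>= 2).
#' @param dl bond length in nm.
#' @param n_chains number of chains.
#' @param seed integer seed (deterministic output).
#' @return list with `chains` (list of `bead_chain`), `truth` (list of the
#'   generator parameters incl. the target mean cosine).
#' @export
generate_wlc_ensemble <- function(l_p, n_beads, dl, n_chains, seed = 1) {
  stopifnot(l_p > 0, dl > 0, n_beads >= 2, n_chains >= 1)
  set.seed(seed)
  straight <- !is.finite(l_p)
  mean_cos <- if (straight) 1 else exp(-dl / l_p)
  kappa <- if (straight) Inf else wlc_kappa(mean_cos)
  chains <- vector("list", n_chains)
  for (c_i in seq_len(n_chains)) {
    e <- matrix(NA_real_, n_beads - 1, 3)
    e[1, ] <- random_unit_vector()
    if (n_beads > 2) {
      for (j in 2:(n_beads - 1)) {
        if (straight) {
          e[j, ] <- e[j - 1, ]
        } else {
          e[j, ] <- rotate_about(e[j - 1, ], sample_vmf_cos(1, kappa),
                                 stats::runif(1, 0, 2 * pi))
        }
      }
    }
    beads <- rbind(0, apply(e * dl, 2, cumsum))
    chains[[c_i]] <- new_bead_chain(beads, unit = c_i)
  }
  list(chains = chains,
       truth = list(l_p = l_p, dl = dl, n_beads = n_beads,
                    n_chains = n_chains, mean_cos = mean_cos, kappa = kappa,
                    seed = seed))
}

#' Generate an Ornstein-Uhlenbeck velocity process
#'
#' Exact discretisation `v_{t+1} = a v_t + s sqrt(1 - a^2) xi`,
#' `a = exp(-gamma dt)`, started from the stationary distribution. The
#' stationary autocorrelation is `s^2 exp(-gamma tau)` and the Green-Kubo
#' diffusion coefficient is `D = s^2 / gamma` per component. Positions, when
#' requested, accumulate the velocity by trapezoidal integration
#' (unwrapped), optionally also wrapped into a periodic box.
#'
#' @param gamma velocity relaxation rate in 1/ps (> 0).
#' @param s stationary velocity standard deviation in nm/ps (>= 0).
#' @param n_steps steps per series.
#' @param dt time step in ps; must satisfy `gamma * dt < 0.1` so the
#'   discrete series resolves the relaxation.
#' @param n_particles number of independent particles.
#' @param n_dim Cartesian components per particle (default 3).
#' @param seed integer seed.
#' @param with_positions also return integrated positions.
#' @param box optional box lengths (nm) for wrapped positions.
#' @return list with `v` (matrix `n_steps x (n_particles * n_dim)`), `dt`,
#'   optionally `x` (unwrapped) and `x_wrapped`, and `truth`
#'   (gamma, s, `D_nm2_ps = s^2/gamma`, `D_cm2_s`).
#' @export
generate_ou_process <- function(gamma, s, n_steps, dt, n_particles = 1,
                                n_dim = 3, seed = 1, with_positions = FALSE,
                                box = NULL) {
  stopifnot(gamma > 0, s >= 0, dt > 0, n_steps >= 2)
  if (gamma * dt >= 0.1) {
    stop("configuration error: gamma * dt = ", gamma * dt,
         " must be < 0.1 for a faithful discretisation")
  }
  set.seed(seed)
  a <- exp(-gamma * dt)
  nser <- n_particles * n_dim
  v <- matrix(NA_real_, n_steps, nser)
  if (s == 0) {
    v[] <- 0
  } else {
    for (j in seq_len(nser)) {
      noise <- stats::rnorm(n_steps, sd = s * sqrt(1 - a^2))
      v[, j] <- stats::filter(noise, a, method = "recursive",
                              init = stats::rnorm(1, sd = s))
    }
  }
  out <- list(v = v, dt = dt,
              truth = list(gamma = gamma, s = s, dt = dt,
                           D_nm2_ps = s^2 / gamma,
                           D_cm2_s = s^2 / gamma * NM2_PER_PS_TO_CM2_PER_S,
                           n_particles = n_particles, n_dim = n_dim,
                           seed = seed))
  if (with_positions) {
    x <- apply(v, 2, function(col) {
      cumsum(c(0, (utils::head(col, -1) + utils::tail(col, -1)) / 2 * dt))[1:n_steps]
    })
    out$x <- x
    if (!is.null(box)) {
      bx <- rep(box, length.out = n_dim)
      xw <- x
      for (j in seq_len(nser)) {
        L <- bx[(j - 1) %% n_dim + 1]
        xw[, j] <- x[, j] %% L
      }
      out$x_wrapped <- xw
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Planted salt-bridge assemblies

# Minimal pseudo-monomer: only the atoms the salt-bridge analyses inspect.
# Residues keep their true sequence indices (1, 2, 3, 4, 25, 26) so that
# K2/K3/E4/E25/C-terminus are identified exactly as in a full peptide.
pseudo_monomer_atoms <- function() {
  rbind(
    data.frame(name = c("N", "H1", "H2", "H3"), resid = 1, resname = "LEU"),
    data.frame(name = c("NZ", "HZ1", "HZ2", "HZ3"), resid = 2, resname = "LYS"),
    data.frame(name = c("NZ", "HZ1", "HZ2", "HZ3"), resid = 3, resname = "LYS"),
    data.frame(name = c("CD", "OE1", "OE2"), resid = 4, resname = "GLU"),
    data.frame(name = c("CD", "OE1", "OE2"), resid = 25, resname = "GLU"),
    data.frame(name = c("C", "OC1", "OC2"), resid = 26, resname = "LEU")
  )
}

# local coordinates (nm) of the pseudo-monomer atoms: distinct groups kept
# >= 0.6 nm apart within the monomer
pseudo_monomer_coords <- function() {
  base <- rbind(
    c(0.00, 0.00, 0.00), c(0.05, 0.05, 0.00), c(-0.05, 0.05, 0.00), c(0.00, -0.07, 0.00),
    c(0.70, 0.00, 0.00), c(0.75, 0.05, 0.00), c(0.65, 0.05, 0.00), c(0.70, -0.07, 0.00),
    c(1.40, 0.00, 0.00), c(1.45, 0.05, 0.00), c(1.35, 0.05, 0.00), c(1.40, -0.07, 0.00),
    c(0.00, 0.70, 0.00), c(0.05, 0.75, 0.00), c(-0.05, 0.75, 0.00),
    c(0.70, 0.70, 0.00), c(0.75, 0.75, 0.00), c(0.65, 0.75, 0.00),
    c(1.40, 0.70, 0.00), c(1.45, 0.75, 0.00), c(1.35, 0.75, 0.00)
  )
  base
}

#' Generate a planted salt-bridge assembly
#'
#' Builds a coarse system of `n_dimers` dimers (two pseudo-monomers each)
#' carrying correctly named donor and acceptor atoms, placed on a lattice so
#' that all groups of different dimers are far apart, then plants one H-O
#' pair at `link_distance` (default 0.30 nm) for every dimer-dimer link of
#' the requested topology. Links use the N-terminal amino hydrogen of one
#' dimer and a C-terminal carboxylate oxygen of the other, so they qualify
#' as dimer-dimer interactions. Optionally one link is routed across the
#' periodic boundary, and a per-frame schedule can toggle links on and off
#' for kinetics tests.
#'
#' @param topology list of components, each a list with `type`
#'   (`"chain"`, `"ring"` or `"singleton"`) and `dimers` (vector of dimer
#'   ids). All ids 1..n_dimers must appear exactly once.
#' @param n_dimers total number of dimers.
#' @param box cubic box length in nm (default sized to the lattice).
#' @param n_frames number of identical (or scheduled) frames.
#' @param schedule optional logical matrix (n_links x n_frames): FALSE moves
#'   that link's donor hydrogen 1.5 nm away for the frame.
#' @param wrap_link index of a link to place across the periodic boundary
#'   (or `NULL`).
#' @param link_distance planted H-O distance in nm.
#' @param with_beads also give every monomer the eight zipper leucine
#'   C-alpha atoms, laid out so each planted oligomer's bead chain is a
#'   worm-like chain with persistence length `bead_l_p`, enabling end-to-end
#'   persistence analysis on the planted assembly.
#' @param bead_l_p persistence length (nm) of the planted bead chains
#'   (`Inf` = straight fibrils).
#' @param bead_dl bead spacing of the planted chains in nm.
#' @param seed integer seed (controls bead-chain geometry).
#' @return list with `system`, `stream`, `links` (data.frame), `truth`
#'   (the topology, with expected chains/rings/singletons).
#' @export
generate_planted_assembly <- function(topology, n_dimers, box = NULL,
                                      n_frames = 1, schedule = NULL,
                                      wrap_link = NULL, link_distance = 0.30,
                                      with_beads = FALSE, bead_l_p = Inf,
                                      bead_dl = 0.52, seed = 1) {
  ids <- unlist(lapply(topology, `[[`, "dimers"))
  if (!setequal(ids, seq_len(n_dimers)) || length(ids) != n_dimers) {
    stop("topology must cover dimer ids 1..n_dimers exactly once")
  }
  set.seed(seed)
  side <- ceiling(n_dimers^(1 / 3))
  spacing <- 4
  if (is.null(box)) {
    box <- max(side * spacing, 8)
    if (with_beads) {
      # keep the box large enough that no planted fibril approaches half the
      # box length, so minimum-image unwrapping of bead chains is unambiguous
      max_comp <- max(vapply(topology, function(cp) length(cp$dimers), integer(1)))
      box <- max(box, ceiling(2.5 * 8 * max_comp * bead_dl))
    }
  }
  cell <- rep(box, 3)
  # lattice centres
  centres <- matrix(NA_real_, n_dimers, 3)
  k <- 1
  for (ix in 0:(side - 1)) for (iy in 0:(side - 1)) for (iz in 0:(side - 1)) {
    if (k > n_dimers) break
    centres[k, ] <- ((c(ix, iy, iz) + 0.3) * spacing) %% box
    k <- k + 1
  }
  tmpl <- pseudo_monomer_atoms()
  tmpl_xyz <- pseudo_monomer_coords()
  # optional zipper C-alpha traces: one worm-like chain per planted
  # component, 8 beads per dimer, CA pairs straddling each bead
  dimer_beads_planted <- vector("list", n_dimers)
  if (with_beads) {
    lresid <- c(1, 5, 8, 12, 15, 19, 22, 26)
    for (comp in topology) {
      dd <- comp$dimers
      nb <- 8 * length(dd)
      wl <- generate_wlc_ensemble(bead_l_p, nb, bead_dl, 1,
                                  seed = seed + dd[1])
      beads <- sweep(wl$chains[[1]]$beads, 2, centres[dd[1], ] - c(1.5, 1.5, 0), "+")
      for (i in seq_along(dd)) {
        dimer_beads_planted[[dd[i]]] <- beads[((i - 1) * 8 + 1):(i * 8), , drop = FALSE]
      }
    }
    set.seed(seed)  # restore determinism of anything drawn later
  }
  atoms <- list()
  pos <- list()
  for (d in seq_len(n_dimers)) {
    for (m in 1:2) {
      at <- tmpl
      off <- centres[d, ] + c(0, 0, (m - 1) * 1.2)
      p <- sweep(tmpl_xyz, 2, off, "+")
      if (with_beads) {
        beads <- dimer_beads_planted[[d]]
        tangent <- beads[2, ] - beads[1, ]
        perp <- c(-tangent[2], tangent[1], 0)
        if (sqrt(sum(perp^2)) < 1e-8) perp <- c(1, 0, 0)
        perp <- perp / sqrt(sum(perp^2)) * 0.4 * (if (m == 1) 1 else -1)
        at <- rbind(at, data.frame(name = "CA", resid = lresid,
                                   resname = "LEU"))
        p <- rbind(p, sweep(beads, 2, perp, "+"))
        ord <- order(at$resid)
        at <- at[ord, ]
        p <- p[ord, , drop = FALSE]
      }
      at$monomer <- (d - 1) * 2 + m
      atoms[[length(atoms) + 1]] <- at
      pos[[length(pos) + 1]] <- p
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$id <- seq_len(nrow(atoms))
  positions <- do.call(rbind, pos)
  system <- molecular_system(atoms)
  # links from the topology
  links <- list()
  for (comp in topology) {
    dd <- comp$dimers
    if (comp$type == "singleton") next
    edges <- cbind(dd[-length(dd)], dd[-1])
    if (comp$type == "ring") edges <- rbind(edges, c(dd[length(dd)], dd[1]))
    for (e in seq_len(nrow(edges))) {
      links[[length(links) + 1]] <- data.frame(donor_dimer = edges[e, 2],
                                               acceptor_dimer = edges[e, 1])
    }
  }
  links <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(donor_dimer = integer(0), acceptor_dimer = integer(0),
               h_row = integer(0), o_row = integer(0))
  # plant each link: move donor H1 (res 1, monomer A of donor dimer) and
  # acceptor OC1 (res 26, monomer A of acceptor dimer) to a pair-specific
  # site between the two dimer centres
  find_atom <- function(dimer, name, resid) {
    m <- (dimer - 1) * 2 + 1
    which(atoms$monomer == m & atoms$name == name & atoms$resid == resid)
  }
  if (nrow(links) > 0) {
    links$h_row <- NA_integer_
    links$o_row <- NA_integer_
    for (e in seq_len(nrow(links))) {
      links$h_row[e] <- find_atom(links$donor_dimer[e], "H1", 1)
      links$o_row[e] <- find_atom(links$acceptor_dimer[e], "OC1", 26)
      # each dimer donates its N-terminal hydrogen to at most one link, so a
      # donor-anchored site is unique per link and >= 1 nm from every group
      site <- (centres[links$donor_dimer[e], ] + c(1.9, 1.9, 1.0)) %% box
      if (!is.null(wrap_link) && e == wrap_link) {
        # route across the +x boundary
        site <- c(box - link_distance / 2 + 0.02, site[2], site[3])
        positions[links$h_row[e], ] <- site
        positions[links$o_row[e], ] <- c((site[1] + link_distance) %% box,
                                         site[2], site[3])
      } else {
        positions[links$h_row[e], ] <- site
        positions[links$o_row[e], ] <- site + c(link_distance, 0, 0)
      }
    }
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pf <- positions
    if (!is.null(schedule) && nrow(links) > 0) {
      off_links <- which(!schedule[, f])
      for (e in off_links) pf[links$h_row[e], 3] <- (pf[links$h_row[e], 3] + 1.5) %% box
    }
    frames[[f]] <- frame(pf, cell, time = (f - 1) * 20)
  }
  expected <- list(
    chains = Filter(Negate(is.null), lapply(topology, function(cp) {
      if (cp$type == "singleton") NULL else cp
    })),
    singletons = unlist(lapply(topology, function(cp) {
      if (cp$type == "singleton") cp$dimers else NULL
    }))
  )
  list(system = system, stream = frame_stream(frames), links = links,
       truth = c(expected, list(topology = topology, seed = seed, box = box)))
}

#' Generate a random planted topology
#'
#' Utility for property tests: partitions `1..n_dimers` into random chains,
#' rings and singletons.
#'
#' @param n_dimers total dimers.
#' @param seed integer seed.
#' @param p_ring probability that a multi-dimer component is a ring.
#' @return a topology list for [generate_planted_assembly()].
#' @export
random_topology <- function(n_dimers, seed = 1, p_ring = 0.3) {
  set.seed(seed)
  ids <- sample(n_dimers)
  topo <- list()
  i <- 1
  while (i <= n_dimers) {
    size <- min(sample(1:5, 1), n_dimers - i + 1)
    dd <- ids[i:(i + size - 1)]
    type <- if (size == 1) "singleton" else if (size >= 3 && stats::runif(1) < p_ring) "ring" else "chain"
    if (type == "ring" && size < 3) type <- "chain"
    topo[[length(topo) + 1]] <- list(type = type, dimers = dd)
    i <- i + size
  }
  topo
}

#' Generate a planted N-terminal contact-classification fixture
#'
#' Builds pseudo-dimers as in [generate_planted_assembly()] and, for every
#' frame and every monomer, places the monomer's N-terminal amino hydrogen
#' either 0.30 nm from a carboxylate oxygen of (a) its own helix's E4,
#' (b) its partner helix's E4 (same coiled coil), (c) the next dimer's
#' C-terminus (different coiled coil), or leaves it unbridged (solvent).
#' Categories are allocated in exact proportions of `mixture` over the
#' (frame, monomer) observations, so the planted percentages are recovered
#' exactly by [classify_n_terminal_contacts()].
#'
#' @param n_dimers number of dimers (>= 2 when `different_cc` > 0).
#' @param n_frames number of frames.
#' @param mixture named proportions for `same_helix`, `same_cc`,
#'   `different_cc`, `solvent` (normalised internally).
#' @param seed integer seed (controls the allocation shuffle).
#' @return list with `system`, `stream`, `truth` (realised `planted_pct`).
#' @export
generate_contact_fixture <- function(n_dimers, n_frames, mixture, seed = 1) {
  cats <- c("same_helix", "same_cc", "different_cc", "solvent")
  stopifnot(all(names(mixture) %in% cats))
  mixture <- mixture[cats]
  mixture[is.na(mixture)] <- 0
  names(mixture) <- cats
  mixture <- mixture / sum(mixture)
  set.seed(seed)
  side <- ceiling(n_dimers^(1 / 3))
  spacing <- 4
  box <- max(side * spacing, 8)
  centres <- matrix(NA_real_, n_dimers, 3)
  k <- 1
  for (ix in 0:(side - 1)) for (iy in 0:(side - 1)) for (iz in 0:(side - 1)) {
    if (k > n_dimers) break
    centres[k, ] <- ((c(ix, iy, iz) + 0.3) * spacing) %% box
    k <- k + 1
  }
  tmpl <- pseudo_monomer_atoms()
  tmpl_xyz <- pseudo_monomer_coords()
  atoms <- list(); pos <- list()
  for (d in seq_len(n_dimers)) {
    for (m in 1:2) {
      at <- tmpl
      at$monomer <- (d - 1) * 2 + m
      atoms[[length(atoms) + 1]] <- at
      pos[[length(pos) + 1]] <-
        sweep(tmpl_xyz, 2, centres[d, ] + c(0, 0, (m - 1) * 1.2), "+")
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$id <- seq_len(nrow(atoms))
  base_pos <- do.call(rbind, pos)
  system <- molecular_system(atoms)
  n_mono <- n_dimers * 2
  # exact category allocation over (frame, monomer) observations
  n_obs <- n_frames * n_mono
  counts <- floor(mixture * n_obs)
  rem <- n_obs - sum(counts)
  if (rem > 0) {
    extra <- order(mixture * n_obs - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  assignment <- sample(rep(cats, counts))
  find_atom <- function(monomer, name, resid) {
    which(atoms$monomer == monomer & atoms$name == name & atoms$resid == resid)
  }
  frames <- vector("list", n_frames)
  obs <- 1
  for (f in seq_len(n_frames)) {
    pf <- base_pos
    for (m in seq_len(n_mono)) {
      cat_m <- assignment[obs]
      obs <- obs + 1
      h <- find_atom(m, "H1", 1)
      d <- ceiling(m / 2)
      partner <- if (m %% 2 == 1) m + 1 else m - 1
      target <- switch(cat_m,
                       same_helix = find_atom(m, "OE1", 4),
                       same_cc = find_atom(partner, "OE1", 4),
                       different_cc = find_atom((d %% n_dimers) * 2 + 1, "OC1", 26),
                       solvent = NA_integer_)
      if (!is.na(target)) pf[h, ] <- pf[target, ] + c(0, 0, 0.30)
    }
    frames[[f]] <- frame(pf, rep(box, 3), time = (f - 1) * 20)
  }
  planted_pct <- 100 * counts / n_obs
  list(system = system, stream = frame_stream(frames),
       truth = list(planted_pct = planted_pct, mixture = mixture, seed = seed))
}

#' Generate two-state Markov interaction kinetics
#'
#' Presence/absence series for `n_pairs` dimer-dimer interactions following
#' a two-state Markov chain with binding rate `k_on` and unbinding rate
#' `k_off`; the mean on-time is `1/k_off` and the stationary bound fraction
#' `k_on / (k_on + k_off)`.
#'
#' @param k_on,k_off rates in 1/ps (> 0).
#' @param n_pairs number of independent interaction pairs.
#' @param n_frames frames per series.
#' @param dt frame interval in ps.
#' @param seed integer seed.
#' @return list with `presence` (logical matrix n_pairs x n_frames), `dt`,
#'   `truth` (rates, mean on-time, stationary fraction).
#' @export
generate_interaction_kinetics <- function(k_on, k_off, n_pairs, n_frames,
                                          dt, seed = 1) {
  stopifnot(k_on > 0, k_off > 0)
  set.seed(seed)
  p_on <- 1 - exp(-k_on * dt)
  p_off <- 1 - exp(-k_off * dt)
  pi_on <- k_on / (k_on + k_off)
  presence <- matrix(FALSE, n_pairs, n_frames)
  presence[, 1] <- stats::runif(n_pairs) < pi_on
  for (f in 2:n_frames) {
    u <- stats::runif(n_pairs)
    presence[, f] <- ifelse(presence[, f - 1], u >= p_off, u < p_on)
  }
  rownames(presence) <- paste0("pair", seq_len(n_pairs))
  list(presence = presence, dt = dt,
       truth = list(k_on = k_on, k_off = k_off, mean_on_time = 1 / k_off,
                    stationary_on = pi_on, seed = seed))
}

#' Generate a solvated-cylinder particle field
#'
#' Pseudo-water particles (single-site, resname `SOL`) are placed in a box
#' as an inhomogeneous Poisson field whose intensity depends only on the
#' radial distance to the z-axis through the box centre, then evolved with
#' Ornstein-Uhlenbeck velocities whose per-particle diffusivity is set from
#' `d_profile` at the particle's initial radius. A minimal axis dimer (two
#' pseudo-monomers of eight leucine C-alpha atoms each, midpoints on the
#' axis) is included so the hydration pipeline runs end to end from the bead
#' chain.
#'
#' @param density_profile function of radius (nm) returning the water number
#'   density (nm^-3).
#' @param d_profile function of radius (nm) returning the local diffusion
#'   coefficient in nm^2/ps.
#' @param box box lengths (nm), length 3; the axis runs along z.
#' @param n_frames number of stored frames.
#' @param dt frame interval in ps (fine, e.g. 0.01 ps).
#' @param gamma velocity relaxation rate in 1/ps (default 8; fast compared
#'   to the frame interval yet resolvable, `gamma * dt < 0.1`).
#' @param seed integer seed.
#' @return list with `system`, `stream`, `axis_chain` (a `bead_chain`),
#'   `truth` (profiles, particle count, initial radii and per-particle D).
#' @export
generate_solvated_cylinder <- function(density_profile, d_profile, box,
                                       n_frames, dt, gamma = 8, seed = 1) {
  stopifnot(length(box) == 3, n_frames >= 3)
  set.seed(seed)
  centre <- box / 2
  # Poisson placement by thinning against the maximum density
  r_grid <- seq(0, sqrt(2) * max(box[1:2]) / 2, length.out = 512)
  rho_max <- max(vapply(r_grid, density_profile, numeric(1)))
  n_cand <- stats::rpois(1, rho_max * prod(box))
  cand <- cbind(stats::runif(n_cand, 0, box[1]), stats::runif(n_cand, 0, box[2]),
                stats::runif(n_cand, 0, box[3]))
  r0 <- sqrt((cand[, 1] - centre[1])^2 + (cand[, 2] - centre[2])^2)
  keep <- stats::runif(n_cand) < vapply(r0, density_profile, numeric(1)) / rho_max
  x0 <- cand[keep, , drop = FALSE]
  r0 <- r0[keep]
  n_p <- nrow(x0)
  if (n_p == 0) stop("density profile produced no particles")
  D_i <- vapply(r0, d_profile, numeric(1))
  s_i <- sqrt(D_i * gamma)
  # axis dimer: 8 leucine CA per monomer, midpoints on the axis
  n_beads <- 8
  zb <- seq(0.5, box[3] - 0.5, length.out = n_beads)
  lresid <- c(1, 5, 8, 12, 15, 19, 22, 26)
  solute_atoms <- do.call(rbind, lapply(1:2, function(m) {
    data.frame(name = "CA", resid = lresid, resname = "LEU", monomer = m)
  }))
  solute_pos <- rbind(cbind(centre[1] + 0.3, centre[2], zb),
                      cbind(centre[1] - 0.3, centre[2], zb))
  water_atoms <- data.frame(name = "OW", resid = seq_len(n_p), resname = "SOL",
                            monomer = 2 + seq_len(n_p))
  atoms <- rbind(solute_atoms, water_atoms)
  atoms$id <- seq_len(nrow(atoms))
  # water monomers map each to its own dimer; solute monomers 1+2 -> dimer 1
  dimer_map <- stats::setNames(c(1, 1, 1 + seq_len(n_p)), c(1, 2, 2 + seq_len(n_p)))
  system <- molecular_system(atoms, dimer_map = dimer_map)
  # OU displacement dynamics per particle
  a <- exp(-gamma * dt)
  if (gamma * dt >= 0.1) stop("gamma * dt must be < 0.1")
  sd_step <- sqrt(1 - a^2)
  v <- matrix(stats::rnorm(n_p * 3), n_p, 3) * s_i
  xw <- x0
  frames <- vector("list", n_frames)
  n_solute <- nrow(solute_pos)
  for (f in seq_len(n_frames)) {
    pf <- rbind(solute_pos, xw)
    frames[[f]] <- frame(pf, box, time = (f - 1) * dt)
    v_new <- a * v + matrix(stats::rnorm(n_p * 3), n_p, 3) * (s_i * sd_step)
    xw <- xw + (v + v_new) / 2 * dt
    xw <- sweep(xw, 2, box, function(x, L) x %% L)
    v <- v_new
  }
  axis_chain <- new_bead_chain(cbind(centre[1], centre[2], zb), unit = 1)
  list(system = system, stream = frame_stream(frames), axis_chain = axis_chain,
       truth = list(n_particles = n_p, r0 = r0, D_nm2_ps = D_i, gamma = gamma,
                    density_profile = density_profile, d_profile = d_profile,
                    box = box, seed = seed))
}

#' Write a generated fixture plus its ground-truth sidecar
#'
#' Writes the structure/trajectory as multi-frame GRO, the monomer-dimer
#' mapping, and a JSON sidecar with the generator's scalar ground-truth
#' parameters (function-valued entries are dropped).
#'
#' @param fixture a generator result with `system`, `stream`, `truth`.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return named list of the written paths.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- file.path(dir, paste0(name, ".gro"))
  write_trajectory(fixture$stream, fixture$system, traj)
  mapf <- file.path(dir, paste0(name, "_dimers.txt"))
  write_dimer_map(fixture$system, mapf)
  truth <- Filter(function(x) !is.function(x) && !is.list(x), fixture$truth)
  sidecar <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  list(trajectory = traj, dimer_map = mapf, truth = sidecar)
}
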