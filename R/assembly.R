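# Salt-bridge detection and the oligomer interaction graph. A contact
# between an ammonium group and a carboxylate group counts as a salt bridge
# when any hydrogen of the NH3+ group is within the cutoff (default 0.35 nm,
# minimum-image) of either carboxylate oxygen. A dimer-dimer interaction is
# a salt bridge between one dimer's {N-terminal amino group, K2, K3} and the
# neighbouring dimer's {C-terminus, E25}. Oligomer chains are the connected
# components of the interaction graph; a circular chain is reported one
# element longer than its dimer count.

#' Salt-bridge detection criteria
#'
#' Donor hydrogens are matched by name on specific residues: `H1/H2/H3` (and
#' `H`) on residue 1 or on a chromophore group (configurable residue names),
#' and `HZ1/HZ2/HZ3` on lysines. Acceptor oxygens: `OE1/OE2` on glutamates
#' and `OC1/OC2/OXT` on the C-terminal residue.
#'
#' @param cutoff H-O distance cutoff in nm (default 0.35).
#' @param chromophore_resnames residue names treated as an N-terminal
#'   chromophore amino group (default `c("ABA","OAB","PAB")`).
#' @param chromophore_h_names atom-name pattern for chromophore amino
#'   hydrogens.
#' @return list of class `salt_bridge_criteria`
#' @export
salt_bridge_criteria <- function(cutoff = 0.35,
                                 chromophore_resnames = c("ABA", "OAB", "PAB"),
                                 chromophore_h_names = "^H[N1-3]?[123]?$") {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff,
                 chromophore_resnames = chromophore_resnames,
                 chromophore_h_names = chromophore_h_names),
            class = "salt_bridge_criteria")
}

# Identify donor (ammonium) hydrogens and acceptor (carboxylate) oxygens.
# Group labels: donors NTER / K<resid>; acceptors CTER / E<resid>.
donor_acceptor_atoms <- function(system, criteria) {
  a <- system$atoms
  last_resid <- stats::ave(a$resid, a$monomer, FUN = max)
  is_chromo <- a$resname %in% criteria$chromophore_resnames
  don_nter <- (a$resid == 1 & !is_chromo & grepl("^H[123]?$", a$name)) |
    (is_chromo & grepl(criteria$chromophore_h_names, a$name))
  don_lys <- a$resname == "LYS" & grepl("^HZ[123]$", a$name)
  donors <- data.frame(row = which(don_nter | don_lys))
  if (nrow(donors) > 0) {
    di <- donors$row
    donors$monomer <- a$monomer[di]
    donors$dimer <- a$dimer[di]
    donors$resid <- a$resid[di]
    donors$group <- ifelse(don_nter[di], "NTER", paste0("K", a$resid[di]))
  }
  acc_glu <- a$resname == "GLU" & grepl("^OE[12]$", a$name)
  acc_cter <- a$resid == last_resid & grepl("^OC[12]$|^OXT$", a$name)
  acceptors <- data.frame(row = which(acc_glu | acc_cter))
  if (nrow(acceptors) > 0) {
    ai <- acceptors$row
    acceptors$monomer <- a$monomer[ai]
    acceptors$dimer <- a$dimer[ai]
    acceptors$resid <- a$resid[ai]
    acceptors$group <- ifelse(acc_cter[ai], "CTER", paste0("E", a$resid[ai]))
  }
  list(donors = donors, acceptors = acceptors)
}

#' Detect salt bridges in one frame
#'
#' All donor-hydrogen / acceptor-oxygen minimum-image distances are scanned;
#' each (donor group, acceptor group) pair whose minimum H-O distance is
#' within the cutoff yields one record, regardless of how many atom pairs
#' qualify.
#'
#' @param fr a [frame()].
#' @param system a [molecular_system()].
#' @param criteria a [salt_bridge_criteria()].
#' @return data.frame with one row per bridged group pair: donor/acceptor
#'   monomer, dimer, resid, group label and the minimum H-O distance (nm).
#' @export
detect_salt_bridges <- function(fr, system, criteria = salt_bridge_criteria()) {
  da <- donor_acceptor_atoms(system, criteria)
  if (nrow(da$donors) == 0) stop("topology error: no ammonium donor atoms found")
  if (nrow(da$acceptors) == 0) stop("topology error: no carboxylate acceptor atoms found")
  dp <- fr$positions[da$donors$row, , drop = FALSE]
  ap <- fr$positions[da$acceptors$row, , drop = FALSE]
  nd <- nrow(dp); na <- nrow(ap)
  # pairwise minimum-image distances (fixture-scale systems: direct product)
  dist2 <- matrix(0, nd, na)
  for (k in 1:3) {
    dk <- outer(dp[, k], ap[, k], "-")
    dk <- dk - fr$cell[k] * floor(dk / fr$cell[k] + 0.5)
    dist2 <- dist2 + dk^2
  }
  hits <- which(dist2 <= criteria$cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(empty_bridge_table())
  }
  br <- data.frame(
    donor_monomer = da$donors$monomer[hits[, 1]],
    donor_dimer = da$donors$dimer[hits[, 1]],
    donor_resid = da$donors$resid[hits[, 1]],
    donor_group = da$donors$group[hits[, 1]],
    acceptor_monomer = da$acceptors$monomer[hits[, 2]],
    acceptor_dimer = da$acceptors$dimer[hits[, 2]],
    acceptor_resid = da$acceptors$resid[hits[, 2]],
    acceptor_group = da$acceptors$group[hits[, 2]],
    distance = sqrt(dist2[hits])
  )
  # one record per (donor group, acceptor group): keep the minimum distance
  key <- paste(br$donor_monomer, br$donor_group, br$donor_resid,
               br$acceptor_monomer, br$acceptor_group, br$acceptor_resid)
  br <- br[order(key, br$distance), ]
  br <- br[!duplicated(paste(br$donor_monomer, br$donor_group, br$donor_resid,
                             br$acceptor_monomer, br$acceptor_group,
                             br$acceptor_resid)), ]
  rownames(br) <- NULL
  br
}

empty_bridge_table <- function() {
  data.frame(donor_monomer = integer(0), donor_dimer = integer(0),
             donor_resid = integer(0), donor_group = character(0),
             acceptor_monomer = integer(0), acceptor_dimer = integer(0),
             acceptor_resid = integer(0), acceptor_group = character(0),
             distance = numeric(0))
}

#' Dimer-dimer interactions from salt bridges
#'
#' A dimer pair (i, j) interacts when at least one bridge links dimer i's
#' N-terminal amino group, K2 or K3 to dimer j's C-terminus or E25 (or vice
#' versa). Intradimer bridges never qualify.
#'
#' @param bridges output of [detect_salt_bridges()].
#' @return two-column matrix of unordered dimer pairs (i < j); zero rows when
#'   no interaction exists.
#' @export
dimer_interactions <- function(bridges) {
  if (nrow(bridges) == 0) return(matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("i", "j"))))
  ok <- bridges$donor_group %in% c("NTER", "K2", "K3") &
    bridges$acceptor_group %in% c("CTER", "E25") &
    bridges$donor_dimer != bridges$acceptor_dimer
  b <- bridges[ok, , drop = FALSE]
  if (nrow(b) == 0) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("i", "j"))))
  pairs <- cbind(i = pmin(b$donor_dimer, b$acceptor_dimer),
                 j = pmax(b$donor_dimer, b$acceptor_dimer))
  unique(pairs)
}

#' Identify oligomer chains from dimer interactions
#'
#' Connected components of the interaction graph. Simple paths become linear
#' chains (reported length = dimer count); components containing a cycle are
#' flagged circular and reported one element longer than their dimer count;
#' isolated dimers are unbound. Branched components (any dimer with three or
#' more partners) are reported as a single chain ordered along their longest
#' simple path, flagged `branched`, with a warning: the partition of dimers
#' into chains is preserved rather than inventing a split rule.
#'
#' @param pairs two-column matrix of dimer pairs ([dimer_interactions()]).
#' @param dimer_ids all dimer ids in the system.
#' @return list with `chains` (list of lists: `dimers` ordered ids,
#'   `circular`, `branched`, `length` reported length) and `unbound`
#'   (vector of singleton dimer ids).
#' @export
identify_chains <- function(pairs, dimer_ids) {
  verts <- as.character(dimer_ids)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(pairs) > 0) {
    g <- igraph::add_edges(g, rbind(match(as.character(pairs[, 1]), verts),
                                    match(as.character(pairs[, 2]), verts)))
  }
  comp <- igraph::components(g)
  chains <- list()
  unbound <- integer(0)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    ids <- as.integer(verts[members])
    if (length(ids) == 1) {
      unbound <- c(unbound, ids)
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    degs <- igraph::degree(sub)
    n <- igraph::vcount(sub)
    m <- igraph::ecount(sub)
    has_cycle <- m >= n
    branched <- any(degs >= 3)
    if (branched) {
      warning("branched oligomer component with ", n,
              " dimers: ordered along its longest simple path")
      order_ids <- longest_path_order(sub)
    } else if (has_cycle) {
      # simple ring: walk the cycle
      order_ids <- as.integer(igraph::V(sub)$name[igraph::dfs(sub, root = 1)$order])
    } else {
      ends <- which(degs == 1)
      p <- igraph::shortest_paths(sub, from = ends[1], to = ends[2])$vpath[[1]]
      order_ids <- as.integer(igraph::V(sub)$name[p])
    }
    reported <- if (has_cycle) length(ids) + 1L else length(ids)
    chains[[length(chains) + 1]] <- list(dimers = order_ids,
                                         circular = has_cycle,
                                         branched = branched,
                                         length = reported)
  }
  list(chains = chains, unbound = sort(unbound))
}

longest_path_order <- function(sub) {
  degs <- igraph::degree(sub)
  leaves <- which(degs <= 1)
  if (length(leaves) < 2) leaves <- seq_len(igraph::vcount(sub))
  best <- NULL
  for (i in seq_along(leaves)) {
    for (jj in seq_along(leaves)) {
      if (jj <= i) next
      sp <- igraph::all_simple_paths(sub, from = leaves[i], to = leaves[jj])
      for (p in sp) if (is.null(best) || length(p) > length(best)) best <- p
    }
  }
  path_ids <- as.integer(igraph::V(sub)$name[best])
  # append off-path members so the partition is preserved
  rest <- setdiff(as.integer(igraph::V(sub)$name), path_ids)
  c(path_ids, rest)
}

#' Chains and unbound dimers of a single frame
#'
#' Convenience wrapper: detect bridges, derive dimer interactions, identify
#' chains.
#'
#' @inheritParams detect_salt_bridges
#' @return as [identify_chains()], plus `pairs` (the interaction matrix).
#' @export
frame_chains <- function(fr, system, criteria = salt_bridge_criteria()) {
  bridges <- detect_salt_bridges(fr, system, criteria)
  pairs <- dimer_interactions(bridges)
  out <- identify_chains(pairs, system$dimers)
  out$pairs <- pairs
  out
}

#' Per-frame assembly timeline of a stream
#'
#' @inheritParams detect_salt_bridges
#' @param stream a [frame_stream()].
#' @return list of per-frame [frame_chains()] results; attribute `times`.
#' @export
assembly_timeline <- function(stream, system, criteria = salt_bridge_criteria()) {
  tl <- lapply(stream$frames, frame_chains, system = system, criteria = criteria)
  attr(tl, "times") <- vapply(stream$frames, function(f) f$time, numeric(1))
  attr(tl, "dt") <- stream$dt
  tl
}

timeline_in_window <- function(tl, window) {
  times <- attr(tl, "times")
  if (is.null(window)) return(tl)
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("empty analysis window [", window[1], ", ", window[2], "] ps")
  out <- tl[keep]
  attr(out, "times") <- times[keep]
  attr(out, "dt") <- attr(tl, "dt")
  out
}

#' Oligomer size distribution with replica statistics
#'
#' Per frame, each chain contributes one count at its reported length
#' (chain-weighted, so the probability mass at size 1 equals the unbound
#' fraction of chains); the per-replica mass function is the normalised
#' pooled histogram over the window, and mean and standard deviation are
#' taken across replicas.
#'
#' @param timelines list of [assembly_timeline()] results (one per replica),
#'   or a single timeline.
#' @param window time range `c(t0, t1)` in ps, or `NULL` for all frames.
#' @return data.frame (size, mean_prob, sd_prob) over all sizes observed.
#' @export
oligomer_size_distribution <- function(timelines, window = NULL) {
  if (!is.null(attr(timelines, "times"))) timelines <- list(timelines)
  per_rep <- lapply(timelines, function(tl) {
    tl <- timeline_in_window(tl, window)
    sizes <- unlist(lapply(tl, function(fc) {
      c(vapply(fc$chains, `[[`, integer(1), "length"),
        rep(1L, length(fc$unbound)))
    }))
    if (length(sizes) == 0) stop("no chains in window")
    table(sizes) / length(sizes)
  })
  all_sizes <- sort(unique(as.integer(unlist(lapply(per_rep, names)))))
  mat <- vapply(per_rep, function(tb) {
    v <- as.numeric(tb[as.character(all_sizes)])
    v[is.na(v)] <- 0
    v
  }, numeric(length(all_sizes)))
  mat <- matrix(mat, nrow = length(all_sizes))
  data.frame(size = all_sizes,
             mean_prob = rowMeans(mat),
             sd_prob = apply(mat, 1, stats::sd))
}

#' Block-averaged unbound-dimer time series with replica statistics
#'
#' @param timelines list of [assembly_timeline()] results (one per replica).
#' @param block block size in ps (>= the frame interval).
#' @return data.frame (time, mean_unbound, sd_unbound), one row per block.
#' @export
unbound_dimer_timeseries <- function(timelines, block) {
  if (!is.null(attr(timelines, "times"))) timelines <- list(timelines)
  dt <- attr(timelines[[1]], "dt")
  if (is.na(dt)) dt <- 1
  if (block < dt) stop("block size (", block, " ps) is below the frame interval (", dt, " ps)")
  per_block <- floor(block / dt)
  per_rep <- lapply(timelines, function(tl) {
    counts <- vapply(tl, function(fc) length(fc$unbound), numeric(1))
    nb <- floor(length(counts) / per_block)
    if (nb == 0) stop("stream shorter than one block")
    colMeans(matrix(counts[1:(nb * per_block)], nrow = per_block))
  })
  nb <- min(vapply(per_rep, length, integer(1)))
  mat <- vapply(per_rep, function(v) v[1:nb], numeric(nb))
  mat <- matrix(mat, nrow = nb)
  t0 <- attr(timelines[[1]], "times")[1]
  data.frame(time = t0 + (seq_len(nb) - 0.5) * per_block * dt,
             mean_unbound = rowMeans(mat),
             sd_unbound = apply(mat, 1, stats::sd))
}

#' Presence matrix of dimer-dimer interactions
#'
#' @param tl an [assembly_timeline()].
#' @return logical matrix, one row per dimer pair ever observed (rownames
#'   `"i-j"`), one column per frame.
#' @export
interaction_presence <- function(tl) {
  keys <- unique(unlist(lapply(tl, function(fc) {
    if (nrow(fc$pairs) == 0) character(0) else paste(fc$pairs[, 1], fc$pairs[, 2], sep = "-")
  })))
  mat <- matrix(FALSE, nrow = length(keys), ncol = length(tl),
                dimnames = list(keys, NULL))
  for (f in seq_along(tl)) {
    p <- tl[[f]]$pairs
    if (nrow(p) > 0) mat[paste(p[, 1], p[, 2], sep = "-"), f] <- TRUE
  }
  mat
}

#' Interaction lifetimes (residence times)
#'
#' Maximal runs of continuous presence are converted to durations
#' `run length x frame interval`, where a run's length counts all frames from
#' its first to its last present frame. Runs separated by at most
#' `gap_tolerance` absent frames are merged. Runs touching the window edges
#' are flagged censored; a run spanning the entire window is censored on both
#' sides and excluded from the cumulative distribution's numerator, so the
#' cumulative distribution reaches 1 only if no interaction survives the
#' whole window.
#'
#' @param presence logical matrix (pairs x frames) as from
#'   [interaction_presence()], or a single logical vector.
#' @param dt frame interval in ps.
#' @param gap_tolerance maximum number of absent frames bridged (default 0).
#' @return list with `lifetimes` (data.frame: pair, start_frame, n_frames,
#'   duration ps, censored_left, censored_right) and `cdf`
#'   (data.frame: duration, cumulative), where `cumulative` is the fraction
#'   of all runs finished within the duration.
#' @export
interaction_lifetimes <- function(presence, dt = 1, gap_tolerance = 0) {
  if (is.vector(presence)) presence <- matrix(presence, nrow = 1)
  nf <- ncol(presence)
  rows <- list()
  for (p in seq_len(nrow(presence))) {
    on <- which(presence[p, ])
    if (length(on) == 0) next
    # merge runs separated by <= gap_tolerance absent frames
    breaks <- which(diff(on) > gap_tolerance + 1)
    starts <- on[c(1, breaks + 1)]
    ends <- on[c(breaks, length(on))]
    rows[[length(rows) + 1]] <- data.frame(
      pair = if (!is.null(rownames(presence))) rownames(presence)[p] else as.character(p),
      start_frame = starts, n_frames = ends - starts + 1,
      duration = (ends - starts + 1) * dt,
      censored_left = starts == 1, censored_right = ends == nf)
  }
  if (length(rows) == 0) {
    lt <- data.frame(pair = character(0), start_frame = integer(0),
                     n_frames = integer(0), duration = numeric(0),
                     censored_left = logical(0), censored_right = logical(0))
    return(list(lifetimes = lt, cdf = data.frame(duration = numeric(0),
                                                 cumulative = numeric(0))))
  }
  lt <- do.call(rbind, rows)
  rownames(lt) <- NULL
  full <- lt$censored_left & lt$censored_right
  dur <- sort(unique(lt$duration))
  cdf <- data.frame(duration = dur,
                    cumulative = vapply(dur, function(d) {
                      sum(lt$duration <= d & !full) / nrow(lt)
                    }, numeric(1)))
  list(lifetimes = lt, cdf = cdf)
}

#' Classify the salt-bridge partners of each N-terminal amino group
#'
#' Per frame and per N-terminal amino group (backbone N-terminus or
#' chromophore amino group), non-exclusive flags record a bridge to a
#' carboxylate (a) in the same alpha-helix, (b) in the partner helix of the
#' same coiled coil, (c) in a different coiled coil; `solvent` counts frames
#' with no bridge at all. Percentages are over frames and groups; mean and
#' standard deviation are across replicas. Because the category flags are
#' non-exclusive, the four percentages can sum to slightly more than 100.
#'
#' @param timelines_or_streams list of [frame_stream()]s (one per replica),
#'   or a single stream.
#' @param system a [molecular_system()].
#' @param criteria a [salt_bridge_criteria()].
#' @return data.frame (category, mean, sd) with categories `same_helix`,
#'   `same_cc`, `different_cc`, `solvent`, percentages in [0, 100].
#' @export
classify_n_terminal_contacts <- function(timelines_or_streams, system,
                                         criteria = salt_bridge_criteria()) {
  streams <- timelines_or_streams
  if (inherits(streams, "frame_stream")) streams <- list(streams)
  a <- system$atoms
  mono2dim <- stats::setNames(a$dimer[!duplicated(a$monomer)],
                              a$monomer[!duplicated(a$monomer)])
  groups <- system$monomers
  per_rep <- vapply(streams, function(stream) {
    tallies <- c(same_helix = 0, same_cc = 0, different_cc = 0, solvent = 0)
    n_obs <- 0
    for (fr in stream$frames) {
      br <- detect_salt_bridges(fr, system, criteria)
      br <- br[br$donor_group == "NTER", , drop = FALSE]
      for (m in groups) {
        bm <- br[br$donor_monomer == m, , drop = FALSE]
        n_obs <- n_obs + 1
        if (nrow(bm) == 0) {
          tallies["solvent"] <- tallies["solvent"] + 1
          next
        }
        same_mono <- bm$acceptor_monomer == m
        same_dim <- bm$acceptor_dimer == mono2dim[as.character(m)] & !same_mono
        diff_dim <- bm$acceptor_dimer != mono2dim[as.character(m)]
        if (any(same_mono)) tallies["same_helix"] <- tallies["same_helix"] + 1
        if (any(same_dim)) tallies["same_cc"] <- tallies["same_cc"] + 1
        if (any(diff_dim)) tallies["different_cc"] <- tallies["different_cc"] + 1
      }
    }
    100 * tallies / n_obs
  }, numeric(4))
  per_rep <- matrix(per_rep, nrow = 4,
                    dimnames = list(c("same_helix", "same_cc", "different_cc",
                                      "solvent"), NULL))
  data.frame(category = rownames(per_rep),
             mean = rowMeans(per_rep),
             sd = apply(per_rep, 1, stats::sd),
             row.names = NULL)
}
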