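# Virtual bead chain through the coiled-coil core. One bead per
# leucine-leucine zipper pair: the bead sits at the midpoint between the two
# leucine C-alpha atoms, i.e. at the center of the coiled coil. Orientation
# vectors between consecutive beads feed the persistence-length estimator;
# the dimer axis (first bead -> last bead) anchors the hydration analysis.

#' Build the virtual bead chain of a dimer or ordered oligomer
#'
#' For each coiled-coil dimer, the zipper leucines are found by scanning each
#' monomer for `LEU` residues carrying a `CA` atom (so an optional N-terminal
#' chromophore group, which contains no leucine, shifts nothing and
#' contributes no bead). Leucines present in both monomers are paired by
#' residue index, ordered N to C, and each bead is the arithmetic midpoint of
#' the two C-alpha positions after minimum-image unwrapping of the monomer
#' pair relative to its first zipper atom, so a chain is never split across
#' the periodic box.
#'
#' For an ordered oligomer (a vector of dimer ids), per-dimer bead runs are
#' concatenated in the given chain order; each subsequent dimer is unwrapped
#' relative to the running chain end and its bead order is flipped when that
#' brings its terminal bead closer to the junction, so that the N-terminus of
#' one dimer meets the C-terminus of the next.
#'
#' @param fr a [frame()].
#' @param system a [molecular_system()].
#' @param unit a single dimer id, or an ordered vector of dimer ids.
#' @return object of class `bead_chain`: list with `beads` (N x 3 matrix,
#'   nm), `spacing` (mean consecutive bead distance, nm), `unit`.
#' @export
build_bead_chain <- function(fr, system, unit) {
  stopifnot(inherits(fr, "md_frame"), inherits(system, "molecular_system"))
  beads <- NULL
  for (d in unit) {
    b <- dimer_beads(fr, system, d)
    if (is.null(beads)) {
      beads <- b
    } else {
      tail_pos <- beads[nrow(beads), ]
      # unwrap this dimer's beads relative to the current chain end
      shift <- minimum_image_displacement(tail_pos, b[1, ], fr$cell) - (b[1, ] - tail_pos)
      b <- sweep(b, 2, shift, "+")
      d_head <- sqrt(sum((b[1, ] - tail_pos)^2))
      shift_rev <- minimum_image_displacement(tail_pos, b[nrow(b), ], fr$cell) -
        (b[nrow(b), ] - tail_pos)
      b_rev <- sweep(dimer_beads(fr, system, d), 2, shift_rev, "+")[rev(seq_len(nrow(b))), ]
      d_tail <- sqrt(sum((b_rev[1, ] - tail_pos)^2))
      if (d_tail < d_head) b <- b_rev
      beads <- rbind(beads, b)
    }
  }
  new_bead_chain(beads, unit)
}

new_bead_chain <- function(beads, unit = NA) {
  beads <- as.matrix(beads)
  if (nrow(beads) < 2) stop("a bead chain needs at least 2 beads")
  seps <- sqrt(rowSums(diff(beads)^2))
  if (any(seps == 0)) stop("degenerate geometry: coincident consecutive beads")
  structure(list(beads = beads, spacing = mean(seps), unit = unit),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("bead_chain: %d beads, mean spacing %.3f nm\n",
              nrow(x$beads), x$spacing))
  invisible(x)
}

dimer_beads <- function(fr, system, dimer_id) {
  a <- system$atoms
  mono <- unique(a$monomer[a$dimer == dimer_id])
  if (length(mono) != 2) {
    stop("dimer ", dimer_id, " does not consist of exactly two monomers")
  }
  zip <- lapply(mono, function(m) {
    sel <- a$monomer == m & a$resname == "LEU" & a$name == "CA"
    data.frame(resid = a$resid[sel], row = which(sel))
  })
  common <- intersect(zip[[1]]$resid, zip[[2]]$resid)
  if (length(common) == 0) {
    stop("topology error: no leucine CA zipper pairs in dimer ", dimer_id,
         " (monomers ", mono[1], ", ", mono[2], ")")
  }
  common <- sort(common)
  rows1 <- zip[[1]]$row[match(common, zip[[1]]$resid)]
  rows2 <- zip[[2]]$row[match(common, zip[[2]]$resid)]
  # unwrap both monomers' zipper atoms relative to the first zipper atom
  ref <- fr$positions[rows1[1], ]
  unwrap <- function(rows) {
    p <- fr$positions[rows, , drop = FALSE]
    sweep(minimum_image_displacement(matrix(ref, nrow(p), 3, byrow = TRUE),
                                     p, fr$cell), 2, ref, "+")
  }
  (unwrap(rows1) + unwrap(rows2)) / 2
}

#' Local chain orientation vectors
#'
#' Unit vectors `e_j = (b_{j+1} - b_j) / ||b_{j+1} - b_j||` along the bead
#' chain, j = 1..N-1.
#'
#' @param chain a `bead_chain`.
#' @return object of class `orientation_set`: (N-1) x 3 matrix of unit rows.
#' @export
chain_orientations <- function(chain) {
  stopifnot(inherits(chain, "bead_chain"))
  d <- diff(chain$beads)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0)) stop("degenerate geometry: coincident consecutive beads")
  e <- d / nrm
  structure(e, class = c("orientation_set", "matrix"))
}

#' Coiled-coil axis from the bead chain
#'
#' The axis is the vector from the first to the last bead, returned as an
#' anchor point plus unit direction together with the end-to-end length.
#'
#' @param chain a `bead_chain`.
#' @return list with `point` (first bead), `direction` (unit), `length` (nm).
#' @export
coiled_coil_axis <- function(chain) {
  stopifnot(inherits(chain, "bead_chain"))
  b1 <- chain$beads[1, ]
  bN <- chain$beads[nrow(chain$beads), ]
  v <- bN - b1
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate geometry: first and last bead coincide")
  list(point = b1, direction = v / len, length = len)
}

#' Export bead coordinates as a data.frame
#'
#' @param chain a `bead_chain`.
#' @param frame_index,chain_id identifiers copied into the output.
#' @return data.frame (frame, chain, j, x, y, z)
#' @export
bead_chain_table <- function(chain, frame_index = NA, chain_id = NA) {
  data.frame(frame = frame_index, chain = chain_id,
             j = seq_len(nrow(chain$beads)),
             x = chain$beads[, 1], y = chain$beads[, 2], z = chain$beads[, 3])
}
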