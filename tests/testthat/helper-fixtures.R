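# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

CC_PEPTIDE_SEQ <- "LKKELAALKKELAALKKELAALKKEL"
AA3 <- c(L = "LEU", K = "LYS", E = "GLU", A = "ALA")

seq_resnames <- function(seq = CC_PEPTIDE_SEQ) {
  unname(AA3[strsplit(seq, "")[[1]]])
}

# CA-only helix: residues of the full sequence along `direction` from
# `origin`, one CA per residue at `rise` nm per residue
make_ca_monomer <- function(monomer_id, origin, direction = c(0, 0, 1),
                            rise = 0.15) {
  resnames <- seq_resnames()
  n <- length(resnames)
  atoms <- data.frame(name = "CA", resid = seq_len(n), resname = resnames,
                      monomer = monomer_id)
  pos <- t(vapply(seq_len(n), function(i) origin + (i - 1) * rise * direction,
                  numeric(3)))
  list(atoms = atoms, pos = pos)
}

# Ideal straight dimer: two parallel CA-only helices offset by `offset`
make_ideal_dimer <- function(offset = c(1, 0, 0), cell = c(20, 20, 20),
                             origin = c(5, 5, 5)) {
  m1 <- make_ca_monomer(1, origin)
  m2 <- make_ca_monomer(2, origin + offset)
  atoms <- rbind(m1$atoms, m2$atoms)
  atoms$id <- seq_len(nrow(atoms))
  system <- molecular_system(atoms)
  fr <- frame(rbind(m1$pos, m2$pos), cell)
  list(system = system, frame = fr)
}

# System whose bead midpoints reproduce a prescribed bead chain exactly:
# per planted bead, two leucine CA atoms at bead +/- d (d perpendicular to
# the local tangent). Returns one monomer pair per 8 beads.
make_system_from_beads <- function(bead_mat, cell = c(50, 50, 50)) {
  n_dimers <- nrow(bead_mat) / 8
  stopifnot(n_dimers == round(n_dimers))
  lresid <- c(1, 5, 8, 12, 15, 19, 22, 26)
  atoms <- list(); pos <- list()
  for (d in seq_len(n_dimers)) {
    rows <- ((d - 1) * 8 + 1):(d * 8)
    beads <- bead_mat[rows, , drop = FALSE]
    tangent <- beads[2, ] - beads[1, ]
    perp <- c(-tangent[2], tangent[1], 0)
    if (sqrt(sum(perp^2)) < 1e-8) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2)) * 0.4
    for (m in 1:2) {
      sgn <- if (m == 1) 1 else -1
      atoms[[length(atoms) + 1]] <-
        data.frame(name = "CA", resid = lresid, resname = "LEU",
                   monomer = (d - 1) * 2 + m)
      pos[[length(pos) + 1]] <- sweep(beads, 2, sgn * perp, "+")
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$id <- seq_len(nrow(atoms))
  list(system = molecular_system(atoms),
       frame = frame(do.call(rbind, pos), cell))
}

# Rotation matrix about a random axis (for covariance tests)
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force minimum-image distance over all 27 periodic images
brute_min_image <- function(a, b, cell) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((b + c(i, j, k) * cell - a)^2))
    best <- min(best, d)
  }
  best
}
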