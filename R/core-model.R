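# Core data model: molecular systems, frames, frame streams, periodic geometry,
# and structure/trajectory I/O. Internal units follow GROMACS conventions:
# lengths in nm, times in ps, velocities in nm/ps. PDB input (Angstrom) is
# converted on read.

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, CL = 35.45, NA. = 22.99)

#' Construct a molecular system
#'
#' A `molecular_system` holds the topology-level information the analyses
#' need: atom identities, residue numbering (1-based within each peptide
#' monomer), and the grouping of atoms into monomers (single helices) and
#' dimers (coiled coils). Coordinates live in [frame()] objects, not here.
#'
#' @param atoms data.frame with columns `id` (integer, unique), `name`
#'   (atom name, e.g. `"CA"`), `resid` (1-based residue index within its
#'   monomer), `resname` (3-letter residue name), `monomer` (integer monomer
#'   id), and optionally `element` and `mass` (amu); missing elements/masses
#'   are inferred from the atom name.
#' @param dimer_map optional integer vector mapping monomer id -> dimer id.
#'   Defaults to consecutive pairing: monomers 1,2 -> dimer 1, 3,4 -> dimer 2,
#'   and so on.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, dimer_map = NULL) {
  stopifnot(is.data.frame(atoms))
  required <- c("id", "name", "resid", "resname", "monomer")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty system: no atoms")
  if (anyDuplicated(atoms$id)) {
    stop("duplicated atom ids: ", paste(unique(atoms$id[duplicated(atoms$id)])[1:3], collapse = ", "))
  }
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$mass)) {
    m <- ATOMIC_MASSES[atoms$element]
    m[is.na(m)] <- 0
    atoms$mass <- unname(m)
  }
  monomers <- sort(unique(atoms$monomer))
  if (is.null(dimer_map)) {
    # default: consecutive monomer pairing in order of appearance
    dimer_map <- stats::setNames(ceiling(seq_along(monomers) / 2), monomers)
  } else {
    if (is.null(names(dimer_map))) names(dimer_map) <- monomers
    if (!all(as.character(monomers) %in% names(dimer_map))) {
      stop("dimer_map does not cover every monomer")
    }
  }
  atoms$dimer <- unname(dimer_map[as.character(atoms$monomer)])
  structure(list(atoms = atoms,
                 monomers = monomers,
                 dimers = sort(unique(atoms$dimer))),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms, %d monomers, %d dimers\n",
              nrow(x$atoms), length(x$monomers), length(x$dimers)))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a [molecular_system()]
#' @return integer atom count
#' @export
n_atoms <- function(system) nrow(system$atoms)

guess_element <- function(name) {
  stripped <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
  substr(stripped, 1, 1)
}

#' Construct a single trajectory frame
#'
#' @param positions numeric matrix (n_atoms x 3), nm.
#' @param cell orthorhombic box lengths, numeric length 3, nm, all > 0.
#' @param time frame time in ps.
#' @param velocities optional numeric matrix (n_atoms x 3), nm/ps.
#' @return object of class `md_frame`
#' @export
frame <- function(positions, cell, time = 0, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!all(is.finite(positions))) stop("non-finite positions")
  cell <- as.numeric(cell)
  if (length(cell) != 3 || any(!is.finite(cell)) || any(cell <= 0)) {
    stop("cell must be three strictly positive box lengths (nm)")
  }
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions))) stop("velocity/position dimension mismatch")
  }
  structure(list(positions = positions, cell = cell, time = time,
                 velocities = velocities),
            class = "md_frame")
}

#' Construct a frame stream
#'
#' An ordered sequence of frames at a constant frame interval.
#'
#' @param frames list of [frame()] objects with strictly increasing times.
#' @return object of class `frame_stream` with element `dt` (ps).
#' @export
frame_stream <- function(frames) {
  if (length(frames) == 0) stop("empty frame stream")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts)) {
      stop("frame interval is not constant within the stream")
    }
    dt <- mean(dts)
  } else {
    dt <- NA_real_
  }
  structure(list(frames = frames, dt = dt), class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("frame_stream: %d frames, dt = %s ps\n", length(x$frames),
              format(x$dt)))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a [frame_stream()]
#' @export
n_frames <- function(stream) length(stream$frames)

#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Displacement from `a` to `b`, wrapped so every component lies in
#' `[-L/2, L/2)`. Its Euclidean norm is the minimum-image distance.
#'
#' @param a,b numeric vectors of length 3, or n x 3 matrices (nm).
#' @param cell box lengths, numeric length 3 (nm).
#' @return displacement(s), same shape as the inputs.
#' @export
minimum_image_displacement <- function(a, b, cell) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite coordinates")
  cell <- as.numeric(cell)
  if (any(cell <= 0)) stop("cell lengths must be positive")
  d <- b - a
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - cell[k] * floor(d[, k] / cell[k] + 0.5)
  } else {
    d <- d - cell * floor(d / cell + 0.5)
  }
  d
}

#' Minimum-image distance
#' @inheritParams minimum_image_displacement
#' @return numeric distance(s), nm
#' @export
minimum_image_distance <- function(a, b, cell) {
  d <- minimum_image_displacement(a, b, cell)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

# ---------------------------------------------------------------------------
# GRO reading/writing. The GRO fixed-column dialect is simple enough that the
# package parses it directly (no installed R package reads GROMACS text
# formats); multi-frame GRO files (concatenated blocks, as written by
# `gmx trjconv`) serve as the plain-text trajectory format.

parse_gro_block <- function(lines, offset = 0) {
  if (length(lines) < 3) stop("malformed GRO block near line ", offset + 1)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("GRO parse error at line ", offset + 2, ": bad atom count")
  if (natoms == 0) stop("empty GRO file: zero atoms (line ", offset + 2, ")")
  if (length(lines) < 3 + natoms) {
    stop("GRO parse error: truncated block starting at line ", offset + 1)
  }
  at <- lines[3:(2 + natoms)]
  resid_full <- suppressWarnings(as.integer(substr(at, 1, 5)))
  if (any(is.na(resid_full))) {
    bad <- which(is.na(resid_full))[1]
    stop("GRO parse error at line ", offset + 2 + bad, ": bad residue field")
  }
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  atomid <- suppressWarnings(as.integer(substr(at, 16, 20)))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  if (any(is.na(c(x, y, z)))) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("GRO parse error at line ", offset + 2 + bad, ": bad coordinates")
  }
  vel <- NULL
  if (nchar(at[1]) >= 68) {
    vx <- suppressWarnings(as.numeric(substr(at, 45, 52)))
    vy <- suppressWarnings(as.numeric(substr(at, 53, 60)))
    vz <- suppressWarnings(as.numeric(substr(at, 61, 68)))
    if (!any(is.na(c(vx, vy, vz)))) vel <- cbind(vx, vy, vz)
  }
  box_fields <- as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])
  if (length(box_fields) >= 9 && any(abs(box_fields[4:9]) > 1e-9)) {
    stop("triclinic cells are not supported; box line has non-zero off-diagonal elements")
  }
  cell <- box_fields[1:3]
  time <- NA_real_
  tm <- regmatches(lines[1], regexpr("t=\\s*-?[0-9.eE+-]+", lines[1]))
  if (length(tm) == 1) time <- as.numeric(sub("t=\\s*", "", tm))
  list(natoms = natoms, resid = resid_full, resname = resname, name = name,
       atomid = atomid, positions = cbind(x, y, z), velocities = vel,
       cell = cell, time = time, nlines = 3 + natoms)
}

# Monomer boundaries: a new monomer starts wherever the residue index
# decreases (each monomer is numbered 1..n internally).
infer_monomers <- function(resid) {
  cumsum(c(TRUE, diff(resid) < 0))
}

#' Read a structure file
#'
#' Reads a PDB or GRO structure into a [molecular_system()] plus its
#' coordinate [frame()]. Monomer grouping: GRO files restart residue
#' numbering at each monomer (the reader splits where the residue index
#' decreases); PDB files use the chain identifier. Dimer membership defaults
#' to consecutive monomer pairing and can be overridden with a mapping file.
#'
#' @param path file path.
#' @param format `"gro"` or `"pdb"`; default guessed from the extension.
#' @param dimer_map optional path to a whitespace-separated two-column file
#'   (monomer id, dimer id), or a named integer vector.
#' @return list with elements `system` ([molecular_system()]) and `frame`
#'   ([frame()]; `cell` is `NA`-free only for GRO input).
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"), dimer_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(dimer_map) && length(dimer_map) == 1) {
    dm <- utils::read.table(dimer_map, col.names = c("monomer", "dimer"))
    dimer_map <- stats::setNames(dm$dimer, dm$monomer)
  }
  if (format == "gro") {
    lines <- readLines(path)
    blk <- parse_gro_block(lines)
    monomer <- infer_monomers(blk$resid)
    atoms <- data.frame(id = seq_len(blk$natoms), name = blk$name,
                        resid = blk$resid, resname = blk$resname,
                        monomer = monomer, stringsAsFactors = FALSE)
    if (anyDuplicated(blk$atomid) && length(unique(blk$atomid)) > 1 &&
        !all(blk$atomid == blk$atomid[1])) {
      # GRO atom numbers wrap at 100000; only flag duplicates in small files
      if (blk$natoms < 99999 && anyDuplicated(blk$atomid)) {
        stop("duplicated atom ids in ", path)
      }
    }
    system <- molecular_system(atoms, dimer_map = dimer_map)
    fr <- frame(blk$positions, blk$cell,
                time = ifelse(is.na(blk$time), 0, blk$time),
                velocities = blk$velocities)
    list(system = system, frame = fr)
  } else {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("PDB input requires the bio3d package")
    }
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    if (nrow(a) == 0) stop("empty PDB file: zero atoms")
    chain <- a$chain
    chain[is.na(chain) | chain == ""] <- "A"
    monomer <- as.integer(factor(chain, levels = unique(chain)))
    # renumber residues 1-based within each monomer
    resid <- a$resno
    for (m in unique(monomer)) {
      sel <- monomer == m
      resid[sel] <- resid[sel] - min(resid[sel]) + 1L
    }
    atoms <- data.frame(id = seq_len(nrow(a)), name = a$elety, resid = resid,
                        resname = a$resid, monomer = monomer,
                        stringsAsFactors = FALSE)
    system <- molecular_system(atoms, dimer_map = dimer_map)
    pos <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
    # PDB rarely carries a usable box here; use a generous bounding cell
    cell <- apply(pos, 2, function(v) diff(range(v))) + 2
    list(system = system, frame = frame(pos, cell))
  }
}

#' Read a multi-frame GRO trajectory
#'
#' @param path path to a concatenated-GRO trajectory file.
#' @param format only `"gro"` is supported for reading trajectories as text;
#'   `"dcd"` is delegated to `bio3d::read.dcd` when bio3d is installed.
#' @param cell for DCD input without box information, the box lengths (nm).
#' @return a [frame_stream()]
#' @export
read_trajectory <- function(path, format = c("gro", "dcd"), cell = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dcd") {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("DCD input requires the bio3d package")
    }
    xyz <- bio3d::read.dcd(path)
    if (is.null(cell)) stop("DCD input requires an explicit cell argument")
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10, cell, time = i - 1)
    })
    return(frame_stream(frames))
  }
  lines <- readLines(path)
  frames <- list()
  off <- 0
  i <- 1
  while (off < length(lines)) {
    blk <- parse_gro_block(lines[(off + 1):length(lines)], offset = off)
    tm <- if (is.na(blk$time)) length(frames) else blk$time
    frames[[length(frames) + 1]] <-
      frame(blk$positions, blk$cell, time = tm, velocities = blk$velocities)
    off <- off + blk$nlines
    i <- i + 1
  }
  frame_stream(frames)
}

format_gro_frame <- function(fr, system, title = "ccfibril") {
  a <- system$atoms
  n <- nrow(a)
  # GRO residue field: running residue number; restart numbering per monomer
  header <- sprintf("%s t= %.5f", title, fr$time)
  pos <- fr$positions
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  a$resid %% 100000, substr(a$resname, 1, 5),
                  substr(a$name, 1, 5), a$id %% 100000,
                  pos[, 1], pos[, 2], pos[, 3])
  if (!is.null(fr$velocities)) {
    body <- paste0(body, sprintf("%8.4f%8.4f%8.4f", fr$velocities[, 1],
                                 fr$velocities[, 2], fr$velocities[, 3]))
  }
  boxline <- sprintf("%10.5f%10.5f%10.5f", fr$cell[1], fr$cell[2], fr$cell[3])
  c(header, sprintf("%5d", n), body, boxline)
}

#' Write a structure or trajectory in GRO format
#'
#' Writes one block per frame (multi-frame GRO). Reading the file back with
#' [read_structure()] / [read_trajectory()] reproduces coordinates to the
#' format precision of 0.001 nm and the monomer/dimer grouping (given the
#' same dimer mapping).
#'
#' @param frames a [frame_stream()] or a single [frame()].
#' @param system the matching [molecular_system()].
#' @param path output path.
#' @param format only `"gro"` is supported.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, system, path, format = "gro") {
  if (!identical(format, "gro")) stop("unsupported output format: ", format)
  if (inherits(frames, "md_frame")) frames <- frame_stream(list(frames))
  if (!inherits(frames, "frame_stream")) stop("frames must be a frame_stream or md_frame")
  if (length(frames$frames) == 0) stop("empty frame stream")
  for (fr in frames$frames) {
    if (nrow(fr$positions) != n_atoms(system)) {
      stop("frame atom count does not match system")
    }
  }
  out <- unlist(lapply(frames$frames, format_gro_frame, system = system))
  writeLines(out, path)
  invisible(path)
}

#' Write a monomer-to-dimer mapping file
#'
#' @param system a [molecular_system()]
#' @param path output path (two whitespace-separated columns).
#' @export
write_dimer_map <- function(system, path) {
  a <- system$atoms
  map <- unique(a[, c("monomer", "dimer")])
  utils::write.table(map[order(map$monomer), ], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
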