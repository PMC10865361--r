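# Run configuration and versioned CSV output. A run config is a flat typed
# key-value document (`key = value` lines, `#` comments); unknown keys are
# rejected fail-fast. Every stage CSV carries a comment header naming the
# producing stage, its parameters and the package version, so re-running an
# identical config over identical inputs reproduces byte-identical bodies.

CONFIG_KEYS <- list(
  stage = "character", seed = "integer", out_dir = "character",
  trajectory = "character", structure = "character", dimer_map = "character",
  cutoff = "numeric", window_start = "numeric", window_end = "numeric",
  block = "numeric", gap_tolerance = "integer",
  min_points = "integer", max_cc = "numeric", source = "character",
  tau_max = "numeric", vacf_window = "numeric", bin_width = "numeric",
  r_max = "numeric", water_resname = "character",
  g0 = "numeric", temperature = "numeric", temperature_unit = "character",
  r = "numeric", h = "numeric", n_cc = "integer", v_box = "numeric",
  n_dimers = "integer", charge = "integer"
)

#' Read a flat run-configuration file
#'
#' @param path file of `key = value` lines; `#` starts a comment. Keys are
#'   validated against the known stage parameters and typed; unknown keys
#'   are an error.
#' @return named list of typed values, class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(vapply(kv, length, integer(1)) != 2)
  if (length(bad) > 0) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  validate_run_config(stats::setNames(as.list(vals), keys))
}

#' Validate and type a run configuration
#'
#' @param config named list (string values allowed; coerced to the declared
#'   type).
#' @return typed `run_config` list.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(CONFIG_KEYS))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(config))) {
    stop("duplicated config key(s): ",
         paste(unique(names(config)[duplicated(names(config))]), collapse = ", "))
  }
  out <- config
  for (k in names(config)) {
    v <- config[[k]]
    out[[k]] <- switch(CONFIG_KEYS[[k]],
                       character = as.character(v),
                       integer = {
                         iv <- suppressWarnings(as.integer(v))
                         if (is.na(iv)) stop("config key ", k, " must be an integer")
                         iv
                       },
                       numeric = {
                         nv <- suppressWarnings(as.numeric(v))
                         if (is.na(nv)) stop("config key ", k, " must be numeric")
                         nv
                       })
  }
  structure(out, class = "run_config")
}

#' Write a stage output CSV with a provenance header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param stage stage name.
#' @param params named list of the stage parameters (serialised into the
#'   header; the output directory is excluded so identical runs into
#'   different directories stay byte-identical).
#' @export
write_stage_csv <- function(df, path, stage, params = list()) {
  params <- params[setdiff(names(params), "out_dir")]
  pstr <- if (length(params) == 0) "" else
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = "|"),
                                character(1)), sep = "=", collapse = " ")
  hdr <- c(sprintf("# stage: %s", stage),
           sprintf("# params: %s", pstr),
           sprintf("# package: ccfibril %s",
                   as.character(utils::packageVersion("ccfibril"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage CSV, skipping the provenance header
#'
#' @param path a file written by [write_stage_csv()].
#' @return data.frame
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run a configured analysis stage
#'
#' Dispatches on `config$stage` and writes the stage's CSV outputs into
#' `config$out_dir` (along with a copy of the config). Stages: `gel_water`,
#' `gel_mesh`, `gel_ions` (no trajectory needed), `assembly` (chain table,
#' size histogram, lifetimes), `persistence` (correlation curves and fits).
#'
#' @param config a `run_config` (or named list; validated first).
#' @return named list of output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  stage <- config$stage
  if (is.null(stage)) stop("config is missing the stage key")
  if (!stage %in% c("gel_water", "gel_mesh", "gel_ions", "assembly", "persistence")) {
    stop("unknown stage: ", stage)
  }
  if (stage %in% c("assembly", "persistence") && is.null(config$trajectory)) {
    stop("stage ", stage, " requires a trajectory key")
  }
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_copy <- file.path(out_dir, "run_config.txt")
  writeLines(paste(names(config), vapply(config, format, character(1)), sep = " = "),
             cfg_copy)
  outputs <- list(config = cfg_copy)
  load_inputs <- function() {
    if (is.null(config$trajectory)) stop("stage ", stage, " requires a trajectory key")
    st <- read_structure(if (is.null(config$structure)) config$trajectory else config$structure,
                         dimer_map = config$dimer_map)
    stream <- read_trajectory(config$trajectory)
    list(system = st$system, stream = stream)
  }
  if (stage == "gel_water") {
    res <- bulk_water_fraction(config$r, config$h, config$n_cc, config$v_box)
    path <- file.path(out_dir, "gel_water.csv")
    write_stage_csv(data.frame(r_nm = config$r, h_nm = config$h,
                               n_cc = config$n_cc, v_box_nm3 = config$v_box,
                               v_cc_nm3 = res$v_cc, bulk_fraction = res$fraction),
                    path, "gel_water", config)
    outputs$gel_water <- path
  } else if (stage == "gel_mesh") {
    unit <- if (is.null(config$temperature_unit)) "K" else config$temperature_unit
    xi <- mesh_size(config$g0, config$temperature, unit)
    path <- file.path(out_dir, "gel_mesh.csv")
    write_stage_csv(data.frame(g0_pa = config$g0, temperature = config$temperature,
                               unit = unit, xi_nm = xi),
                    path, "gel_mesh", config)
    outputs$gel_mesh <- path
  } else if (stage == "gel_ions") {
    n <- counterion_count(config$n_dimers, config$charge)
    path <- file.path(out_dir, "gel_ions.csv")
    write_stage_csv(data.frame(n_dimers = config$n_dimers,
                               charge = config$charge, counterions = n),
                    path, "gel_ions", config)
    outputs$gel_ions <- path
  } else if (stage == "assembly") {
    inp <- load_inputs()
    crit <- salt_bridge_criteria(if (is.null(config$cutoff)) 0.35 else config$cutoff)
    tl <- assembly_timeline(inp$stream, inp$system, crit)
    chain_rows <- do.call(rbind, lapply(seq_along(tl), function(f) {
      fc <- tl[[f]]
      if (length(fc$chains) == 0) return(NULL)
      do.call(rbind, lapply(seq_along(fc$chains), function(ci) {
        ch <- fc$chains[[ci]]
        data.frame(frame = f, chain = ci, size = ch$length,
                   circular = ch$circular,
                   dimers = paste(ch$dimers, collapse = "|"))
      }))
    }))
    if (is.null(chain_rows)) chain_rows <- data.frame()
    p1 <- file.path(out_dir, "assembly_chains.csv")
    write_stage_csv(chain_rows, p1, "assembly", config)
    window <- if (!is.null(config$window_start)) c(config$window_start, config$window_end) else NULL
    hist <- oligomer_size_distribution(list(tl), window)
    p2 <- file.path(out_dir, "assembly_sizes.csv")
    write_stage_csv(hist, p2, "assembly", config)
    gap <- if (is.null(config$gap_tolerance)) 0 else config$gap_tolerance
    lf <- interaction_lifetimes(interaction_presence(tl),
                                dt = ifelse(is.na(inp$stream$dt), 1, inp$stream$dt),
                                gap_tolerance = gap)
    p3 <- file.path(out_dir, "assembly_lifetimes.csv")
    write_stage_csv(lf$lifetimes, p3, "assembly", config)
    outputs <- c(outputs, list(chains = p1, sizes = p2, lifetimes = p3))
  } else if (stage == "persistence") {
    inp <- load_inputs()
    src <- if (is.null(config$source)) "assembly" else config$source
    res <- persistence_from_trajectory(
      inp$stream, inp$system, source = src,
      min_points = if (is.null(config$min_points)) 2000 else config$min_points,
      max_cc = if (is.null(config$max_cc)) 7 else config$max_cc)
    rows <- do.call(rbind, lapply(names(res$estimates), function(cls) {
      e <- res$estimates[[cls]]
      data.frame(class = as.integer(cls), L_P_nm = e$L_P, stderr_nm = e$stderr,
                 divergent = e$divergent, n_samples = e$n_samples)
    }))
    p1 <- file.path(out_dir, "persistence.csv")
    write_stage_csv(rows, p1, "persistence", config)
    curves <- do.call(rbind, lapply(names(res$curves), function(cls) {
      cbind(class = as.integer(cls), as.data.frame(res$curves[[cls]]))
    }))
    p2 <- file.path(out_dir, "persistence_curves.csv")
    write_stage_csv(curves, p2, "persistence", config)
    outputs <- c(outputs, list(persistence = p1, curves = p2))
  } else {
    stop("unknown stage: ", stage)
  }
  outputs
}
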