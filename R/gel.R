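# Closed-form macroscopic hydrogel calculators: mesh size from the plateau
# modulus (one k_B T of elastic energy stored per mesh volume), the loss
# tangent, the cylindrical solvation-shell bulk-water fraction, and
# counterion bookkeeping.

KB_J_PER_K <- 1.380649e-23  # SI-exact Boltzmann constant

as_kelvin <- function(temperature, unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature + 273.15 else temperature
}

#' Hydrogel mesh size from the plateau modulus
#'
#' Assuming each mesh of size `xi` stores an elastic energy of `k_B T`,
#' `G_0 = k_B T / xi^3`, so `xi = (k_B T / G_0)^(1/3)`. Because no true
#' modulus plateau may exist, the caller picks the frequency at which `G_0`
#' is read off and the result is an upper estimate.
#'
#' @param G0 plateau storage modulus in Pa (> 0).
#' @param temperature temperature (> 0 in K).
#' @param unit `"K"` (default) or `"C"`.
#' @return mesh size in nm.
#' @export
mesh_size <- function(G0, temperature, unit = c("K", "C")) {
  TK <- as_kelvin(temperature, unit)
  if (any(G0 <= 0)) stop("G0 must be positive")
  if (any(TK <= 0)) stop("temperature must be positive (K)")
  (KB_J_PER_K * TK / G0)^(1 / 3) * 1e9
}

#' Loss tangent
#'
#' `tan(delta) = G'' / G'`: below 1 the elastic response dominates
#' (gel-like), above 1 the viscous response dominates. Vectorised over
#' frequency sweeps.
#'
#' @param Gp storage modulus G' in Pa (> 0).
#' @param Gpp loss modulus G'' in Pa (>= 0).
#' @return dimensionless ratio(s).
#' @export
loss_tangent <- function(Gp, Gpp) {
  if (any(Gp <= 0)) stop("storage modulus G' must be positive")
  if (any(Gpp < 0)) stop("loss modulus G'' must be non-negative")
  Gpp / Gp
}

#' Bulk-water volume fraction outside cylindrical solvation shells
#'
#' Each coiled-coil dimer together with its solvation shell is approximated
#' as a cylinder of volume `V_cc = pi r^2 h`; the bulk-water fraction of a
#' box holding `n_cc` dimers is `1 - n_cc V_cc / V_box`. Overlap between
#' cylinders is ignored, making the bound-water estimate an upper bound.
#'
#' @param r shell radius in nm.
#' @param h cylinder height (dimer length) in nm.
#' @param n_cc number of coiled-coil dimers in the box.
#' @param v_box box volume in nm^3.
#' @return list with `fraction` (bulk-water volume fraction in [0, 1]) and
#'   `v_cc` (single-cylinder volume, nm^3).
#' @export
bulk_water_fraction <- function(r, h, n_cc, v_box) {
  if (r <= 0 || h <= 0 || v_box <= 0) stop("r, h and v_box must be positive")
  if (n_cc < 0) stop("n_cc must be non-negative")
  v_cc <- pi * r^2 * h
  occupied <- n_cc * v_cc
  if (occupied > v_box) {
    stop("infeasible geometry: ", n_cc, " cylinders of ", signif(v_cc, 4),
         " nm^3 exceed the box volume ", v_box, " nm^3")
  }
  list(fraction = 1 - occupied / v_box, v_cc = v_cc)
}

#' Counterions needed to neutralise a box of charged dimers
#'
#' @param n_dimers number of coiled-coil dimers (>= 0).
#' @param charge_per_dimer integer net charge per dimer in units of e
#'   (default +8 for a dimer whose lysines and N-termini are protonated and
#'   glutamates and C-termini deprotonated).
#' @return number of monovalent counterions.
#' @export
counterion_count <- function(n_dimers, charge_per_dimer = 8) {
  if (any(n_dimers < 0)) stop("n_dimers must be non-negative")
  n_dimers * abs(charge_per_dimer)
}
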