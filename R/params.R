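#' Energy model and interaction-geometry parameters
#'
#' All tunable constants of the interface-descriptor engine in one place:
#' the implicit-solvation boundary parameters (solvent probe 1.4 A, per-element
#' solute radii, solvent/solute dielectrics 78/1), a generic Lennard-Jones
#' table, the Coulomb constant, the 10->12 A switched nonbonded cutoff, and
#' the geometric criteria plus per-interaction energy constants for the five
#' interface interaction detectors. Individual entries can be overridden via
#' `...`.
#'
#' @param ... named overrides of any default entry.
#' @return a list of class "energy_model_params".
#' @examples
#' p <- energy_model_params(hbond_dmax = 2.4)
#' p$probe_radius   # 1.4
#' @export
energy_model_params <- function(...) {
  p <- list(
    probe_radius       = 1.4,     # A, solvent probe
    radius_polar_h     = 0.32,    # A, polar hydrogens
    radius_apolar_h    = 1.017,   # A, other hydrogens
    element_radii      = c(C = 1.8, O = 1.344, N = 1.14, S = 2.0, F = 1.30),
    dielectric_solvent = 78,
    dielectric_solute  = 1,
    coulomb_constant   = 1389.35, # kJ A / mol per unit-charge pair
    # generic per-element LJ parameters (sigma A, epsilon kJ/mol),
    # Lorentz-Berthelot combining
    lj_sigma   = c(H = 2.00, C = 3.40, N = 3.25, O = 2.96, S = 3.56, F = 3.12),
    lj_epsilon = c(H = 0.0657, C = 0.4577, N = 0.7113, O = 0.8786,
                   S = 1.046, F = 0.255),
    cutoff       = 12,  # A, nonbonded cutoff
    switch_start = 10,  # A, smooth switch begins
    # interaction detector criteria + per-interaction energy constants (kJ/mol)
    hbond_dmax        = 2.5,  # A, H...acceptor
    hbond_angle_min   = 120,  # deg, D-H...A
    hbond_heavy_dmax  = 3.5,  # A, donor...acceptor fallback without hydrogens
    hbond_energy      = 8.0,
    hydrophobic_dmax  = 5.0,  # A, apolar C...apolar C
    hydrophobic_energy = 2.0,
    cation_pi_dmax    = 6.0,  # A, cation to ring centroid
    cation_pi_angle_max = 45, # deg, normal vs centroid->cation
    cation_pi_energy  = 8.0,
    pi_pi_stack_dmax  = 5.5,  # A, centroid-centroid, stacked
    pi_pi_stack_angle = 30,   # deg, inter-normal, stacked
    pi_pi_t_dmax      = 7.0,  # A, T-shaped
    pi_pi_t_angle     = c(60, 90),
    pi_pi_energy      = 6.0,
    ion_ion_dmax      = 6.0,  # A, opposite-charge group centers
    ion_ion_energy    = 12.0,
    # solvation surrogate coefficients
    surface_tension   = 0.0227,  # kJ/mol/A^2, hydrophobic (apolar SASA) term
    nonpolar_coef     = 0.010,   # kJ/mol/A^2, vdw-solvation (total SASA) term
    # packing/quality surrogate
    contact_cutoff    = 4.5,   # A, heavy-atom contact
    clash_cutoff      = 2.2,   # A, heavy-atom clash
    contact_energy    = -1.0,  # kJ/mol per heavy-atom contact
    mq_clash_weight   = 2.0,
    # SASA numerical resolution
    sasa_points       = 242,
    ring_planarity_tol = 0.3   # A, max out-of-plane deviation
  )
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("energy_model_params(): unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    p[names(ov)] <- ov
  }
  stopifnot(p$dielectric_solvent >= 1, p$dielectric_solute >= 1,
            all(p$element_radii > 0), p$probe_radius > 0)
  class(p) <- "energy_model_params"
  p
}

# Solute radius for one atom given its element and polarity class.
.atom_radius <- function(element, polarity_class, params) {
  ifelse(element == "H",
         ifelse(polarity_class == "polar_hydrogen",
                params$radius_polar_h, params$radius_apolar_h),
         unname(params$element_radii[element]))
}

# Smooth cubic switching function: 1 below switch_start, 0 beyond cutoff.
.switch_fn <- function(r, params) {
  s <- rep(1, length(r))
  off <- r >= params$cutoff
  mid <- r > params$switch_start & !off
  x <- (r[mid] - params$switch_start) / (params$cutoff - params$switch_start)
  s[mid] <- 1 - 3 * x^2 + 2 * x^3
  s[off] <- 0
  s
}
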