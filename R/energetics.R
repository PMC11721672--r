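# Nonbonded energetics: switched Coulomb + Lennard-Jones cross terms,
# Shrake-Rupley solvent-accessible surface area, and the implicit-solvation
# surrogate (generalized-Born polar term with the documented solute radii and
# dielectrics, SASA-proportional nonpolar and hydrophobic terms).

#' Cross-set electrostatic and van der Waals energies
#'
#' Coulomb sum (solute dielectric, no solvent screening) and 6-12
#' Lennard-Jones sum over all cross-set atom pairs, with a smooth switch from
#' `switch_start` to `cutoff` so well-separated sets contribute exactly zero.
#'
#' @param atoms_a,atoms_b atom data.frames (columns x, y, z, charge, element).
#' @param params [energy_model_params()].
#' @return named numeric: `elec` and `vdw`, kJ/mol.
#' @export
pairwise_potential <- function(atoms_a, atoms_b, params = energy_model_params()) {
  if (!nrow(atoms_a) || !nrow(atoms_b)) return(c(elec = 0, vdw = 0))
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.1))
    stop("pairwise_potential(): overlapping atoms (r < 0.1 A), clash guard",
         call. = FALSE)
  s <- .switch_fn(r, params); dim(s) <- dim(r)
  q <- outer(atoms_a$charge, atoms_b$charge)
  elec <- sum(params$coulomb_constant * q / r / params$dielectric_solute * s)
  sig <- (params$lj_sigma[atoms_a$element] %o% rep(1, nrow(atoms_b)) +
          rep(1, nrow(atoms_a)) %o% params$lj_sigma[atoms_b$element]) / 2
  eps <- sqrt(params$lj_epsilon[atoms_a$element] %o%
              params$lj_epsilon[atoms_b$element])
  sr6 <- (sig / r)^6
  vdw <- sum(4 * eps * (sr6^2 - sr6) * s)
  c(elec = elec, vdw = vdw)
}

# Deterministic unit-sphere point set (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotate coordinates into their principal-axis frame so the fixed SASA point
# set is carried along with the molecule: rigid motions of the input then
# leave the quadrature, and hence the computed areas, unchanged. Axis signs
# are fixed by the third coordinate moment (order-invariant); the third axis
# is the right-handed cross product. For coordinate sets that are exactly
# mirror-symmetric the sign is immaterial for area totals.
.canonical_frame <- function(xyz) {
  if (nrow(xyz) < 2) return(xyz)
  Xc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  V <- ev$vectors
  for (j in 1:2) {
    pr <- drop(Xc %*% V[, j])
    s <- sum(pr^3)
    if (abs(s) < 1e-9) s <- sum(pr^5)
    if (s < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  Xc %*% V
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley numerical SASA with a deterministic spiral point set on each
#' atom's solvent-extended sphere (radius + probe). An isolated atom of
#' radius r therefore has SASA 4*pi*(r + probe)^2 up to quadrature.
#'
#' @param atoms atom data.frame with columns x, y, z, radius.
#' @param params [energy_model_params()]; `sasa_points` sets the resolution.
#' @param canonicalize rotate the coordinates into their principal-axis
#'   frame first, making the result invariant under rigid motion of the
#'   input; disable when several atom subsets must share one frame.
#' @return numeric vector of per-atom areas in A^2.
#' @export
sasa <- function(atoms, params = energy_model_params(), canonicalize = TRUE) {
  n <- nrow(atoms)
  if (!n) return(numeric())
  pts <- .sphere_points(params$sasa_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (canonicalize) xyz <- .canonical_frame(xyz)
  rext <- atoms$radius + params$probe_radius
  out <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose extended spheres can occlude atom i
    dd <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dd < rext[i] + rext & seq_len(n) != i)
    surf <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(surf))
    for (j in nb) {
      acc[acc] <- colSums((t(surf[acc, , drop = FALSE]) - xyz[j, ])^2) >
        rext[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rext[i]^2 * sum(acc) / params$sasa_points
  }
  out
}

#' Implicit-solvation terms for a set of atoms
#'
#' Polar term: generalized-Born screening between the solute dielectric and
#' the solvent dielectric, using each atom's solute radius as its effective
#' Born radius, so an isolated ion reproduces the Born formula exactly. The
#' cross-atom GB terms carry the same distance switch as the nonbonded
#' potential, which makes the binding solvation of a well-separated complex
#' exactly zero. Nonpolar term: `nonpolar_coef` times total SASA. Hydrophobic
#' term: `surface_tension` times apolar (apolar carbon/hydrogen) SASA.
#'
#' @param atoms atom data.frame (x, y, z, charge, radius, polarity_class).
#' @param params [energy_model_params()].
#' @param areas optional precomputed per-atom SASA (saves recomputation).
#' @param canonicalize passed to [sasa()].
#' @return named numeric: `polar`, `nonpolar`, `hydrophobic`, kJ/mol.
#' @export
solvation_terms <- function(atoms, params = energy_model_params(),
                            areas = NULL, canonicalize = TRUE) {
  n <- nrow(atoms)
  if (!n) return(c(polar = 0, nonpolar = 0, hydrophobic = 0))
  tau <- 1 / params$dielectric_solute - 1 / params$dielectric_solvent
  k <- params$coulomb_constant
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  q <- atoms$charge; R <- atoms$radius
  # self terms (Born limit) + switched cross terms
  polar <- -0.5 * k * tau * sum(q^2 / R)
  if (n > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
    RR <- outer(R, R)
    fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
    s <- .switch_fn(sqrt(d2), params); dim(s) <- dim(d2)
    qq <- outer(q, q)
    off <- upper.tri(d2)
    polar <- polar - 0.5 * k * tau * 2 * sum((qq / fgb * s)[off])
  }
  if (is.null(areas)) areas <- sasa(atoms, params, canonicalize)
  apolar <- atoms$polarity_class %in% c("apolar_carbon", "apolar_hydrogen")
  c(polar = polar,
    nonpolar = params$nonpolar_coef * sum(areas),
    hydrophobic = params$surface_tension * sum(areas[apolar]))
}

#' Binding-energy decomposition of a receptor-peptide complex
#'
#' Each term is computed for the complex and for the receptor and peptide
#' alone (coordinates frozen) and differenced. `BEelec`/`BEvdw` are the
#' switched cross-interface Coulomb and Lennard-Jones sums,
#' `BEpot = BEelec + BEvdw`; `BSelec`/`BSvdw`/`BShydro` are the binding
#' changes of the three solvation terms, `BS = BSelec + BSvdw`; and the
#' overall binding score is `BE = BEpot - BS - BShydro`. The identities hold
#' exactly by construction.
#'
#' @param cx a "complex_structure".
#' @param params [energy_model_params()].
#' @return named numeric vector: BEpot, BEelec, BEvdw, BS, BSelec, BSvdw,
#'   BShydro, BE (kJ/mol).
#' @export
binding_terms <- function(cx, params = energy_model_params()) {
  pep <- .pep_mask(cx)
  # one canonical frame for the complex and both parts: rigid-motion
  # invariance AND exact cancellation for separated halves
  at <- cx$atoms
  xyz <- .canonical_frame(as.matrix(at[, c("x", "y", "z")]))
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  rec_at <- at[!pep, , drop = FALSE]
  pep_at <- at[pep, , drop = FALSE]
  pe <- pairwise_potential(rec_at, pep_at, params)
  sc <- solvation_terms(at, params, canonicalize = FALSE)
  sr <- solvation_terms(rec_at, params, canonicalize = FALSE)
  sp <- solvation_terms(pep_at, params, canonicalize = FALSE)
  ds <- sc - sr - sp
  bepot <- unname(pe["elec"] + pe["vdw"])
  bs <- unname(ds["polar"] + ds["nonpolar"])
  c(BEpot = bepot, BEelec = unname(pe["elec"]), BEvdw = unname(pe["vdw"]),
    BS = bs, BSelec = unname(ds["polar"]), BSvdw = unname(ds["nonpolar"]),
    BShydro = unname(ds["hydrophobic"]),
    BE = bepot - bs - unname(ds["hydrophobic"]))
}
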