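# Geometric detection of the five cross-interface interaction types and the
# derived count/energy summary descriptors.

.interaction_row <- function(kind, rec, pep, distance, angle, energy) {
  data.frame(kind = kind,
             receptor_atoms = paste(rec, collapse = "+"),
             peptide_atoms = paste(pep, collapse = "+"),
             distance = distance, angle = angle, energy = energy,
             stringsAsFactors = FALSE)
}

.empty_interactions <- function() {
  data.frame(kind = character(), receptor_atoms = character(),
             peptide_atoms = character(), distance = numeric(),
             angle = numeric(), energy = numeric(), stringsAsFactors = FALSE)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

.dist_vec <- function(a, b) sqrt(sum((a - b)^2))

# angle (deg) between two vectors, folded to [0, 90] when fold = TRUE
.vec_angle <- function(u, v, fold = FALSE) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  a <- acos(pmin(1, pmax(-1, cs))) * 180 / pi
  if (fold) min(a, 180 - a) else a
}

#' Detect cross-interface hydrogen bonds
#'
#' With explicit polar hydrogens: an H-bond requires d(H...acceptor) <=
#' `hbond_dmax` and a donor-H...acceptor angle >= `hbond_angle_min`. Without
#' any polar hydrogens in the structure, the heavy-atom fallback criterion
#' d(donor...acceptor) <= `hbond_heavy_dmax` applies. The per-bond energy is
#' `-hbond_energy` scaled by distance and angle ramps in [0, 1], capped at 0.
#'
#' @param cx a "complex_structure".
#' @param params [energy_model_params()].
#' @return data.frame of interactions (possibly zero rows).
#' @export
detect_hydrogen_bonds <- function(cx, params = energy_model_params()) {
  at <- cx$atoms; pep <- .pep_mask(cx)
  out <- list()
  polar_h <- which(at$polarity_class == "polar_hydrogen")
  use_h <- length(polar_h) > 0
  if (use_h) {
    # attach each polar H to its nearest donor heavy atom in the same residue
    for (h in polar_h) {
      same_res <- which(at$chain_id == at$chain_id[h] &
                        at$residue_number == at$residue_number[h] &
                        at$is_donor)
      if (!length(same_res)) next
      dd <- sqrt((at$x[same_res] - at$x[h])^2 + (at$y[same_res] - at$y[h])^2 +
                 (at$z[same_res] - at$z[h])^2)
      if (min(dd) > 1.3) next
      d_at <- same_res[which.min(dd)]
      acc <- which(at$is_acceptor & (pep != pep[h]))
      for (a in acc) {
        ha <- .dist_vec(c(at$x[h], at$y[h], at$z[h]),
                        c(at$x[a], at$y[a], at$z[a]))
        if (ha > params$hbond_dmax) next
        ang <- .vec_angle(c(at$x[d_at] - at$x[h], at$y[d_at] - at$y[h],
                            at$z[d_at] - at$z[h]),
                          c(at$x[a] - at$x[h], at$y[a] - at$y[h],
                            at$z[a] - at$z[h]))
        if (ang < params$hbond_angle_min) next
        fd <- .clamp01((params$hbond_dmax - ha) / (params$hbond_dmax - 2.0))
        fa <- .clamp01((ang - params$hbond_angle_min) /
                       (180 - params$hbond_angle_min))
        e <- min(0, -params$hbond_energy * fd * fa)
        rec_side <- if (pep[h]) a else c(d_at, h)
        pep_side <- if (pep[h]) c(d_at, h) else a
        out[[length(out) + 1]] <- .interaction_row(
          "hbond", at$serial[rec_side], at$serial[pep_side], ha, ang, e)
      }
    }
  } else {
    don <- which(at$is_donor)
    for (d_at in don) {
      acc <- which(at$is_acceptor & (pep != pep[d_at]))
      for (a in acc) {
        da <- .dist_vec(c(at$x[d_at], at$y[d_at], at$z[d_at]),
                        c(at$x[a], at$y[a], at$z[a]))
        if (da > params$hbond_heavy_dmax) next
        fd <- .clamp01((params$hbond_heavy_dmax - da) /
                       (params$hbond_heavy_dmax - 2.8))
        e <- min(0, -params$hbond_energy * fd)
        rec_side <- if (pep[d_at]) a else d_at
        pep_side <- if (pep[d_at]) d_at else a
        out[[length(out) + 1]] <- .interaction_row(
          "hbond", at$serial[rec_side], at$serial[pep_side], da, NA_real_, e)
      }
    }
  }
  if (!length(out)) return(.empty_interactions())
  do.call(rbind, out)
}

#' Detect cross-interface hydrophobic contacts
#'
#' Apolar (non-aromatic) carbon pairs across the interface within
#' `hydrophobic_dmax`; aromatic-ring carbons are excluded so that stacked
#' rings are classified as pi-pi interactions, not hydrophobic ones.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame of interactions.
#' @export
detect_hydrophobic_contacts <- function(cx, params = energy_model_params()) {
  at <- cx$atoms; pep <- .pep_mask(cx)
  apol <- at$polarity_class == "apolar_carbon" & !at$is_aromatic
  ri <- which(apol & !pep); pi <- which(apol & pep)
  out <- list()
  for (i in ri) for (j in pi) {
    d <- .dist_vec(c(at$x[i], at$y[i], at$z[i]), c(at$x[j], at$y[j], at$z[j]))
    if (d > params$hydrophobic_dmax) next
    f <- .clamp01((params$hydrophobic_dmax - d) / (params$hydrophobic_dmax - 4.0))
    out[[length(out) + 1]] <- .interaction_row(
      "hydrophobic", at$serial[i], at$serial[j], d, NA_real_,
      min(0, -params$hydrophobic_energy * f))
  }
  if (!length(out)) return(.empty_interactions())
  do.call(rbind, out)
}

#' Detect cross-interface cation-pi interactions
#'
#' A cation-group center within `cation_pi_dmax` of an aromatic-ring centroid
#' on the opposite side of the interface, with the centroid-to-cation vector
#' within `cation_pi_angle_max` of the ring normal.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame of interactions.
#' @export
detect_cation_pi <- function(cx, params = energy_model_params()) {
  at <- cx$atoms
  out <- list()
  for (cc in cx$charge_centers) {
    if (cc$sign <= 0) next
    cat_pep <- cc$chain_id == cx$peptide_chain
    for (rg in cx$rings) {
      ring_pep <- rg$chain_id == cx$peptide_chain
      if (cat_pep == ring_pep) next
      d <- .dist_vec(cc$center, rg$centroid)
      if (d > params$cation_pi_dmax) next
      ang <- .vec_angle(rg$normal, cc$center - rg$centroid, fold = TRUE)
      if (ang > params$cation_pi_angle_max) next
      fd <- .clamp01((params$cation_pi_dmax - d) / (params$cation_pi_dmax - 4.5))
      fa <- .clamp01((params$cation_pi_angle_max - ang) / params$cation_pi_angle_max)
      rec <- if (cat_pep) at$serial[rg$atom_idx] else at$serial[cc$atom_idx]
      pp  <- if (cat_pep) at$serial[cc$atom_idx] else at$serial[rg$atom_idx]
      out[[length(out) + 1]] <- .interaction_row(
        "cation_pi", rec, pp, d, ang, min(0, -params$cation_pi_energy * fd * fa))
    }
  }
  if (!length(out)) return(.empty_interactions())
  do.call(rbind, out)
}

#' Detect cross-interface pi-pi interactions
#'
#' Ring pairs across the interface, either stacked (centroid distance <=
#' `pi_pi_stack_dmax`, inter-normal angle <= `pi_pi_stack_angle`) or T-shaped
#' (distance <= `pi_pi_t_dmax`, angle within `pi_pi_t_angle`).
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame of interactions.
#' @export
detect_pi_pi <- function(cx, params = energy_model_params()) {
  at <- cx$atoms
  out <- list()
  for (r1 in cx$rings) {
    if (r1$chain_id == cx$peptide_chain) next
    for (r2 in cx$rings) {
      if (r2$chain_id != cx$peptide_chain) next
      d <- .dist_vec(r1$centroid, r2$centroid)
      ang <- .vec_angle(r1$normal, r2$normal, fold = TRUE)
      stacked <- d <= params$pi_pi_stack_dmax && ang <= params$pi_pi_stack_angle
      tshape <- d <= params$pi_pi_t_dmax &&
        ang >= params$pi_pi_t_angle[1] && ang <= params$pi_pi_t_angle[2]
      if (!stacked && !tshape) next
      f <- if (stacked)
        .clamp01((params$pi_pi_stack_dmax - d) / (params$pi_pi_stack_dmax - 3.5))
      else
        .clamp01((params$pi_pi_t_dmax - d) / (params$pi_pi_t_dmax - 5.0))
      out[[length(out) + 1]] <- .interaction_row(
        "pi_pi", at$serial[r1$atom_idx], at$serial[r2$atom_idx], d, ang,
        min(0, -params$pi_pi_energy * f))
    }
  }
  if (!length(out)) return(.empty_interactions())
  do.call(rbind, out)
}

#' Detect cross-interface ionic (salt-bridge) interactions
#'
#' Opposite-sign charged-group centers across the interface within
#' `ion_ion_dmax`; like-sign pairs are never counted.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame of interactions.
#' @export
detect_ion_ion <- function(cx, params = energy_model_params()) {
  at <- cx$atoms
  out <- list()
  for (c1 in cx$charge_centers) {
    if (c1$chain_id == cx$peptide_chain) next
    for (c2 in cx$charge_centers) {
      if (c2$chain_id != cx$peptide_chain) next
      if (c1$sign * c2$sign >= 0) next
      d <- .dist_vec(c1$center, c2$center)
      if (d > params$ion_ion_dmax) next
      f <- .clamp01((params$ion_ion_dmax - d) / (params$ion_ion_dmax - 3.0))
      out[[length(out) + 1]] <- .interaction_row(
        "ion_ion", at$serial[c1$atom_idx], at$serial[c2$atom_idx], d,
        NA_real_, min(0, -params$ion_ion_energy * f))
    }
  }
  if (!length(out)) return(.empty_interactions())
  do.call(rbind, out)
}

#' Detect all five interface interaction types
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data.frame combining the output of the five detectors.
#' @export
detect_interactions <- function(cx, params = energy_model_params()) {
  rbind(detect_hydrogen_bonds(cx, params),
        detect_hydrophobic_contacts(cx, params),
        detect_cation_pi(cx, params),
        detect_pi_pi(cx, params),
        detect_ion_ion(cx, params))
}

#' Summarise interactions into the 12 interaction descriptors
#'
#' Per-kind counts and energy sums plus their totals: `InteractionCount` is
#' the exact sum of the five counts and `InteractionEnergy` the exact sum of
#' the five energies.
#'
#' @param interactions data.frame from [detect_interactions()].
#' @return named numeric vector of length 12.
#' @export
interaction_summaries <- function(interactions) {
  kinds <- c("hbond", "hydrophobic", "cation_pi", "pi_pi", "ion_ion")
  counts <- vapply(kinds, function(k) sum(interactions$kind == k), 0)
  energies <- vapply(kinds, function(k)
    sum(interactions$energy[interactions$kind == k]), 0)
  out <- c(counts, energies, sum(counts), sum(energies))
  names(out) <- c("HbondCount", "HydrophobicCount", "CationPiCount",
                  "PiPiCount", "IonIonCount",
                  "HbondEnergy", "HydrophobicEnergy", "CationPiEnergy",
                  "PiPiEnergy", "IonIonEnergy",
                  "InteractionCount", "InteractionEnergy")
  out
}
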