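# Interface interaction detectors against hand-placed geometries.

# minimal carbonyl (receptor) + amide N-H (peptide) at chosen H...O distance
# and D-H...A angle
hbond_geometry <- function(d_ho, angle_deg) {
  a <- angle_deg * pi / 180
  # H at origin, O along +x at d_ho, N at unit bond length so the
  # N-H...O angle equals angle_deg
  make_structure(list(
    list("C", "GLY", "R", 1, d_ho + 1.23, 0, 0, "C"),
    list("O", "GLY", "R", 1, d_ho, 0, 0, "O"),
    list("H", "ALA", "P", 1, 0, 0, 0, "H"),
    list("N", "ALA", "P", 1, cos(a), sin(a), 0, "N")))
}

test_that("hydrogen bonds require the distance and angle criteria", {
  ok <- detect_hydrogen_bonds(hbond_geometry(2.0, 180))
  expect_equal(nrow(ok), 1)
  expect_lt(ok$energy, 0)
  expect_equal(nrow(detect_hydrogen_bonds(hbond_geometry(3.5, 180))), 0)
  expect_equal(nrow(detect_hydrogen_bonds(hbond_geometry(2.0, 90))), 0)
})

test_that("heavy-atom fallback applies when no hydrogens are present", {
  no_h <- function(d_no) make_structure(list(
    list("C", "GLY", "R", 1, d_no + 1.23, 0, 0, "C"),
    list("O", "GLY", "R", 1, d_no, 0, 0, "O"),
    list("N", "ALA", "P", 1, 0, 0, 0, "N")))
  expect_equal(nrow(detect_hydrogen_bonds(no_h(3.0))), 1)
  expect_equal(nrow(detect_hydrogen_bonds(no_h(3.8))), 0)
})

test_that("hydrophobic contacts need apolar carbon pairs within range", {
  pair <- function(d, rec_atom = c("CB", "ALA", "C")) make_structure(list(
    list(rec_atom[1], rec_atom[2], "R", 1, 0, 0, 0, rec_atom[3]),
    list("CB", "ALA", "P", 1, d, 0, 0, "C")))
  expect_equal(nrow(detect_hydrophobic_contacts(pair(4.0))), 1)
  expect_equal(nrow(detect_hydrophobic_contacts(pair(6.0))), 0)
  # carbonyl oxygen is not apolar: no contact
  expect_equal(nrow(detect_hydrophobic_contacts(
    pair(4.0, c("O", "GLY", "O")))), 0)
})

test_that("cation-pi requires distance and alignment with the ring normal", {
  geom <- function(d, in_plane = FALSE) {
    xyz <- pepqsar:::.ring_coords(c(0, 0, 0))
    nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rows <- lapply(1:6, function(i)
      list(nms[i], "PHE", "R", 1, xyz[i, 1], xyz[i, 2], 0, "C"))
    pos <- if (in_plane) c(d, 0, 0) else c(0, 0, d)
    rows[[7]] <- list("NZ", "LYS", "P", 1, pos[1], pos[2], pos[3], "N")
    make_structure(rows)
  }
  expect_equal(nrow(detect_cation_pi(geom(4.5))), 1)
  expect_equal(nrow(detect_cation_pi(geom(10))), 0)
  expect_equal(nrow(detect_cation_pi(geom(4.5, in_plane = TRUE))), 0)
})

test_that("pi-pi detects stacked and T-shaped rings only in range", {
  two_rings <- function(d, perpendicular = FALSE) {
    xyz1 <- pepqsar:::.ring_coords(c(0, 0, 0))
    nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rows <- lapply(1:6, function(i)
      list(nms[i], "PHE", "R", 1, xyz1[i, 1], xyz1[i, 2], 0, "C"))
    for (i in 1:6) {
      if (perpendicular) {
        # ring in the xz-plane (normal along y), centered at (0, 0, d)
        rows[[6 + i]] <- list(nms[i], "PHE", "P", 1, xyz1[i, 1], 0,
                              d + xyz1[i, 2], "C")
      } else {
        rows[[6 + i]] <- list(nms[i], "PHE", "P", 1, xyz1[i, 1], xyz1[i, 2],
                              d, "C")
      }
    }
    make_structure(rows)
  }
  expect_equal(detect_pi_pi(two_rings(3.8))$kind, "pi_pi")
  expect_equal(nrow(detect_pi_pi(two_rings(5.0, perpendicular = TRUE))), 1)
  expect_equal(nrow(detect_pi_pi(two_rings(9.0))), 0)
})

test_that("ion pairs require opposite signs within range", {
  ions <- function(d, pep_kind = "cation") {
    rows <- list(
      list("OD1", "ASP", "R", 1, 0, 1.1, 0, "O"),
      list("OD2", "ASP", "R", 1, 0, -1.1, 0, "O"))
    if (pep_kind == "cation")
      rows[[3]] <- list("NZ", "LYS", "P", 1, d, 0, 0, "N")
    else {
      rows[[3]] <- list("OD1", "ASP", "P", 1, d, 1.1, 0, "O")
      rows[[4]] <- list("OD2", "ASP", "P", 1, d, -1.1, 0, "O")
    }
    make_structure(rows)
  }
  expect_equal(nrow(detect_ion_ion(ions(4.0))), 1)
  expect_equal(nrow(detect_ion_ion(ions(9.0))), 0)
  expect_equal(nrow(detect_ion_ion(ions(4.0, "anion"))), 0)  # like signs
})

test_that("interaction summaries are the exact per-kind sums", {
  fake <- data.frame(
    kind = c(rep("hbond", 2), "hydrophobic", "pi_pi", rep("ion_ion", 3)),
    receptor_atoms = "1", peptide_atoms = "2", distance = 3, angle = NA,
    energy = c(-4, -2, -1, -3, -5, -5, -2), stringsAsFactors = FALSE)
  s <- interaction_summaries(fake)
  expect_equal(unname(s["InteractionCount"]), 7)
  expect_equal(unname(s["HbondCount"]), 2)
  expect_equal(unname(s["InteractionEnergy"]), sum(fake$energy))
  z <- interaction_summaries(fake[0, ])
  expect_true(all(z == 0))
  one_each <- read_structure(gen_toy_complex(toy_complex_spec(
    c("hbond", "hydrophobic", "cation_pi", "pi_pi", "ion_ion"))), "P")
  s1 <- interaction_summaries(detect_interactions(one_each))
  expect_equal(unname(s1[paste0(c("Hbond", "Hydrophobic", "CationPi", "PiPi",
                                  "IonIon"), "Count")]), rep(1, 5))
  expect_equal(unname(s1["InteractionCount"]), 5)
})

test_that("detectors agree with an independent all-pairs oracle", {
  params <- energy_model_params()
  pdb <- gen_toy_complex(toy_complex_spec(
    c("hydrophobic", "ion_ion", "hydrophobic", "hbond", "pi_pi",
      "hydrophobic", "ion_ion"), decoys = 4))
  cx <- read_structure(pdb, "P")
  at <- cx$atoms
  pep <- at$chain_id == cx$peptide_chain
  d <- as.matrix(dist(at[, c("x", "y", "z")]))
  # oracle: raw double loop over the distance matrix
  apol <- at$polarity_class == "apolar_carbon" & !at$is_aromatic
  n_hp <- sum(outer(apol & !pep, apol & pep) & d <= params$hydrophobic_dmax)
  expect_equal(nrow(detect_hydrophobic_contacts(cx, params)), n_hp)
  # oracle for ion pairs over charge centers
  cc <- cx$charge_centers
  n_ii <- 0
  for (i in seq_along(cc)) for (j in seq_along(cc)) {
    if (cc[[i]]$chain_id != cx$peptide_chain &&
        cc[[j]]$chain_id == cx$peptide_chain &&
        cc[[i]]$sign * cc[[j]]$sign < 0 &&
        sqrt(sum((cc[[i]]$center - cc[[j]]$center)^2)) <= params$ion_ion_dmax)
      n_ii <- n_ii + 1
  }
  expect_equal(nrow(detect_ion_ion(cx, params)), n_ii)
  # oracle for H-bonds (H present: H-based criterion)
  hs <- which(at$polarity_class == "polar_hydrogen")
  n_hb <- 0
  for (h in hs) {
    dn <- which(at$is_donor & at$chain_id == at$chain_id[h] &
                at$residue_number == at$residue_number[h])
    dn <- dn[which.min(d[h, dn])]
    for (a in which(at$is_acceptor & (pep != pep[h]))) {
      if (d[h, a] > params$hbond_dmax) next
      u <- unlist(at[dn, c("x", "y", "z")]) - unlist(at[h, c("x", "y", "z")])
      v <- unlist(at[a, c("x", "y", "z")]) - unlist(at[h, c("x", "y", "z")])
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      if (ang >= params$hbond_angle_min) n_hb <- n_hb + 1
    }
  }
  expect_equal(nrow(detect_hydrogen_bonds(cx, params)), n_hb)
})
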