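# Seeded synthetic-data generators: descriptor tables with known linear
# ground truth, toy complexes with geometrically planted interactions, and
# Ala/Aib scan datasets with planted per-position effects.

#' Specification for a synthetic descriptor table
#'
#' Defaults mirror the study's statistical regime: 31 peptides, 26
#' descriptors with the canonical names, a sparse two-term linear signal on
#' the binding-energy descriptors, and Gaussian noise sized so the
#' population R2 is about 0.6.
#'
#' @param n rows (peptides).
#' @param p descriptors; 26 gives the canonical names, other values get
#'   `X1..Xp`.
#' @param true_terms named subset carrying signal.
#' @param true_weights per-term weights (response units per descriptor unit).
#' @param intercept response baseline (pEC50 log units).
#' @param noise_sd Gaussian noise standard deviation; the default
#'   `sqrt(2/3) * sqrt(2)` ~ 1.155 gives population R2 = 0.6 with two
#'   orthogonal unit-weight terms.
#' @param collinearity optional list of blocks, each
#'   `list(terms = c(...), rho = r)`, inducing pairwise correlation `r`
#'   within the block via a Cholesky mix.
#' @param seed integer seed (mandatory).
#' @return list of class "descriptor_sim_spec".
#' @export
descriptor_sim_spec <- function(n = 31, p = 26,
                                true_terms = c("BEpot", "BSvdw"),
                                true_weights = c(-1, 1),
                                intercept = 8,
                                noise_sd = sqrt(sum(true_weights^2) * 2 / 3),
                                collinearity = NULL, seed) {
  if (missing(seed)) stop("descriptor_sim_spec(): seed is required",
                          call. = FALSE)
  stopifnot(length(true_terms) == length(true_weights),
            length(true_terms) <= p, noise_sd >= 0)
  if (!is.null(collinearity))
    for (b in collinearity)
      if (abs(b$rho) >= 1)
        stop("collinearity entries must lie in (-1, 1)", call. = FALSE)
  structure(list(n = n, p = p, true_terms = true_terms,
                 true_weights = true_weights, intercept = intercept,
                 noise_sd = noise_sd, collinearity = collinearity,
                 seed = as.integer(seed)),
            class = "descriptor_sim_spec")
}

#' Generate a synthetic descriptor table
#'
#' Descriptors are drawn standard normal, then each collinearity block is
#' mixed to its target equicorrelation structure; the response is
#' `intercept + sum(weights * true_terms) + N(0, noise_sd)`. The same seed
#' reproduces the table bit for bit.
#'
#' @param spec a [descriptor_sim_spec()].
#' @return data.frame with columns `id`, `pec50` and the descriptor columns.
#' @export
gen_descriptor_table <- function(spec) {
  stopifnot(inherits(spec, "descriptor_sim_spec"))
  nm <- if (spec$p == 26) descriptor_names() else paste0("X", seq_len(spec$p))
  miss <- setdiff(spec$true_terms, nm)
  if (length(miss))
    stop("gen_descriptor_table(): true term(s) not among descriptors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  withr::with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p,
                dimnames = list(NULL, nm))
    for (b in spec$collinearity) {
      cols <- match(b$terms, nm)
      if (anyNA(cols))
        stop("gen_descriptor_table(): unknown block term(s)", call. = FALSE)
      m <- length(cols)
      R <- matrix(b$rho, m, m); diag(R) <- 1
      L <- tryCatch(chol(R), error = function(e)
        stop("gen_descriptor_table(): correlation block not positive definite",
             call. = FALSE))
      X[, cols] <- X[, cols] %*% L
    }
    y <- spec$intercept +
      drop(X[, spec$true_terms, drop = FALSE] %*% spec$true_weights) +
      stats::rnorm(spec$n, 0, spec$noise_sd)
    data.frame(id = sprintf("SYN-%03d", seq_len(spec$n)), pec50 = y, X,
               stringsAsFactors = FALSE)
  })
}

# ---- toy complexes ---------------------------------------------------------

#' Specification for a toy receptor-peptide complex
#'
#' Each planted interaction is realized as a minimal atom group placed in
#' its own spatial cluster (clusters are 25 A apart, beyond every detection
#' cutoff) at a geometry satisfying its detector criterion with at least a
#' 10 percent margin; decoy atoms are placed far from the peptide chain and
#' violate every criterion with a margin.
#'
#' @param interactions character vector (or list of `list(kind = ...)`) of
#'   planted interaction kinds among hbond, hydrophobic, cation_pi, pi_pi,
#'   ion_ion; kinds may repeat.
#' @param decoys number of decoy receptor carbon atoms.
#' @param receptor_chain,peptide_chain chain identifiers.
#' @return list of class "toy_complex_spec".
#' @export
toy_complex_spec <- function(interactions = character(), decoys = 0,
                             receptor_chain = "R", peptide_chain = "P") {
  kinds <- vapply(interactions, function(x)
    if (is.list(x)) x$kind else x, "")
  ok <- c("hbond", "hydrophobic", "cation_pi", "pi_pi", "ion_ion")
  if (length(kinds) && !all(kinds %in% ok))
    stop("toy_complex_spec(): unknown interaction kind(s): ",
         paste(setdiff(kinds, ok), collapse = ", "), call. = FALSE)
  structure(list(kinds = unname(kinds), decoys = decoys,
                 receptor_chain = receptor_chain,
                 peptide_chain = peptide_chain),
            class = "toy_complex_spec")
}

# hexagonal aromatic ring in the xy-plane (normal = z), C-C 1.39 A
.ring_coords <- function(center) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
        center[3])
}

#' Generate a toy receptor-peptide complex as PDB text
#'
#' @param spec a [toy_complex_spec()].
#' @return character vector of PDB lines, parseable by [read_structure()].
#' @export
gen_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  atoms <- list()
  serial <- 0L; rres <- 0L; pres <- 0L
  add <- function(name, res, chain, resno, x, y, z, element) {
    serial <<- serial + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = serial, name = name, residue_name = res, chain_id = chain,
      residue_number = resno, x = x, y = y, z = z, element = element,
      stringsAsFactors = FALSE)
  }
  add_ring <- function(res, chain, resno, center) {
    xyz <- .ring_coords(center)
    nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (i in 1:6) add(nms[i], res, chain, resno,
                       xyz[i, 1], xyz[i, 2], xyz[i, 3], "C")
  }
  R <- spec$receptor_chain; P <- spec$peptide_chain
  for (ci in seq_along(spec$kinds)) {
    ox <- 25 * (ci - 1)  # cluster offset, beyond all cutoffs
    kind <- spec$kinds[ci]
    rres <- rres + 1L; pres <- pres + 1L
    switch(kind,
      hbond = {
        # receptor carbonyl C=O, peptide backbone N-H pointing at O
        add("C", "GLY", R, rres, ox + 0.00, 0, 0, "C")
        add("O", "GLY", R, rres, ox + 1.23, 0, 0, "O")
        add("H", "ALA", P, pres, ox + 3.23, 0, 0, "H")  # d(H...O) = 2.0
        add("N", "ALA", P, pres, ox + 4.23, 0, 0, "N")  # angle 180
      },
      hydrophobic = {
        add("CB", "ALA", R, rres, ox, 0, 0, "C")
        add("CB", "ALA", P, pres, ox + 4.0, 0, 0, "C")
      },
      cation_pi = {
        add_ring("PHE", R, rres, c(ox, 0, 0))
        add("NZ", "LYS", P, pres, ox, 0, 4.5, "N")  # on the ring normal
      },
      pi_pi = {
        add_ring("PHE", R, rres, c(ox, 0, 0))
        add_ring("PHE", P, pres, c(ox, 0, 3.8))    # parallel stack
      },
      ion_ion = {
        add("OD1", "ASP", R, rres, ox, 1.1, 0, "O")
        add("OD2", "ASP", R, rres, ox, -1.1, 0, "O")
        add("NZ", "LYS", P, pres, ox + 4.0, 0, 0, "N")  # centers 4.0 A apart
      })
  }
  if (spec$decoys > 0) {
    for (d in seq_len(spec$decoys)) {
      rres <- rres + 1L
      add("CB", "ALA", R, rres, -30, 10 * d, 0, "C")
    }
  }
  if (!length(atoms))
    stop("gen_toy_complex(): empty specification", call. = FALSE)
  at <- do.call(rbind, atoms)
  if (spec$decoys > 0 && !any(at$chain_id == P)) {
    pres <- pres + 1L
    serial <- serial + 1L
    at <- rbind(at, data.frame(serial = serial, name = "CB",
                               residue_name = "ALA", chain_id = P,
                               residue_number = pres, x = -30, y = -15,
                               z = 0, element = "C", stringsAsFactors = FALSE))
  }
  d <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
  if (any(d[upper.tri(d)] < 0.8))
    stop("gen_toy_complex(): overlapping atom placements", call. = FALSE)
  write_structure(at)
}

# ---- scan datasets ---------------------------------------------------------

#' Specification for a synthetic Ala/Aib scan dataset
#'
#' @param position_effects_ala,position_effects_aib length-11 pEC50 deltas
#'   for the Ala and Aib substitution at each position.
#' @param methylation_constant planted backbone-methylation contribution
#'   common to all Aib records (0.97 matches the study scaffold).
#' @param parent_pec50 pEC50 of the unmethylated parent.
#' @param noise_sd assay noise, log10 units.
#' @param seed integer seed (mandatory when `noise_sd > 0`).
#' @return list of class "scan_sim_spec".
#' @export
scan_sim_spec <- function(position_effects_ala = rep(0, 11),
                          position_effects_aib = rep(0, 11),
                          methylation_constant = 0.97,
                          parent_pec50 = 9.92, noise_sd = 0, seed = 1L) {
  stopifnot(length(position_effects_ala) == 11,
            length(position_effects_aib) == 11, noise_sd >= 0)
  structure(list(position_effects_ala = position_effects_ala,
                 position_effects_aib = position_effects_aib,
                 methylation_constant = methylation_constant,
                 parent_pec50 = parent_pec50, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scan_sim_spec")
}

#' Generate a synthetic Ala/Aib scan dataset
#'
#' Produces parent, Ala-scan and Aib-scan records with
#' `pec50 = parent + position effect (+ methylation constant for Aib rows)
#' + noise`, and the pair table wiring each position's Aib/Ala couple plus
#' the constant-defining parent pair.
#'
#' @param spec a [scan_sim_spec()].
#' @return list with `records` (id, pec50, series, position) and `pairs`
#'   (position, aib_id, ala_id, role) ready for [build_methylation_table()].
#' @export
gen_scan_dataset <- function(spec) {
  stopifnot(inherits(spec, "scan_sim_spec"))
  withr::with_seed(spec$seed, {
    noise <- function() stats::rnorm(1, 0, spec$noise_sd)
    ids <- character(); pec <- numeric(); ser <- character(); pos <- integer()
    put <- function(id, p, s, k) {
      ids <<- c(ids, id); pec <<- c(pec, p); ser <<- c(ser, s)
      pos <<- c(pos, k)
    }
    put("SYN-ALA-P", spec$parent_pec50 + noise(), "parent", NA_integer_)
    put("SYN-AIB-P",
        spec$parent_pec50 + spec$methylation_constant + noise(),
        "parent", NA_integer_)
    for (k in 1:11) {
      put(sprintf("SYN-ALA-%02d", k),
          spec$parent_pec50 + spec$position_effects_ala[k] + noise(),
          "ala_scan", k)
      put(sprintf("SYN-AIB-%02d", k),
          spec$parent_pec50 + spec$position_effects_aib[k] +
            spec$methylation_constant + noise(),
          "aib_scan", k)
    }
  })
  records <- data.frame(id = ids, pec50 = pec, series = ser, position = pos,
                        stringsAsFactors = FALSE)
  pairs <- rbind(
    data.frame(position = 6L, aib_id = "SYN-AIB-P", ala_id = "SYN-ALA-P",
               role = "parent", stringsAsFactors = FALSE),
    data.frame(position = 1:11, aib_id = sprintf("SYN-AIB-%02d", 1:11),
               ala_id = sprintf("SYN-ALA-%02d", 1:11), role = "scan",
               stringsAsFactors = FALSE))
  list(records = records, pairs = pairs)
}
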