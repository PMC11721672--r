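# PDB-format reading/writing and complex assembly: atom classification,
# aromatic-ring and charged-group enumeration.

.resolve_pdb_lines <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb))
    return(readLines(pdb, warn = FALSE))
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

.element_from_name <- function(name) {
  s <- sub("^[0-9]+", "", name)
  two <- toupper(substr(s, 1, 2))
  if (two %in% c("CL", "BR")) return(two)
  toupper(substr(s, 1, 1))
}

#' Read a receptor-peptide complex from PDB-format text
#'
#' Parses ATOM/HETATM records, assigns each atom its polarity class, partial
#' charge, donor/acceptor flags and solute radius from the residue template
#' registry (see [register_residue_template()] for extending it to further
#' noncanonical residues), and enumerates aromatic rings and charged-group
#' centers. The chain named `peptide_chain` is the ligand; all other chains
#' form the receptor.
#'
#' @param pdb a file path, a single string with embedded newlines, or a
#'   character vector of PDB lines.
#' @param peptide_chain single chain identifier of the peptide.
#' @param params an [energy_model_params()] object (radii, planarity
#'   tolerance).
#' @return an object of class "complex_structure": a list with `atoms` (one
#'   row per atom), `receptor_chains`, `peptide_chain`, `rings` (list of
#'   aromatic rings with member indices, centroid and unit normal) and
#'   `charge_centers` (list of ionized-group centers with sign).
#' @export
read_structure <- function(pdb, peptide_chain, params = energy_model_params()) {
  lines <- .resolve_pdb_lines(pdb)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel))
    stop("read_structure(): no ATOM/HETATM records found", call. = FALSE)
  ln <- which(sel); lines <- lines[sel]

  num <- function(chars, what) {
    v <- suppressWarnings(as.numeric(chars))
    if (anyNA(v))
      stop("read_structure(): unparseable ", what, " at line ",
           ln[which(is.na(v))[1]], call. = FALSE)
    v
  }
  atoms <- data.frame(
    serial  = as.integer(num(substr(lines, 7, 11), "serial")),
    name    = trimws(substr(lines, 13, 16)),
    residue_name   = toupper(trimws(substr(lines, 18, 20))),
    chain_id       = trimws(substr(lines, 22, 22)),
    residue_number = as.integer(num(substr(lines, 23, 26), "residue number")),
    x = num(substr(lines, 31, 38), "x coordinate"),
    y = num(substr(lines, 39, 46), "y coordinate"),
    z = num(substr(lines, 47, 54), "z coordinate"),
    element = toupper(trimws(substr(lines, 77, 78))),
    stringsAsFactors = FALSE)
  blank <- atoms$element == ""
  if (any(blank))
    atoms$element[blank] <- vapply(atoms$name[blank], .element_from_name, "")
  supported <- c("H", "C", "N", "O", "S", "F")
  if (!all(atoms$element %in% supported))
    stop("read_structure(): unsupported element(s): ",
         paste(setdiff(unique(atoms$element), supported), collapse = ", "),
         call. = FALSE)

  as_structure(atoms, peptide_chain, params)
}

#' Build a complex structure from an atom table
#'
#' The assembly step behind [read_structure()]: takes parsed atom records
#' (columns serial, name, residue_name, chain_id, residue_number, x, y, z,
#' element) and performs classification, ring and charged-group enumeration.
#' Useful for programmatic structure construction without a PDB round-trip.
#'
#' @param atoms atom data.frame.
#' @param peptide_chain single chain identifier of the peptide.
#' @param params an [energy_model_params()] object.
#' @return a "complex_structure" object.
#' @export
as_structure <- function(atoms, peptide_chain,
                         params = energy_model_params()) {
  chains <- unique(atoms$chain_id)
  if (!(peptide_chain %in% chains))
    stop("read_structure(): peptide chain '", peptide_chain,
         "' not present (chains: ", paste(chains, collapse = ", "), ")",
         call. = FALSE)
  if (length(chains) < 2)
    stop("read_structure(): need at least two chains (receptor + peptide), ",
         "found only '", chains, "'", call. = FALSE)

  res_key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name)
  unknown <- unique(atoms$residue_name[
    vapply(atoms$residue_name, function(r) is.null(.get_template(r)), TRUE)])
  if (length(unknown))
    stop("read_structure(): no template for residue(s): ",
         paste(unknown, collapse = ", "),
         "; add one with register_residue_template()", call. = FALSE)

  atoms$polarity_class <- NA_character_
  atoms$charge <- NA_real_
  atoms$is_donor <- atoms$is_acceptor <- atoms$is_aromatic <- FALSE
  rings <- list(); centers <- list()
  for (key in unique(res_key)) {
    idx <- which(res_key == key)
    tmpl <- .get_template(atoms$residue_name[idx[1]])
    cl <- .classify_residue_atoms(atoms[idx, , drop = FALSE], tmpl)
    atoms$polarity_class[idx] <- cl$polarity_class
    atoms$charge[idx] <- cl$charge
    atoms$is_donor[idx] <- cl$donor
    atoms$is_acceptor[idx] <- cl$acceptor
    atoms$is_aromatic[idx] <- cl$aromatic
    for (ring in tmpl$rings) {
      m <- idx[match(ring, atoms$name[idx])]
      if (anyNA(m)) next  # partial residue: ring not realized
      rings[[length(rings) + 1]] <-
        .make_ring(m, atoms, params$ring_planarity_tol, key)
    }
    if (!is.null(tmpl$cation)) {
      m <- idx[match(tmpl$cation, atoms$name[idx])]
      if (!anyNA(m))
        centers[[length(centers) + 1]] <-
          list(atom_idx = m, sign = +1,
               center = colMeans(atoms[m, c("x", "y", "z")]),
               chain_id = atoms$chain_id[m[1]])
    }
    if (!is.null(tmpl$anion)) {
      m <- idx[match(tmpl$anion, atoms$name[idx])]
      if (!anyNA(m))
        centers[[length(centers) + 1]] <-
          list(atom_idx = m, sign = -1,
               center = colMeans(atoms[m, c("x", "y", "z")]),
               chain_id = atoms$chain_id[m[1]])
    }
  }
  atoms$radius <- .atom_radius(atoms$element, atoms$polarity_class, params)

  structure(list(atoms = atoms,
                 receptor_chains = setdiff(chains, peptide_chain),
                 peptide_chain = peptide_chain,
                 rings = rings, charge_centers = centers),
            class = "complex_structure")
}

# Ring geometry: centroid + unit normal by principal-plane fit; enforce the
# coplanarity invariant.
.make_ring <- function(idx, atoms, tol, key) {
  xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  dev <- abs(sweep(xyz, 2, ctr) %*% normal)
  if (max(dev) > tol)
    stop("read_structure(): non-planar aromatic ring in residue ", key,
         " (max out-of-plane deviation ", signif(max(dev), 3), " A)",
         call. = FALSE)
  list(atom_idx = idx, centroid = ctr, normal = normal / sqrt(sum(normal^2)),
       chain_id = atoms$chain_id[idx[1]])
}

#' Write a complex back to PDB-format text
#'
#' @param x a "complex_structure" or an atom data.frame with the
#'   [read_structure()] columns.
#' @param path optional file to write; the lines are always returned.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_structure <- function(x, path = NULL) {
  atoms <- if (inherits(x, "complex_structure")) x$atoms else x
  name4 <- ifelse(nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
                  sprintf("%-4s", paste0(" ", atoms$name)))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, name4, substr(atoms$residue_name, 1, 3), atoms$chain_id,
    atoms$residue_number, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
  lines <- c(lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("Receptor-peptide complex:", nrow(x$atoms), "atoms\n")
  cat("  receptor chain(s):", paste(x$receptor_chains, collapse = ", "),
      " peptide chain:", x$peptide_chain, "\n")
  cat("  aromatic rings:", length(x$rings),
      " charged-group centers:", length(x$charge_centers), "\n")
  invisible(x)
}

# Logical index of peptide-side atoms.
.pep_mask <- function(cx) cx$atoms$chain_id == cx$peptide_chain
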