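# Residue atom templates: polar hydrogens, aromatic rings, charged groups and
# partial-charge assignment. Templates cover the 20 canonical residues plus
# the noncanonical residues of the 11-mer scaffold (AIB, BIP and fluorinated
# Phe as PHF); users can extend the registry with
# register_residue_template().

.template_env <- new.env(parent = emptyenv())

.phe_ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")

.default_templates <- function() {
  t <- list()
  plain <- c("ALA", "GLY", "VAL", "LEU", "ILE", "MET", "PRO", "AIB")
  for (r in plain) t[[r]] <- list()
  t$SER <- list(polar_h = "HG",  hydroxyl = c("OG", "HG"))
  t$THR <- list(polar_h = "HG1", hydroxyl = c("OG1", "HG1"))
  t$CYS <- list(polar_h = "HG")
  t$TYR <- list(polar_h = "HH", hydroxyl = c("OH", "HH"),
                rings = list(.phe_ring))
  t$PHE <- list(rings = list(.phe_ring))
  t$PHF <- list(rings = list(.phe_ring))   # ring-fluorinated Phe variants
  t$TRP <- list(polar_h = "HE1",
                rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))
  t$HIS <- list(polar_h = c("HD1", "HE2"),
                rings = list(c("CG", "ND1", "CD2", "CE1", "NE2")))
  t$BIP <- list(rings = list(.phe_ring,
                             c("C1P", "C2P", "C3P", "C4P", "C5P", "C6P")))
  t$LYS <- list(polar_h = c("HZ1", "HZ2", "HZ3"), cation = "NZ")
  t$ARG <- list(polar_h = c("HE", "HH11", "HH12", "HH21", "HH22"),
                cation = c("NE", "CZ", "NH1", "NH2"))
  t$ASP <- list(anion = c("OD1", "OD2"))
  t$GLU <- list(anion = c("OE1", "OE2"))
  t$ASN <- list(polar_h = c("HD21", "HD22"))
  t$GLN <- list(polar_h = c("HE21", "HE22"))
  t
}

.init_templates <- function() {
  if (!length(ls(.template_env)))
    for (nm in names(.default_templates()))
      assign(nm, .default_templates()[[nm]], envir = .template_env)
}

#' Register or override a residue template
#'
#' Extends the residue registry used by [read_structure()] to classify atoms.
#' A template is a list with optional entries `polar_h` (names of hydrogens
#' bonded to N/O), `rings` (list of aromatic-ring atom-name vectors),
#' `cation`/`anion` (atom names of the ionized group), `hydroxyl`
#' (c(O-name, H-name)) and `charges` (named partial-charge overrides).
#'
#' @param residue_name 3+ letter residue code as used in the PDB file.
#' @param template template list (see Details).
#' @export
register_residue_template <- function(residue_name, template) {
  .init_templates()
  stopifnot(is.character(residue_name), length(residue_name) == 1,
            is.list(template))
  assign(toupper(residue_name), template, envir = .template_env)
  invisible(template)
}

#' List registered residue templates
#' @return named list of templates.
#' @export
residue_templates <- function() {
  .init_templates()
  as.list(.template_env)
}

.get_template <- function(residue_name) {
  .init_templates()
  if (!exists(residue_name, envir = .template_env, inherits = FALSE))
    return(NULL)
  get(residue_name, envir = .template_env, inherits = FALSE)
}

# Polarity class, donor/acceptor flags and partial charge for the atoms of
# one residue. `atoms` is the atom data.frame subset for a single residue.
.classify_residue_atoms <- function(atoms, tmpl) {
  n <- nrow(atoms)
  cls <- character(n); chg <- numeric(n)
  donor <- logical(n); acceptor <- logical(n)
  nm <- atoms$name; el <- atoms$element
  backbone_polar_h <- c("H", "HN", "H1", "H2", "H3")
  polar_h <- c(backbone_polar_h, tmpl$polar_h)
  charged_atoms <- c(tmpl$cation, tmpl$anion)
  hydrox <- tmpl$hydroxyl

  for (i in seq_len(n)) {
    cls[i] <- switch(el[i],
      H = if (nm[i] %in% polar_h) "polar_hydrogen" else "apolar_hydrogen",
      C = if (nm[i] == "C") "polar_heavy" else "apolar_carbon",
      N = , O = , S = , F = "polar_heavy",
      stop("unsupported element: ", el[i], call. = FALSE))
    if (nm[i] %in% charged_atoms) cls[i] <- "charged"
    # donors: N-H and O-H heavy atoms; acceptors: all O plus His-type ring N
    if (el[i] == "N") donor[i] <- TRUE
    if (el[i] == "O") acceptor[i] <- TRUE
    if (!is.null(hydrox) && nm[i] == hydrox[1]) donor[i] <- TRUE
    # charges: unit formal charges on ionized groups, small polar offsets
    chg[i] <- 0
    if (nm[i] %in% tmpl$anion) chg[i] <- -0.5
    else if (!is.null(tmpl$cation)) {
      if (identical(tmpl$cation, "NZ") && nm[i] == "NZ") chg[i] <- 1
      else if (nm[i] %in% c("NH1", "NH2")) chg[i] <- 0.5
    }
    if (chg[i] == 0) {
      if (el[i] == "O") chg[i] <- -0.40
      else if (el[i] == "N") chg[i] <- -0.35
      else if (cls[i] == "polar_hydrogen") chg[i] <- 0.30
      else if (nm[i] == "C") chg[i] <- 0.45
      else if (nm[i] == "CA") chg[i] <- 0.05
    }
    if (!is.null(tmpl$charges) && nm[i] %in% names(tmpl$charges))
      chg[i] <- unname(tmpl$charges[nm[i]])
  }
  # His-type aromatic nitrogens also accept
  ring_atoms <- unlist(tmpl$rings)
  acceptor <- acceptor | (el == "N" & nm %in% ring_atoms)
  aromatic <- nm %in% ring_atoms & el != "H"
  list(polarity_class = cls, charge = chg, donor = donor,
       acceptor = acceptor, aromatic = aromatic)
}
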