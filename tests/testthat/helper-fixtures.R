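# Shared fixture builders: hand-placed atom sets, rigid-body transforms and
# a tiny worked regression table.

# Build a two-chain structure from explicit atom placements.
# rows: list of c(name, resname, chain, resno, x, y, z, element)
make_structure <- function(rows, peptide_chain = "P",
                           params = energy_model_params()) {
  at <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r[[1]], residue_name = r[[2]],
               chain_id = r[[3]], residue_number = as.integer(r[[4]]),
               x = as.numeric(r[[5]]), y = as.numeric(r[[6]]),
               z = as.numeric(r[[7]]), element = r[[8]],
               stringsAsFactors = FALSE)
  }))
  read_structure(write_structure(at), peptide_chain, params)
}

# Apply a rigid rotation + translation to the atoms of a PDB text and
# return the transformed structure.
rigid_transform <- function(pdb_lines, peptide_chain, angles = c(0.3, 0.7, 1.1),
                            shift = c(5, -3, 2)) {
  cx <- read_structure(pdb_lines, peptide_chain)
  at <- cx$atoms
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Rm <- rz(angles[1]) %*% rx(angles[2]) %*% rz(angles[3])
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(Rm)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  as_structure(at, peptide_chain)
}

# Fixed 5-row worked regression table (arbitrary but frozen values).
worked_table <- function() {
  data.frame(id = paste0("w", 1:5),
             pec50 = c(7.1, 8.3, 6.9, 9.0, 7.7),
             x1 = c(1.2, -0.4, 0.8, -1.5, 0.3),
             x2 = c(0.5, 1.1, -0.9, 0.2, -0.6))
}

# Normal-equation OLS oracle: solve (X'X) b = X'y directly.
ols_oracle <- function(table, terms, response = "pec50") {
  X <- cbind(1, as.matrix(table[terms]))
  y <- table[[response]]
  drop(solve(t(X) %*% X, t(X) %*% y))
}
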