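# Packing / model-quality surrogate scores and the assembled 26-descriptor
# vector.

# Heavy-atom contact statistics for a set of atoms. "Local" pairs are
# residue pairs with sequence separation 1..2 within a chain, plus any
# cross-chain pair (sequence separation undefined across chains).
.contact_stats <- function(atoms, params) {
  heavy <- which(atoms$element != "H")
  nh <- length(heavy)
  if (nh < 2)
    return(list(n_heavy = nh, contacts = 0, local = 0, clashes = 0))
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  same_res <- outer(atoms$residue_number[heavy], atoms$residue_number[heavy],
                    "==") &
              outer(atoms$chain_id[heavy], atoms$chain_id[heavy], "==")
  sep <- abs(outer(atoms$residue_number[heavy], atoms$residue_number[heavy],
                   "-"))
  cross <- outer(atoms$chain_id[heavy], atoms$chain_id[heavy], "!=")
  up <- upper.tri(d)
  pair_ok <- up & !same_res
  contact <- pair_ok & d <= params$contact_cutoff
  local <- contact & (cross | (!cross & sep >= 1 & sep <= 2))
  clash <- pair_ok & d < params$clash_cutoff
  list(n_heavy = nh, contacts = sum(contact), local = sum(local),
       clashes = sum(clash))
}

.pack_scores_one <- function(atoms, params) {
  cs <- .contact_stats(atoms, params)
  pack3d <- params$contact_energy * cs$contacts
  pack1d <- params$contact_energy * cs$local
  mq <- if (cs$n_heavy > 0)
    (cs$contacts - params$mq_clash_weight * cs$clashes) / cs$n_heavy
  else 0
  c(MQ = mq, Pack1D = pack1d, Pack3D = pack3d)
}

#' Packing and model-quality descriptors
#'
#' Surrogate packing scores built from heavy-atom contact counts: `Pack3D`
#' is the summed contact energy over all residue-distinct heavy-atom pairs
#' within `contact_cutoff` (more packing, more negative); `Pack1D` restricts
#' to sequence-local pairs (separation 1-2 within a chain) plus cross-chain
#' pairs; `MQ` is a unitless quality score, contact density penalised by
#' clash density. Each is computed for the complex and for the receptor and
#' peptide alone (coordinates frozen), and the `Bind*` descriptors are the
#' complex-minus-parts differences.
#'
#' @param cx a "complex_structure".
#' @param params [energy_model_params()].
#' @return named numeric: CompMQ, BindMQ, CompPack1D, BindPack1D,
#'   CompPack3D, BindPack3D.
#' @export
packing_scores <- function(cx, params = energy_model_params()) {
  pep <- .pep_mask(cx)
  comp <- .pack_scores_one(cx$atoms, params)
  rec <- .pack_scores_one(cx$atoms[!pep, , drop = FALSE], params)
  pp <- .pack_scores_one(cx$atoms[pep, , drop = FALSE], params)
  bind <- comp - rec - pp
  c(CompMQ = unname(comp["MQ"]), BindMQ = unname(bind["MQ"]),
    CompPack1D = unname(comp["Pack1D"]), BindPack1D = unname(bind["Pack1D"]),
    CompPack3D = unname(comp["Pack3D"]), BindPack3D = unname(bind["Pack3D"]))
}

#' Canonical names of the 26 interface descriptors
#'
#' Fixed order: 5 interaction counts, 5 interaction energies, the two totals,
#' 6 quality/packing descriptors, 8 binding-energy/solvation descriptors.
#'
#' @return character vector of length 26.
#' @export
descriptor_names <- function() {
  c("HbondCount", "HydrophobicCount", "CationPiCount", "PiPiCount",
    "IonIonCount",
    "HbondEnergy", "HydrophobicEnergy", "CationPiEnergy", "PiPiEnergy",
    "IonIonEnergy",
    "InteractionCount", "InteractionEnergy",
    "CompMQ", "BindMQ", "CompPack1D", "BindPack1D", "CompPack3D",
    "BindPack3D",
    "BEpot", "BEelec", "BEvdw", "BS", "BSelec", "BSvdw", "BShydro", "BE")
}

#' Compute the full 26-descriptor vector for one complex
#'
#' Assembles the interaction summaries, packing/quality scores and
#' binding-energy decomposition in the canonical [descriptor_names()] order.
#'
#' @param cx a "complex_structure".
#' @param params [energy_model_params()].
#' @return named numeric vector of length 26.
#' @export
descriptor_vector <- function(cx, params = energy_model_params()) {
  out <- c(interaction_summaries(detect_interactions(cx, params)),
           packing_scores(cx, params),
           binding_terms(cx, params))
  out[descriptor_names()]
}
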