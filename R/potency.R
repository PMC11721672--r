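#' Convert an EC50 in nanomolar to pEC50
#'
#' pEC50 is the negative decadic logarithm of the *molar* EC50, so an EC50 of
#' 1 nM corresponds to pEC50 = 9 and 0.1 nM to pEC50 = 10.
#'
#' @param ec50 numeric vector of EC50 values in nM; must be finite and > 0.
#' @param id optional record labels used in error messages.
#' @return numeric vector of pEC50 values (log10 units).
#' @seealso [pec50_to_ec50()] for the inverse.
#' @examples
#' ec50_to_pec50(c(1, 0.1))   # 9, 10
#' @export
ec50_to_pec50 <- function(ec50, id = NULL) {
  bad <- !is.finite(ec50) | ec50 <= 0
  if (any(bad)) {
    lab <- if (is.null(id)) paste(which(bad), collapse = ", ") else
      paste(id[bad], collapse = ", ")
    stop("ec50_to_pec50(): non-positive, censored or missing EC50 for record(s): ",
         lab, call. = FALSE)
  }
  9 - log10(ec50)
}

#' Convert a pEC50 back to an EC50 in nanomolar
#'
#' @param pec50 numeric vector, log10 units.
#' @return EC50 in nM.
#' @export
pec50_to_ec50 <- function(pec50) {
  if (any(!is.finite(pec50))) stop("pec50_to_ec50(): non-finite pEC50", call. = FALSE)
  10^(9 - pec50)
}

#' Reference Calpha-methylation constant from the two scan parents
#'
#' The Aib-scan parent differs from the Ala-scan parent only by
#' Calpha-methylation of the position-6 side chain, so the difference of their
#' pEC50 values isolates the potency contribution of a single backbone methyl
#' group. For the packaged dataset this is 10.89 - 9.92 = 0.97 log units.
#'
#' @param pec50_aib_parent pEC50 of the Calpha-methylated (Aib-scan) parent.
#' @param pec50_ala_parent pEC50 of the unmethylated (Ala-scan) parent.
#' @return the reference constant, log10 units.
#' @export
reference_methylation_constant <- function(pec50_aib_parent, pec50_ala_parent) {
  if (!is.finite(pec50_aib_parent) || !is.finite(pec50_ala_parent))
    stop("reference_methylation_constant(): non-finite input", call. = FALSE)
  pec50_aib_parent - pec50_ala_parent
}

#' Per-position Calpha-methylation contribution
#'
#' The methylation contribution at a position is the Aib/Ala pEC50 gap at that
#' position, corrected by the reference constant measured at position 6:
#' \code{dpec50 = pec50_aib - pec50_ala - constant}.
#'
#' @param pec50_aib pEC50 of the Aib (methylated) analog.
#' @param pec50_ala pEC50 of the Ala analog at the same position.
#' @param constant reference methylation constant (0.97 for the packaged data).
#' @return dpEC50, log10 units. Positive values mean Calpha-methylation at
#'   that position is favourable beyond the backbone-generic effect.
#' @export
methylation_contribution <- function(pec50_aib, pec50_ala, constant) {
  if (any(!is.finite(c(pec50_aib, pec50_ala, constant))))
    stop("methylation_contribution(): non-finite input", call. = FALSE)
  pec50_aib - pec50_ala - constant
}

#' Build the full per-position methylation-contribution table
#'
#' Computes the reference constant from the parent pair (role "parent" in
#' `pairs`), then applies it uniformly to every scan pair. pEC50 values are
#' taken from the dataset's `pec50` column.
#'
#' @param dataset a peptide data.frame as returned by [glp1_peptides()];
#'   must have columns `id` and `pec50`.
#' @param pairs a data.frame of scan pairs with columns `position`, `aib_id`,
#'   `ala_id` and `role` ("parent" for the constant-defining pair, "scan"
#'   otherwise), as returned by [methylation_pairs()].
#' @param constant optional override of the reference constant; by default it
#'   is computed from the parent pair.
#' @return a data.frame with one row per scan pair: `position`, `aib_id`,
#'   `ala_id`, `pec50_aib`, `pec50_ala`, `reference_constant`, `dpec50`.
#' @examples
#' tab <- build_methylation_table(glp1_peptides(), methylation_pairs())
#' tab[tab$position == 11, "dpec50"]   # 1.11
#' @export
build_methylation_table <- function(dataset, pairs, constant = NULL) {
  stopifnot(is.data.frame(dataset), is.data.frame(pairs))
  if (nrow(pairs) == 0) {
    return(data.frame(position = integer(), aib_id = character(),
                      ala_id = character(), pec50_aib = numeric(),
                      pec50_ala = numeric(), reference_constant = numeric(),
                      dpec50 = numeric(), stringsAsFactors = FALSE))
  }
  lookup <- function(ids) {
    idx <- match(ids, dataset$id)
    if (anyNA(idx))
      stop("build_methylation_table(): unknown peptide id(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    p <- dataset$pec50[idx]
    if (anyNA(p))
      stop("build_methylation_table(): missing pec50 for record(s): ",
           paste(ids[is.na(p)], collapse = ", "), call. = FALSE)
    p
  }
  if (is.null(constant)) {
    par <- pairs[pairs$role == "parent", , drop = FALSE]
    if (nrow(par) != 1)
      stop("build_methylation_table(): pairs must contain exactly one parent pair ",
           "(or pass `constant` explicitly)", call. = FALSE)
    constant <- reference_methylation_constant(lookup(par$aib_id),
                                               lookup(par$ala_id))
  }
  scan <- pairs[pairs$role != "parent", , drop = FALSE]
  pa <- lookup(scan$aib_id)
  pb <- lookup(scan$ala_id)
  data.frame(position = as.integer(scan$position),
             aib_id = scan$aib_id, ala_id = scan$ala_id,
             pec50_aib = pa, pec50_ala = pb,
             reference_constant = constant,
             dpec50 = methylation_contribution(pa, pb, constant),
             stringsAsFactors = FALSE)
}

#' Ordinal potency class relative to a series parent
#'
#' Bins each peptide by fold-loss of potency against its series parent using
#' decade-scaled bins: within 3x of the parent, (3,30]x, (30,300]x, more than
#' 300x, and a lowest class for right-censored (EC50 out of assay range)
#' records. The classification depends only on the EC50 ratio, so it is
#' invariant under common rescaling of both concentrations.
#'
#' @param ec50 EC50 in nM, `NA` allowed when `censored` is TRUE.
#' @param parent_ec50 parent EC50 in nM (> 0).
#' @param censored logical vector flagging out-of-range records.
#' @return an ordered factor with levels (worst to best)
#'   "censored" < ">300x" < "30-300x" < "3-30x" < "<=3x".
#' @export
potency_class <- function(ec50, parent_ec50, censored = FALSE) {
  stopifnot(all(is.finite(parent_ec50)), all(parent_ec50 > 0))
  n <- max(length(ec50), length(censored))
  ec50 <- rep_len(ec50, n); censored <- rep_len(censored, n)
  parent_ec50 <- rep_len(parent_ec50, n)
  lev <- c("censored", ">300x", "30-300x", "3-30x", "<=3x")
  fold <- ec50 / parent_ec50
  cls <- ifelse(censored | !is.finite(fold), "censored",
         ifelse(fold <= 3, "<=3x",
         ifelse(fold <= 30, "3-30x",
         ifelse(fold <= 300, "30-300x", ">300x"))))
  factor(cls, levels = lev, ordered = TRUE)
}

#' Squared Pearson correlation between two position-paired potency series
#'
#' Used to compare scanning series (e.g. an Ala scan of the ultra-short
#' peptide against a published full-length Ala scan) position by position.
#'
#' @param series_a,series_b numeric pEC50 vectors, paired by position.
#' @return squared Pearson correlation coefficient (R^2).
#' @export
scan_series_r2 <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("scan_series_r2(): series lengths differ", call. = FALSE)
  if (length(series_a) < 3)
    stop("scan_series_r2(): need at least 3 paired values", call. = FALSE)
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("scan_series_r2(): zero-variance series, correlation undefined",
         call. = FALSE)
  stats::cor(series_a, series_b)^2
}
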