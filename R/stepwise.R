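# Stepwise term selection, Y-randomization and the two model-selection
# protocols.

# Canonical candidate ordering: fixed descriptor order first, remaining
# names alphabetical. This is the documented tie-break for equal p-values.
.canonical_order <- function(terms) {
  canon <- descriptor_names()
  c(intersect(canon, terms), sort(setdiff(terms, canon)))
}

#' Stepwise multiple linear regression
#'
#' Forward selection with backward elimination on partial-F (equivalently
#' added-term t-test) p-values: at each step the candidate with the smallest
#' p-value is added if p <= `alpha`, then any included term whose p-value has
#' risen above `alpha` is dropped. The procedure terminates when no addition
#' or removal is possible and may return the intercept-only model. Ties are
#' broken by canonical descriptor-name order, so the result is deterministic
#' and independent of candidate-list order. Candidates with (near) zero
#' variance or that would make the design rank-deficient are skipped.
#'
#' @param table descriptor table.
#' @param candidates character vector of candidate descriptor names.
#' @param alpha inclusion/exclusion p-value threshold (0.05 by default).
#' @param response response column name.
#' @return a "qsar_mlr" fit with an added `selection` component recording
#'   the alpha, the candidate set and the add/drop path.
#' @examples
#' tab <- gen_descriptor_table(descriptor_sim_spec(seed = 7))
#' fit <- stepwise_qsar(tab, descriptor_names())
#' fit$terms
#' @export
stepwise_qsar <- function(table, candidates, alpha = 0.05,
                          response = "pec50") {
  if (!length(candidates))
    stop("stepwise_qsar(): empty candidate set", call. = FALSE)
  .check_table(table, candidates, response)
  candidates <- .canonical_order(candidates)
  current <- character()
  path <- character()
  repeat {
    changed <- FALSE
    # forward: best addable candidate
    best_p <- Inf; best_term <- NULL
    for (cand in setdiff(candidates, current)) {
      fit <- tryCatch(qsar_mlr(table, c(current, cand), response),
                      error = function(e) NULL)
      if (is.null(fit)) next
      p <- unname(fit$p_t[cand])
      if (is.finite(p) && p < best_p - 1e-12) { best_p <- p; best_term <- cand }
    }
    if (!is.null(best_term) && best_p <= alpha) {
      current <- c(current, best_term)
      path <- c(path, paste0("+", best_term))
      changed <- TRUE
    }
    # backward: drop any term above alpha (worst first)
    repeat {
      if (!length(current)) break
      fit <- qsar_mlr(table, current, response)
      worst <- which.max(fit$p_t)
      if (fit$p_t[worst] > alpha) {
        path <- c(path, paste0("-", current[worst]))
        current <- current[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- qsar_mlr(table, current, response)
  fit$selection <- list(alpha = alpha, candidates = candidates, path = path)
  fit
}

#' Y-randomization of a fitted term set
#'
#' Permutes the response `n_trials` times (seeded), refits the fixed term
#' set on each permuted response and records the per-trial R2 and Q2. The
#' chance-correlation penalty is
#' `cRp2 = sqrt(R2) * sqrt(R2 - mean R2_random)`, clipped to 0 when the
#' radicand is negative. Optionally a fresh stepwise selection can be run
#' per trial instead of refitting the fixed terms.
#'
#' @param table descriptor table.
#' @param terms term set of the model under test.
#' @param n_trials number of permutations (50 by default).
#' @param seed integer seed (mandatory; the procedure is stochastic).
#' @param response response column name.
#' @param reselect if TRUE, run stepwise selection over `candidates` on each
#'   permuted response instead of refitting `terms`.
#' @param candidates candidate set for `reselect = TRUE`.
#' @param alpha stepwise alpha for `reselect = TRUE`.
#' @return list of class "y_randomization": `n_trials`, `r2_trials`,
#'   `q2_trials`, `mean_r2`, `mean_q2`, `model_r2`, `crp2`.
#' @export
y_randomize <- function(table, terms, n_trials = 50, seed,
                        response = "pec50", reselect = FALSE,
                        candidates = NULL, alpha = 0.05) {
  stopifnot(n_trials >= 1)
  if (missing(seed)) stop("y_randomize(): seed is required", call. = FALSE)
  model <- qsar_mlr(table, terms, response)
  r2s <- q2s <- numeric(n_trials)
  withr::with_seed(seed, {
    for (t in seq_len(n_trials)) {
      perm <- table
      perm[[response]] <- sample(table[[response]])
      fit <- if (reselect)
        stepwise_qsar(perm, candidates, alpha, response)
      else qsar_mlr(perm, terms, response)
      r2s[t] <- fit$r2
      q2s[t] <- fit$q2
    }
  })
  crp2 <- crp2_statistic(model$r2, mean(r2s))
  structure(list(n_trials = n_trials, r2_trials = r2s, q2_trials = q2s,
                 mean_r2 = mean(r2s), mean_q2 = mean(q2s),
                 model_r2 = model$r2, crp2 = crp2),
            class = "y_randomization")
}

#' Chance-correlation penalty cRp2
#'
#' `cRp2 = sqrt(R2 * (R2 - mean R2_random))`, clipped to 0 when the model R2
#' does not exceed the random-permutation mean.
#'
#' @param r2 model R2.
#' @param mean_r2_random mean R2 over Y-randomized refits.
#' @return cRp2, dimensionless.
#' @export
crp2_statistic <- function(r2, mean_r2_random) {
  rad <- r2 * (r2 - mean_r2_random)
  if (rad < 0) 0 else sqrt(rad)
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf(
    "Y-randomization (%d trials): mean R2 = %.3f, mean Q2 = %.3f, cRp2 = %.3f\n",
    x$n_trials, x$mean_r2, x$mean_q2, x$crp2))
  invisible(x)
}

#' Selection bounds from reference models
#'
#' The promising-model window for adjusted R2: above the single-term
#' binding-energy reference (underfit bound) and below the between-assay
#' experimental agreement (overfit bound).
#'
#' @param lower_r2adj underfit bound (0.37 for the study data).
#' @param upper_r2adj overfit bound (0.62 for the study data).
#' @return list of class "selection_bounds".
#' @export
selection_bounds <- function(lower_r2adj = 0.37, upper_r2adj = 0.62) {
  if (!(lower_r2adj < upper_r2adj))
    stop("selection_bounds(): lower bound must be below upper bound",
         call. = FALSE)
  structure(list(lower_r2adj = lower_r2adj, upper_r2adj = upper_r2adj),
            class = "selection_bounds")
}

#' Bounded (multi-criterion) model selection
#'
#' Labels each candidate model pass/underfit/overfit by its adjusted R2
#' against the [selection_bounds()] window, flags the significance criteria
#' (overall p(F) <= 0.05, all per-term p(t) <= 0.05, all VIF < 5, Q2 above
#' the reference margin), and ranks passing candidates by adjusted R2.
#'
#' @param candidates list of "qsar_mlr" fits.
#' @param bounds a [selection_bounds()] object.
#' @param q2_ref reference Q2 a promising model must clearly exceed (0.24
#'   for the study's reference model).
#' @return data.frame of verdicts, ranked passes first.
#' @export
select_model_bounded <- function(candidates, bounds = selection_bounds(),
                                 q2_ref = 0.24) {
  stopifnot(inherits(bounds, "selection_bounds"))
  if (!length(candidates))
    return(data.frame(model = character(), r2_adj = numeric(),
                      verdict = character(), p_f_ok = logical(),
                      p_t_ok = logical(), vif_ok = logical(),
                      q2_ok = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("model", seq_along(candidates))
  rows <- lapply(seq_along(candidates), function(i) {
    f <- candidates[[i]]
    verdict <- if (f$r2_adj <= bounds$lower_r2adj) "underfit"
    else if (f$r2_adj > bounds$upper_r2adj) "overfit"
    else "pass"
    data.frame(model = nm[i], r2_adj = f$r2_adj, verdict = verdict,
               p_f_ok = is.finite(f$p_f) && f$p_f <= 0.05,
               p_t_ok = all(f$p_t <= 0.05),
               vif_ok = all(f$vif < 5),
               q2_ok = f$q2 > q2_ref,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  pass <- which(out$verdict == "pass")
  out$rank[pass[order(-out$r2_adj[pass])]] <- seq_along(pass)
  out[order(is.na(out$rank), out$rank), , drop = FALSE]
}

#' AICc-ranked model selection with an interpretability gate
#'
#' Iterates the candidate models in ascending AICc order and returns the
#' first whose physical-interpretability flag is TRUE; if none passes, an
#' explicit failure result is returned.
#'
#' @param candidates list of "qsar_mlr" fits (AICc defined for all).
#' @param interpretability_flags logical vector, one per candidate.
#' @return list with `chosen` (a fit or NULL), `chosen_name`, `failed`,
#'   and the ranking order.
#' @export
select_model_aic <- function(candidates, interpretability_flags) {
  stopifnot(length(candidates) == length(interpretability_flags))
  aiccs <- vapply(candidates, function(f) f$aicc, 0)
  if (anyNA(aiccs))
    stop("select_model_aic(): AICc undefined for some candidate", call. = FALSE)
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("model", seq_along(candidates))
  ord <- order(aiccs)
  for (i in ord) {
    if (isTRUE(interpretability_flags[i]))
      return(list(chosen = candidates[[i]], chosen_name = nm[i],
                  failed = FALSE, order = nm[ord]))
  }
  list(chosen = NULL, chosen_name = NA_character_, failed = TRUE,
       order = nm[ord])
}
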