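# Ordinary least squares QSAR fitting with the full validation statistics
# ladder. qsar_mlr() is the core fitting function; stepwise_qsar() wraps it
# with p-value driven term selection.

#' Descriptor sets by type
#'
#' The canonical grouping of the 26 interface descriptors: the 12
#' interaction descriptors, the 6 quality/packing descriptors, the 8
#' binding-energy (force-field/solvation) descriptors, and all 26 mixed.
#'
#' @return named list of descriptor-name vectors.
#' @export
descriptor_sets <- function() {
  nm <- descriptor_names()
  list(interaction = nm[1:12],
       quality_packing = nm[13:18],
       nova_terms = nm[19:26],
       mixed = nm)
}

.check_table <- function(table, terms, response) {
  stopifnot(is.data.frame(table))
  if (!response %in% names(table))
    stop("response column '", response, "' not in table", call. = FALSE)
  miss <- setdiff(terms, names(table))
  if (length(miss))
    stop("term(s) not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  y <- table[[response]]
  if (anyNA(y) || (length(terms) && anyNA(as.matrix(table[terms]))))
    stop("qsar table must have no missing values", call. = FALSE)
  if (nrow(table) < 5) stop("need at least 5 rows", call. = FALSE)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  invisible(TRUE)
}

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of the response (pEC50 by default) on a named
#' descriptor subset, with the complete validation ladder computed up front:
#' R2 and adjusted R2, the overall F-test, per-term t-tests, variance
#' inflation factors, AIC and AICc (Gaussian form, `n*ln(RSS/n) + 2k` with k
#' counting the intercept and slopes), and leave-one-out Q2.
#'
#' @param table data.frame with the response column and descriptor columns.
#' @param terms character vector of descriptor names; empty for the
#'   intercept-only model.
#' @param response name of the response column.
#' @return an object of class "qsar_mlr" with components `terms`, `weights`
#'   (coefficients), `se`, `intercept`, `r2`, `r2_adj`, `p_f`, `p_t`, `vif`,
#'   `aic`, `aicc`, `q2`, `equation_text`, `fitted`, `residuals`, `n`, `k`.
#' @examples
#' tab <- gen_descriptor_table(descriptor_sim_spec(seed = 1))
#' fit <- qsar_mlr(tab, c("BEpot", "BSvdw"))
#' summary(fit)
#' @export
qsar_mlr <- function(table, terms = character(), response = "pec50") {
  .check_table(table, terms, response)
  y <- table[[response]]
  n <- length(y)
  X <- cbind(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
             if (length(terms)) as.matrix(table[terms]) else NULL)
  k <- ncol(X)
  if (n <= k)
    stop("qsar_mlr(): need n > number of parameters (n = ", n, ", k = ", k,
         ")", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < k) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):k]]
    stop("qsar_mlr(): design matrix rank-deficient; collinear term(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k)
  sigma2 <- rss / (n - k)
  xtx_inv <- solve(crossprod(X))
  se <- stats::setNames(sqrt(diag(xtx_inv) * sigma2), colnames(X))
  tval <- beta / se
  p_t <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  p <- k - 1
  p_f <- if (p > 0) {
    fstat <- ((tss - rss) / p) / sigma2
    stats::pf(fstat, p, n - k, lower.tail = FALSE)
  } else NA_real_
  aic <- n * log(rss / n) + 2 * k
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  h <- rowSums((X %*% xtx_inv) * X)
  press <- sum((res / (1 - h))^2)
  q2 <- 1 - press / tss
  vifs <- if (length(terms) >= 2) vif(table, terms) else
    stats::setNames(rep(1, length(terms)), terms)
  out <- list(terms = terms,
              weights = beta[-1], se = se[-1],
              intercept = unname(beta[1]), intercept_se = unname(se[1]),
              r2 = r2, r2_adj = r2_adj,
              p_f = p_f,
              p_t = stats::setNames(p_t[-1], terms),
              p_t_intercept = unname(p_t[1]),
              vif = vifs,
              aic = aic, aicc = aicc, q2 = q2,
              aic_convention = "n*ln(RSS/n) + 2k, k = intercept + slopes",
              fitted = fitted, residuals = res, rss = rss,
              n = n, k = k, response = response,
              y = y, table_terms = table[terms],
              reference = FALSE)
  out$equation_text <- .render_equation(out)
  class(out) <- "qsar_mlr"
  out
}

#' @rdname qsar_mlr
#' @export
fit_ols <- qsar_mlr

.render_equation <- function(fit) {
  resp <- if (fit$response == "pec50") "pEC50" else fit$response
  fmt <- function(v) formatC(signif(v, 3), format = "fg", flag = "#")
  rhs <- ""
  for (i in seq_along(fit$terms)) {
    w <- fit$weights[i]
    piece <- paste0(fmt(abs(w)), fit$terms[i])
    rhs <- if (i == 1)
      paste0(if (w < 0) "-" else "", piece)
    else paste(rhs, if (w < 0) "-" else "+", piece)
  }
  b <- fit$intercept
  rhs <- if (nzchar(rhs))
    paste(rhs, if (b < 0) "-" else "+", fmt(abs(b)))
  else fmt(b)
  paste(resp, "=", rhs)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` comes from regressing descriptor
#' j on the other descriptors in the set.
#'
#' @param table data.frame containing the descriptor columns.
#' @param terms character vector of at least two descriptor names.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(table, terms) {
  if (length(terms) < 2)
    stop("vif(): need at least two terms", call. = FALSE)
  X <- as.matrix(table[terms])
  out <- stats::setNames(numeric(length(terms)), terms)
  for (j in seq_along(terms)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2j <- 1 - rss / tss
    if (r2j >= 1 - 1e-12)
      stop("vif(): perfect collinearity involving term '", terms[j], "'",
           call. = FALSE)
    out[j] <- 1 / (1 - r2j)
  }
  out
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - PRESS/TSS` with TSS about the full-sample mean. By default the
#' PRESS statistic is obtained through the hat-matrix identity
#' `e_i / (1 - h_ii)`; `refit = TRUE` performs the n explicit refits instead
#' (the two agree to numerical precision).
#'
#' @param table data.frame with response and descriptors.
#' @param terms descriptor subset.
#' @param response response column name.
#' @param refit use explicit n-refit computation.
#' @return Q2, dimensionless.
#' @export
loocv_q2 <- function(table, terms, response = "pec50", refit = FALSE) {
  stopifnot(is.data.frame(table), response %in% names(table))
  y <- table[[response]]
  n <- length(y)
  if (n < 3) stop("loocv_q2(): need n >= 3", call. = FALSE)
  if (anyNA(y) || (length(terms) && anyNA(as.matrix(table[terms]))))
    stop("loocv_q2(): missing values", call. = FALSE)
  X <- cbind(1, if (length(terms)) as.matrix(table[terms]) else NULL)
  tss <- sum((y - mean(y))^2)
  if (!refit) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X))
      stop("loocv_q2(): rank-deficient design", call. = FALSE)
    h <- rowSums((X %*% chol2inv(qr.R(qrx))) * X)
    if (any(h > 1 - 1e-10))
      stop("loocv_q2(): a leave-one-out design is rank-deficient", call. = FALSE)
    res <- y - drop(X %*% qr.coef(qrx, y))
    press <- sum((res / (1 - h))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      qri <- qr(X[-i, , drop = FALSE])
      if (qri$rank < ncol(X))
        stop("loocv_q2(): leave-one-out design rank-deficient at row ", i,
             call. = FALSE)
      pred <- drop(X[i, ] %*% qr.coef(qri, y[-i]))
      press <- press + (y[i] - pred)^2
    }
  }
  1 - press / tss
}

#' AIC and AICc of a fitted model
#'
#' Gaussian-likelihood form `AIC = n*ln(RSS/n) + 2k` with k counting the
#' intercept and slopes; `AICc = AIC + 2k(k+1)/(n-k-1)`. The convention is
#' recorded on the fit as `aic_convention`.
#'
#' @param fit a "qsar_mlr" object.
#' @return named numeric: aic, aicc.
#' @export
aic_aicc <- function(fit) {
  stopifnot(inherits(fit, "qsar_mlr"))
  if (fit$n <= fit$k + 1)
    stop("aic_aicc(): AICc undefined for n <= k + 1", call. = FALSE)
  c(aic = fit$aic, aicc = fit$aicc)
}

#' Single-term binding-energy reference model
#'
#' Fits the response on the overall binding score BE alone; this benchmark
#' sets the lower bound on the adjusted R2 any multi-descriptor model must
#' beat.
#'
#' @param table descriptor table with a `BE` column.
#' @param response response column name.
#' @return "qsar_mlr" object with `reference = TRUE`.
#' @export
reference_binding_model <- function(table, response = "pec50") {
  if (!"BE" %in% names(table))
    stop("reference_binding_model(): no BE column", call. = FALSE)
  fit <- qsar_mlr(table, "BE", response)
  fit$reference <- TRUE
  fit
}

# --- S3 methods -------------------------------------------------------------

#' @export
print.qsar_mlr <- function(x, ...) {
  cat(if (x$reference) "Reference binding-energy model\n" else "QSAR model\n")
  cat("  ", x$equation_text, "\n", sep = "")
  cat(sprintf("  n = %d, terms = %d, R2_adj = %.3f, Q2 = %.3f\n",
              x$n, length(x$terms), x$r2_adj, x$q2))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  structure(list(fit = object), class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  R2 = %.4f, R2_adj = %.4f, Q2 = %.4f\n", f$r2, f$r2_adj, f$q2))
  cat(sprintf("  p(F) = %s, AIC = %.3f, AICc = %.3f\n",
              format.pval(f$p_f), f$aic, f$aicc))
  if (length(f$terms)) {
    tab <- data.frame(weight = f$weights, se = f$se, p_t = f$p_t,
                      vif = f$vif[f$terms])
    print(tab, digits = 4)
  }
  cat(sprintf("  intercept = %.4f (p = %s)\n", f$intercept,
              format.pval(f$p_t_intercept)))
  invisible(x)
}

#' @export
coef.qsar_mlr <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted

#' Predict from a fitted QSAR model
#' @param object a "qsar_mlr" fit.
#' @param newdata data.frame with the model's descriptor columns; omitted
#'   for in-sample fitted values.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  miss <- setdiff(object$terms, names(newdata))
  if (length(miss))
    stop("predict(): newdata lacks term(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- cbind(1, if (length(object$terms))
    as.matrix(newdata[object$terms]) else NULL)
  drop(X %*% c(object$intercept, object$weights))
}

#' Observed-versus-fitted plot for a QSAR model
#' @param x a "qsar_mlr" fit.
#' @param ... passed to [plot()].
#' @export
plot.qsar_mlr <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "fitted pEC50", ylab = "observed pEC50",
       main = x$equation_text, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
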