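# OLS engine, cross-validation and the statistics ladder.

test_that("OLS recovers exact linear relations and the intercept-only model", {
  tab <- data.frame(id = 1:10, pec50 = 2 * (1:10) + 1, x1 = 1:10,
                    x2 = rnorm(10))
  fit <- fit_ols(tab, "x1")
  expect_equal(unname(fit$weights["x1"]), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  null <- fit_ols(tab, character())
  expect_equal(null$r2, 0)
  expect_true(is.na(null$p_f))
  expect_equal(null$intercept, mean(tab$pec50))
})

test_that("OLS weights match the normal-equation oracle to 1e-10", {
  tab <- worked_table()
  fit <- qsar_mlr(tab, c("x1", "x2"))
  oracle <- ols_oracle(tab, c("x1", "x2"))
  expect_equal(unname(c(fit$intercept, fit$weights)), unname(oracle),
               tolerance = 1e-10)
})

test_that("rank deficiency is reported with the collinear term names", {
  tab <- worked_table()
  tab$x3 <- tab$x1
  expect_error(qsar_mlr(tab, c("x1", "x3")), "x3")
})

test_that("equation text renders signed weights like the study reports", {
  tab <- gen_descriptor_table(descriptor_sim_spec(seed = 5))
  fit <- qsar_mlr(tab, c("BEpot", "BSvdw"))
  expect_match(fit$equation_text, "^pEC50 = -?[0-9.]+BEpot [+-] [0-9.]+BSvdw [+-] [0-9.]+$")
})

test_that("LOOCV Q2 matches hand computation and the refit identity", {
  # noiseless linear data: perfect cross-validated prediction
  lin <- data.frame(id = 1:8, pec50 = 3 * (1:8) - 2, x1 = 1:8)
  expect_equal(loocv_q2(lin, "x1"), 1, tolerance = 1e-10)
  # (0,0), (1,1), (2,0): PRESS = 4 + 1 + 4 = 9, TSS = 2/3, Q2 = -12.5
  tri <- data.frame(id = 1:3, pec50 = c(0, 1, 0), x1 = c(0, 1, 2))
  expect_equal(loocv_q2(tri, "x1"), -12.5, tolerance = 1e-10)
  # hat-matrix shortcut equals the explicit n refits
  tab <- gen_descriptor_table(descriptor_sim_spec(seed = 9))
  expect_equal(loocv_q2(tab, c("BEpot", "BSvdw")),
               loocv_q2(tab, c("BEpot", "BSvdw"), refit = TRUE),
               tolerance = 1e-10)
})

test_that("VIF matches the closed form and flags collinearity", {
  n <- 40
  set.seed(21)
  u <- rnorm(n); e <- rnorm(n)
  # construct exact sample correlation 0.9
  uc <- scale(u)[, 1]
  ec <- residuals(lm(e ~ uc)); ec <- ec / sqrt(sum(ec^2) / (n - 1))
  tab <- data.frame(id = 1:n, pec50 = rnorm(n), x1 = uc,
                    x2 = 0.9 * uc + sqrt(1 - 0.81) * ec)
  v <- vif(tab, c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
  # orthogonal predictors: VIF 1
  tab$x3 <- ec
  expect_equal(unname(vif(tab, c("x1", "x3"))), c(1, 1), tolerance = 1e-8)
  tab$x4 <- tab$x1
  expect_error(vif(tab, c("x1", "x4")), "collinearity")
})

test_that("AIC follows the declared Gaussian convention", {
  tab <- gen_descriptor_table(descriptor_sim_spec(n = 31, seed = 13))
  fit <- qsar_mlr(tab, c("BEpot", "BSvdw"))  # k = 3
  expect_equal(fit$aic, 31 * log(fit$rss / 31) + 2 * 3, tolerance = 1e-12)
  expect_equal(fit$aicc - fit$aic, 24 / 27, tolerance = 1e-12)
  ab <- aic_aicc(fit)
  expect_equal(unname(ab), c(fit$aic, fit$aicc))
  # adding a pure-noise term cannot reduce RSS but pays the 2k penalty
  set.seed(4)
  worse <- 0
  for (s in 1:20) {
    t2 <- gen_descriptor_table(descriptor_sim_spec(n = 31, seed = 100 + s))
    f2 <- qsar_mlr(t2, c("BEpot", "BSvdw"))
    f3 <- qsar_mlr(t2, c("BEpot", "BSvdw", "CompMQ"))
    expect_lte(f3$rss, f2$rss + 1e-9)
    if (f3$aic > f2$aic) worse <- worse + 1
  }
  expect_gt(worse, 10)  # the penalty usually dominates for a noise term
  tiny <- data.frame(id = 1:5, pec50 = rnorm(5), x1 = rnorm(5),
                     x2 = rnorm(5), x3 = rnorm(5))
  f <- qsar_mlr(tiny, c("x1", "x2", "x3"))
  expect_error(aic_aicc(f), "AICc undefined")
})

test_that("basic fit invariants hold across random tables", {
  for (s in 1:5) {
    tab <- gen_descriptor_table(descriptor_sim_spec(seed = 400 + s))
    fit <- qsar_mlr(tab, c("BEpot", "BSvdw", "CompMQ"))
    expect_lte(fit$r2_adj, fit$r2)
    expect_lte(fit$q2, fit$r2)
    expect_true(all(fit$vif >= 1))
    # permuting rows changes nothing
    perm <- tab[sample(nrow(tab)), ]
    fitp <- qsar_mlr(perm, c("BEpot", "BSvdw", "CompMQ"))
    expect_equal(fitp$weights, fit$weights, tolerance = 1e-10)
    expect_equal(fitp$q2, fit$q2, tolerance = 1e-10)
    # rescaling a descriptor rescales its weight and nothing else
    sc <- tab; sc$BEpot <- sc$BEpot * 10
    fits <- qsar_mlr(sc, c("BEpot", "BSvdw", "CompMQ"))
    expect_equal(unname(fits$weights["BEpot"]),
                 unname(fit$weights["BEpot"]) / 10, tolerance = 1e-10)
    expect_equal(fits$r2, fit$r2, tolerance = 1e-12)
    expect_equal(fits$aic, fit$aic, tolerance = 1e-10)
    expect_equal(fits$p_t, fit$p_t, tolerance = 1e-10)
    expect_equal(fits$q2, fit$q2, tolerance = 1e-10)
  }
})

test_that("predict and residuals methods are consistent", {
  tab <- gen_descriptor_table(descriptor_sim_spec(seed = 31))
  fit <- qsar_mlr(tab, c("BEpot", "BSvdw"))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, tab), fitted(fit))
  expect_equal(residuals(fit), tab$pec50 - fitted(fit))
  expect_error(predict(fit, tab[, "id", drop = FALSE]), "BEpot")
  expect_equal(unname(coef(fit)["(Intercept)"]), fit$intercept)
})
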