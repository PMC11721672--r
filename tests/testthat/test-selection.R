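# Stepwise selection, Y-randomization and the two model-selection protocols.

test_that("stepwise selects exactly the planted strong term", {
  set.seed(2)
  n <- 50
  tab <- data.frame(id = 1:n, x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
  tab$pec50 <- 3 * tab$x1 + rnorm(n, 0, 0.1)
  fit <- stepwise_qsar(tab, paste0("x", 1:5))
  expect_identical(fit$terms, "x1")
  # exhaustive best-subset oracle agrees on which single term matters
  rss1 <- vapply(paste0("x", 1:5), function(t) qsar_mlr(tab, t)$rss, 0)
  expect_equal(names(which.min(rss1)), "x1")
})

test_that("two orthogonal strong terms are both selected, order-independently", {
  n <- 60
  set.seed(8)
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  tab <- data.frame(id = 1:n, x1 = x1, x2 = x2, x3 = rnorm(n), x4 = rnorm(n))
  tab$pec50 <- 2 * x1 - 1.5 * x2 + rnorm(n, 0, 0.3)
  f1 <- stepwise_qsar(tab, c("x1", "x2", "x3", "x4"))
  f2 <- stepwise_qsar(tab, c("x4", "x3", "x2", "x1"))
  expect_setequal(f1$terms, c("x1", "x2"))
  expect_identical(sort(f1$terms), sort(f2$terms))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})

test_that("pure-noise responses mostly yield the intercept-only model", {
  nulls <- 0
  for (s in 1:100) {
    withr::with_seed(7000 + s, {
      n <- 50
      tab <- data.frame(id = 1:n, pec50 = rnorm(n), x1 = rnorm(n),
                        x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n),
                        x5 = rnorm(n))
    })
    fit <- stepwise_qsar(tab, paste0("x", 1:5), alpha = 0.05)
    if (!length(fit$terms)) nulls <- nulls + 1
  }
  expect_gte(nulls, 70)
})

test_that("stepwise AICc is near the best-subset optimum", {
  ok <- 0
  for (s in 1:30) {
    tab <- gen_descriptor_table(descriptor_sim_spec(
      n = 40, p = 8, true_terms = c("X1", "X2"), true_weights = c(1, -0.8),
      seed = 1200 + s))
    fit <- stepwise_qsar(tab, paste0("X", 1:8))
    subsets <- unlist(lapply(0:3, function(k)
      combn(paste0("X", 1:8), k, simplify = FALSE)), recursive = FALSE)
    best <- min(vapply(subsets, function(ss) qsar_mlr(tab, ss)$aicc, 0))
    if (fit$aicc <= best + 2) ok <- ok + 1
  }
  expect_gte(ok, 27)  # >= 90%
})

test_that("Y-randomization is seeded, unbiased under the null, and feeds cRp2", {
  tab <- gen_descriptor_table(descriptor_sim_spec(seed = 77))
  yr1 <- y_randomize(tab, c("BEpot", "BSvdw"), n_trials = 30, seed = 5)
  yr2 <- y_randomize(tab, c("BEpot", "BSvdw"), n_trials = 30, seed = 5)
  expect_identical(yr1$r2_trials, yr2$r2_trials)
  # permuted-response R2 has null expectation ~ k/(n-1) for k regressors
  yr <- y_randomize(tab, c("BEpot", "BSvdw"), n_trials = 200, seed = 11)
  expect_lt(abs(yr$mean_r2 - 2 / 30), 3 * sd(yr$r2_trials) / sqrt(200))
  expect_equal(yr$crp2, crp2_statistic(yr$model_r2, yr$mean_r2))
  # formula limits
  expect_equal(crp2_statistic(0.5, 0), 0.5)
  expect_equal(crp2_statistic(0.3, 0.6), 0)
})

test_that("the single-term binding-energy reference model behaves", {
  tab <- gen_descriptor_table(descriptor_sim_spec(seed = 19))
  tab$pec50 <- -0.5 * tab$BE + 2
  ref <- reference_binding_model(tab)
  expect_true(ref$reference)
  expect_equal(ref$r2, 1, tolerance = 1e-10)
  tab$BE <- 1
  expect_error(reference_binding_model(tab), "collinear|rank")
  # planted-slope coverage: recovered slope within 2 SE most of the time
  hits <- 0
  for (s in 1:200) {
    t2 <- gen_descriptor_table(descriptor_sim_spec(
      n = 31, p = 26, true_terms = "BE", true_weights = -0.01,
      noise_sd = 0.5, seed = 5000 + s))
    f <- reference_binding_model(t2)
    if (abs(unname(f$weights["BE"]) + 0.01) <= 2 * unname(f$se["BE"]))
      hits <- hits + 1
  }
  expect_gte(hits, 0.95 * 200 * 0.9)  # binomial slack below the 95% target
})

test_that("bounded selection labels candidates and ranks the passes", {
  fake <- function(r2a, q2 = 0.5, pf = 0.01, pt = 0.01, v = 1.2) {
    structure(list(r2_adj = r2a, q2 = q2, p_f = pf,
                   p_t = c(a = pt), vif = c(a = v)), class = "qsar_mlr")
  }
  cands <- list(lo = fake(0.31), mid = fake(0.41), hi = fake(0.58),
                over = fake(0.63))
  out <- select_model_bounded(cands, selection_bounds(0.37, 0.62))
  expect_equal(out$verdict[out$model == "lo"], "underfit")
  expect_equal(out$verdict[out$model == "over"], "overfit")
  expect_equal(out$model[out$rank == 1 & !is.na(out$rank)], "hi")
  expect_equal(nrow(select_model_bounded(list())), 0)
  expect_error(selection_bounds(0.7, 0.6), "below")
})

test_that("AICc selection applies the interpretability gate in order", {
  fake <- function(aicc) structure(list(aicc = aicc), class = "qsar_mlr")
  cands <- list(m1 = fake(-7.4), m2 = fake(-5.4))
  pick <- select_model_aic(cands, c(FALSE, TRUE))
  expect_equal(pick$chosen_name, "m2")
  expect_false(pick$failed)
  fail <- select_model_aic(cands, c(FALSE, FALSE))
  expect_true(fail$failed)
  expect_null(fail$chosen)
  single <- select_model_aic(list(only = fake(1)), TRUE)
  expect_equal(single$chosen_name, "only")
})
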