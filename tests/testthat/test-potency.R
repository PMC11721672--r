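# Potency conversions and the Calpha-methylation decomposition.

test_that("EC50/pEC50 conversion follows the molar convention and round-trips", {
  expect_equal(ec50_to_pec50(1), 9)
  expect_equal(ec50_to_pec50(0.1), 10)
  # 7.4 nM, frozen from -log10(7.4e-9)
  expect_equal(ec50_to_pec50(7.4), 8.1307682802, tolerance = 1e-9)
  x <- 10^seq(-4, 4, length.out = 25)
  expect_equal(pec50_to_ec50(ec50_to_pec50(x)), x, tolerance = 1e-12)
  expect_error(ec50_to_pec50(0), "non-positive")
  expect_error(ec50_to_pec50(NA_real_, id = "RXL-3038"), "RXL-3038")
})

test_that("reference methylation constant is the parent pEC50 difference", {
  expect_equal(reference_methylation_constant(10.89, 9.92), 0.97)
  expect_equal(reference_methylation_constant(8.2, 8.2), 0)
  expect_equal(reference_methylation_constant(11, 10), 1)
  expect_error(reference_methylation_constant(NA, 1), "non-finite")
})

test_that("methylation contribution reproduces the printed per-position values", {
  expect_equal(methylation_contribution(8.08, 6.00, 0.97), 1.11)  # position 11
  expect_equal(methylation_contribution(7.80, 6.46, 0.97), 0.37)  # position 4
  expect_equal(methylation_contribution(5.5, 5.5, 0), 0)
})

test_that("dpec50 is antisymmetric under Aib/Ala swap with negated constant", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 5, 11); b <- runif(1, 5, 11); k <- runif(1, -2, 2)
    expect_equal(methylation_contribution(a, b, k) +
                   methylation_contribution(b, a, -k), 0)
  }
})

test_that("packaged methylation table matches the printed values within 0.01", {
  tab <- build_methylation_table(glp1_peptides(), methylation_pairs())
  expect_equal(nrow(tab), 11)
  expect_equal(tab$position, 1:11)
  expect_equal(unique(tab$reference_constant), 0.97)
  printed <- methylation_pairs()
  printed <- printed[printed$role == "scan", ]
  expect_true(all(abs(tab$dpec50 - printed$dpec50_printed) <= 0.01 + 1e-9))
  # agreement is exact except positions 1 and 9 (last-digit rounding upstream)
  exact <- setdiff(1:11, c(1, 9))
  expect_equal(tab$dpec50[exact], printed$dpec50_printed[exact],
               tolerance = 1e-9)
})

test_that("methylation table handles empty input and bad references", {
  pep <- glp1_peptides()
  empty <- build_methylation_table(pep, methylation_pairs()[0, ])
  expect_equal(nrow(empty), 0)
  bad <- methylation_pairs()
  bad$aib_id[2] <- "RXL-9999"
  expect_error(build_methylation_table(pep, bad), "RXL-9999")
  noval <- pep; noval$pec50[noval$id == "RXL-3009"] <- NA
  expect_error(build_methylation_table(noval, methylation_pairs()),
               "RXL-3009")
})

test_that("synthetic scans with planted effects are recovered exactly", {
  ala <- c(-0.2, 0, -1.1, -2.3, -0.9, -4.4, -1.3, -0.2, -0.8, -3.9, -3.9)
  aib <- c(-0.5, 0, -1.2, -1.0, -0.8, -2.9, -2.8, -2.0, -1.9, -4.9, -0.8)
  sim <- gen_scan_dataset(scan_sim_spec(ala, aib, methylation_constant = 0.8,
                                        noise_sd = 0))
  tab <- build_methylation_table(sim$records, sim$pairs)
  expect_equal(tab$dpec50, aib - ala, tolerance = 1e-12)
  # zero effects, zero noise: every contribution vanishes
  sim0 <- gen_scan_dataset(scan_sim_spec(noise_sd = 0))
  tab0 <- build_methylation_table(sim0$records, sim0$pairs)
  expect_equal(tab0$dpec50, rep(0, 11))
})

test_that("potency classes bin by fold-loss and rescale invariantly", {
  expect_equal(as.character(potency_class(0.1, 0.1)), "<=3x")
  expect_equal(as.character(potency_class(NA, 0.1, censored = TRUE)),
               "censored")
  expect_equal(as.character(potency_class(1.0, 0.1)), "3-30x")
  ec <- c(0.1, 0.5, 5, 50, 500)
  expect_identical(potency_class(ec, 0.1), potency_class(ec * 7, 0.7))
  expect_true(is.ordered(potency_class(ec, 0.1)))
  prof <- potency_profile()
  expect_true(all(prof$potency_class[prof$censored] == "censored"))
  expect_equal(as.character(prof$potency_class[prof$id == "RXL-3000"]), "<=3x")
})

test_that("scan series correlation handles the degenerate cases", {
  a <- c(7.1, 8.2, 6.3, 9.4)
  expect_equal(scan_series_r2(a, a), 1)
  expect_equal(scan_series_r2(a, -a), 1)
  expect_equal(scan_series_r2(c(1, 2, 3, 4), c(1, 2, 2, 1)), 0)
  expect_error(scan_series_r2(a, rep(5, 4)), "zero-variance")
  expect_error(scan_series_r2(a, a[1:3]), "lengths differ")
})

test_that("packaged dataset satisfies the structural invariants", {
  pep <- glp1_peptides()
  expect_equal(nrow(pep), 40)
  expect_equal(sum(pep$in_training_31), 31)
  expect_true(all(as.matrix(pep[paste0("p", 1:11)]) %in%
                    residue_vocabulary()))
  expect_true(all(is.na(pep$ec50_nM[pep$censored])))
  expect_true(all(pep$ec50_nM[!pep$censored] > 0))
  # the Aib-11 analog's printed pEC50 agrees with its EC50 within rounding
  dev <- validate_peptides(pep, tol = 0.06)
  expect_false("RXL-3052" %in% dev$id)
  # strict mode flags the records whose printed pEC50 came from separate runs
  expect_error(validate_peptides(pep, strict = TRUE), "disagreement")
  bad <- pep; bad$p3[2] <- "Xyz"
  expect_error(validate_peptides(bad), "Xyz")
  # every training record has an analysis pEC50
  expect_true(all(is.finite(analysis_pec50(pep)[pep$in_training_31])))
})
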