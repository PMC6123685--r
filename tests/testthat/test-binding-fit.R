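test_that("Scatchard analysis is exact on noiseless single-site data", {
  s <- gen_saturation(Bmax = 10, Kd = 5, grid = c(3, 5, 10, 20))
  res <- scatchard_bmax(s$free_nM, s$bound)
  expect_equal(res$Bmax, 10, tolerance = 1e-9)
  expect_equal(res$Kd, 5, tolerance = 1e-9)
  # isotherm identities: F = Kd gives Bmax/2; huge F approaches Bmax
  s2 <- gen_saturation(8, 2, grid = c(2, 2e6, 4))
  expect_equal(scatchard_bmax(s2$free_nM, s2$bound)$Bmax, 8, tolerance = 1e-6)
  # non-saturable (linear) data must be refused
  expect_error(scatchard_bmax(c(1, 2, 4, 8), c(1, 2, 4, 8) * 0.3),
               "no saturable binding")
})

test_that("Scatchard recovers Bmax within 5% at 2% noise", {
  s <- gen_saturation(10, 5, grid = seq(3, 20, length.out = 8),
                      noise_sd = 0.2, seed = 2024)
  res <- scatchard_bmax(s$free_nM, s$bound)
  expect_lt(abs(res$Bmax - 10) / 10, 0.05)
})

test_that("Bmax normalization is plain elementwise division", {
  expect_equal(normalize_to_bmax(c(1, 2, 4), 8), c(0.125, 0.25, 0.5))
  expect_equal(normalize_to_bmax(0, 3), 0)
  expect_error(normalize_to_bmax(1, 0), "invalid normalization")
})

test_that("noiseless curves return the generating parameters exactly", {
  p <- wt_params()
  cv <- gen_binding_curve(p, noise_sd = 0, replicates = 1)
  f <- fit_binding_curve(cv)
  expect_equal(f$status, "ok")
  expect_equal(f$pCa50, 4.79, tolerance = 1e-6)
  expect_equal(f$params$Amax, 0.4, tolerance = 1e-6)
  expect_equal(-log10(f$params$KI), 3, tolerance = 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
})

test_that("fits are invariant to row order and uniform replication", {
  p <- wt_params()
  cv <- gen_binding_curve(p, noise_sd = 0.02, replicates = 4, seed = 7)
  f1 <- fit_binding_curve(cv)
  shuffled <- cv[sample(nrow(cv)), ]
  f2 <- fit_binding_curve(shuffled)
  expect_equal(f2$pCa50, f1$pCa50, tolerance = 1e-8)
  doubled <- rbind(as.data.frame(cv), as.data.frame(cv))
  f3 <- fit_binding_curve(doubled)
  expect_equal(f3$pCa50, f1$pCa50, tolerance = 1e-6)
})

test_that("monophasic mode fits high-salt curves without inactivation", {
  p <- binding_params(0.8, 1e-5, 1e6, 2, 1)   # effectively no I-site
  cv <- gen_binding_curve(p, noise_sd = 0, replicates = 1)
  f <- fit_binding_curve(cv, inactivation = FALSE)
  expect_equal(f$pCa50, 5, tolerance = 1e-6)
  expect_equal(f$params$Amax, 0.8, tolerance = 1e-6)
})

test_that("curves with no binding are flagged not determined", {
  cv <- binding_curve(rep(seq(8, 3, length.out = 6), each = 4),
                      abs(rep(0.002, 24)), rep(1:4, 6))
  f <- fit_binding_curve(cv)
  expect_equal(f$status, "not_determined")
  expect_true(is.na(f$pCa50))
  expect_null(f$params)
})

test_that("pCa50 recovery over many synthetic curves matches the SEM scale", {
  set.seed(2025)
  errs <- replicate(60, {
    pKA <- runif(1, 4.3, 5.7)
    p <- binding_params(runif(1, 0.2, 0.6), 10^(-pKA),
                        10^(-runif(1, 2.5, 3.5)), 2, 1)
    cv <- gen_binding_curve(p, noise_sd = 0.02, replicates = 4,
                            seed = sample.int(1e6, 1))
    fit_binding_curve(cv)$pCa50 - pKA
  })
  expect_lt(median(abs(errs)), 0.03)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("Hill-coefficient selection maximizes summed R-squared", {
  # single-candidate grid is a forced choice
  p <- wt_params()
  cv <- gen_binding_curve(p, noise_sd = 0.01, replicates = 2, seed = 3)
  sel1 <- select_hill_coefficients(list(cv), grid_nA = 2, grid_nI = 1)
  expect_equal(c(sel1$nA, sel1$nI), c(2, 1))
  # noiseless panel generated with nA = 1.5 prefers 1.5 over 2.0
  curves <- lapply(c(4.6, 5.0, 5.4), function(pKA) {
    gen_binding_curve(binding_params(0.4, 10^(-pKA), 1e-3, nA = 1.5, nI = 1),
                      noise_sd = 0, replicates = 1)
  })
  sel2 <- select_hill_coefficients(curves, grid_nA = c(1.5, 2), grid_nI = 1)
  expect_equal(sel2$nA, 1.5)
  # reproducibility: same seeded panel, same selection
  panel <- lapply(1:3, function(i) gen_binding_curve(
    wt_params(), noise_sd = 0.02, replicates = 4, seed = 50 + i))
  a <- select_hill_coefficients(panel, grid_nA = c(1.5, 2, 2.5), grid_nI = c(0.5, 1))
  b <- select_hill_coefficients(panel, grid_nA = c(1.5, 2, 2.5), grid_nI = c(0.5, 1))
  expect_identical(a$sum_r2, b$sum_r2)
  expect_equal(c(a$nA, a$nI), c(b$nA, b$nI))
})

test_that("sensitization table computes shifts, folds, and propagates status", {
  p_wt <- wt_params()
  p_mut <- binding_params(0.4, 10^(-4.79) / 8, 1e-3, 2, 1)
  mk <- function(p, g, cond, seed) {
    fit_binding_curve(gen_binding_curve(p, noise_sd = 0, replicates = 1,
                                        genotype = g, condition = cond))
  }
  fits <- list(mk(p_wt, "WT", "control"), mk(p_wt, "WT", "caffeine-10mM"),
               mk(p_mut, "M8", "control"))
  tab <- sensitization_table(fits)
  wt_row <- tab[tab$genotype == "WT", ]
  expect_equal(wt_row$delta_pCa50, 0, tolerance = 1e-6)
  expect_equal(wt_row$resting_fold_vs_wt, 1, tolerance = 1e-4)
  m_row <- tab[tab$genotype == "M8", ]
  expect_equal(m_row$resting_fold_vs_wt, 63.85, tolerance = 0.1 / 63.85)
  expect_true(is.na(m_row$pCa50_caffeine))
  expect_match(m_row$status, "caffeine:absent")
  # not-determined rows carry NA fields, never zeros
  nd <- fit_binding_curve(binding_curve(rep(seq(8, 3, length.out = 6), each = 2),
                                        rep(0.001, 12), rep(1:2, 6)))
  nd$genotype <- "NULLMUT"; nd$condition <- "control"
  tab2 <- sensitization_table(c(fits, list(nd)))
  nd_row <- tab2[tab2$genotype == "NULLMUT", ]
  expect_true(is.na(nd_row$pCa50_control))
  expect_match(nd_row$status, "not_determined")
  # a missing or failed WT control is an error
  expect_error(sensitization_table(fits[3]), "wild-type control")
})
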