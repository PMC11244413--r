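test_that("structural additivity of NSUR predictions is exact", {
  sim <- sba_simulate(sba_sim_config(n_plots = 80, seed = 41))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  pr <- predict(fit)
  expect_identical(pr$sba_P + pr$sba_B, pr$sba_t)
  # cross-module consistency: the B component equals the bare form predictor
  expect_equal(pr$sba_B,
               sba_eval("M1", fit$species$B$coefficients,
                        sim$table$si_B, sim$table$adbh_B, sim$table$sdi_B),
               tolerance = 1e-12)
})

test_that("with an identity covariance one iteration equals stacked OLS", {
  sim <- sba_simulate(sba_sim_config(n_plots = 100, seed = 43, rho = 0.6))
  # stacked OLS separates across equations with no shared parameters, so
  # the independent equation-wise fits are the oracle
  nlsP <- sba_nls("M6", sim$table, stratum = "P", seed = 5)
  nlsB <- sba_nls("M1", sim$table, stratum = "B", seed = 5)
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table, sigma = "identity",
                  max_fgls_iter = 1,
                  start = list(P = nlsP$coefficients, B = nlsB$coefficients))
  expect_equal(fit$species$P$coefficients, nlsP$coefficients,
               tolerance = 1e-8)
  expect_equal(fit$species$B$coefficients, nlsB$coefficients,
               tolerance = 1e-8)
})

test_that("independent errors make NSUR coincide with equation-wise NLS", {
  sim <- sba_simulate(sba_sim_config(n_plots = 400, seed = 47, rho = 0,
                                     sigma_P = 0.6, sigma_B = 0.4))
  nlsB <- sba_nls("M1", sim$table, stratum = "B",
                  start = truth_nsur_B, control = sba_control(n_starts = 1))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  # fully identified B equation: NSUR estimates within 2 NLS SEs
  expect_true(all(abs(fit$species$B$coefficients - nlsB$coefficients)
                  <= 2 * nlsB$se))
  # estimated cross-equation covariance near zero (2/sqrt(n) bound)
  expect_lt(abs(fit$sigma[1, 2]), 2 / sqrt(400))
  # and the error variances are recovered
  expect_equal(sqrt(fit$sigma[1, 1]), 0.6, tolerance = 0.1)
  expect_equal(sqrt(fit$sigma[2, 2]), 0.4, tolerance = 0.1)
})

test_that("the generalized objective is non-increasing within FGLS steps", {
  sim <- sba_simulate(sba_sim_config(n_plots = 150, seed = 53, rho = 0.7))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  expect_gte(fit$n_fgls_iter, 1)
  expect_true(all(fit$trace[, "obj_after"]
                  <= fit$trace[, "obj_before"] + 1e-8))
  expect_true(all(eigen(fit$sigma, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_equal(fit$sigma, t(fit$sigma))
})

test_that("cross-correlation yields an NSUR efficiency gain over NLS", {
  sim <- sba_simulate(sba_sim_config(n_plots = 400, seed = 59, rho = 0.8,
                                     sigma_P = 0.6, sigma_B = 0.4))
  ctrl <- sba_control(n_starts = 1)
  nls_fits <- list(
    P = sba_nls("M6", sim$table, stratum = "P", start = truth_nsur_P,
                control = ctrl),
    B = sba_nls("M1", sim$table, stratum = "B", start = truth_nsur_B,
                control = ctrl))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  eg <- efficiency_gain(fit, nls_fits)
  expect_lt(median(eg$ratio, na.rm = TRUE), 1)

  # without cross-correlation the ratios sit near one
  sim0 <- sba_simulate(sba_sim_config(n_plots = 400, seed = 61, rho = 0,
                                      sigma_P = 0.6, sigma_B = 0.4))
  nls0 <- list(
    P = sba_nls("M6", sim0$table, stratum = "P", start = truth_nsur_P,
                control = ctrl),
    B = sba_nls("M1", sim0$table, stratum = "B", start = truth_nsur_B,
                control = ctrl))
  fit0 <- sba_nsur(c(P = "M6", B = "M1"), sim0$table,
                   start = list(P = truth_nsur_P, B = truth_nsur_B))
  eg0 <- efficiency_gain(fit0, nls0)
  # identified Korf B equation: near-unit ratios
  expect_true(all(abs(eg0$ratio[eg0$species == "B"] - 1) < 0.1))

  wrong <- list(P = nls_fits$B, B = nls_fits$B)
  expect_error(efficiency_gain(fit, wrong), "mismatched")
})

test_that("including the measured total uses a ridge-stabilised covariance", {
  sim <- sba_simulate(sba_sim_config(n_plots = 120, seed = 67))
  fit <- sba_nsur(c(P = "M6", B = "M1"), sim$table, include_total = TRUE,
                  start = list(P = truth_nsur_P, B = truth_nsur_B))
  expect_true(fit$converged)
  expect_identical(dim(fit$sigma_full), c(3L, 3L))
  # the 3x3 covariance is invertible despite eps_t = eps_P + eps_B
  expect_true(all(eigen(fit$sigma_full, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})
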