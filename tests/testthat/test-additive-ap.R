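ap_config <- function(n, seed, sigma_P = 0.5, sigma_B = 0.5, rho = 0.5)
  sba_sim_config(n_plots = n, seed = seed, structure = "proportional",
                 forms = list(P = "M6", B = "M1"),
                 coefs = list(P = truth_ap_P, B = truth_ap_B),
                 total_form = "M1", total_coef = truth_ap_t,
                 sigma_P = sigma_P, sigma_B = sigma_B, rho = rho)

test_that("noiseless share-structured data is reproduced exactly", {
  sim <- sba_simulate(ap_config(50, seed = 31, sigma_P = 0, sigma_B = 0))
  fit <- sba_ap("M1", c(P = "M6", B = "M1"), sim$table, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$sse_species, 1e-10)
  pr <- predict(fit)
  expect_equal(pr$sba_P, sim$table$sba_P, tolerance = 1e-5)
  expect_equal(pr$sba_B, sim$table$sba_B, tolerance = 1e-5)
})

test_that("identical species equations split the total in half", {
  cov <- data.frame(si = c(12, 16), adbh = c(25, 35), sdi = c(300, 500))
  pr <- predict_additive("ap",
    species_forms = list(P = sba_form("M1"), B = sba_form("M1")),
    species_coefs = list(P = truth_ap_B, B = truth_ap_B),
    newdata = list(P = cov, B = cov, t = cov),
    total_form = "M1", total_coef = truth_ap_t)
  expect_equal(pr$sba_P, pr$sba_t / 2, tolerance = 1e-12)
  expect_equal(pr$sba_B, pr$sba_t / 2, tolerance = 1e-12)
})

test_that("AP predictions match a hand evaluation of the share formula", {
  covP <- data.frame(si = 14.7, adbh = 26, sdi = 469.2)
  covB <- data.frame(si = 14.8, adbh = 29, sdi = 242.7)
  covt <- data.frame(si = 15.8, adbh = 28, sdi = 698.3)
  pr <- predict_additive("ap",
    species_forms = list(P = sba_form("M6"), B = sba_form("M1")),
    species_coefs = list(P = truth_ap_P, B = truth_ap_B),
    newdata = list(P = covP, B = covB, t = covt),
    total_form = "M1", total_coef = truth_ap_t)
  # second, independent implementation of the weight structure
  fP <- truth_ap_P[1] * covP$si^truth_ap_P[2] *
    (1 - exp(-truth_ap_P[3] * (covP$sdi / 1000)^truth_ap_P[4] *
               covP$adbh))^truth_ap_P[5]
  fB <- m1_by_hand(truth_ap_B, covB$si, covB$adbh, covB$sdi)
  ft <- m1_by_hand(truth_ap_t, covt$si, covt$adbh, covt$sdi)
  expect_equal(pr$sba_t, ft, tolerance = 1e-12)
  expect_equal(pr$sba_P, fP / (fP + fB) * ft, tolerance = 1e-12)
  expect_equal(pr$sba_B, fB / (fP + fB) * ft, tolerance = 1e-12)
})

test_that("share weights are invariant to a common rescaling of both species", {
  cov <- list(P = data.frame(si = c(12, 18), adbh = c(20, 40),
                             sdi = c(250, 600)),
              B = data.frame(si = c(13, 17), adbh = c(22, 38),
                             sdi = c(150, 400)),
              t = data.frame(si = c(12.5, 17.5), adbh = c(21, 39),
                             sdi = c(400, 1000)))
  forms <- list(P = sba_form("M6"), B = sba_form("M1"))
  base <- predict_additive("ap", forms,
    list(P = truth_ap_P, B = truth_ap_B), cov,
    total_form = "M1", total_coef = truth_ap_t)
  for (c_ in c(0.1, 7, 1000)) {
    scaled_P <- truth_ap_P; scaled_P[1] <- scaled_P[1] * c_
    scaled_B <- truth_ap_B; scaled_B[1] <- scaled_B[1] * c_
    pr <- predict_additive("ap", forms,
      list(P = scaled_P, B = scaled_B), cov,
      total_form = "M1", total_coef = truth_ap_t)
    expect_equal(pr, base, tolerance = 1e-10)
  }
})

test_that("AP recovers the share structure on proportionally generated data", {
  sim <- sba_simulate(ap_config(300, seed = 77))
  fit <- sba_ap("M1", c(P = "M6", B = "M1"), sim$table, seed = 2)
  expect_true(fit$converged)
  expect_true(fit$rank_deficient)  # common species scale not identified
  # total-equation coefficients recovered within 3 SE (fully identified)
  ft <- fit$total_fit
  expect_true(all(abs(coef(ft) - truth_ap_t) <= 3 * ft$se))
  # the fitted share surface tracks the generating shares closely
  pr <- predict(fit)
  w_hat <- pr$sba_P / pr$sba_t
  w_true <- sim$truth$mu_P / (sim$truth$mu_P + sim$truth$mu_B)
  expect_lt(max(abs(w_hat - w_true)), 0.05)
  # the identified B-equation shape coefficients are recovered within 3 SE
  dB <- abs(fit$species$B$coefficients - truth_ap_B)[-1]
  expect_true(all(dB <= 3 * fit$species$B$se[-1]))
})

test_that("simultaneous three-equation estimation agrees with two stages", {
  sim <- sba_simulate(ap_config(150, seed = 55))
  two <- sba_ap("M1", c(P = "M6", B = "M1"), sim$table, seed = 3)
  one <- sba_ap("M1", c(P = "M6", B = "M1"), sim$table, seed = 3,
                simultaneous = TRUE)
  expect_true(one$converged)
  # same model space; predictions should agree closely though the
  # objectives differ (joint vs staged)
  expect_equal(predict(one)$sba_t, predict(two)$sba_t, tolerance = 0.05)
})
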