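test_that("Reineke SDI matches its closed form and rejects bad input", {
  expect_equal(reineke_sdi(500, 20), 500)  # dg at reference diameter
  expect_equal(reineke_sdi(1000, 10), 1000 * (20 / 10)^(-1.605),
               tolerance = 1e-12)
  # strictly increasing in dg for fixed stem count
  dg <- seq(5, 40, by = 1)
  expect_true(all(diff(reineke_sdi(800, dg)) > 0))
  expect_error(reineke_sdi(0, 15), "positive")
  expect_error(reineke_sdi(500, -2), "positive")
})

test_that("form registry reports parameter counts and SDI scaling", {
  counts <- c(korf = 3, schumacher = 2, richards = 3,
              M1 = 4, M2 = 4, M3 = 6, M4 = 6, M5 = 5, M6 = 5)
  for (id in names(counts))
    expect_identical(sba_form(id)$n_params, as.integer(counts[[id]]))
  for (id in sba_forms())
    expect_identical(sba_form(id)$sdi_scaled, id %in% c("M2", "M4", "M6"))
})

test_that("extended forms match independent hand evaluations", {
  # all covariate effects switched off leaves the scale parameter
  expect_equal(sba_eval("M1", c(7.3, 0, 0, 0), 12, 30, 400), 7.3)
  # Korf M1 with the published B-equation coefficients at the mean covariates
  got <- sba_eval("M1", truth_nsur_B, mean_cov_B$si, mean_cov_B$adbh,
                  mean_cov_B$sdi)
  expect_equal(got, m1_by_hand(truth_nsur_B, 14.8, 29, 242.7),
               tolerance = 1e-12)
  expect_equal(got, 6.9, tolerance = 0.01)
  # Richards bracket collapses to zero when the rate parameter is zero
  expect_equal(sba_eval("M6", c(20, 0.3, 0, 2, 0.5), 15, 30, 500), 0)
  # Schumacher / Korf / Richards base forms against direct arithmetic
  expect_equal(sba_eval("schumacher", c(30, 12), 15, 25, 400),
               30 * exp(-12 / 25), tolerance = 1e-12)
  expect_equal(sba_eval("korf", c(30, 5, 0.7), 15, 25, 400),
               30 * exp(-5 * 25^(-0.7)), tolerance = 1e-12)
  expect_equal(sba_eval("richards", c(30, 0.04, 1.4), 15, 25, 400),
               30 * (1 - exp(-0.04 * 25))^1.4, tolerance = 1e-12)
  # M3 Schumacher extension with age-varying exponents
  b3 <- c(-3.377, -30.547, 0.801, 0.452, 6.049, -4.446)
  expect_equal(sba_eval("M3", b3, 15.8, 28, 698.3),
               exp(-3.377 - 30.547 / 28) * 698.3^(0.801 + 6.049 / 28) *
                 15.8^(0.452 - 4.446 / 28),
               tolerance = 1e-12)
})

test_that("M1 predictions are monotone in SDI and ADBH for positive rates", {
  b <- c(0.01, 0.3, 4, 1.05)  # b2 > 0, b3 > 0
  sdi <- seq(100, 900, by = 50)
  expect_true(all(diff(sba_eval("M1", b, 15, 30, sdi)) > 0))
  adbh <- seq(15, 45, by = 1)
  expect_true(all(diff(sba_eval("M1", b, 15, adbh, 400)) > 0))
})

test_that("SDI/1000 variants equal unscaled variants after rescaling b0", {
  grid <- expand.grid(si = c(9, 15, 21), adbh = c(15, 28, 42),
                      sdi = c(120, 450, 800))
  b1 <- c(0.013, 0.289, 4.454, 1.029)
  b2 <- b1; b2[1] <- b1[1] * 1000^b1[4]
  expect_equal(sba_eval("M2", b2, grid$si, grid$adbh, grid$sdi),
               sba_eval("M1", b1, grid$si, grid$adbh, grid$sdi),
               tolerance = 1e-10)
})

test_that("Richards forms approach the site asymptote b0 * SI^b1 at old age", {
  b5 <- c(25, 0.25, 0.01, 1.5, 0.8)
  expect_equal(sba_eval("M5", b5, 16, 1e6, 500), 25 * 16^0.25,
               tolerance = 1e-6)
  b6 <- c(25, 0.25, 0.5, 1.5, 0.8)
  expect_equal(sba_eval("M6", b6, 16, 1e6, 500), 25 * 16^0.25,
               tolerance = 1e-6)
})

test_that("evaluation declines on invalid parameters or overflow", {
  expect_error(sba_eval("M1", c(0.01, 0.3, 4), 15, 30, 400), "parameters")
  expect_error(sba_eval("M1", c(-1, 0.3, 4, 1), 15, 30, 400), "positive")
  # extreme exponent overflows past the log-space guard and carries covariates
  err <- tryCatch(sba_eval("M1", c(1, 300, 0, 0), 20, 30, 400),
                  sba_eval_error = function(e) e)
  expect_s3_class(err, "sba_eval_error")
  expect_true(is.data.frame(err$covariates))
  expect_error(sba_eval("M6", c(20, 0.3, -0.1, 2, 0.5), 15, 30, 500),
               "non-negative")
  expect_error(sba_eval("M1", c(0.01, 0.3, 4, 1), -5, 30, 400), "positive")
})
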