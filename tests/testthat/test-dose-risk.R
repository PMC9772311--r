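# Expected values below are frozen from independent hand/spreadsheet
# arithmetic of the four dose/risk equations at the cohort means:
#   CDI = 0.039*16*29.66*301.06 / (74.45*9000)  = 8.3158e-3
#   CR  = CDI * 0.6                              = 4.9895e-3
#   EC  = 0.039*10.81*29.66*301.06 / 216000      = 1.7429e-2
#   HQ  = EC / 2.0e-3                            = 8.7143
test_that("dose and risk equations reproduce hand-computed cohort values", {
  f <- mean_factors_bd
  cdi <- chronic_daily_intake(f)
  ec <- exposure_concentration(f)
  expect_equal(cdi, 8.3158e-3, tolerance = 1e-4)
  expect_equal(ec, 1.7429e-2, tolerance = 1e-4)
  expect_equal(cancer_risk(cdi, bd_preset$tox), 4.9895e-3, tolerance = 1e-4)
  expect_equal(hazard_quotient(ec, bd_preset$tox), 8.7143, tolerance = 1e-4)

  # styrene: CDI = 12.108*16*29.66*301.06/670050 = 2.5817;
  # CR = CDI * 5.7e-4 = 1.4716e-3; HQ = EC / 1.0 = 5.4110
  fs <- mean_factors_st
  expect_equal(cancer_risk(chronic_daily_intake(fs), st_preset$tox),
               1.4716e-3, tolerance = 1e-4)
  expect_equal(hazard_quotient(exposure_concentration(fs), st_preset$tox),
               5.4110, tolerance = 1e-4)
})

test_that("zero concentration and linearity limits hold", {
  f0 <- cohort_mean_factors(C = 0)
  expect_identical(chronic_daily_intake(f0), 0)
  expect_identical(exposure_concentration(f0), 0)
  f2 <- cohort_mean_factors(C = 2 * 0.039)
  expect_equal(chronic_daily_intake(f2),
               2 * chronic_daily_intake(mean_factors_bd), tolerance = 1e-12)
  expect_equal(exposure_concentration(f2),
               2 * exposure_concentration(mean_factors_bd),
               tolerance = 1e-12)
  # continuous exposure: ET = 24, EF = 365, ED*8760 = AT_hours => EC = C
  fc <- exposure_factors(C = 5, IR = 16, ED = 10, EF = 365, BW = 70,
                         ET = 24, AT_days = 3650)
  expect_equal(exposure_concentration(fc), 5, tolerance = 1e-12)
})

test_that("CDI scales inversely with body weight; cross-check ratio holds", {
  f1 <- cohort_mean_factors()
  f2 <- exposure_factors(C = 0.039, IR = 16, ED = 29.66, EF = 301.06,
                         BW = 2 * 74.45, ET = 10.81, AT_days = 9000)
  expect_equal(chronic_daily_intake(f2), chronic_daily_intake(f1) / 2,
               tolerance = 1e-12)
  # closed form: EC/CDI = (ET * BW * AT_days) / (IR * AT_hours)
  expect_equal(exposure_concentration(f1) / chronic_daily_intake(f1),
               (10.81 * 74.45 * 9000) / (16 * 216000), tolerance = 1e-12)
})

test_that("risk classification applies the boundary conventions", {
  res <- data.frame(CR = c(5.13e-3, 1e-6, 9.9e-7),
                    HQ = c(8.67, 0.99, 1.0))
  out <- classify_risk(res)
  expect_identical(out$cr_acceptable, c(FALSE, TRUE, TRUE))
  expect_identical(out$hq_acceptable, c(FALSE, TRUE, FALSE))
  full <- assess_risk(mean_factors_bd, bd_preset$tox)
  expect_false(full$cr_acceptable)
  expect_false(full$hq_acceptable)
  expect_error(classify_risk(res, cr_threshold = 0), "positive")
})

test_that("equations accept aligned vectors without change of semantics", {
  f <- exposure_factors(C = c(0.039, 12.108), IR = 16,
                        ED = c(29.66, 29.66), EF = 301.06,
                        BW = c(74.45, 74.45), ET = 10.81, AT_days = 9000)
  cdi <- chronic_daily_intake(f)
  expect_length(cdi, 2L)
  expect_equal(cdi[1L], chronic_daily_intake(mean_factors_bd),
               tolerance = 1e-12)
  expect_equal(cdi[2L], chronic_daily_intake(mean_factors_st),
               tolerance = 1e-12)
})

test_that("factor invariants are enforced", {
  expect_error(cohort_mean_factors(C = -1), "non-negative")
  expect_error(exposure_factors(C = 1, ED = 30, EF = 400, BW = 70,
                                ET = 8, AT_days = 9000), "EF")
  expect_error(exposure_factors(C = 1, ED = 30, EF = 300, BW = 70,
                                ET = 25, AT_days = 9000), "ET")
  expect_error(exposure_factors(C = 1, ED = 30, EF = 300, BW = 0,
                                ET = 8, AT_days = 9000), "BW")
  expect_error(tox_profile("X", SF = -1, RfC = 1), "non-negative")
  expect_error(tox_profile("X", SF = 1, RfC = 0), "positive")
})
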