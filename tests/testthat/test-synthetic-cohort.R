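test_that("default cohort has the study's counts and record structure", {
  study <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(study$workers), 75L)
  expect_equal(sum(study$records$analyte == "BD"), 225L)
  expect_equal(sum(study$records$analyte == "ST"), 225L)
  expect_equal(sum(study$blanks$analyte == "BD"), 22L)
  expect_true(all(study$records$duration >= 70 &
                    study$records$duration <= 120))
  expect_true(all(study$records$flow_rate == 0.2))
  # blanks stay well under 1% of the typical front mass
  for (a in c("BD", "ST")) {
    rec <- study$records[study$records$analyte == a, ]
    expect_lt(rec$blank_mass[1L], 0.01 * stats::median(rec$mass_front))
  }
})

test_that("tiny and degenerate cohorts behave", {
  tiny <- generate_cohort(cohort_spec(n_workers = 1, samples_per_worker = 1,
                                      n_blanks = 0, seed = 2))
  expect_equal(nrow(tiny$records), 2L)  # one per analyte
  # zero-variance spec: every worker sits at the cohort means and
  # concentrations recover exactly
  pt <- cohort_spec(
    n_workers = 5, seed = 3,
    factor_distributions = list(
      BW = dist_spec("BW", "point", value = 74.45),
      ED = dist_spec("ED", "point", value = 29.66),
      EF = dist_spec("EF", "point", value = 301.06),
      ET = dist_spec("ET", "point", value = 10.81)),
    concentration_distributions = list(
      BD = dist_spec("C", "point", value = 0.039)),
    recovery = c(BD = 0.87))
  study <- generate_cohort(pt)
  expect_true(all(study$workers$BW == 74.45))
  rep <- recover_parameters(study)
  expect_true(all(rep$within_k_se))
  expect_true(all(abs(rep$rel_error) < 1e-9))
})

test_that("processing the records inverts the mass equation exactly", {
  study <- generate_cohort(cohort_spec(seed = 4))
  conc <- concentration_from_record(study$records)
  expect_equal(conc, study$truth$c_true, tolerance = 1e-10)
})

test_that("parameter recovery is unbiased across seeds", {
  # the generate -> process -> estimate round trip should sit within 3 SE
  # of truth in the vast majority of runs (each check is a ~99.7% interval)
  reports <- lapply(1:10, function(s) {
    recover_parameters(generate_cohort(cohort_spec(seed = s)))
  })
  flags <- do.call(rbind, reports)$within_k_se
  expect_gt(mean(flags), 0.95)
})

test_that("mass noise produces spread but no systematic bias", {
  spec <- cohort_spec(seed = 5, mass_noise_gsd = 1.2)
  study <- generate_cohort(spec)
  conc <- concentration_from_record(study$records)
  expect_gt(stats::sd(conc / study$truth$c_true), 0.05)
  # multiplicative noise is mean-one by construction
  expect_equal(mean(conc / study$truth$c_true), 1, tolerance = 0.05)
})

test_that("analysing with the wrong recovery shows the expected bias", {
  study <- generate_cohort(cohort_spec(seed = 6))
  rec <- study$records[study$records$analyte == "BD", ]
  truth <- study$truth$c_true[study$records$analyte == "BD"]
  wrong <- rec
  wrong$recovery <- 1.0   # generated at 0.87, analysed at 1.0
  biased <- concentration_from_record(wrong)
  expect_equal(mean(biased / truth), 0.87, tolerance = 1e-6)
})

test_that("doubling true concentrations doubles downstream mean risk", {
  half <- cohort_spec(seed = 7, concentration_distributions = list(
    BD = dist_spec("C", "lognormal", mean = 0.039, gsd = 2.5)))
  dbl <- cohort_spec(seed = 7, concentration_distributions = list(
    BD = dist_spec("C", "lognormal", mean = 0.078, gsd = 2.5)))
  m1 <- mean(shift_concentrations(generate_cohort(half)$records)$concentration)
  m2 <- mean(shift_concentrations(generate_cohort(dbl)$records)$concentration)
  expect_equal(m2 / m1, 2, tolerance = 1e-9)
  cr1 <- assess_risk(cohort_mean_factors(C = m1), bd_preset$tox)$CR
  cr2 <- assess_risk(cohort_mean_factors(C = m2), bd_preset$tox)$CR
  expect_equal(cr2 / cr1, 2, tolerance = 1e-9)
})

test_that("identical spec and seed give identical studies", {
  a <- generate_cohort(cohort_spec(seed = 8))
  b <- generate_cohort(cohort_spec(seed = 8))
  expect_identical(a$records, b$records)
  expect_identical(a$workers, b$workers)
})

test_that("cohort spec validation rejects inconsistent inputs", {
  expect_error(cohort_spec(n_workers = 0), "counts")
  expect_error(cohort_spec(recovery = c(BD = 1.2, ST = 0.89)), "recovery")
  expect_error(cohort_spec(duration_range = c(120, 70)), "duration_range")
  expect_error(cohort_spec(mass_noise_gsd = 0.9), "mass_noise_gsd")
  expect_error(
    cohort_spec(concentration_distributions = list(
      XX = dist_spec("C", "point", value = 1))),
    "recovery")
})
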