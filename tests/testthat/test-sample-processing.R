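one_record <- function(front, rear = 0, blank = 0, flow = 0.2,
                       duration = 120, recovery = 0.87,
                       worker = "W001", analyte = "BD") {
  sampling_records(worker, analyte, front, rear, blank, flow, duration,
                   recovery)
}

test_that("record reduction applies blank and recovery corrections", {
  # hand arithmetic: (0.50 + 0.02 - 0.005) / (0.87 * 0.2 * 120)
  r <- one_record(0.50, 0.02, 0.005)
  expect_equal(concentration_from_record(r), 0.02467, tolerance = 1e-3)
  expect_identical(concentration_from_record(one_record(0, 0, 0)), 0)
  # blank exceeding the sample mass floors at zero, never negative
  expect_identical(concentration_from_record(one_record(0.1, 0, 0.5)), 0)
})

test_that("record reduction is monotone in each physical direction", {
  base <- concentration_from_record(one_record(0.50, 0.02, 0.005))
  expect_gt(concentration_from_record(one_record(0.60, 0.02, 0.005)), base)
  expect_gt(concentration_from_record(one_record(0.50, 0.10, 0.005)), base)
  expect_lt(concentration_from_record(one_record(0.50, 0.02, 0.05)), base)
  expect_lt(concentration_from_record(one_record(0.50, 0.02, 0.005,
                                                 recovery = 0.95)), base)
  expect_lt(concentration_from_record(one_record(0.50, 0.02, 0.005,
                                                 flow = 0.3)), base)
  expect_lt(concentration_from_record(one_record(0.50, 0.02, 0.005,
                                                 duration = 200)), base)
})

test_that("record invariants are enforced", {
  expect_error(one_record(-0.1), "non-negative")
  expect_error(one_record(0.5, flow = 0), "flow_rate")
  expect_error(one_record(0.5, duration = -10), "duration")
  expect_error(one_record(0.5, recovery = 0), "recovery")
  expect_error(one_record(0.5, recovery = 1.2), "recovery")
})

test_that("breakthrough flag uses the rear/front criterion", {
  expect_true(breakthrough_flag(one_record(400, 50), threshold = 0.10))
  expect_false(breakthrough_flag(one_record(400, 0), threshold = 0.10))
  expect_false(breakthrough_flag(one_record(0, 0), threshold = 0.10))
  # boundary: rear exactly at threshold * front is not flagged
  expect_false(breakthrough_flag(one_record(400, 40), threshold = 0.10))
  expect_error(breakthrough_flag(one_record(1, 0), threshold = 1.5), "0, 1")
})

test_that("shift averaging weights by duration and bounds the result", {
  # equal durations: plain mean
  eq <- sampling_records(rep("W001", 3), rep("BD", 3),
                         c(0.03, 0.04, 0.05) * 0.87 * 0.2 * 100,
                         0, 0, 0.2, 100, 0.87)
  expect_equal(shift_average(eq)$concentration, 0.04, tolerance = 1e-9)
  # durations 70 and 120 with concentrations 0.10 and 0.01:
  # (70*0.10 + 120*0.01) / 190 = 0.043158 by hand
  uneq <- sampling_records(rep("W001", 2), rep("BD", 2),
                           c(0.10 * 0.87 * 0.2 * 70,
                             0.01 * 0.87 * 0.2 * 120),
                           0, 0, 0.2, c(70, 120), 0.87)
  expect_equal(shift_average(uneq)$concentration, 0.0432, tolerance = 1e-3)
  expect_equal(shift_average(uneq, weighted = FALSE)$concentration, 0.055,
               tolerance = 1e-9)
  # single record: identity
  single <- one_record(0.50, 0.02, 0.005)
  expect_equal(shift_average(single)$concentration,
               concentration_from_record(single))
  # the average always lies within the member range
  set.seed(42)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    r <- sampling_records(rep("W", n), rep("BD", n), runif(n, 0, 2),
                          runif(n, 0, 0.1), runif(n, 0, 0.01), 0.2,
                          runif(n, 70, 120), 0.87)
    conc <- concentration_from_record(r)
    avg <- shift_average(r)$concentration
    expect_gte(avg, min(conc))
    expect_lte(avg, max(conc))
  }
})

test_that("shift averaging rejects empty and mixed groups", {
  r <- sampling_records(c("A", "B"), "BD", 0.5, 0, 0, 0.2, 100, 0.87)
  expect_error(shift_average(r), "one worker_id")
  r2 <- sampling_records("A", c("BD", "ST"), 0.5, 0, 0, 0.2, 100, 0.87)
  expect_error(shift_average(r2), "one worker_id and one analyte")
  expect_error(shift_average(r[0, ]), "at least one record")
})

test_that("shift_concentrations groups by worker and analyte, OR-ing flags", {
  r <- sampling_records(
    worker_id = c("W1", "W1", "W2", "W1"),
    analyte = c("BD", "BD", "BD", "ST"),
    mass_front = c(0.5, 0.4, 400, 0.6), mass_rear = c(0, 0.2, 0, 0),
    blank_mass = 0, flow_rate = 0.2, duration = 100,
    recovery = c(0.87, 0.87, 0.87, 0.89))
  out <- shift_concentrations(r)
  expect_equal(nrow(out), 3L)
  expect_equal(out$n_samples[out$worker_id == "W1" & out$analyte == "BD"], 2L)
  expect_true(out$breakthrough_flagged[out$worker_id == "W1" &
                                         out$analyte == "BD"])
  expect_false(out$breakthrough_flagged[out$worker_id == "W2"])
})

test_that("sampling-record CSV round trip preserves the table", {
  r <- sampling_records(c("W1", "W2"), "BD", c(0.5, 0.6), c(0, 0.01),
                        0.005, 0.2, c(70, 120), 0.87)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sampling_records(r, path)
  back <- read_sampling_records(path)
  expect_equal(back$mass_front, r$mass_front)
  expect_equal(back$duration, r$duration)
  expect_equal(concentration_from_record(back), concentration_from_record(r))
  # a malformed header is reported by column name
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(worker_id = "W1"), bad, row.names = FALSE)
  expect_error(read_sampling_records(bad), "missing columns")
})
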