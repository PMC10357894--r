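test_that("two-column files read back as written, up- and down-sweep", {
  f <- withr::local_tempfile(fileext = ".dat")
  field <- seq(3203, by = 1, length.out = 32)
  intensity <- sin(field / 5)
  writeLines(c("# comment", "; another", paste(field, intensity)), f)
  s <- read_spectrum(f)
  expect_equal(s$field, field)
  expect_equal(s$intensity, intensity)

  writeLines(paste(rev(field), rev(intensity)), f)
  expect_message(s2 <- read_spectrum(f), "reversed")
  expect_equal(s2$field, field)
  expect_equal(s2$intensity, intensity)
  expect_true(s2$meta$reversed)
})

test_that("parse errors name the offending line; short files rejected", {
  f <- withr::local_tempfile(fileext = ".dat")
  rows <- paste(seq(100, by = 1, length.out = 20), 0.5)
  rows[7] <- "100 banana"
  writeLines(rows, f)
  expect_error(read_spectrum(f), "line 7")

  writeLines(paste(1:8, 1:8), f)
  expect_error(read_spectrum(f), "at least 16")
})

test_that("csv dialect with header and mT conversion work", {
  f <- withr::local_tempfile(fileext = ".csv")
  field <- seq(320, by = 0.1, length.out = 20)
  writeLines(c("field_g,intensity", paste(field, 1:20, sep = ",")), f)
  s <- read_spectrum(f, dialect = "csv")
  expect_equal(s$field, field)
  s10 <- read_spectrum(f, mT = TRUE)
  expect_equal(s10$field, field * 10)
})

test_that("spectrum writers round-trip at full precision", {
  s <- single_line_spectrum(n = 64, range = c(3290, 3310))
  for (fmt in c("two_column_ascii", "csv")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_spectrum(s, f, fmt)
    s2 <- read_spectrum(f, dialect = if (fmt == "csv") "csv" else "auto")
    expect_identical(s2$field, s$field)
    expect_identical(s2$intensity, s$intensity)
  }
})

test_that("to_uniform is the identity on uniform dyadic input", {
  field <- seq(3000, by = 0.5, length.out = 1024)
  s <- esr_spectrum(field, rnorm(1024))
  u <- to_uniform(s)
  expect_identical(u$intensity, s$intensity)
  expect_identical(c(u$pad_left, u$pad_right), c(0L, 0L))
  expect_identical(to_uniform(u), u)   # idempotent
})

test_that("non-dyadic input pads to the next power of two", {
  field <- seq(3000, by = 0.5, length.out = 1000)
  u <- to_uniform(esr_spectrum(field, rnorm(1000)))
  expect_length(u$intensity, 1024)
  expect_identical(u$pad_left + u$pad_right, 24L)
  expect_equal(abs(u$pad_left - u$pad_right) <= 1L, TRUE)
  expect_equal(u$step_gauss, 0.5)
})

test_that("non-uniform grids resample to the median step, matching approx", {
  field <- c(seq(0, 9.9, by = 0.1), seq(10.2, 14.9, by = 0.3),
             seq(15, 20, by = 0.1))
  y <- sin(field)
  s <- esr_spectrum(field, y)
  u <- to_uniform(s)
  expect_equal(u$step_gauss, 0.1)
  core <- strip_pads(u)
  oracle <- approx(field, y, xout = core$field, rule = 2)$y
  expect_equal(core$intensity, oracle, tolerance = 1e-12)
})

test_that("stripping pads restores the resampled signal exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(500:1500, 1)
    field <- seq(2500, by = 0.37, length.out = n)
    s <- esr_spectrum(field, rnorm(n))
    u <- to_uniform(s)
    core <- strip_pads(u)
    expect_equal(core$intensity,
                 approx(field, s$intensity, xout = core$field, rule = 2)$y,
                 tolerance = 1e-12)
    expect_true(all(core$field >= u$original_range[1] - 1e-9))
    expect_true(all(core$field <= u$original_range[2] + 1e-9))
  }
})

test_that("spectrum validation rejects malformed input", {
  expect_error(esr_spectrum(1:20, 1:19), "same length")
  expect_error(esr_spectrum(c(1:10, 10:1), rep(0, 20)), "increasing")
  expect_error(esr_spectrum(1:20, 1:20, mw_frequency_ghz = -1), "positive")
})
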