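test_that("stick patterns follow the first-order multiplicity rule", {
  s1 <- spin_system(center = 3300,
                    couplings = list(list(A = 16, I = 1, n = 1)))
  st <- stick_pattern(s1)
  expect_equal(st$position, c(3284, 3300, 3316))
  expect_equal(st$intensity, rep(1 / 3, 3))

  s2 <- spin_system(center = 0,
                    couplings = list(list(A = 10, I = 1, n = 2)))
  expect_equal(stick_pattern(s2)$intensity, c(1, 2, 3, 2, 1) / 9)

  s3 <- spin_system(center = 0,
                    couplings = list(list(A = 2, I = 0.5, n = 4)))
  expect_equal(stick_pattern(s3)$intensity, c(1, 4, 6, 4, 1) / 16)
})

test_that("stick patterns agree with brute-force quantum-number enumeration", {
  for (I in c(0.5, 1, 1.5)) for (n in 1:6) {
    st <- stick_pattern(spin_system(center = 100,
                                    couplings = list(list(A = 3, I = I, n = n))))
    oracle <- brute_force_sticks(100, 3, I, n)
    expect_equal(nrow(st), as.integer(2 * n * I + 1))
    expect_equal(st$position, oracle$position)
    expect_equal(st$intensity, oracle$intensity, tolerance = 1e-12)
  }
})

test_that("nested couplings multiply multiplicities and conserve intensity", {
  s <- spin_system(center = 3258.5,
                   couplings = list(list(A = 37, I = 1.5, n = 1),
                                    list(A = 26.5, I = 1, n = 2)))
  st <- stick_pattern(s)
  expect_equal(nrow(st), 20L)   # 4 x 5
  expect_equal(sum(st$intensity), 1)
  expect_error(spin_system(center = 0,
                           couplings = list(list(A = 1, I = 10, n = 500))),
               "10\\^4")
})

test_that("a noiseless derivative line is antisymmetric about its center", {
  s <- render_spectrum(sim_recipe(list(
    spin_system(center = 3000, lineshape = "lorentzian", linewidth = 4)),
    c(2900, 3100), 1025))
  i0 <- which.min(abs(s$field - 3000))
  for (k in 1:300)
    expect_equal(s$intensity[i0 + k], -s$intensity[i0 - k], tolerance = 1e-8)
})

test_that("rendering is deterministic and leaves the global RNG untouched", {
  rec <- sim_recipe(list(spin_system(center = 50, linewidth = 2)),
                    c(0, 100), 256, noise_sigma = 0.05, seed = 99)
  a <- render_spectrum(rec)
  b <- render_spectrum(rec)
  expect_identical(a$intensity, b$intensity)

  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(render_spectrum(rec)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("noise level matches the requested fraction of the signal maximum", {
  rec0 <- sim_recipe(list(spin_system(center = 50, linewidth = 2)),
                     c(0, 100), 4096, noise_sigma = 0, seed = 1)
  clean <- render_spectrum(rec0)$intensity
  rec <- sim_recipe(list(spin_system(center = 50, linewidth = 2)),
                    c(0, 100), 4096, noise_sigma = 0.02, seed = 1)
  noisy <- render_spectrum(rec)$intensity
  expect_equal(sd(noisy - clean), 0.02 * max(abs(clean)), tolerance = 0.05)
})

test_that("rendering is linear in the spin systems (noise free)", {
  a <- spin_system(center = 40, linewidth = 3)
  b <- spin_system(center = 70, linewidth = 5, lineshape = "lorentzian")
  ra <- render_spectrum(sim_recipe(list(a), c(0, 100), 256))
  rb <- render_spectrum(sim_recipe(list(b), c(0, 100), 256))
  rab <- render_spectrum(sim_recipe(list(a, b), c(0, 100), 256))
  expect_equal(rab$intensity, ra$intensity + rb$intensity, tolerance = 1e-12)
})

test_that("double integral tracks total stick intensity for equal weights", {
  di <- function(s) {
    first <- cumsum(c(0, diff(s$field)) * s$intensity)
    sum(c(0, diff(s$field)) * first)
  }
  a <- render_spectrum(sim_recipe(list(
    spin_system(center = 400, linewidth = 4)), c(0, 1000), 4096))
  b <- render_spectrum(sim_recipe(list(
    spin_system(center = 600, linewidth = 9,
                couplings = list(list(A = 15, I = 1, n = 1)))),
    c(0, 1000), 4096))
  expect_equal(di(a), di(b), tolerance = 0.01)
})

test_that("sticks near the sweep edge raise the coverage flag", {
  s <- render_spectrum(sim_recipe(list(
    spin_system(center = 95, linewidth = 4)), c(0, 100), 256))
  expect_true(s$meta$coverage_warning)
})

test_that("benchmark presets carry their documented ground truth", {
  cu <- make_benchmark("cuqu_like", seed = 1)[[1]]
  expect_equal(cu$truth[c("A_fine", "n", "A_cu", "g")],
               list(A_fine = 26.5, n = 2, A_cu = 37, g = 2.0427))
  expect_equal(cu$truth$h4 - cu$truth$h1, 111)

  panel <- make_benchmark("mixture_panel", seed = 1)
  expect_equal(vapply(panel, function(e) e$truth$minor_fraction, 0),
               c(1 / 3, 1 / 5, 1 / 11, 1 / 21))
  expect_error(make_benchmark("nope"), "arg")
})
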