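make_pair <- function(seed = 1) {
  list(a = make_benchmark("gpar_cuqu_like", seed = seed)[[1]]$spectrum,
       b = make_benchmark("gpar_cuqua_like", seed = seed)[[1]]$spectrum)
}
win_panel <- list(c(2596, 2684), c(2690, 2780))

test_that("mixing is linear, commutative and identity-preserving", {
  p <- make_pair()
  m0 <- mix_spectra(mixture_spec(list(p$a, p$b), c(1, 0)))
  ref <- approx(p$a$field, p$a$intensity, xout = m0$field)$y
  expect_equal(m0$intensity, ref, tolerance = 1e-12)

  m3 <- mix_spectra(mixture_spec(list(p$a, p$a), c(2, 1)))
  expect_equal(m3$intensity,
               3 * approx(p$a$field, p$a$intensity, xout = m3$field)$y,
               tolerance = 1e-12)

  m41 <- mix_spectra(mixture_spec(list(p$a, p$b), c(4, 1)))
  ya <- approx(p$a$field, p$a$intensity, xout = m41$field)$y
  yb <- approx(p$b$field, p$b$intensity, xout = m41$field)$y
  expect_equal(m41$intensity - 4 * ya - yb, rep(0, length(ya)),
               tolerance = 1e-12)

  mab <- mix_spectra(mixture_spec(list(p$a, p$b), c(2, 1)))
  mba <- mix_spectra(mixture_spec(list(p$b, p$a), c(1, 2)))
  expect_equal(mab$intensity, mba$intensity, tolerance = 1e-12)
  expect_equal(mab$meta$mixture$minor_fraction, 1 / 3)
})

test_that("disjoint field ranges cannot be mixed", {
  s1 <- esr_spectrum(seq(100, 200, length.out = 64), rnorm(64))
  s2 <- esr_spectrum(seq(300, 400, length.out = 64), rnorm(64))
  expect_error(mix_spectra(mixture_spec(list(s1, s2), c(1, 1))), "overlap")
})

test_that("normalization options rescale components as documented", {
  p <- make_pair()
  m <- mix_spectra(mixture_spec(list(p$a, p$b), c(1, 1),
                                normalization = "max_abs"))
  ya <- approx(p$a$field, p$a$intensity, xout = m$field)$y
  yb <- approx(p$b$field, p$b$intensity, xout = m$field)$y
  expect_equal(m$intensity, ya / max(abs(ya)) + yb / max(abs(yb)),
               tolerance = 1e-12)
})

test_that("a spectrum mixed with itself is a single component", {
  p <- make_pair()
  m <- mix_spectra(mixture_spec(list(p$a, p$a), c(3, 1)))
  rep <- analyze_mixture(m, win_panel,
                         ref_components = list(gpar_cuqu_like = p$a))
  expect_identical(rep$components_found, 1L)
})

test_that("both components are identified at 2:1 and the minor survives 20:1", {
  hit201 <- logical(3)
  for (seed in 1:3) {
    panel <- make_benchmark("mixture_panel", seed = seed)
    r21 <- analyze_mixture(panel[[1]]$spectrum, win_panel)
    lab <- unlist(lapply(r21$windows, `[[`, "assignments"))
    expect_setequal(intersect(lab, c("gpar_cuqu_like", "gpar_cuqua_like")),
                    c("gpar_cuqu_like", "gpar_cuqua_like"))
    expect_true(r21$minor_detected)

    r201 <- analyze_mixture(panel[[4]]$spectrum, win_panel)
    expect_equal(r201$minor_fraction, 1 / 21)
    hit201[seed] <- r201$minor_detected
  }
  # a 4.8% minor component is at the detection limit: require detection in
  # the majority of noise realizations, not in every one
  expect_gt(mean(hit201), 0.5)
})

test_that("assignment uses spacing and position only, never amplitude", {
  # scaling the mixture intensity must not change any assignment
  panel <- make_benchmark("mixture_panel", seed = 1)
  m <- panel[[2]]$spectrum
  m2 <- m; m2$intensity <- m2$intensity * 1e3
  r1 <- analyze_mixture(m, win_panel)
  r2 <- analyze_mixture(m2, win_panel)
  expect_identical(lapply(r1$windows, `[[`, "assignments"),
                   lapply(r2$windows, `[[`, "assignments"))
})

test_that("the detection-limit scan reports the panel honestly", {
  p <- make_pair(seed = 1)
  tab <- detection_limit_scan(p$a, p$b,
                              list(c(2, 1), c(4, 1), c(1, 0)), win_panel)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$minor_fraction, c(1 / 3, 1 / 5, 0))
  expect_false(tab$minor_detected[3])   # degenerate 1:0 ratio
  expect_true(all(tab$minor_detected[1:2]))
  expect_equal(attr(tab, "smallest_detected_fraction"), 1 / 5)
})
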