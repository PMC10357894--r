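test_that("peak detection handles degenerate and exact cases", {
  f <- seq(3200, 3400, by = 0.5)
  expect_identical(nrow(detect_peaks(rep(0, length(f)), f)), 0L)

  bump <- exp(-(f - 3300)^2 / 8)
  pk <- detect_peaks(bump, f)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$position - 3300), 0.25)
})

test_that("a simulator comb is detected at its known spacing", {
  centers <- 3250 + 26.5 * (0:4)
  sys <- lapply(centers, function(cc)
    spin_system(center = cc, lineshape = "gaussian", linewidth = 3))
  s <- render_spectrum(sim_recipe(sys, c(3180, 3430), 1024))
  pk <- detect_peaks(s$intensity, s$field, polarity = "positive")
  expect_identical(nrow(pk), 5L)
  expect_true(all(abs(diff(pk$position) - 26.5) < 0.1))
})

test_that("even grouping recovers the nine-line 12.5 G comb", {
  pos <- 2700 + 12.5 * (-4:4)
  g <- find_even_groups(data.frame(position = pos, amplitude = 1))
  expect_length(g, 1L)
  expect_equal(g[[1]]$n_lines, 9L)
  expect_equal(g[[1]]$mean_spacing, 12.5)
  expect_equal(g[[1]]$center, 2700)
  expect_equal(g[[1]]$span, g[[1]]$mean_spacing * (g[[1]]$n_lines - 1))
})

test_that("uneven runs are rejected and reported as artifacts", {
  pk <- data.frame(position = c(3200, 3210, 3235), amplitude = 1)
  g <- find_even_groups(pk, cv_tol = 0.10)
  expect_length(g, 0L)
  expect_equal(attr(g, "artifacts"), c(3200, 3210, 3235))
})

test_that("grouping matches the brute-force run enumeration with off-grid peaks", {
  set.seed(5)
  for (rep in 1:10) {
    comb <- 3000 + 20 * (0:6) + rnorm(7, 0, 0.3)
    spur <- sort(runif(2, 3005, 3115))
    # keep the spurious peaks off the comb grid
    spur <- spur[vapply(spur, function(x) min(abs(x - comb)) > 4, TRUE)]
    pos <- sort(c(comb, spur))
    g <- find_even_groups(data.frame(position = pos, amplitude = 1),
                          cv_tol = 0.05)
    oracle <- brute_force_best_run(pos, cv_tol = 0.05)
    expect_false(is.null(oracle))
    best <- g[[order(-vapply(g, `[[`, 0L, "n_lines"),
                     vapply(g, `[[`, 0, "spacing_cv"))[1]]]
    expect_equal(best$line_positions, pos[oracle$i:oracle$j])
  }
})

test_that("an injected off-comb peak cannot shift the recovered spacing", {
  comb <- 3100 + 15 * (0:7)
  base <- find_even_groups(data.frame(position = comb, amplitude = 1))
  for (spur in c(3103, 3141, 3196)) {
    pos <- sort(c(comb, spur))
    g <- find_even_groups(data.frame(position = pos, amplitude = 1))
    best <- g[[which.max(vapply(g, `[[`, 0L, "n_lines"))]]
    expect_lt(abs(best$mean_spacing - base[[1]]$mean_spacing),
              0.10 * base[[1]]$mean_spacing)
  }
})

test_that("coupling equals the mean line spacing", {
  g3 <- find_even_groups(data.frame(position = c(3203, 3229.5, 3256),
                                    amplitude = 1))[[1]]
  expect_equal(coupling_from_group(g3), 26.5)
  expect_equal(g3$span, 53)
  g9 <- find_even_groups(data.frame(position = 2700 + 12.5 * (0:8),
                                    amplitude = 1))[[1]]
  expect_equal(coupling_from_group(g9), 12.5)
  expect_error(coupling_from_group(
    structure(list(n_lines = 2L), class = "multiplet_group")), "at least 3")
})

test_that("multiplicity arithmetic inverts m = 2nI + 1 exactly", {
  expect_identical(nuclei_from_multiplicity(5, 1), 2L)
  expect_identical(nuclei_from_multiplicity(9, 1), 4L)
  expect_identical(nuclei_from_multiplicity(4, 1), NA_integer_)
  expect_identical(nuclei_from_multiplicity(4, 0.5), 3L)
  for (I in c(0.5, 1, 1.5)) for (n in 1:6)
    expect_identical(nuclei_from_multiplicity(multiplicity_from_nuclei(n, I), I),
                     n)
})

test_that("edge groups yield the canonical quartet assignment", {
  lo <- find_even_groups(data.frame(position = c(3150, 3176.5, 3203),
                                    amplitude = 1))[[1]]
  hi <- find_even_groups(data.frame(position = c(3314, 3340.5, 3367),
                                    amplitude = 1))[[1]]
  r <- infer_multiplicity_from_edges(list(lo, hi), c(3100, 3420), I = 1)
  expect_identical(r$m, 5L)
  expect_identical(r$n, 2L)
  expect_equal(r$h1, 3203)
  expect_equal(r$h4, 3314)
  expect_equal(r$A_fine, 26.5)

  expect_null(infer_multiplicity_from_edges(list(), c(3100, 3420), I = 1))
  expect_null(infer_multiplicity_from_edges(list(lo, hi), c(1, 2), I = 1))
})

test_that("quartet arithmetic reproduces the printed worked example", {
  q <- cu_quartet_params(3203, 3314, 9.316)
  expect_equal(q$A_cu, 37)
  expect_equal(q$g, 2.0427, tolerance = 0.0005 / 2.0427)
  expect_equal(q$quartet_positions, c(3203, 3240, 3277, 3314))

  expect_equal(cu_quartet_params(3000, 3003, 9.3)$A_cu, 1)
  # conversion-constant identity: g(B = 714.4773 nu) == 1 for any nu
  for (nu in c(1, 9.3, 94)) {
    expect_equal(cu_quartet_params(714.4773 * nu - 1, 714.4773 * nu + 1,
                                   nu)$g, 1)
  }
  expect_error(cu_quartet_params(3314, 3203, 9.316), "exceed")
  expect_error(cu_quartet_params(3203, 3314, -1), "positive")
})
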