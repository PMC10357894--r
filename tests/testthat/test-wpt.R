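test_that("filter sets satisfy the quadrature-mirror identities", {
  for (nm in c("db6", "db9", "coif3")) {
    w <- wavelet_filters(nm)
    h <- w$rec_lo; g <- w$rec_hi; L <- w$length
    expect_equal(sum(h), sqrt(2), tolerance = 1e-10)
    expect_equal(sum(g), 0, tolerance = 1e-10)
    expect_equal(sum(h^2), 1, tolerance = 1e-10)
    expect_equal(sum(g^2), 1, tolerance = 1e-10)
    expect_equal(sum(h * g), 0, tolerance = 1e-10)
    for (k in seq_len(L / 2 - 1)) {
      expect_lt(abs(sum(h[1:(L - 2 * k)] * h[(2 * k + 1):L])), 1e-10)
      expect_lt(abs(sum(g[1:(L - 2 * k)] * g[(2 * k + 1):L])), 1e-10)
    }
    expect_identical(w$dec_lo, rev(h))
  }
})

test_that("degenerate and bounds cases behave as specified", {
  u <- rep(0, 256)
  t0 <- wpt_decompose(u, "db9", 4)
  expect_true(all(vapply(t0$nodes, function(x) all(x == 0), TRUE)))

  x <- rnorm(1024)
  expect_error(wpt_decompose(x, "db9", 11), "10")
  expect_error(wpt_decompose(rnorm(100), "db9", 2), "power of two")
  t1 <- wpt_decompose(x, "db9", 2)
  expect_error(wpt_reconstruct(t1, "AAA"), "valid level-3")
  expect_error(wpt_reconstruct(t1, "AX"), "over \\{A, D\\}")
})

test_that("coefficient lengths, root identity, and determinism hold", {
  set.seed(42)
  x <- rnorm(512)
  t1 <- wpt_decompose(x, "db6", 4)
  for (i in seq_along(t1$nodes))
    expect_length(t1$nodes[[i]], 512 / 2^nchar(names(t1$nodes)[i]))
  expect_equal(wpt_reconstruct(t1, ""), x)
  t2 <- wpt_decompose(x, "db6", 4)
  expect_identical(t1$nodes, t2$nodes)
})

test_that("per-level reconstruction and energy conservation hold for all wavelets", {
  set.seed(7)
  for (nm in c("db6", "db9", "coif3")) {
    for (p in c(256, 1024)) {
      x <- rnorm(p)
      t <- wpt_decompose(x, nm, 4)
      for (lvl in 1:4) {
        paths <- names(t$nodes)[nchar(names(t$nodes)) == lvl]
        energy <- sum(vapply(t$nodes[paths], function(cf) sum(cf^2), 0))
        expect_rel_equal(energy, sum(x^2), 1e-10)
        recon <- Reduce(`+`, lapply(paths, wpt_reconstruct, t = t))
        expect_rel_equal(recon, x, 1e-10)
      }
    }
  }
})

test_that("a sinusoid concentrates in the node whose band contains it", {
  # band assignment oracle: node_band() computes each node's frequency
  # interval from the filter-bank branching; the test frequency is chosen
  # interior to one level-3 band
  p <- 1024
  # center of the AAD band; a frequency near a low-level split boundary
  # (e.g. 0.25) would legitimately spread over both subtrees, since the
  # iterated filters have the widest transition at the first split
  f0 <- 0.09375
  x <- sin(2 * pi * f0 * seq_len(p))
  t <- wpt_decompose(x, "db9", 3)
  paths <- names(t$nodes)[nchar(names(t$nodes)) == 3L]
  target <- paths[vapply(paths, function(pp) {
    b <- node_band(pp); b[1] <= f0 && f0 < b[2]
  }, TRUE)]
  expect_length(target, 1L)
  energies <- vapply(paths, function(pp) sum(wpt_reconstruct(t, pp)^2), 0)
  expect_gt(energies[target] / sum(energies), 0.90)
})

test_that("node_band tiles [0, 1/2] at every level in Gray-code order", {
  for (lvl in 1:4) {
    paths <- do.call(paste0, expand.grid(rep(list(c("A", "D")), lvl)))
    bands <- t(vapply(paths, node_band, numeric(2)))
    o <- order(bands[, 1])
    expect_equal(unname(bands[o, 1]),
                 seq(0, 0.5 - 2^-(lvl + 1), by = 2^-(lvl + 1)))
    expect_equal(unname(bands[o, 2] - bands[o, 1]),
                 rep(2^-(lvl + 1), 2^lvl))
  }
  expect_equal(node_band("A"), c(0, 0.25))
  expect_equal(node_band("AAD"), c(0.0625, 0.125))
})

test_that("the DWT chain coincides with the packet tree's A-branch", {
  set.seed(11)
  x <- rnorm(256)
  ch <- dwt_chain(x, "db9", 4)
  t <- wpt_decompose(x, "db9", 4)
  for (j in 1:4) {
    expect_identical(ch[[j]]$A, t$nodes[[strrep("A", j)]])
    expect_identical(ch[[j]]$D, t$nodes[[paste0(strrep("A", j - 1), "D")]])
  }
  # inverse transform from level 3: A3 + D3 + D2 + D1 reproduces the input
  total <- ch[[3]]$recon_A + ch[[3]]$recon_D + ch[[2]]$recon_D + ch[[1]]$recon_D
  expect_rel_equal(total, x, 1e-10)
})

test_that("display labels put the newest filter first and append the level", {
  expect_identical(paper_node_label("AAD"), "DAA3")
  expect_identical(paper_node_label("AADA"), "ADAA4")
  expect_identical(paper_node_label("A"), "A1")
  expect_identical(paper_node_label(""), "S0")
})

test_that("tree dumps are one readable CSV per node", {
  d <- withr::local_tempdir()
  u <- to_uniform(single_line_spectrum(n = 64, range = c(3290, 3310)))
  t <- wpt_decompose(u, "db9", 2)
  files <- wpt_dump(t, d)
  expect_length(files, 6L)   # 2 + 4 nodes
  tab <- read.csv(files[1])
  expect_identical(names(tab), c("field_g", "recon_intensity"))
  expect_equal(nrow(tab), t$p)
})
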