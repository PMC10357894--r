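# Brute-force oracles, independent of the implementation paths they check.

# First-order stick pattern by explicit enumeration of all nuclear
# magnetic quantum-number combinations.
brute_force_sticks <- function(center, A, I, n) {
  mI <- seq(-I, I, by = 1)
  grid <- do.call(expand.grid, rep(list(mI), n))
  pos <- center + A * rowSums(grid)
  agg <- tapply(rep(1, length(pos)), round(pos, 9), sum)
  data.frame(position = as.numeric(names(agg)),
             intensity = as.numeric(agg) / length(pos))
}

# Even-group search by direct enumeration of every contiguous run.
brute_force_best_run <- function(pos, cv_tol = 0.1, min_lines = 3L) {
  best <- NULL
  np <- length(pos)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (j - i + 1L < min_lines) next
    d <- diff(pos[i:j])
    cv <- stats::sd(d) / mean(d)
    if (!is.finite(cv) || cv > cv_tol) next
    if (is.null(best) || (j - i) > (best$j - best$i) ||
        ((j - i) == (best$j - best$i) && cv < best$cv))
      best <- list(i = i, j = j, cv = cv)
  }
  best
}

# A small noiseless spectrum with a single derivative Gaussian line.
single_line_spectrum <- function(center = 3300, lw = 2, range = c(3250, 3350),
                                 n = 512) {
  sys <- spin_system(center = center, lineshape = "gaussian", linewidth = lw)
  render_spectrum(sim_recipe(list(sys), range, n))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
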