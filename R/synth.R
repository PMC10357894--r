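#' Define a first-order spin system
#'
#' A spin system is a resonance center plus a set of isotropic first-order
#' hyperfine couplings.  The center is given either directly in gauss or as
#' a g value plus microwave frequency.  The simulator is deliberately
#' first-order and region-wise: each system stands for one locally regular
#' multiplet (e.g. the g-perp quartet of a frozen Cu(II) complex, or one
#' g-par manifold), not for a full anisotropic powder pattern.
#'
#' @param center Center field (G), or `NULL` to derive it from `g`.
#' @param g g value (used with `mw_frequency_ghz` when `center` is `NULL`).
#' @param mw_frequency_ghz Microwave frequency (GHz).
#' @param couplings List of couplings, each `list(A = <G>, I = <spin>,
#'   n = <equivalent nuclei>)`.
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @param linewidth Peak-to-peak width of the first-derivative line (G).
#' @param amplitude Overall intensity scale (area of the absorption line).
#' @return A list of class `spin_system`.
#' @export
spin_system <- function(center = NULL, g = NULL, mw_frequency_ghz = NULL,
                        couplings = list(),
                        lineshape = c("gaussian", "lorentzian"),
                        linewidth = 1, amplitude = 1) {
  lineshape <- match.arg(lineshape)
  if (is.null(center)) {
    if (is.null(g) || is.null(mw_frequency_ghz))
      stop("give either center, or g plus mw_frequency_ghz")
    center <- G_PER_GHZ * mw_frequency_ghz / g
  }
  stopifnot(linewidth > 0, amplitude >= 0)
  nlines <- 1
  for (cp in couplings) {
    stopifnot(cp$A >= 0, cp$I > 0, cp$n >= 1)
    nlines <- nlines * (2 * cp$I * cp$n + 1)
  }
  if (nlines > 1e4)
    stop("coupling set implies more than 10^4 lines (", nlines, ")")
  structure(list(center = center, couplings = couplings,
                 lineshape = lineshape, linewidth = linewidth,
                 amplitude = amplitude,
                 mw_frequency_ghz = mw_frequency_ghz),
            class = "spin_system")
}

#' First-order stick pattern of a spin system
#'
#' Positions are `center + sum_i(A_i * m_i)` over all nuclear magnetic
#' quantum-number combinations; for n equivalent spin-I nuclei this merges
#' into `2 n I + 1` distinct positions with multinomial intensity ratios.
#' Total intensity is normalized to 1.
#'
#' @param s A `spin_system`.
#' @return Data frame with columns `position` (G) and `intensity`.
#' @examples
#' s <- spin_system(center = 3300,
#'                  couplings = list(list(A = 16, I = 1, n = 1)))
#' stick_pattern(s)  # 3 sticks at 3284/3300/3316, each 1/3
#' @export
stick_pattern <- function(s) {
  stopifnot(inherits(s, "spin_system"))
  pos <- 0; int <- 1
  for (cp in s$couplings) {
    mI <- seq(-cp$I, cp$I, by = 1)       # single-nucleus projections
    for (k in seq_len(cp$n)) {
      pos <- as.vector(outer(pos, cp$A * mI, `+`))
      int <- as.vector(outer(int, rep(1, length(mI)), `*`))
      # merge degenerate positions as we go to keep the list small
      key <- round(pos / (1e-9 * max(1, cp$A)), 0)
      agg <- rowsum(int, key)
      ord <- order(as.numeric(rownames(agg)))
      upos <- vapply(split(pos, key), `[[`, 0, 1)
      pos <- as.numeric(upos[ord]); int <- as.numeric(agg[ord])
    }
  }
  data.frame(position = s$center + pos, intensity = int / sum(int))
}

# first derivative of area-normalized absorption lineshapes;
# lw is the peak-to-peak width of the derivative
.deriv_line <- function(x, lw, shape) {
  if (shape == "gaussian") {
    sg <- lw / 2
    -(x / (sg^3 * sqrt(2 * pi))) * exp(-x^2 / (2 * sg^2))
  } else {
    gam <- sqrt(3) / 2 * lw
    -(2 * gam * x / pi) / (x^2 + gam^2)^2
  }
}

#' Define a simulation recipe
#'
#' @param systems List of `spin_system` objects, or of
#'   `list(system, weight)` pairs (weight defaults to 1).
#' @param field_range Numeric length-2 sweep limits (G).
#' @param n_points Number of field points (>= 64).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   the maximum absolute clean signal (0 = noise free).
#' @param seed Integer seed for the noise generator; the same recipe and
#'   seed give bit-identical output.
#' @return A list of class `sim_recipe`.
#' @export
sim_recipe <- function(systems, field_range, n_points = 1024L,
                       noise_sigma = 0, seed = 1L) {
  systems <- lapply(systems, function(el) {
    if (inherits(el, "spin_system")) list(system = el, weight = 1)
    else list(system = el[[1]], weight = el[[2]])
  })
  stopifnot(length(field_range) == 2L, field_range[2] > field_range[1],
            n_points >= 64L, noise_sigma >= 0)
  structure(list(systems = systems, field_range = field_range,
                 n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "sim_recipe")
}

#' Render a recipe into a derivative-mode spectrum
#'
#' Each stick is convolved with the first derivative of the system's
#' lineshape at its peak-to-peak width; systems are summed with their
#' weights; seeded white Gaussian noise is added.  Simulation ground truth
#' (couplings, centers, weights) is attached in `meta$truth`.  If any stick
#' lies closer than 5 linewidths to the sweep limits a
#' `meta$coverage_warning` flag is set (not an error).
#'
#' @param recipe A `sim_recipe`.
#' @param label Spectrum label.
#' @param mw_frequency_ghz Microwave frequency metadata for the output.
#' @return An `esr_spectrum`.
#' @export
render_spectrum <- function(recipe, label = "synthetic",
                            mw_frequency_ghz = NA_real_) {
  stopifnot(inherits(recipe, "sim_recipe"))
  field <- seq(recipe$field_range[1], recipe$field_range[2],
               length.out = recipe$n_points)
  clean <- numeric(recipe$n_points)
  coverage_warning <- FALSE
  for (el in recipe$systems) {
    s <- el$system
    if (s$amplitude == 0) next
    st <- stick_pattern(s)
    if (any(st$position - 5 * s$linewidth < recipe$field_range[1]) ||
        any(st$position + 5 * s$linewidth > recipe$field_range[2]))
      coverage_warning <- TRUE
    for (i in seq_len(nrow(st))) {
      clean <- clean + el$weight * s$amplitude * st$intensity[i] *
        .deriv_line(field - st$position[i], s$linewidth, s$lineshape)
    }
    if (is.na(mw_frequency_ghz) && !is.null(s$mw_frequency_ghz))
      mw_frequency_ghz <- s$mw_frequency_ghz
  }
  y <- clean
  if (recipe$noise_sigma > 0) {
    scale <- max(abs(clean))
    if (scale == 0) scale <- 1
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(recipe$seed)
    y <- clean + stats::rnorm(length(clean), 0, recipe$noise_sigma * scale)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  }
  esr_spectrum(field, y, mw_frequency_ghz, label = label,
               meta = list(
                 truth = list(systems = recipe$systems,
                              noise_sigma = recipe$noise_sigma,
                              seed = recipe$seed),
                 coverage_warning = coverage_warning))
}

#' Benchmark spectra with known ground truth
#'
#' Seeded presets emulating the regimes the analysis is designed for.  All
#' couplings, linewidths and sampling steps are fixed properties of the
#' presets (documented in the methods vignette); the noise level and seed
#' are the only knobs.
#'
#' \describe{
#'   \item{`tempo_like`}{Nitroxide at 9.33 GHz: one 14N (A = 17 G) triplet,
#'     12 equivalent protons at `A_H` = 0.20 G, Lorentzian lines, swept
#'     over linewidths 0.10/0.14/0.20/0.28 G (resolved to unresolved).}
#'   \item{`tempol_like`}{As above with `A_H` = 0.44 G and linewidths
#'     0.22/0.31/0.44/0.62 G.}
#'   \item{`cuqu_like`}{Cu(II) g-perp quartet at 9.316 GHz: A_Cu = 37 G
#'     (I = 3/2) centered so the edge lines fall at 3203/3314 G
#'     (g = 2.0427), two nitrogens at 26.5 G, Gaussian width 18 G
#'     (unresolved).}
#'   \item{`cuqua_like`}{As above with g = 2.0411, A_Cu = 23.3 G and three
#'     nitrogens at 21.3 G, Gaussian width 15 G.}
#'   \item{`gpar_cuqu_like` / `gpar_cuqua_like`}{Single g-par manifolds on
#'     a common 2550--2850 G grid: a 5-line 17 G nitrogen multiplet
#'     centered at 2640 G, and a 7-line 16 G multiplet centered at 2724 G,
#'     Gaussian width 8 G (partially resolved).}
#'   \item{`mixture_panel`}{Weighted sums of the two g-par manifolds at
#'     ratios 2:1, 4:1, 10:1 and 20:1 (minor fractions 1/3, 1/5, 1/11,
#'     1/21), each component carrying its own seeded noise.}
#' }
#'
#' @param name Preset name.
#' @param seed Base seed for the noise generators.
#' @param noise_sigma Noise standard deviation as a fraction of the maximum
#'   signal (default 0.01, i.e. SNR 100).
#' @return A list of entries `list(spectrum, truth)`; `truth` is a named
#'   list of the quantities the analysis should recover.
#' @export
make_benchmark <- function(name = c("tempo_like", "tempol_like", "cuqu_like",
                                    "cuqua_like", "gpar_cuqu_like",
                                    "gpar_cuqua_like", "mixture_panel"),
                           seed = 1L, noise_sigma = 0.01) {
  name <- match.arg(name)
  seed <- as.integer(seed)

  nitroxide <- function(A_H, linewidths, label) {
    out <- list()
    for (k in seq_along(linewidths)) {
      lw <- linewidths[k]
      sys <- spin_system(center = 3323, mw_frequency_ghz = 9.33,
                         couplings = list(list(A = 17, I = 1, n = 1),
                                          list(A = A_H, I = 0.5, n = 12)),
                         lineshape = "lorentzian", linewidth = lw)
      rec <- sim_recipe(list(sys), field_range = c(3289, 3357),
                        n_points = 4096L, noise_sigma = noise_sigma,
                        seed = seed + k)
      out[[k]] <- list(
        spectrum = render_spectrum(rec, sprintf("%s lw=%.2f", label, lw)),
        truth = list(A_fine = A_H, A_coarse = 17, n_H = 12, I = 0.5,
                     linewidth = lw))
    }
    out
  }

  cu_perp <- function(g, A_cu, A_N, n_N, lw, label) {
    center <- G_PER_GHZ * 9.316 / g
    sys <- spin_system(center = center, mw_frequency_ghz = 9.316,
                       couplings = list(list(A = A_cu, I = 1.5, n = 1),
                                        list(A = A_N, I = 1, n = n_N)),
                       lineshape = "gaussian", linewidth = lw)
    rec <- sim_recipe(list(sys), field_range = c(3000, 3499.4),
                      n_points = 228L, noise_sigma = noise_sigma,
                      seed = seed)
    list(list(spectrum = render_spectrum(rec, label),
              truth = list(A_fine = A_N, n = n_N, A_cu = A_cu, g = g,
                           h1 = center - 1.5 * A_cu,
                           h4 = center + 1.5 * A_cu,
                           window = c(center - 1.5 * A_cu - (A_N * n_N + lw),
                                      center + 1.5 * A_cu + (A_N * n_N + lw)))))
  }

  gpar <- function(center, A_N, n_N, label, sd) {
    sys <- spin_system(center = center,
                       couplings = list(list(A = A_N, I = 1, n = n_N)),
                       lineshape = "gaussian", linewidth = 8)
    rec <- sim_recipe(list(sys), field_range = c(2550, 2849.2),
                      n_points = 188L, noise_sigma = noise_sigma, seed = sd)
    list(spectrum = render_spectrum(rec, label, 9.316),
         truth = list(A_fine = A_N, n = n_N, m = 2 * n_N + 1,
                      center = center))
  }

  switch(name,
    tempo_like = nitroxide(0.20, c(0.10, 0.14, 0.20, 0.28), "tempo_like"),
    tempol_like = {
      out <- list()
      lws <- c(0.22, 0.31, 0.44, 0.62)
      for (k in seq_along(lws)) {
        sys <- spin_system(center = 3323, mw_frequency_ghz = 9.33,
                           couplings = list(list(A = 17, I = 1, n = 1),
                                            list(A = 0.44, I = 0.5, n = 12)),
                           lineshape = "lorentzian", linewidth = lws[k])
        rec <- sim_recipe(list(sys), field_range = c(3272, 3374.35),
                          n_points = 2048L, noise_sigma = noise_sigma,
                          seed = seed + k)
        out[[k]] <- list(
          spectrum = render_spectrum(rec, sprintf("tempol_like lw=%.2f", lws[k])),
          truth = list(A_fine = 0.44, A_coarse = 17, n_H = 12, I = 0.5,
                       linewidth = lws[k]))
      }
      out
    },
    cuqu_like = cu_perp(2.0427, 37, 26.5, 2, 18, "cuqu_like"),
    cuqua_like = cu_perp(2.0411, 23.3, 21.3, 3, 15, "cuqua_like"),
    gpar_cuqu_like = list(gpar(2640, 17, 2, "gpar_cuqu_like", seed)),
    gpar_cuqua_like = list(gpar(2724, 16, 3, "gpar_cuqua_like", seed + 1L)),
    mixture_panel = {
      a <- gpar(2640, 17, 2, "gpar_cuqu_like", seed)
      b <- gpar(2724, 16, 3, "gpar_cuqua_like", seed + 1L)
      wins <- list(c(2596, 2684), c(2690, 2780))
      refs <- list(
        gpar_cuqu_like = component_reference(a$spectrum, wins),
        gpar_cuqua_like = component_reference(b$spectrum, wins))
      ratios <- list(c(2, 1), c(4, 1), c(10, 1), c(20, 1))
      lapply(ratios, function(r) {
        m <- mix_spectra(mixture_spec(
          list(a$spectrum, b$spectrum), weights = r))
        m$label <- sprintf("mixture %d:%d", r[1], r[2])
        m$meta$references <- refs
        m$meta$ref_spacings <- c(gpar_cuqu_like = 17, gpar_cuqua_like = 16)
        list(spectrum = m,
             truth = list(ratio = r, minor_fraction = r[2] / sum(r),
                          spacing_major = 17, spacing_minor = 16,
                          window_major = c(2596, 2684),
                          window_minor = c(2690, 2780)))
      })
    })
}
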