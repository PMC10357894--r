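#' Specify a weighted spectral mixture
#'
#' @param components List of at least two `esr_spectrum` objects with
#'   overlapping field ranges.
#' @param weights Positive weights, one per component.
#' @param normalization `"none"` (default: raw weighted summation),
#'   `"max_abs"` (components scaled to unit maximum absolute intensity
#'   before weighting) or `"double_integral"` (components scaled to unit
#'   double integral of the derivative signal, i.e. equal spin count).
#' @param labels Component labels (defaults to the spectra's labels).
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(components, weights,
                         normalization = c("none", "max_abs", "double_integral"),
                         labels = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(length(components) >= 2L,
            length(weights) == length(components), all(weights >= 0),
            any(weights > 0))
  lapply(components, validate_spectrum)
  if (is.null(labels))
    labels <- vapply(seq_along(components), function(i) {
      l <- components[[i]]$label
      if (nzchar(l)) l else paste0("component_", i)
    }, "")
  structure(list(components = components, weights = as.numeric(weights),
                 normalization = normalization, labels = labels),
            class = "mixture_spec")
}

.double_integral <- function(field, y) {
  first <- cumsum(c(0, diff(field)) * y)          # absorption
  sum(c(0, diff(field)) * first)                  # its area
}

#' Mix spectra into a composite spectrum
#'
#' Components are resampled by linear interpolation onto the coarsest
#' common uniform grid over the intersection of their field ranges,
#' optionally normalized, then summed with their weights.  The mixing
#' recipe (weights, labels, normalization, minor fraction) is recorded in
#' the output metadata.
#'
#' @param spec A [mixture_spec()].
#' @return An `esr_spectrum`.
#' @export
mix_spectra <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  lo <- max(vapply(spec$components, function(s) s$field[1], 0))
  hi <- min(vapply(spec$components, function(s) s$field[length(s$field)], 0))
  if (hi <= lo) stop("component field ranges do not overlap")
  step <- max(vapply(spec$components,
                     function(s) stats::median(diff(s$field)), 0))
  n <- as.integer(floor((hi - lo) / step)) + 1L
  if (n < 16L) stop("common field range too short after resampling")
  grid <- lo + step * (seq_len(n) - 1L)

  total <- numeric(n)
  for (i in seq_along(spec$components)) {
    s <- spec$components[[i]]
    y <- stats::approx(s$field, s$intensity, xout = grid, rule = 2)$y
    y <- switch(spec$normalization,
                none = y,
                max_abs = y / max(abs(y)),
                double_integral = y / .double_integral(grid, y))
    total <- total + spec$weights[i] * y
  }
  wsum <- sum(spec$weights)
  minor <- which.min(spec$weights)
  freq <- stats::na.omit(vapply(spec$components,
                                function(s) s$mw_frequency_ghz, 0))
  esr_spectrum(grid, total,
               mw_frequency_ghz = if (length(freq)) freq[1] else NA_real_,
               label = paste(spec$labels, collapse = " + "),
               meta = list(mixture = list(
                 weights = spec$weights, labels = spec$labels,
                 normalization = spec$normalization,
                 minor_label = spec$labels[minor],
                 minor_fraction = spec$weights[minor] / wsum)))
}

#' Reference line positions of a pure component
#'
#' Runs the extraction pipeline on a pure-component spectrum and collects
#' its multiplet line positions and pooled spacing per window.  Because the
#' reference is measured with the same read-out as the mixture analysis,
#' systematic position offsets (e.g. the lobe phase of an oscillating
#' component) cancel when mixture groups are matched against it.
#'
#' @param s A pure-component `esr_spectrum`.
#' @param windows List of field windows (G), as in [analyze_mixture()].
#' @param config An [extract_config()].
#' @return List with `positions` (all multiplet line fields, G) and
#'   `spacing` (pooled mean spacing, G).
#' @export
component_reference <- function(s, windows, config = extract_config()) {
  # For a pure component, some windows hold only its band-limited ringing,
  # which also forms even runs.  Each window is therefore analyzed on its
  # own (so another window's runs cannot steer the spacing estimate), and
  # the window holding the component's signal energy -- a pure spectrum's
  # multiplet lives where its intensity is -- defines the component's
  # spacing; groups from any window consistent with that spacing
  # contribute reference line positions.
  u <- to_uniform(s)
  sp0 <- strip_pads(u)
  per_win <- lapply(windows, function(w) {
    cfg <- config
    cfg$windows <- list(w)
    r <- extract_hyperfine(s, cfg)
    idx <- sp0$field >= w[1] & sp0$field <= w[2]
    list(spacing = r$A_fine,
         rms = if (is.na(r$A_fine)) 0 else sqrt(mean(sp0$intensity[idx]^2)),
         groups = r$windows[[1]]$groups)
  })
  rms <- vapply(per_win, `[[`, 0, "rms")
  if (all(rms == 0))
    return(list(positions = numeric(0), spacing = NA_real_))
  spacing <- per_win[[which.max(rms)]]$spacing
  # reference positions come only from windows carrying real component
  # energy: a low-energy window holds the component's ringing, whose
  # even runs continue the same spacing and would later masquerade as a
  # second component at those positions
  pos <- unlist(lapply(per_win[rms >= 0.25 * max(rms)], function(pw)
    unlist(lapply(pw$groups, function(g) {
      if (abs(g$mean_spacing - spacing) / spacing <= 0.2) g$line_positions
      else NULL
    }))))
  list(positions = sort(unname(pos)), spacing = spacing)
}

#' Identify mixture components as distinct evenly spaced line groups
#'
#' Runs the extraction pipeline on a composite spectrum and, per field
#' window, reports every evenly spaced line group together with a
#' component assignment.  Assignment never uses amplitude.  With full
#' references (line positions of the pure components, see
#' [component_reference()]) a group is assigned to the component whose
#' measured line grid its positions follow, with spacing proximity as the
#' tie break -- position consistency is what separates a genuine minor
#' multiplet from the band-limited continuation of the major component's
#' comb, whose positions also form an even run.  With spacing-only
#' references the assignment falls back to spacing proximity.  Two groups
#' whose spacings differ by more than `distinct_tol` (relative) count as
#' distinct components.  Partial multiplets (down to `min_lines` of the
#' full m lines) are admitted, since overlap routinely hides part of a
#' minor component's multiplet.
#'
#' @param m An `esr_spectrum`, typically from [mix_spectra()].
#' @param windows List of numeric length-2 field windows (G).
#' @param config An [extract_config()]; mixture analysis defaults to
#'   `cv_tol = 0.12`: two interleaved combs a few percent apart in spacing
#'   beat against each other, wobbling peak positions by up to ~15% of a
#'   period, so the grouping tolerance must admit that jitter (distinctness
#'   of components is judged by the tighter `distinct_tol`).
#' @param references Named list, one entry per candidate component: either
#'   a single spacing (G) or a list with `positions` and `spacing`.
#'   Defaults to `m$meta$references`, then `m$meta$ref_spacings`.
#' @param ref_components Named list of pure-component spectra from which
#'   references are measured when `references` is not given.
#' @param distinct_tol Relative spacing difference above which two groups
#'   are distinct components (default 0.05: the regime of interest
#'   separates components ~6% apart).
#' @return A list of class `mixture_report` with one entry per window
#'   (`window`, `groups`, `assignments`, `spacings`), plus top-level
#'   `components_found`, `minor_detected`, `minor_fraction`.
#' @export
analyze_mixture <- function(m, windows,
                            config = extract_config(cv_tol = 0.12),
                            references = NULL, ref_components = NULL,
                            distinct_tol = 0.05) {
  if (is.numeric(windows) && length(windows) == 2L) windows <- list(windows)
  if (is.null(references)) {
    if (!is.null(ref_components)) {
      references <- lapply(ref_components, component_reference,
                           windows = windows, config = config)
    } else if (!is.null(m$meta$references)) {
      references <- m$meta$references
    } else if (!is.null(m$meta$ref_spacings)) {
      references <- as.list(m$meta$ref_spacings)
    }
  }
  cfg <- config
  cfg$windows <- windows
  res <- extract_hyperfine(m, cfg)

  minor_label <- m$meta$mixture$minor_label
  minor_fraction <- m$meta$mixture$minor_fraction
  if (is.null(minor_fraction)) minor_fraction <- NA_real_

  assign_group <- function(g) {
    if (is.null(references) || length(references) == 0L) return("unassigned")
    frac <- vapply(references, function(rf) {
      if (is.list(rf) && !is.null(rf$positions) && length(rf$positions)) {
        tol <- 0.3 * rf$spacing
        mean(vapply(g$line_positions, function(x)
          min(abs(x - rf$positions)) <= tol, TRUE))
      } else NA_real_
    }, 0)
    spac <- vapply(references, function(rf)
      if (is.list(rf)) rf$spacing else as.numeric(rf), 0)
    srel <- abs(g$mean_spacing - spac) / spac
    if (all(is.na(frac))) {
      # spacing-only references
      j <- which.min(srel)
      if (srel[j] <= distinct_tol) return(names(references)[j])
      return("unassigned")
    }
    ok <- which(!is.na(frac) & frac >= 0.6)
    if (length(ok) == 0L) return("unassigned")
    top <- max(frac[ok])
    cand <- ok[frac[ok] >= top - 0.1]
    j <- cand[which.min(srel[cand])]
    names(references)[j]
  }

  per_window <- lapply(res$windows, function(e) {
    groups <- e$groups
    spacings <- vapply(groups, `[[`, 0, "mean_spacing")
    assignments <- vapply(groups, assign_group, "")
    list(window = e$window, groups = groups, spacings = spacings,
         assignments = assignments, artifacts = e$artifacts)
  })

  # count distinct spacing clusters among assigned groups (unassigned
  # groups are artifacts -- ringing continuations or noise runs); with no
  # references at all, every group counts
  all_spacings <- unlist(lapply(per_window, function(w) {
    keep <- if (is.null(references)) rep(TRUE, length(w$spacings))
            else w$assignments != "unassigned"
    w$spacings[keep]
  }))
  n_comp <- 0L
  if (length(all_spacings)) {
    sp <- sort(all_spacings)
    n_comp <- 1L
    last <- sp[1]
    for (v in sp[-1]) {
      if ((v - last) / v > distinct_tol) n_comp <- n_comp + 1L
      last <- v
    }
  }
  assigned <- unlist(lapply(per_window, `[[`, "assignments"))
  minor_detected <- !is.null(minor_label) && minor_label %in% assigned

  structure(list(windows = per_window,
                 components_found = n_comp,
                 minor_detected = minor_detected,
                 minor_fraction = minor_fraction,
                 provenance = res$provenance),
            class = "mixture_report")
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf("<mixture_report: %d window(s), %d distinct spacing component(s)%s>\n",
              length(x$windows), x$components_found,
              if (!is.na(x$minor_fraction))
                sprintf(", minor (%.1f%%) %s", 100 * x$minor_fraction,
                        if (x$minor_detected) "detected" else "not detected")
              else ""))
  for (w in x$windows) {
    cat(sprintf("  window %g..%g G:", w$window[1], w$window[2]))
    if (length(w$groups) == 0L) cat(" no groups\n")
    else cat(sprintf(" %s\n", paste(sprintf("%d lines @ %.3g G [%s]",
      vapply(w$groups, `[[`, 0L, "n_lines"), w$spacings, w$assignments),
      collapse = "; ")))
  }
  invisible(x)
}

#' Scan the detection limit of a minor component
#'
#' Mixes two spectra at a series of ratios and records, per ratio, whether
#' the minor component's line-spacing group is still identified.
#'
#' @param a,b `esr_spectrum` objects (b is the minor component when its
#'   weight is the smaller one).
#' @param ratios List of numeric length-2 weight pairs, e.g.
#'   `list(c(2, 1), c(20, 1))`.
#' @param windows,config,references Passed to [analyze_mixture()].
#'   References default to measuring the two pure inputs with
#'   [component_reference()].
#' @return Data frame with columns `ratio`, `minor_fraction`,
#'   `minor_detected`, plus attribute `smallest_detected_fraction`.
#' @export
detection_limit_scan <- function(a, b, ratios, windows,
                                 config = extract_config(cv_tol = 0.12),
                                 references = NULL) {
  if (is.null(references)) {
    lab <- function(s, fb) if (nzchar(s$label)) s$label else fb
    references <- list(component_reference(a, windows, config),
                       component_reference(b, windows, config))
    names(references) <- make.unique(c(lab(a, "component_1"),
                                       lab(b, "component_2")))
  }
  rows <- lapply(ratios, function(r) {
    stopifnot(length(r) == 2L)
    if (r[2] == 0) {
      return(data.frame(ratio = sprintf("%g:%g", r[1], r[2]),
                        minor_fraction = 0, minor_detected = FALSE))
    }
    mm <- mix_spectra(mixture_spec(list(a, b), weights = r))
    rep <- analyze_mixture(mm, windows, config, references)
    data.frame(ratio = sprintf("%g:%g", r[1], r[2]),
               minor_fraction = rep$minor_fraction,
               minor_detected = rep$minor_detected)
  })
  out <- do.call(rbind, rows)
  det <- out$minor_fraction[out$minor_detected]
  attr(out, "smallest_detected_fraction") <-
    if (length(det)) min(det) else NA_real_
  out
}
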