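#' Detect peaks in a spectral component
#'
#' Finds local extrema above a prominence floor and refines each position by
#' three-point parabolic interpolation.  By default extrema of the absolute
#' value are used, because the structure-bearing detail components oscillate
#' with alternating sign; `polarity = "positive"` restricts detection to
#' maxima of the signed component (one peak per oscillation period), which
#' is what the multiplet-extraction pipeline uses so that the inter-peak
#' spacing equals the line spacing rather than half of it.
#'
#' @param component Numeric vector (a full-length node reconstruction or a
#'   raw spectrum).
#' @param field Field axis (G), same length.
#' @param prominence Minimum peak height as a fraction of
#'   `max(abs(component))` (default 0.05).
#' @param polarity `"abs"`, `"positive"` or `"negative"`.
#' @return A data frame of class `peak_list` with columns `position` (G,
#'   refined), `amplitude` (signed component value at the grid extremum)
#'   and `height` (detection-scale value).  Zero rows when no peak
#'   qualifies; an all-zero component yields an empty list, not an error.
#' @export
detect_peaks <- function(component, field, prominence = 0.05,
                         polarity = c("abs", "positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(component) == length(field))
  y <- switch(polarity, abs = abs(component), positive = component,
              negative = -component)
  empty <- structure(data.frame(position = numeric(0),
                                amplitude = numeric(0),
                                height = numeric(0)),
                     class = c("peak_list", "data.frame"))
  mx <- max(abs(component))
  if (mx == 0) return(empty)
  thr <- prominence * mx
  n <- length(y)
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  is_pk <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] >= thr
  idx <- i[is_pk]
  if (length(idx) == 0L) return(empty)
  # parabolic refinement on the detection scale
  ym <- y[idx - 1L]; y0 <- y[idx]; yp <- y[idx + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- ifelse(abs(denom) > 0, 0.5 * (ym - yp) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  step <- field[idx + 1L] - field[idx]
  pos <- field[idx] + delta * step
  out <- data.frame(position = pos, amplitude = component[idx],
                    height = y0 + 0.25 * (yp - ym) * delta)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"),
            prominence_threshold = prominence)
}

.make_group <- function(positions, amplitudes = rep(NA_real_, length(positions))) {
  d <- diff(positions)
  ms <- mean(d)
  cv <- if (length(d) > 1L) stats::sd(d) / ms else 0
  structure(list(
    line_positions = positions, amplitudes = amplitudes,
    mean_spacing = ms, spacing_cv = cv,
    span = positions[length(positions)] - positions[1],
    center = (positions[1] + positions[length(positions)]) / 2,
    n_lines = length(positions)
  ), class = "multiplet_group")
}

#' @export
print.multiplet_group <- function(x, ...) {
  cat(sprintf("<multiplet_group: %d lines, spacing %.4g G (cv %.3g), center %.6g G>\n",
              x$n_lines, x$mean_spacing, x$spacing_cv, x$center))
  invisible(x)
}

#' Group peaks into evenly spaced multiplets
#'
#' A genuine hyperfine multiplet shows a uniform inter-peak spacing, while
#' decomposition artifacts show varying spacing; that evenness is the sole
#' acceptance criterion used here.  Maximal runs of consecutive peaks whose
#' spacing coefficient of variation is at most `cv_tol` and that contain at
#' least `min_lines` peaks are accepted; overlapping candidate runs are
#' resolved in favor of more lines, then lower cv.  Peaks belonging to no
#' accepted run are reported as artifacts.
#'
#' @param peaks A `peak_list` (sorted by position).
#' @param cv_tol Maximum spacing coefficient of variation (default 0.10).
#' @param min_lines Minimum lines per group (default 3).
#' @return List of `multiplet_group` objects ordered by first line, with an
#'   attribute `artifacts`: positions of the unexplained peaks.
#' @export
find_even_groups <- function(peaks, cv_tol = 0.10, min_lines = 3L) {
  pos <- peaks$position
  amp <- if (!is.null(peaks$amplitude)) peaks$amplitude else rep(NA_real_, length(pos))
  np <- length(pos)
  if (np < min_lines)
    return(structure(list(), artifacts = pos))

  # enumerate contiguous candidate runs meeting the evenness criterion,
  # with running spacing sums (runs capped at 64 lines; hyperfine
  # multiplets in practice have far fewer)
  max_run <- 64L
  d_all <- diff(pos)
  ci <- integer(0); cj <- integer(0); cn <- integer(0); ccv <- numeric(0)
  for (i in seq_len(np - min_lines + 1L)) {
    s1 <- 0; s2 <- 0
    jmax <- min(np, i + max_run - 1L)
    for (j in seq.int(i + 1L, jmax)) {
      d <- d_all[j - 1L]
      s1 <- s1 + d; s2 <- s2 + d * d
      nd <- j - i
      if (j - i + 1L < min_lines) next
      mu <- s1 / nd
      v <- max(0, (s2 - nd * mu * mu) / (nd - 1L))
      cv <- sqrt(v) / mu
      if (is.finite(cv) && cv <= cv_tol) {
        ci <- c(ci, i); cj <- c(cj, j); cn <- c(cn, j - i + 1L)
        ccv <- c(ccv, cv)
      }
    }
  }
  if (length(ci) == 0L)
    return(structure(list(), artifacts = pos))
  ord <- order(-cn, ccv)
  used <- rep(FALSE, np)
  groups <- list()
  for (k in ord) {
    rng <- ci[k]:cj[k]
    if (any(used[rng])) next
    used[rng] <- TRUE
    groups[[length(groups) + 1L]] <- .make_group(pos[rng], amp[rng])
  }
  groups <- groups[order(vapply(groups, function(g) g$line_positions[1], 0))]
  structure(groups, artifacts = pos[!used])
}

#' Hyperfine coupling constant of an evenly spaced multiplet
#'
#' The coupling constant in gauss equals the mean inter-line spacing,
#' i.e. the group span divided by the number of intervals.
#'
#' @param g A `multiplet_group` with at least 3 lines.
#' @return Coupling constant A in gauss.
#' @export
coupling_from_group <- function(g) {
  stopifnot(inherits(g, "multiplet_group"))
  if (g$n_lines < 3L)
    stop("a multiplet group needs at least 3 lines, got ", g$n_lines)
  g$mean_spacing
}

#' Number of equivalent nuclei from a multiplet line count
#'
#' Inverts the first-order multiplicity rule m = 2 n I + 1 for n equivalent
#' spin-I nuclei.
#'
#' @param m Observed number of lines (>= 2).
#' @param I Nuclear spin (1 for 14N, 1/2 for 1H, 3/2 for Cu).
#' @return Integer n, or `NA` when `(m - 1) / (2 I)` is not a positive
#'   integer (inconsistent multiplicity).
#' @examples
#' nuclei_from_multiplicity(5, 1)  # 2
#' nuclei_from_multiplicity(9, 1)  # 4
#' nuclei_from_multiplicity(4, 1)  # NA
#' @export
nuclei_from_multiplicity <- function(m, I) {
  stopifnot(m >= 2, I > 0)
  n <- (m - 1) / (2 * I)
  if (abs(n - round(n)) > 1e-9 || round(n) < 1) return(NA_integer_)
  as.integer(round(n))
}

#' Multiplicity of n equivalent spin-I nuclei
#' @param n Number of equivalent nuclei.
#' @param I Nuclear spin.
#' @return m = 2 n I + 1.
#' @export
multiplicity_from_nuclei <- function(n, I) 2 * n * I + 1

#' Infer the nitrogen multiplicity and quartet edge fields
#'
#' In the g-perp window of a Cu(II) spectrum the copper quartet lines h-1
#' ... h-4 each split into an m-line nitrogen multiplet; overlap hides the
#' interior, but the leading lines of the h-1 multiplet and the trailing
#' lines of the h-4 multiplet remain clean at the window edges.  This takes
#' the lowest- and highest-field even groups inside the window, scores the
#' candidate multiplicities m = 2 n I + 1 (n = 1..6) by how well the edge
#' line counts match the expected `ceiling((m + 1) / 2)` visible lines and
#' by the agreement of the two groups' spacings, and returns the
#' best-scoring consistent assignment.
#'
#' The low group holds the leading lines of the h-1 multiplet, which is
#' centered at h-1, and the high group the trailing lines of the h-4
#' multiplet, so the cleanest markers are the two outermost lines of the
#' whole pattern: `h1 = lowest line + (m - 1)/2 * A` and `h4 = highest
#' line - (m - 1)/2 * A`.  (With three clean 26.5 G lines from 3150 G and
#' a high edge ending at 3367 G this gives the canonical h-1 = 3203 G,
#' h-4 = 3314 G quartet.)  Candidate multiplicities are scored on missing
#' edge lines only -- spectral overlap routinely extends a run inward, so
#' extra lines never penalize -- and a candidate is valid only when the
#' implied quartet spans at least two nitrogen spacings; among valid
#' zero-penalty candidates the largest m (the most structure explained)
#' wins.
#'
#' @param groups List of `multiplet_group` objects.
#' @param window Numeric length-2: field window (G) to consider.
#' @param I Nuclear spin of the splitting nuclei (default 1, nitrogen).
#' @param count_slack Total allowed mismatch, in lines, between observed and
#'   expected edge line counts (default 2: spectral overlap may hide one
#'   line per edge).
#' @return `NULL` when no consistent candidate exists; otherwise a list
#'   with `m`, `n`, `h1`, `h4`, `A_fine` (spacing pooled over both edge
#'   groups) and `score`.
#' @export
infer_multiplicity_from_edges <- function(groups, window, I = 1,
                                          count_slack = 2L) {
  inw <- Filter(function(g) g$line_positions[1] >= window[1] &&
                  g$line_positions[g$n_lines] <= window[2], groups)
  if (length(inw) == 0L) return(NULL)
  firsts <- vapply(inw, function(g) g$line_positions[1], 0)
  lasts <- vapply(inw, function(g) g$line_positions[g$n_lines], 0)
  lo <- inw[[which.min(firsts)]]
  hi <- inw[[which.max(lasts)]]
  if (identical(lo, hi) && length(inw) < 2L) return(NULL)

  # pooled spacing, weighted by interval count
  w_lo <- lo$n_lines - 1L; w_hi <- hi$n_lines - 1L
  A <- (lo$mean_spacing * w_lo + hi$mean_spacing * w_hi) / (w_lo + w_hi)
  spacing_mismatch <- abs(lo$mean_spacing - hi$mean_spacing) / A

  x_lo <- lo$line_positions[1]
  x_hi <- hi$line_positions[hi$n_lines]
  best <- NULL
  for (n in 1:6) {
    m <- 2 * n * I + 1
    if (abs(m - round(m)) > 1e-9) next
    m <- as.integer(round(m))
    k <- as.integer(ceiling((m + 1) / 2))   # expected visible edge lines
    score <- max(0L, k - lo$n_lines) + max(0L, k - hi$n_lines)
    if (score > count_slack) next
    h1 <- x_lo + (m - 1) / 2 * A
    h4 <- x_hi - (m - 1) / 2 * A
    if (h4 < h1 + 2 * A) next               # quartet must outspan the comb
    if (is.null(best) || score < best$score ||
        (score == best$score && m > best$m))
      best <- list(m = m, n = n, score = score, h1 = h1, h4 = h4)
  }
  if (is.null(best) || spacing_mismatch > 0.25) return(NULL)
  list(m = best$m, n = best$n, h1 = best$h1, h4 = best$h4,
       A_fine = A, score = best$score)
}

#' Cu(II) quartet parameters from the edge line fields
#'
#' The copper nucleus (I = 3/2) splits the g-perp resonance into four
#' equally spaced lines h-1 ... h-4, so the copper hyperfine coupling is
#' one third of the outer separation and the g value follows from the
#' quartet center and the microwave frequency:
#' `A_Cu = (h4 - h1) / 3`, `g = 714.4773 * nu[GHz] / B_center[G]` with
#' `B_center = (h1 + h4) / 2` (714.4773 G GHz^-1 is h/mu_B, CODATA 2018).
#'
#' @param h1,h4 Fields (G) of the first and last quartet line, `h4 > h1`.
#' @param mw_frequency_ghz Microwave frequency (GHz), positive.
#' @return List with `A_cu` (G), `g`, `center` (G) and `quartet_positions`
#'   (the four implied line fields).
#' @examples
#' cu_quartet_params(3203, 3314, 9.316)  # A_cu = 37 G, g = 2.0427
#' @export
cu_quartet_params <- function(h1, h4, mw_frequency_ghz) {
  if (!(h4 > h1)) stop("h4 must exceed h1 (got h1 = ", h1, ", h4 = ", h4, ")")
  if (!(mw_frequency_ghz > 0)) stop("mw_frequency_ghz must be positive")
  A_cu <- (h4 - h1) / 3
  center <- (h1 + h4) / 2
  g <- G_PER_GHZ * mw_frequency_ghz / center
  list(A_cu = A_cu, g = g, center = center,
       quartet_positions = h1 + A_cu * 0:3)
}
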