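# Conversion constant h/mu_B in G * GHz^-1 (CODATA 2018):
# g = (h/mu_B) * nu / B  with nu in GHz and B in gauss.
G_PER_GHZ <- 714.4773

# Orthonormal scaling (lowpass reconstruction) filters.  Values are the
# standard published Daubechies / Coiflet coefficient tables, stored to
# double precision.  The quadrature-mirror identities are asserted in the
# test suite to 1e-10.
.scaling_filters <- list(
  db6 = rev(c(
    -1.0773010853084796e-03, 4.7772575109455108e-03, 5.5384220116149613e-04,
    -3.1582039317486030e-02, 2.7522865530305727e-02, 9.7501605587323043e-02,
    -1.2976686756726194e-01, -2.2626469396543983e-01, 3.1525035170919763e-01,
    7.5113390802109536e-01, 4.9462389039845306e-01, 1.1154074335010947e-01)),
  db9 = rev(c(
    3.9347320316271603e-05, -2.5196318894271012e-04, 2.3038576352319597e-04,
    1.8476468830562265e-03, -4.2815036824634303e-03, -4.7232047577513972e-03,
    2.2361662123679096e-02, 2.5094711483145197e-04, -6.7632829061329974e-02,
    3.0725681479333380e-02, 1.4854074933810638e-01, -9.6840783222976456e-02,
    -2.9327378327917492e-01, 1.3319738582500756e-01, 6.5728807805130052e-01,
    6.0482312369011115e-01, 2.4383467461259034e-01, 3.8077947363878345e-02)),
  coif3 = rev(c(
    -3.4599773197272781e-05, -7.0983302506379004e-05, 4.6621695982040288e-04,
    1.1175187708306303e-03, -2.5745176881367972e-03, -9.0079761367306242e-03,
    1.5880544863669452e-02, 3.4555027573297738e-02, -8.2301927106299827e-02,
    -7.1799821619154838e-02, 4.2848347637737000e-01, 7.9377722262608719e-01,
    4.0517690240911824e-01, -6.1123390002972552e-02, -6.5771911281469364e-02,
    2.3452696142077168e-02, 7.7825964256727463e-03, -3.7935128643808019e-03))
)

#' Orthogonal wavelet filter set
#'
#' Returns the analysis and synthesis filters of one of the three orthogonal
#' wavelets supported by the decomposition engine.  `db9` is the default
#' wavelet throughout the package; `db6` and `coif3` are provided to check
#' the robustness of an analysis against the choice of wavelet.
#'
#' The highpass (wavelet) filter is derived from the scaling filter `h` by
#' the alternating-flip rule `g[k] = (-1)^k h[L - 1 - k]`, so the pair
#' satisfies the quadrature-mirror (perfect reconstruction) identities of an
#' orthonormal filter bank.
#'
#' @param name One of `"db9"`, `"db6"`, `"coif3"`.
#' @return An object of class `wavelet_spec`: a list with elements `name`,
#'   `length`, `rec_lo`, `rec_hi` (synthesis filters) and `dec_lo`, `dec_hi`
#'   (analysis filters, the time-reversed synthesis filters).
#' @examples
#' w <- wavelet_filters("db9")
#' sum(w$rec_lo^2)           # unit energy
#' sum(w$rec_lo * w$rec_hi)  # orthogonal pair
#' @export
wavelet_filters <- function(name = c("db9", "db6", "coif3")) {
  name <- match.arg(name)
  h <- .scaling_filters[[name]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(list(
    name = name, length = L,
    rec_lo = h, rec_hi = g,
    dec_lo = rev(h), dec_hi = rev(g)
  ), class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec %s: %d-tap orthonormal filter pair>\n",
              x$name, x$length))
  invisible(x)
}

.as_wavelet <- function(w) {
  if (inherits(w, "wavelet_spec")) w else wavelet_filters(w)
}
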