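#' Construct a field-swept ESR spectrum
#'
#' The basic container consumed by every stage of the analysis: a magnetic
#' field axis in gauss and the first-derivative absorption intensity
#' recorded at each field, plus the microwave frequency needed for g-value
#' work.
#'
#' @param field Numeric vector of magnetic-field values (gauss), strictly
#'   increasing.
#' @param intensity Numeric vector, same length as `field`; first-derivative
#'   intensity in arbitrary units.
#' @param mw_frequency_ghz Microwave frequency in GHz (`NA` when unknown;
#'   required only for g-value extraction).
#' @param label Free-text label.
#' @param meta Named list of additional metadata (temperature, modulation
#'   amplitude, source file, simulation ground truth, ...).
#' @return An object of class `esr_spectrum`.
#' @export
esr_spectrum <- function(field, intensity, mw_frequency_ghz = NA_real_,
                         label = "", meta = list()) {
  s <- structure(list(
    field = as.numeric(field), intensity = as.numeric(intensity),
    mw_frequency_ghz = as.numeric(mw_frequency_ghz)[1],
    label = as.character(label)[1], meta = meta
  ), class = "esr_spectrum")
  validate_spectrum(s)
  s
}

#' Validate an ESR spectrum object
#'
#' Checks the container invariants: equal-length finite field/intensity
#' vectors with at least 16 points and a strictly increasing field axis.
#' Called by the constructor and by [read_spectrum()]; exported so that
#' externally assembled objects can be checked too.
#'
#' @param s An `esr_spectrum`.
#' @return `s`, invisibly; errors on violation.
#' @export
validate_spectrum <- function(s) {
  if (!is.numeric(s$field) || !is.numeric(s$intensity))
    stop("field and intensity must be numeric")
  if (length(s$field) != length(s$intensity))
    stop("field and intensity must have the same length")
  if (length(s$field) < 16L)
    stop("spectrum must have at least 16 points, got ", length(s$field))
  if (anyNA(s$field) || anyNA(s$intensity) ||
      any(!is.finite(s$field)) || any(!is.finite(s$intensity)))
    stop("field and intensity must be finite and non-missing")
  if (any(diff(s$field) <= 0))
    stop("field axis must be strictly increasing")
  if (!is.na(s$mw_frequency_ghz) && s$mw_frequency_ghz <= 0)
    stop("mw_frequency_ghz must be positive")
  invisible(s)
}

#' @export
print.esr_spectrum <- function(x, ...) {
  cat(sprintf("<esr_spectrum%s: %d points, %.6g..%.6g G%s>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$field), x$field[1], x$field[length(x$field)],
              if (is.na(x$mw_frequency_ghz)) ""
              else sprintf(", %.6g GHz", x$mw_frequency_ghz)))
  invisible(x)
}

#' @export
plot.esr_spectrum <- function(x, ...,
                              xlab = "Magnetic field (G)",
                              ylab = "dI/dB (arb. units)", type = "l") {
  graphics::plot(x$field, x$intensity, type = type,
                 xlab = xlab, ylab = ylab,
                 main = if (nzchar(x$label)) x$label else "", ...)
  invisible(x)
}

#' Read a two-column ESR spectrum from a text file
#'
#' Accepts whitespace- or comma-separated two-column text (column 1 = field
#' in gauss, column 2 = intensity) with `#` or `;` comment lines, and CSV
#' with a `field_g,intensity` header.  A strictly decreasing field axis
#' (down-sweep) is reversed on read, together with the intensity column.
#'
#' @param path File path.
#' @param mw_frequency_ghz Microwave frequency in GHz, stored as metadata.
#' @param dialect `"auto"` (default), `"two_column_ascii"` or `"csv"`.
#' @param mT If `TRUE`, field values are read as millitesla and converted
#'   to gauss (x 10).
#' @return An `esr_spectrum`.
#' @export
read_spectrum <- function(path, mw_frequency_ghz = NA_real_,
                          dialect = c("auto", "two_column_ascii", "csv"),
                          mT = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#;]|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no data rows in ", path)

  header <- grepl("^\\s*field_g\\s*,", lines[1], ignore.case = TRUE)
  if (dialect == "csv" && !header && grepl("[A-Za-z]", lines[1]))
    header <- TRUE
  if (header) { lines <- lines[-1]; lineno <- lineno[-1] }

  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  field <- numeric(length(parts)); intensity <- numeric(length(parts))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop(sprintf("cannot parse numeric field/intensity pair on line %d of %s: '%s'",
                   lineno[i], path, lines[i]))
    field[i] <- v[1]; intensity[i] <- v[2]
  }
  if (mT) field <- field * 10

  reversed <- FALSE
  if (length(field) > 1L && all(diff(field) < 0)) {
    field <- rev(field); intensity <- rev(intensity); reversed <- TRUE
    message("field axis was decreasing; both columns reversed on read")
  }
  s <- esr_spectrum(field, intensity, mw_frequency_ghz,
                    label = basename(path),
                    meta = list(source_file = path, reversed = reversed))
  s
}

#' Write a spectrum to a two-column text file
#'
#' @param s An `esr_spectrum`.
#' @param path Output path.
#' @param format `"two_column_ascii"` (space separated) or `"csv"` (with a
#'   `field_g,intensity` header).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("two_column_ascii", "csv")) {
  format <- match.arg(format)
  validate_spectrum(s)
  sep <- if (format == "csv") "," else " "
  rows <- paste(sprintf("%.17g", s$field), sprintf("%.17g", s$intensity),
                sep = sep)
  hdr <- if (format == "csv") "field_g,intensity"
         else sprintf("# %s | field (G), dI/dB", s$label)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.next_pow2 <- function(n) as.integer(round(2^ceiling(log2(n))))

.is_pow2 <- function(n) n > 0 && abs(log2(n) - round(log2(n))) < 1e-12

#' Resample a spectrum onto a uniform dyadic grid
#'
#' Downstream dyadic decimation requires a constant sampling step and a
#' power-of-two length.  The intensity is linearly interpolated onto a
#' uniform grid whose step is the median of the input steps, then padded to
#' the next power of two.  Symmetric (mirror) padding is the default: it
#' avoids the edge discontinuities that zero padding would inject into the
#' detail components of a derivative spectrum.
#'
#' Already-uniform inputs (relative step deviation below 1e-6) of dyadic
#' length pass through unchanged with `pad_left = pad_right = 0`.
#'
#' @param s An `esr_spectrum`.
#' @param pad_mode `"symmetric"` (mirror about the edge), `"zero"`, or
#'   `"edge"` (repeat the edge value).
#' @return An object of class `esr_uniform` (inherits `esr_spectrum`) with
#'   extra fields `step_gauss`, `pad_left`, `pad_right`, `original_range`
#'   and `n_interp` (grid points before padding).
#' @export
to_uniform <- function(s, pad_mode = c("symmetric", "zero", "edge")) {
  pad_mode <- match.arg(pad_mode)
  validate_spectrum(s)
  if (inherits(s, "esr_uniform")) return(s)

  d <- diff(s$field)
  step <- stats::median(d)
  uniform <- max(abs(d - step)) / step < 1e-6

  if (uniform && .is_pow2(length(s$field))) {
    grid <- s$field; y <- s$intensity; n_interp <- length(grid)
    pl <- 0L; pr <- 0L
  } else {
    n_interp <- as.integer(floor((s$field[length(s$field)] - s$field[1]) /
                                   step + 1e-9)) + 1L
    grid <- s$field[1] + step * (seq_len(n_interp) - 1L)
    y <- stats::approx(s$field, s$intensity, xout = grid, rule = 2)$y
    n_out <- .next_pow2(n_interp)
    extra <- as.integer(n_out - n_interp)
    pl <- extra %/% 2L; pr <- extra - pl
    pad_vals <- function(v, k, side) {
      if (k == 0L) return(numeric(0))
      switch(pad_mode,
        zero = rep(0, k),
        edge = rep(if (side == "l") v[1] else v[length(v)], k),
        symmetric = if (side == "l") rev(v[seq_len(min(k, length(v)))])
                    else rev(rev(v)[seq_len(min(k, length(v)))])
      )
    }
    lv <- pad_vals(y, pl, "l"); rv <- pad_vals(y, pr, "r")
    # mirror padding cannot exceed the signal length; fall back to edge
    if (length(lv) < pl) lv <- c(rep(lv[1], pl - length(lv)), lv)
    if (length(rv) < pr) rv <- c(rv, rep(rv[length(rv)], pr - length(rv)))
    y <- c(lv, y, rv)
    grid <- s$field[1] + step * (seq_len(n_interp + pl + pr) - 1L - pl)
  }

  structure(list(
    field = grid, intensity = y,
    mw_frequency_ghz = s$mw_frequency_ghz, label = s$label,
    meta = s$meta,
    step_gauss = step, pad_left = pl, pad_right = pr,
    original_range = range(s$field), n_interp = n_interp,
    pad_mode = pad_mode
  ), class = c("esr_uniform", "esr_spectrum"))
}

#' Remove padding from a uniform spectrum
#'
#' Inverse of the padding step of [to_uniform()]: restricts a uniform
#' spectrum (or any same-length signal evaluated on its grid) back to the
#' resampled original field range.
#'
#' @param u An `esr_uniform`.
#' @param signal Optional replacement intensity vector of the padded length
#'   (e.g. a reconstructed component); defaults to `u$intensity`.
#' @return An `esr_spectrum` on the unpadded grid.
#' @export
strip_pads <- function(u, signal = NULL) {
  stopifnot(inherits(u, "esr_uniform"))
  y <- if (is.null(signal)) u$intensity else signal
  stopifnot(length(y) == length(u$field))
  idx <- seq.int(u$pad_left + 1L, u$pad_left + u$n_interp)
  esr_spectrum(u$field[idx], y[idx], u$mw_frequency_ghz, u$label, u$meta)
}
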