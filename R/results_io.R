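# stable flat-table views of the two result objects; key names documented
# in the README

.group_row <- function(g) {
  data.frame(n_lines = g$n_lines, mean_spacing_G = g$mean_spacing,
             spacing_cv = g$spacing_cv, span_G = g$span,
             center_G = g$center,
             line_positions_G = paste(sprintf("%.17g", g$line_positions),
                                      collapse = ";"))
}

.hyperfine_df <- function(r) {
  qp <- r$quartet_positions
  data.frame(
    A_fine_G = r$A_fine, n_nuclei = r$n_nuclei,
    nuclear_spin = r$nuclear_spin, A_cu_G = r$A_cu, g_value = r$g_value,
    h1_G = qp[1], h2_G = qp[2], h3_G = qp[3], h4_G = qp[4],
    region = r$region, no_structure = r$no_structure,
    wavelet = r$provenance$wavelet, level = r$provenance$level,
    node = r$provenance$node_label)
}

.mixture_df <- function(r) {
  rows <- list()
  for (w in r$windows) {
    if (length(w$groups) == 0L) next
    for (i in seq_along(w$groups)) {
      g <- .group_row(w$groups[[i]])
      g <- cbind(data.frame(window_lo_G = w$window[1],
                            window_hi_G = w$window[2]), g,
                 data.frame(assigned_component = w$assignments[i],
                            minor_detected = r$minor_detected,
                            minor_fraction = r$minor_fraction))
      rows[[length(rows) + 1L]] <- g
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(window_lo_G = numeric(0), window_hi_G = numeric(0),
                     n_lines = integer(0), mean_spacing_G = numeric(0),
                     spacing_cv = numeric(0), span_G = numeric(0),
                     center_G = numeric(0), line_positions_G = character(0),
                     assigned_component = character(0),
                     minor_detected = logical(0), minor_fraction = numeric(0))
    return(df)
  }
  do.call(rbind, rows)
}

.write_csv_precise <- function(df, path) {
  fmt <- vapply(seq_along(df), function(j) {
    if (is.numeric(df[[j]])) sprintf("%.17g", df[[j]])
    else as.character(df[[j]])
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  if (nrow(df) == 0L) fmt <- matrix(character(0), ncol = ncol(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path)
}

#' Write an analysis result to CSV or JSON
#'
#' CSV gives a flat table (one row for a hyperfine result; one row per
#' detected group for a mixture report, header only when empty).  JSON
#' serializes the full object at full double precision and round-trips
#' through [read_result()].
#'
#' @param result A `hyperfine_result` or `mixture_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!inherits(result, c("hyperfine_result", "mixture_report")))
    stop("result must be a hyperfine_result or mixture_report")
  if (format == "json") {
    strip <- function(x) {
      if (is.list(x) && !is.data.frame(x)) {
        x <- lapply(x, strip)
        attributes(x) <- list(names = names(x))
      }
      x
    }
    payload <- list(type = class(result)[1], data = strip(unclass(result)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  } else {
    df <- if (inherits(result, "hyperfine_result")) .hyperfine_df(result)
          else .mixture_df(result)
    .write_csv_precise(df, path)
  }
  invisible(path)
}

#' Read back a result written by [write_result()]
#'
#' JSON restores the full `hyperfine_result` / `mixture_report` object;
#' CSV returns the flat data frame.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return A result object (JSON) or data frame (CSV).
#' @export
read_result <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv")
    return(utils::read.csv(path, stringsAsFactors = FALSE))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  nums <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_
                             else as.numeric(v), 0)
  relist_group <- function(g)
    .make_group(nums(g$line_positions),
                if (!is.null(g$amplitudes)) nums(g$amplitudes)
                else rep(NA_real_, length(g$line_positions)))
  relist_window <- function(w) {
    w$window <- nums(w$window)
    w$groups <- lapply(w$groups, relist_group)
    if (!is.null(w$artifacts)) w$artifacts <- nums(w$artifacts)
    for (f in c("A_fine", "A_cu", "g_value")) {
      if (f %in% names(w)) w[[f]] <- num1(w[[f]])
    }
    if ("quartet_positions" %in% names(w))
      w$quartet_positions <- nums(w$quartet_positions)
    if ("spacings" %in% names(w)) w$spacings <- nums(w$spacings)
    if ("assignments" %in% names(w))
      w$assignments <- as.character(unlist(w$assignments))
    w
  }
  obj <- payload$data
  obj$windows <- lapply(obj$windows, relist_window)
  if (identical(payload$type, "hyperfine_result")) {
    for (f in c("A_fine", "A_cu", "g_value", "nuclear_spin"))
      obj[[f]] <- num1(obj[[f]])
    obj$n_nuclei <- if (is.null(obj$n_nuclei)) NA_integer_
                    else as.integer(obj$n_nuclei)
    obj$quartet_positions <- nums(obj$quartet_positions)
    obj$no_structure <- isTRUE(obj$no_structure)
    class(obj) <- "hyperfine_result"
  } else if (identical(payload$type, "mixture_report")) {
    obj$components_found <- as.integer(obj$components_found)
    obj$minor_detected <- isTRUE(obj$minor_detected)
    obj$minor_fraction <- num1(obj$minor_fraction)
    class(obj) <- "mixture_report"
  }
  obj
}
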