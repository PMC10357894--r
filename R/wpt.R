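# One periodized analysis step: circular correlation with filter f,
# decimated by two.  Rows of the implied operator are the even circular
# shifts of f, so with the orthonormal scaling/wavelet pair the two-channel
# step is an orthogonal map and the synthesis step below is its transpose.
.ana_step <- function(x, f) {
  n <- length(x); m <- n %/% 2L
  out <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (j in seq_along(f)) {
    out <- out + f[j] * x[((base + (j - 1L)) %% n) + 1L]
  }
  out
}

# Transpose of .ana_step for a channel pair: upsample-and-filter both
# channels and sum.  Either channel may be NULL (treated as zero), which is
# how single-node reconstructions are computed.
.syn_step <- function(a, d, lo, hi) {
  m <- if (is.null(a)) length(d) else length(a)
  n <- 2L * m
  x <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (j in seq_along(lo)) {
    idx <- ((base + (j - 1L)) %% n) + 1L
    contrib <- numeric(m)
    if (!is.null(a)) contrib <- contrib + lo[j] * a
    if (!is.null(d)) contrib <- contrib + hi[j] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

.check_path <- function(path) {
  if (!is.character(path) || length(path) != 1L ||
      grepl("[^AD]", path))
    stop("node path must be a string over {A, D}, e.g. \"AAD\"")
  path
}

#' Wavelet packet decomposition of a uniform spectrum
#'
#' Builds the full binary tree of approximation (lowpass, `A`) and detail
#' (highpass, `D`) coefficient nodes down to `max_level`.  The transform is
#' the periodized orthogonal filter bank, so at every level the 2^j nodes
#' form an orthogonal decomposition of the input: coefficient energy is
#' conserved and the sum of the single-node reconstructions reproduces the
#' input to machine precision.
#'
#' Node paths are written root-to-node, so `"AAD"` is the detail component
#' split off the twice-approximated branch at level 3 (rendered `DAA3` in
#' the level-suffixed display convention, see [paper_node_label()]).
#'
#' @param u An `esr_uniform` (see [to_uniform()]) or a plain numeric vector
#'   of power-of-two length.
#' @param wavelet A `wavelet_spec` or wavelet name (default `"db9"`).
#' @param max_level Deepest level to decompose to; must not exceed
#'   `N = log2(p)` where `p` is the signal length.
#' @return An object of class `wpt_tree`: list with `wavelet`, `max_level`,
#'   `p`, `field`, `source` and `nodes` (named list, path -> coefficient
#'   vector of length `p / 2^level`; the root path is `""`).
#' @seealso [wpt_reconstruct()], [wpt_node()], [dwt_chain()]
#' @export
wpt_decompose <- function(u, wavelet = "db9", max_level = 5L) {
  w <- .as_wavelet(wavelet)
  if (inherits(u, "esr_uniform")) {
    x <- u$intensity; field <- u$field; src <- u
  } else if (is.numeric(u)) {
    x <- as.numeric(u); field <- seq_along(x); src <- NULL
  } else stop("u must be an esr_uniform or a numeric vector (see to_uniform)")
  p <- length(x)
  if (!.is_pow2(p)) stop("signal length must be a power of two, got ", p)
  N <- as.integer(round(log2(p)))
  max_level <- as.integer(max_level)
  if (max_level < 1L || max_level > N)
    stop(sprintf("max_level must be in 1..N = log2(p) = %d, got %d",
                 N, max_level))

  nodes <- list(); nodes[[1]] <- x; names(nodes) <- ""
  frontier <- ""
  for (lvl in seq_len(max_level)) {
    nxt <- character(0)
    for (pp in frontier) {
      xx <- nodes[[match(pp, names(nodes))]]
      a <- .ana_step(xx, w$dec_lo)
      d <- .ana_step(xx, w$dec_hi)
      nodes[[paste0(pp, "A")]] <- a
      nodes[[paste0(pp, "D")]] <- d
      nxt <- c(nxt, paste0(pp, "A"), paste0(pp, "D"))
    }
    frontier <- nxt
  }
  structure(list(wavelet = w, max_level = max_level, p = p, N = N,
                 field = field, source = src, nodes = nodes),
            class = "wpt_tree")
}

#' @export
print.wpt_tree <- function(x, ...) {
  cat(sprintf("<wpt_tree: %s wavelet, p = %d, %d levels, %d nodes>\n",
              x$wavelet$name, x$p, x$max_level, length(x$nodes) - 1L))
  invisible(x)
}

.tree_coeffs <- function(t, path) {
  i <- match(path, names(t$nodes))
  if (is.na(i)) {
    lvl <- nchar(path)
    valid <- names(t$nodes)[nchar(names(t$nodes)) == lvl]
    stop(sprintf("unknown node path '%s'; valid level-%d paths: %s",
                 path, lvl, paste(valid, collapse = ", ")))
  }
  t$nodes[[i]]
}

#' Reconstruct a single tree node to full length
#'
#' Inverts the filter bank with every coefficient outside the named node set
#' to zero, returning that node's contribution to the input signal on the
#' original field axis.  Summing the reconstructions of all 2^j nodes of one
#' level reproduces the input exactly (orthogonal transform).
#'
#' @param t A `wpt_tree`.
#' @param path Node path over `{A, D}` (root-to-node); `""` returns the
#'   input signal itself.
#' @return Numeric vector of length `t$p`.
#' @export
wpt_reconstruct <- function(t, path) {
  .check_path(path)
  x <- .tree_coeffs(t, path)
  w <- t$wavelet
  letters <- strsplit(path, "")[[1]]
  for (ch in rev(letters)) {
    # synthesis is the transpose of the analysis step, so it upsamples
    # through the same (analysis) filters
    x <- if (ch == "A") .syn_step(x, NULL, w$dec_lo, w$dec_hi)
         else .syn_step(NULL, x, w$dec_lo, w$dec_hi)
  }
  x
}

#' Extract one node of a packet tree
#'
#' @param t A `wpt_tree`.
#' @param path Node path (see [wpt_reconstruct()]).
#' @return A list of class `wpt_node`: `path`, `level`, `coeffs`, `recon`
#'   (full-length single-node reconstruction) and `field`.
#' @export
wpt_node <- function(t, path) {
  .check_path(path)
  structure(list(path = path, level = nchar(path),
                 coeffs = .tree_coeffs(t, path),
                 recon = wpt_reconstruct(t, path),
                 field = t$field),
            class = "wpt_node")
}

#' @export
print.wpt_node <- function(x, ...) {
  cat(sprintf("<wpt_node %s (%s): level %d, %d coefficients>\n",
              if (nzchar(x$path)) x$path else "<root>",
              paper_node_label(x$path), x$level, length(x$coeffs)))
  invisible(x)
}

#' Plain discrete wavelet transform chain
#'
#' The DWT repeatedly splits only the approximation branch; its level-j
#' components coincide with the packet-tree nodes `"A...A"` and `"A...AD"`.
#'
#' @param u As in [wpt_decompose()].
#' @param wavelet Wavelet name or `wavelet_spec`.
#' @param levels Number of levels.
#' @return List with one element per level: `list(level, A, D, recon_A,
#'   recon_D)` where `A`/`D` are coefficient vectors and the `recon_*`
#'   entries are full-length single-node reconstructions.
#' @export
dwt_chain <- function(u, wavelet = "db9", levels = 4L) {
  t <- wpt_decompose(u, wavelet, max_level = levels)
  lapply(seq_len(levels), function(j) {
    ap <- strrep("A", j)
    dp <- paste0(strrep("A", j - 1L), "D")
    list(level = j,
         A = .tree_coeffs(t, ap), D = .tree_coeffs(t, dp),
         recon_A = wpt_reconstruct(t, ap),
         recon_D = wpt_reconstruct(t, dp))
  })
}

#' Nominal frequency band of a packet node
#'
#' Returns the frequency interval (cycles per sample, within `[0, 0.5]`)
#' that a node's filter path selects.  Because highpass-and-decimate
#' reverses the spectrum of the retained band, the A/D children swap roles
#' in every branch below an odd number of `D` steps (Gray-code frequency
#' ordering); this bookkeeping is handled here.
#'
#' @param path Node path over `{A, D}`.
#' @return Numeric length-2: band limits in cycles/sample.
#' @examples
#' node_band("A")    # 0 .. 0.25
#' node_band("AAD")  # 0.0625 .. 0.125
#' @export
node_band <- function(path) {
  .check_path(path)
  lo <- 0; hi <- 0.5; inv <- FALSE
  for (ch in strsplit(path, "")[[1]]) {
    mid <- (lo + hi) / 2
    take_low <- (ch == "A") != inv
    if (take_low) hi <- mid else lo <- mid
    if (ch == "D") inv <- !inv
  }
  c(lo, hi)
}

# Sum of the reconstructions of all level-`level` nodes whose nominal band
# intersects [f_lo, f_hi]: an orthogonal projection onto a contiguous
# frequency band assembled from the packet tree.  With the frequency of
# interest interior to the union, the edge images that perturb single-node
# reconstructions cancel.
.band_reconstruct <- function(t, f_lo, f_hi, level) {
  level <- min(level, t$max_level)
  paths <- names(t$nodes)[nchar(names(t$nodes)) == level]
  out <- numeric(t$p)
  for (pp in paths) {
    b <- node_band(pp)
    if (b[2] > f_lo && b[1] < f_hi) out <- out + wpt_reconstruct(t, pp)
  }
  out
}

#' Level-suffixed display name of a node path
#'
#' Converts a root-to-node path such as `"AAD"` into the display convention
#' that appends the newest filter on the left and suffixes the level:
#' `"DAA3"`.  The root is rendered `"S0"` (the source signal).
#'
#' @param path Node path over `{A, D}`.
#' @return Character scalar.
#' @examples
#' paper_node_label("AAD")   # "DAA3"
#' paper_node_label("AADA")  # "ADAA4"
#' @export
paper_node_label <- function(path) {
  .check_path(path)
  if (!nzchar(path)) return("S0")
  paste0(paste(rev(strsplit(path, "")[[1]]), collapse = ""), nchar(path))
}

#' Dump all nodes of a tree as per-node CSV files
#'
#' Writes one `field_g,recon_intensity` CSV per node into `dir` (created if
#' needed), named `<wavelet>_level<j>_<label>.csv`.
#'
#' @param t A `wpt_tree`.
#' @param dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
wpt_dump <- function(t, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setdiff(names(t$nodes), "")
  files <- character(0)
  for (pp in paths) {
    f <- file.path(dir, sprintf("%s_level%d_%s.csv",
                                t$wavelet$name, nchar(pp),
                                paper_node_label(pp)))
    r <- wpt_reconstruct(t, pp)
    writeLines(c("field_g,recon_intensity",
                 paste(sprintf("%.17g", t$field),
                       sprintf("%.17g", r), sep = ",")), f)
    files <- c(files, f)
  }
  invisible(files)
}
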