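#' Intensity histogram of a gray image
#'
#' Counts pixels over \code{nbins} equal-width bins spanning \code{[0, 1]}.
#' The upper edge is inclusive so the counts always sum to the pixel total.
#'
#' @param image Gray image matrix in \code{[0, 1]}.
#' @param nbins Number of bins (at least 8); default 256, matching 8-bit
#'   sources.
#' @return Object of class \code{intensity_histogram} with fields
#'   \code{bin_centers}, \code{counts}, \code{nbins}.
#' @export
compute_histogram <- function(image, nbins = 256) {
  if (nbins < 8) stop("nbins must be >= 8")
  v <- as.vector(image)
  if (any(v < 0 | v > 1)) stop("image intensities must lie in [0, 1]")
  idx <- pmin(floor(v * nbins) + 1L, nbins)
  structure(list(
    bin_centers = (seq_len(nbins) - 0.5) / nbins,
    counts = tabulate(idx, nbins),
    nbins = as.integer(nbins)
  ), class = "intensity_histogram")
}

#' Trim the leading flat tail of a histogram segment
#'
#' Takes the first \code{segment_fraction} of the bins (the default half
#' mirrors splitting the histogram into two equal parts) and drops the
#' maximal leading run of flat bins, i.e. bins whose count does not exceed
#' \code{flat_tol}. Only the leading run is removed; no bin with count above
#' the tolerance is ever dropped.
#'
#' @param hist An \code{intensity_histogram}.
#' @param segment_fraction Fraction of bins forming the search segment
#'   (default 0.5).
#' @param flat_tol Count at or below which a bin is considered flat
#'   (default 0: exact zeros).
#' @return Object of class \code{histogram_segment}: \code{knots} (bin
#'   centers), \code{counts}, \code{start_index}, \code{segment_end}
#'   (indices into the full histogram).
#' @export
trim_flat_tail <- function(hist, segment_fraction = 0.5, flat_tol = 0) {
  stopifnot(inherits(hist, "intensity_histogram"))
  n_seg <- min(hist$nbins, max(1L, ceiling(hist$nbins * segment_fraction)))
  cnt <- hist$counts[seq_len(n_seg)]
  nonflat <- which(cnt > flat_tol)
  if (!length(nonflat)) {
    cond <- structure(class = c("lminseg_no_mass", "error", "condition"),
                      list(message = "no histogram mass in the current segment; extend it",
                           call = sys.call(-1)))
    stop(cond)
  }
  start <- nonflat[1]
  structure(list(
    knots = hist$bin_centers[start:n_seg],
    counts = hist$counts[start:n_seg],
    start_index = start,
    segment_end = n_seg
  ), class = "histogram_segment")
}

#' Savitzky--Golay smoothing of histogram counts
#'
#' Smooths a count sequence with a Savitzky--Golay filter so the general
#' tendency of the histogram is preserved while bin-level noise is damped.
#' If the sequence is shorter than the window, the window is reduced to the
#' largest valid odd value (with a warning); the polynomial order is lowered
#' if even that window cannot accommodate it.
#'
#' @param raw Numeric vector of counts.
#' @param window Odd filter window length (default 11).
#' @param polyorder Polynomial order, smaller than the window (default 3).
#' @return Numeric vector of the same length.
#' @export
smooth_counts <- function(raw, window = 11, polyorder = 3) {
  n <- length(raw)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > n) {
    window <- if (n %% 2 == 1) n else n - 1L
    warning("sequence shorter than window; reduced window to ", window)
  }
  if (polyorder >= window) {
    polyorder <- window - 1L
    warning("polyorder reduced to ", polyorder, " to fit the window")
  }
  if (window < 2L) return(as.numeric(raw))
  signal::sgolayfilt(as.numeric(raw), p = polyorder, n = window)
}

#' Construct a smoothed segment
#'
#' Bundles the trimmed knots with their smoothed frequencies and the cubic
#' spline degree used for extrema localization.
#'
#' @param knots Ordered bin centers.
#' @param values Smoothed frequencies at the knots.
#' @param spline_degree Interpolating spline degree (default 3).
#' @param segment_end Index of the last knot in the parent histogram.
#' @return Object of class \code{smoothed_segment}.
#' @export
smoothed_segment <- function(knots, values, spline_degree = 3, segment_end = length(knots)) {
  stopifnot(length(knots) == length(values))
  structure(list(knots = knots, values = values,
                 spline_degree = as.integer(spline_degree),
                 segment_end = as.integer(segment_end)),
            class = "smoothed_segment")
}

# All alternating extrema of the densely sampled spline, in increasing x.
# Plateaus resolve to their smallest-index sample; strict rise/fall on the
# approaching side is required, so monotone stretches yield nothing.
.extrema_sequence <- function(segment, dense_factor = 10) {
  k <- segment$knots
  sf <- stats::splinefun(k, segment$values, method = "fmm")
  xs <- seq(k[1], k[length(k)], length.out = max(50L, dense_factor * length(k)))
  ys <- sf(xs)
  n <- length(ys)
  i <- 2:(n - 1)
  is_max <- ys[i] > ys[i - 1] & ys[i] >= ys[i + 1]
  is_min <- ys[i] < ys[i - 1] & ys[i] <= ys[i + 1]
  idx <- i[is_max | is_min]
  if (!length(idx)) return(data.frame(x = numeric(0), type = character(0)))
  data.frame(x = xs[idx], type = ifelse(is_max[match(idx, i)], "max", "min"),
             stringsAsFactors = FALSE)
}

# Ordered (maximum, following minimum) pairs from the extrema sequence.
.extrema_pairs <- function(segment, dense_factor = 10) {
  ext <- .extrema_sequence(segment, dense_factor)
  out <- list()
  if (nrow(ext) >= 2) {
    for (i in seq_len(nrow(ext) - 1)) {
      if (ext$type[i] == "max") {
        j <- which(ext$type == "min" & seq_len(nrow(ext)) > i)
        if (length(j)) out[[length(out) + 1L]] <- c(ext$x[i], ext$x[j[1]])
      }
    }
  }
  out
}

#' First local maximum and minimum of a smoothed segment
#'
#' Fits a cubic interpolating spline through the (knot, value) pairs,
#' samples it on a dense grid (10 samples per knot by default), and scans in
#' increasing intensity for the first strict local maximum followed by the
#' first strict local minimum.
#'
#' @param segment A \code{smoothed_segment} with at least 5 knots.
#' @param dense_factor Dense-grid oversampling factor (default 10).
#' @return Object of class \code{extrema_pair}: \code{x_c} (first maximum),
#'   \code{x_c1} (first minimum after it), and their nearest knot indices.
#' @export
find_first_extrema <- function(segment, dense_factor = 10) {
  stopifnot(inherits(segment, "smoothed_segment"))
  if (length(segment$knots) < 5) stop("segment must have at least 5 knots")
  pairs <- .extrema_pairs(segment, dense_factor)
  if (!length(pairs)) {
    cond <- structure(class = c("lminseg_no_extrema", "error", "condition"),
                      list(message = "extrema not found in segment; extend it",
                           call = sys.call(-1)))
    stop(cond)
  }
  p <- pairs[[1]]
  extrema_pair(p[1], p[2], segment$knots)
}

#' @rdname find_first_extrema
#' @param x_c,x_c1 Intensities of the maximum and the minimum.
#' @param knots Knot sequence used to report indices.
#' @export
extrema_pair <- function(x_c, x_c1, knots = NULL) {
  if (x_c1 <= x_c) stop("the first local minimum must follow the first local maximum")
  idx <- if (!is.null(knots)) {
    c(which.min(abs(knots - x_c)), which.min(abs(knots - x_c1)))
  } else c(NA_integer_, NA_integer_)
  structure(list(x_c = x_c, x_c1 = x_c1,
                 index_max = idx[1], index_min = idx[2]),
            class = "extrema_pair")
}

#' Search for the first peak/valley pair, extending the segment on failure
#'
#' Starts from the trimmed first half of the histogram; whenever no
#' maximum-then-minimum pair is found (or the segment is entirely flat), the
#' segment end is incremented by \code{increment_frac} of the bin count and
#' the search restarts, until the full histogram is exhausted.
#'
#' @param hist An \code{intensity_histogram}.
#' @param segment_fraction Initial segment fraction (default 0.5).
#' @param increment_frac Extension step as a fraction of \code{nbins}
#'   (default 0.1).
#' @param window,polyorder Savitzky--Golay parameters.
#' @param flat_tol Flatness tolerance for the leading-tail trim.
#' @return An \code{extrema_pair}.
#' @export
search_extrema_with_extension <- function(hist, segment_fraction = 0.5,
                                          increment_frac = 0.1,
                                          window = 11, polyorder = 3,
                                          flat_tol = 0) {
  segs <- .segments_with_extension(hist, segment_fraction, increment_frac,
                                   window, polyorder, flat_tol)
  for (seg in segs) {
    pairs <- .extrema_pairs(seg)
    if (length(pairs)) return(extrema_pair(pairs[[1]][1], pairs[[1]][2], seg$knots))
  }
  cond <- structure(class = c("lminseg_no_bimodal", "error", "condition"),
                    list(message = "no bimodal structure: histogram exhausted without a maximum/minimum pair",
                         call = sys.call()))
  stop(cond)
}

# Lazy-ish list of smoothed segments for increasing segment ends.
.segments_with_extension <- function(hist, segment_fraction, increment_frac,
                                     window, polyorder, flat_tol) {
  fracs <- unique(pmin(1, seq(segment_fraction, 1 + increment_frac, by = increment_frac)))
  out <- list()
  for (f in fracs) {
    seg <- tryCatch(trim_flat_tail(hist, f, flat_tol),
                    lminseg_no_mass = function(e) NULL)
    if (is.null(seg) || length(seg$knots) < 5) next
    # a single populated bin has no peak/valley structure; smoothing a delta
    # spike only manufactures filter ripples
    if (sum(seg$counts > flat_tol) < 2) next
    sm <- suppressWarnings(smooth_counts(seg$counts, window, polyorder))
    out[[length(out) + 1L]] <- smoothed_segment(seg$knots, sm, 3L, seg$segment_end)
  }
  out
}

#' @export
print.extrema_pair <- function(x, ...) {
  cat(sprintf("extrema pair: first maximum x_c = %.4f, first minimum x_c+1 = %.4f\n",
              x$x_c, x$x_c1))
  invisible(x)
}
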