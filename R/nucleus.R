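#' Initial value guiding the nucleus threshold search
#'
#' Computes \code{Max(A)/n1 + Min(A)/n2} from the per-image intensity
#' extremes. With the defaults \code{n1 = n2 = 3} and a near-zero minimum
#' the value sits close to 1/3, which on stained smears falls in the valley
#' between the dark nucleus mode and the cytoplasm mode.
#'
#' @param image Gray image matrix in \code{[0, 1]}.
#' @param n1,n2 Positive integer divisors of the maximum and minimum
#'   (defaults 3 and 3).
#' @return The initial intensity value; warns if it falls outside the open
#'   interval \code{(Min(A), Max(A))}.
#' @export
compute_initial_value <- function(image, n1 = 3, n2 = 3) {
  if (n1 < 1 || n2 < 1) stop("n1 and n2 must be integers >= 1")
  mx <- max(image); mn <- min(image)
  t0 <- mx / n1 + mn / n2
  if (!(t0 > mn && t0 < mx)) {
    warning(sprintf("initial value %.4f falls outside the open intensity range (%.4f, %.4f)",
                    t0, mn, mx))
  }
  t0
}

#' Estimate the nucleus threshold by the four-branch rule
#'
#' Given the initial value, the first histogram peak/valley pair and the
#' margin \code{Er}, selects the threshold near the valley:
#' \itemize{
#'   \item condition (a) \code{x_c < T_nc0} must hold (the peak precedes the
#'     initial value); its violation raises a retry signal;
#'   \item (b) \code{|T_nc0 - x_c1| <= Er}: midpoint \code{(T_nc0 + x_c1)/2};
#'   \item (c) \code{|T_nc0 - x_c1| > Er} and \code{T_nc0 > x_c1}:
#'     \code{(T_nc0 + x_c1 + Er)/2};
#'   \item (d) \code{|T_nc0 - x_c1| > Er} and \code{T_nc0 < x_c1}:
#'     \code{(T_nc0 + x_c1 - Er)/2}.
#' }
#' Exact equality \code{|T_nc0 - x_c1| = Er} is treated as branch (b); the
#' three formulas coincide there, so the choice is value-neutral.
#'
#' @param T_nc0 Initial value from \code{\link{compute_initial_value}}.
#' @param extrema An \code{extrema_pair}.
#' @param Er Positive margin controlling the branch choice (default 0.07).
#' @return Object of class \code{threshold_estimate} with fields
#'   \code{T_nc0}, \code{x_c}, \code{x_c1}, \code{Er}, \code{epsilon_t},
#'   \code{branch}.
#' @export
estimate_threshold <- function(T_nc0, extrema, Er = 0.07) {
  if (Er <= 0) stop("Er must be positive")
  stopifnot(inherits(extrema, "extrema_pair"))
  if (extrema$x_c >= T_nc0) {
    cond <- structure(class = c("lminseg_condition_a", "error", "condition"),
                      list(message = sprintf(
                        "condition (a) violated: first maximum %.4f is not below the initial value %.4f",
                        extrema$x_c, T_nc0), call = sys.call()))
    stop(cond)
  }
  x1 <- extrema$x_c1
  d <- abs(T_nc0 - x1)
  if (d <= Er) {
    branch <- "b"; eps <- (T_nc0 + x1) / 2
  } else if (T_nc0 > x1) {
    branch <- "c"; eps <- (T_nc0 + x1 + Er) / 2
  } else {
    branch <- "d"; eps <- (T_nc0 + x1 - Er) / 2
  }
  threshold_estimate(T_nc0, extrema$x_c, x1, Er, eps, branch)
}

#' @rdname estimate_threshold
#' @param x_c,x_c1 First local maximum and minimum used.
#' @param epsilon_t Selected threshold.
#' @param branch Branch taken: one of \code{"b"}, \code{"c"}, \code{"d"},
#'   \code{"fallback"}.
#' @param n1,n2 Divisors used for \code{T_nc0} (recorded for audit).
#' @export
threshold_estimate <- function(T_nc0, x_c, x_c1, Er, epsilon_t, branch,
                               n1 = NA_integer_, n2 = NA_integer_) {
  lo <- min(T_nc0, x_c1, na.rm = TRUE) - Er / 2
  hi <- max(T_nc0, x_c1, na.rm = TRUE) + Er / 2
  if (epsilon_t < lo - 1e-12 || epsilon_t > hi + 1e-12) {
    stop("internal error: epsilon_t outside its admissible interval")
  }
  structure(list(T_nc0 = T_nc0, x_c = x_c, x_c1 = x_c1, Er = Er,
                 epsilon_t = epsilon_t, branch = branch,
                 n1 = n1, n2 = n2),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("threshold estimate: epsilon_t = %.4f (branch %s)\n", x$epsilon_t, x$branch))
  cat(sprintf("  T_nc0 = %.4f, x_c = %s, x_c+1 = %s, Er = %.3f\n",
              x$T_nc0,
              ifelse(is.na(x$x_c), "NA", sprintf("%.4f", x$x_c)),
              ifelse(is.na(x$x_c1), "NA", sprintf("%.4f", x$x_c1)), x$Er))
  invisible(x)
}

#' Reconstruct the image around the nucleus threshold
#'
#' Pixels at or below \code{epsilon_t} are mapped to the image minimum; all
#' others are left unchanged. The operation is idempotent and monotone in
#' \code{epsilon_t}.
#'
#' @param image Gray image matrix.
#' @param epsilon_t Threshold in \code{[0, 1]}.
#' @return Reconstructed gray image matrix.
#' @export
reconstruct_nucleus_image <- function(image, epsilon_t) {
  stopifnot(epsilon_t >= 0, epsilon_t <= 1)
  mn <- min(image)
  out <- image
  out[image <= epsilon_t] <- mn
  out
}

#' Binarize the nucleus (dark class)
#'
#' @param image Gray image matrix.
#' @param epsilon_t Threshold; foreground is \code{f <= epsilon_t}.
#' @return Binary mask (integer 0/1 matrix); warns when the mask is entirely
#'   foreground or entirely background.
#' @export
binarize_nucleus <- function(image, epsilon_t) {
  mask <- matrix(as.integer(image <= epsilon_t), nrow(image), ncol(image))
  s <- sum(mask)
  if (s == 0L) warning("suspicious threshold: empty nucleus mask")
  if (s == length(mask)) warning("suspicious threshold: all-foreground nucleus mask")
  mask
}

#' Remove small objects and fill holes
#'
#' 8-connected components smaller than \code{min_object_area} pixels are
#' removed, then fully enclosed holes are filled.
#'
#' @param mask Binary mask.
#' @param min_object_area Minimum component area in pixels.
#' @return Cleaned binary mask.
#' @export
postprocess_mask <- function(mask, min_object_area = 0) {
  lab <- label_components(mask)
  if (max(lab) > 0L && min_object_area > 0) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_object_area)
    mask <- matrix(as.integer(lab %in% keep & lab > 0L), nrow(mask), ncol(mask))
  } else {
    mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  }
  filled <- .from_ebi(EBImage::fillHull(.as_ebi(mask)))
  matrix(as.integer(filled != 0), nrow(mask), ncol(mask))
}

#' Segment the nucleus of a white blood cell
#'
#' Full nucleus pipeline: histogram, flat-tail trim, Savitzky--Golay
#' smoothing, spline extrema search with segment extension, four-branch
#' threshold estimation, binarization and morphological cleanup. When the
#' current segment yields only peak/valley pairs violating condition (a),
#' later pairs and then extended segments are tried; if the histogram is
#' exhausted (or has no bimodal structure at all) the method falls back to
#' \code{epsilon_t = T_nc0}.
#'
#' @param image Gray image matrix in \code{[0, 1]}.
#' @param er Branch margin \code{Er} (default 0.07).
#' @param n1,n2 Divisors for the initial value (defaults 3, 3).
#' @param nbins Histogram bins (default 256).
#' @param min_area_frac Minimum object area as a fraction of the image area
#'   (default 0.005).
#' @param window,polyorder Savitzky--Golay parameters (defaults 11, 3).
#' @return List with \code{mask} (binary nucleus mask) and \code{estimate}
#'   (a \code{threshold_estimate} audit record).
#' @export
segment_nucleus <- function(image, er = 0.07, n1 = 3, n2 = 3, nbins = 256,
                            min_area_frac = 0.005, window = 11, polyorder = 3) {
  T_nc0 <- compute_initial_value(image, n1, n2)
  hist <- compute_histogram(image, nbins)
  est <- NULL
  segs <- .segments_with_extension(hist, 0.5, 0.1, window, polyorder, 0)
  for (seg in segs) {
    for (p in .extrema_pairs(seg)) {
      if (p[1] < T_nc0) {
        est <- estimate_threshold(T_nc0, extrema_pair(p[1], p[2], seg$knots), er)
        break
      }
    }
    if (!is.null(est)) break
  }
  if (is.null(est)) {
    est <- threshold_estimate(T_nc0, NA_real_, NA_real_, er, T_nc0, "fallback")
  }
  est$n1 <- as.integer(n1); est$n2 <- as.integer(n2)
  mask <- binarize_nucleus(image, est$epsilon_t)
  mask <- postprocess_mask(mask, min_object_area = min_area_frac * length(image))
  list(mask = mask, estimate = est)
}
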