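#' Generate the family of whole-cell thresholds
#'
#' Builds \code{n} step values \code{er_i} spanning the interval
#' \code{[Min(A), Max(A)/3]} inclusively (\code{er_i = a_l + i * delta_h}
#' with \code{delta_h = (a_u - a_l)/(n - 1)}) and offsets each by the base
#' \code{(Max(A) + T_nc0)/2}. Raw thresholds above \code{Max(A)} are
#' recorded but their applied (clipped) counterparts saturate at
#' \code{Max(A)}, with a warning; the formula-exact raw family keeps the
#' strict ordering and endpoint identities.
#'
#' @param image Gray image matrix.
#' @param T_nc0 Initial value (see \code{\link{compute_initial_value}}).
#' @param n Number of thresholds (at least 2; default 10).
#' @return Object of class \code{wbc_threshold_family} with fields
#'   \code{a_l}, \code{a_u}, \code{n}, \code{delta_h}, \code{steps},
#'   \code{thresholds} (clipped, used on images), \code{thresholds_raw},
#'   \code{base}.
#' @export
generate_wbc_thresholds <- function(image, T_nc0, n = 10) {
  if (n < 2) stop("n must be >= 2")
  mx <- max(image); mn <- min(image)
  if (mx <= mn) stop("degenerate input: constant image has no threshold interval")
  a_l <- mn
  a_u <- mx / 3
  delta_h <- (a_u - a_l) / (n - 1)
  steps <- a_l + (seq_len(n) - 1) * delta_h
  base <- (mx + T_nc0) / 2
  raw <- base + steps
  clipped <- pmin(raw, mx)
  if (any(raw > mx)) {
    warning(sprintf("%d threshold(s) exceed Max(A) = %.4f and are clipped when applied",
                    sum(raw > mx), mx))
  }
  structure(list(a_l = a_l, a_u = a_u, n = as.integer(n), delta_h = delta_h,
                 steps = steps, thresholds = clipped, thresholds_raw = raw,
                 base = base),
            class = "wbc_threshold_family")
}

#' @export
print.wbc_threshold_family <- function(x, ...) {
  cat(sprintf("wbc threshold family: n = %d, delta_h = %.4f, interval [%.4f, %.4f]\n",
              x$n, x$delta_h, x$a_l, x$a_u))
  cat("  thresholds:", paste(sprintf("%.4f", x$thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' Floor an image at a threshold
#'
#' Pixels at or below \code{T} are raised to \code{T}; others are left
#' unchanged, so the output dominates the input pointwise.
#'
#' @param image Gray image matrix.
#' @param T Threshold in \code{[0, 1]}.
#' @return Thresholded gray image.
#' @export
threshold_image <- function(image, T) {
  stopifnot(T >= 0, T <= 1)
  pmax(image, T)
}

#' Average of the thresholded reconstructions
#'
#' Pixel-wise mean of the \code{n} floor images, one per family threshold.
#' Flattens intensity variation inside the cell (every pixel below all
#' thresholds maps to the same mean) while keeping the background bright.
#'
#' @param image Gray image matrix.
#' @param family A \code{wbc_threshold_family}.
#' @return Averaged gray image; dominates the input pointwise.
#' @export
average_reconstruction <- function(image, family) {
  stopifnot(inherits(family, "wbc_threshold_family"), family$n >= 1)
  acc <- matrix(0, nrow(image), ncol(image))
  for (T in family$thresholds) acc <- acc + pmax(image, T)
  acc / family$n
}

#' Otsu threshold over a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over all candidate
#' splits of a \code{nbins}-bin histogram on \code{[0, 1]}; ties resolve to
#' the smallest split. The returned threshold is the upper edge of the last
#' bin of the dark class, so binarizing with \code{f <= t} reproduces the
#' optimal split exactly.
#'
#' @param image Gray image matrix with at least two distinct values.
#' @param nbins Number of bins (default 256).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(image, nbins = 256) {
  v <- as.vector(image)
  if (length(unique(v)) < 2) stop("degenerate input: constant image has no Otsu threshold")
  h <- compute_histogram(image, nbins)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$bin_centers)
  mu_t <- mu[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- omega[k]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 / (w0[valid] * w1[valid])
  k_star <- which.max(sigma_b)
  k_star / nbins
}

#' Seed pixel from the segmented nucleus
#'
#' Returns the centroid of the largest 8-connected nucleus component,
#' snapped to the nearest mask pixel when the centroid falls outside (lobed
#' nuclei). Coordinates are 0-based \code{(row, col)}.
#'
#' @param nucleus Binary nucleus mask (non-empty).
#' @return Integer vector \code{c(row, col)}, 0-based.
#' @export
select_seed_from_nucleus <- function(nucleus) {
  if (sum(nucleus != 0) == 0) {
    stop("empty nucleus mask: run nucleus segmentation first")
  }
  lab <- label_components(nucleus)
  areas <- tabulate(lab[lab > 0L])
  big <- which.max(areas)
  idx <- which(lab == big, arr.ind = TRUE)
  cen <- floor(colMeans(idx))          # 1-based floor centroid
  cen <- pmax(cen, 1)
  if (lab[cen[1], cen[2]] != big) {
    d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
    cen <- idx[which.min(d2), ]
  }
  as.integer(cen) - 1L
}

#' Extract the seed-containing foreground component
#'
#' @param binary Binary mask.
#' @param seed 0-based \code{c(row, col)} coordinate inside the image.
#' @return Binary mask of the single 8-connected component containing the
#'   seed.
#' @export
extract_wbc_by_seed <- function(binary, seed) {
  r <- seed[1] + 1L; c <- seed[2] + 1L
  if (r < 1 || r > nrow(binary) || c < 1 || c > ncol(binary)) {
    stop("seed out of image bounds")
  }
  lab <- label_components(binary)
  target <- lab[r, c]
  if (target == 0L) {
    fg <- which(lab > 0L, arr.ind = TRUE)
    if (!nrow(fg)) stop("seed not on foreground: mask is empty")
    d2 <- (fg[, 1] - r)^2 + (fg[, 2] - c)^2
    near <- fg[which.min(d2), ] - 1L
    stop(sprintf("seed not on foreground; nearest foreground pixel is (%d, %d)",
                 near[1], near[2]))
  }
  matrix(as.integer(lab == target), nrow(binary), ncol(binary))
}

#' Cytoplasm by subtraction
#'
#' The cytoplasm is the whole cell minus the nucleus. Nucleus pixels falling
#' outside the cell mask are clipped from the subtraction with a warning.
#'
#' @param wbc Binary whole-cell mask.
#' @param nucleus Binary nucleus mask of the same shape.
#' @return Binary cytoplasm mask.
#' @export
compute_cytoplasm <- function(wbc, nucleus) {
  if (!all(dim(wbc) == dim(nucleus))) stop("mask shapes differ")
  outside <- sum(nucleus != 0 & wbc == 0)
  if (outside > 0) {
    warning(outside, " nucleus pixel(s) lie outside the cell mask and are clipped")
  }
  matrix(as.integer(wbc != 0 & nucleus == 0), nrow(wbc), ncol(wbc))
}

#' Segment the whole white blood cell and its cytoplasm
#'
#' Averaged multi-threshold reconstruction, Otsu binarization of the dark
#' class, morphological cleanup, nucleus-seeded component extraction, and
#' cytoplasm subtraction. Intended for images where the cell is well
#' separated from red blood cells; see \code{\link{segment_wbc_watershed}}
#' and \code{\link{segment_wbc_slic}} for touching cells.
#'
#' @param image Gray image matrix.
#' @param nucleus Binary nucleus mask (non-empty).
#' @param n_thresholds Size of the threshold family (default 10).
#' @param T_nc0 Initial value; computed from the image with
#'   \code{n1 = n2 = 3} when \code{NULL}.
#' @param min_area_frac Minimum object area fraction for cleanup.
#' @return List with \code{wbc}, \code{cytoplasm} (binary masks) and
#'   \code{otsu_t} (the Otsu threshold applied to the averaged image).
#' @export
segment_wbc <- function(image, nucleus, n_thresholds = 10, T_nc0 = NULL,
                        min_area_frac = 0.005) {
  if (sum(nucleus != 0) == 0) stop("empty nucleus mask: run nucleus segmentation first")
  if (is.null(T_nc0)) T_nc0 <- compute_initial_value(image)
  fam <- generate_wbc_thresholds(image, T_nc0, n_thresholds)
  a_wbc <- average_reconstruction(image, fam)
  t <- otsu_threshold(a_wbc)
  bin <- matrix(as.integer(a_wbc <= t), nrow(image), ncol(image))
  # the averaged reconstruction compresses contrast, so the Otsu dark class
  # can grow noise fringes; a small opening severs them before cleanup
  bin <- .from_ebi(EBImage::opening(.as_ebi(bin), .disc(2L)))
  bin <- matrix(as.integer(bin != 0), nrow(image), ncol(image))
  bin <- postprocess_mask(bin, min_object_area = min_area_frac * length(image))
  seed <- select_seed_from_nucleus(nucleus)
  wbc <- tryCatch(extract_wbc_by_seed(bin, seed), error = function(e) {
    fg <- which(bin > 0L, arr.ind = TRUE)
    if (!nrow(fg)) stop("whole-cell binarization produced an empty mask")
    d2 <- (fg[, 1] - (seed[1] + 1L))^2 + (fg[, 2] - (seed[2] + 1L))^2
    near <- fg[which.min(d2), ] - 1L
    warning("nucleus seed fell on background; snapped to the nearest foreground pixel")
    extract_wbc_by_seed(bin, as.integer(near))
  })
  cyto <- suppressWarnings(compute_cytoplasm(wbc, nucleus))
  list(wbc = wbc, cytoplasm = cyto, otsu_t = t)
}
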