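#' Whole-cell segmentation by marker-controlled watershed
#'
#' Fallback for images in which red blood cells touch the white cell. The
#' grayscale image is Otsu-binarized (dark class foreground), the Euclidean
#' distance transform of the foreground is computed, and markers are placed
#' at local maxima of the distance map separated by at least half the
#' distance-map maximum (the marker count is chosen automatically, never by
#' the user). The markers are grown over the inverted distance map within
#' the foreground; watershed regions overlapping the nucleus are retained,
#' the nucleus-seeded connected component is kept, and the mask is cleaned.
#'
#' Before retention, adjacent basins are merged wherever their shared
#' boundary runs through thick foreground (boundary distance values of at
#' least \code{merge_frac} times the distance-map maximum): watershed lines
#' crossing the body of a lobed cell are artifacts of its shape, whereas
#' genuine detachment necks between a cell and a touching red cell are thin.
#' Over-segmentation of the cell itself is therefore harmless.
#'
#' @param image Gray image matrix.
#' @param nucleus Binary nucleus mask (non-empty).
#' @param min_separation Minimum marker separation in pixels; default
#'   \code{max(distance map) / 2}.
#' @param merge_frac Basins whose shared boundary reaches this fraction of
#'   the distance-map maximum are merged before retention (default 0.25).
#' @param min_area_frac Minimum object area fraction for cleanup.
#' @return Binary whole-cell mask.
#' @export
segment_wbc_watershed <- function(image, nucleus, min_separation = NULL,
                                  merge_frac = 0.25, min_area_frac = 0.005) {
  if (sum(nucleus != 0) == 0) stop("empty nucleus mask: run nucleus segmentation first")
  t <- otsu_threshold(image)
  fg <- matrix(as.integer(image <= t), nrow(image), ncol(image))
  if (sum(fg) == 0) stop("empty foreground after Otsu binarization")
  d <- .from_ebi(EBImage::distmap(.as_ebi(fg)))
  dmax <- max(d)
  if (is.null(min_separation)) min_separation <- dmax / 2
  r <- max(1L, ceiling(min_separation))
  dil <- .from_ebi(EBImage::dilate(.as_ebi(d), .disc(r)))
  peaks <- matrix(as.integer(d > 0 & d >= dil - 1e-9 & d > 1), nrow(d), ncol(d))
  markers <- label_components(peaks)
  if (max(markers) == 0L) markers <- label_components(matrix(as.integer(d == dmax), nrow(d), ncol(d)))
  ws <- .from_ebi(EBImage::propagate(.as_ebi(dmax - d), .as_ebi(markers),
                                     mask = .as_ebi(fg)))
  ws <- .merge_thick_boundaries(ws, d, merge_frac * dmax)
  keep <- setdiff(unique(ws[nucleus != 0]), 0)
  mask <- matrix(as.integer(ws %in% keep), nrow(image), ncol(image))
  mask <- postprocess_mask(mask, min_object_area = min_area_frac * length(image))
  seed <- select_seed_from_nucleus(nucleus)
  if (mask[seed[1] + 1L, seed[2] + 1L] == 0L) {
    mask[nucleus != 0] <- 1L   # guarantee the seed region is present
  }
  extract_wbc_by_seed(mask, seed)
}

# Merge adjacent watershed basins whose shared boundary crosses foreground
# at least `cut` thick (in distance-transform units); detachment necks stay.
.merge_thick_boundaries <- function(ws, d, cut) {
  K <- max(ws)
  if (K <= 1L) return(ws)
  nr <- nrow(ws); nc <- ncol(ws)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (sh in list(c(1L, 0L), c(0L, 1L))) {
    a <- ws[seq_len(nr - sh[1]), seq_len(nc - sh[2])]
    b <- ws[(1L + sh[1]):nr, (1L + sh[2]):nc]
    dm <- pmin(d[seq_len(nr - sh[1]), seq_len(nc - sh[2])],
               d[(1L + sh[1]):nr, (1L + sh[2]):nc])
    for (idx in which(a > 0 & b > 0 & a != b & dm >= cut)) {
      ra <- find(a[idx]); rb <- find(b[idx])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  grp <- vapply(seq_len(K), find, 1L)
  nz <- ws > 0
  ws[nz] <- grp[ws[nz]]
  ws
}

#' Whole-cell segmentation by SLIC superpixels
#'
#' Fallback for touching cells exploiting superpixel boundary adherence.
#' Superpixels are retained when their pixel majority lies inside the
#' dilated nucleus, or when their mean gray intensity does not exceed a
#' cytoplasm-informed cut (mean intensity of the annulus around the nucleus
#' plus \code{intensity_tol}); under-segmentation of the cell is preferred
#' to leakage into neighboring red cells. The union of retained superpixels
#' is reduced to the nucleus-seeded connected component and cleaned.
#'
#' @param image Gray matrix or \code{[rows, cols, 3]} color array; SLIC runs
#'   on the color data when available.
#' @param nucleus Binary nucleus mask (non-empty).
#' @param n_segments Number of superpixels (at least 4; default 100).
#' @param compactness SLIC compactness (default 10).
#' @param dilate_radius Nucleus dilation radius for the majority test
#'   (default 3 px).
#' @param intensity_tol Intensity slack above the cytoplasm estimate
#'   (default 0.05).
#' @param min_area_frac Minimum object area fraction for cleanup.
#' @return Binary whole-cell mask.
#' @export
segment_wbc_slic <- function(image, nucleus, n_segments = 100, compactness = 10,
                             dilate_radius = 3, intensity_tol = 0.05,
                             min_area_frac = 0.005) {
  if (n_segments < 4) stop("n_segments must be >= 4")
  if (sum(nucleus != 0) == 0) stop("empty nucleus mask: run nucleus segmentation first")
  gray <- if (length(dim(image)) == 3L) .luminance(image) else image
  labels <- slic_superpixels(image, n_segments, compactness)
  dilnuc <- .from_ebi(EBImage::dilate(.as_ebi(nucleus != 0), .disc(dilate_radius))) != 0
  ring_r <- max(5L, round(0.08 * min(dim(gray))))
  ring <- .from_ebi(EBImage::dilate(.as_ebi(nucleus != 0), .disc(ring_r))) != 0 & nucleus == 0
  cut <- if (any(ring)) mean(gray[ring]) + intensity_tol else intensity_tol
  keep <- matrix(FALSE, nrow(gray), ncol(gray))
  for (k in seq_len(max(labels))) {
    sel <- labels == k
    if (!any(sel)) next
    if (mean(dilnuc[sel]) > 0.5 || mean(gray[sel]) <= cut) keep[sel] <- TRUE
  }
  keep[nucleus != 0] <- TRUE
  mask <- matrix(as.integer(keep), nrow(gray), ncol(gray))
  seed <- select_seed_from_nucleus(nucleus)
  mask <- extract_wbc_by_seed(mask, seed)
  postprocess_mask(mask, min_object_area = min_area_frac * length(gray))
}
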