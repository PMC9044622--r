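#' @importFrom stats splinefun rnorm runif sd cor median
#' @importFrom utils head
NULL

# Internal conversions between the package's row-major matrix convention
# (m[row, col], values in [0,1]) and EBImage's [x = col, y = row] layout.
.as_ebi <- function(m) EBImage::Image(t(m))
.from_ebi <- function(img) t(EBImage::imageData(img))
.disc <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

# BT.601 luminance weights used for every RGB -> gray conversion.
.LUMA <- c(0.299, 0.587, 0.114)

.luminance <- function(arr) {
  # arr: [rows, cols, channels>=3]
  .LUMA[1] * arr[, , 1] + .LUMA[2] * arr[, , 2] + .LUMA[3] * arr[, , 3]
}

#' Read a micrograph as a normalized grayscale image
#'
#' Decodes a raster image (PNG/JPG/BMP/TIFF, RGB or single-channel) and
#' returns a numeric matrix of intensities in \code{[0, 1]}, indexed
#' \code{m[row, col]}. RGB input is converted with ITU-R BT.601 luminance
#' weights (0.299, 0.587, 0.114). Values are normalized by the stored dtype
#' maximum (the codec does this for 8- and 16-bit files); a min--max rescale
#' is applied only if the decoded values still exceed \code{[0, 1]}, so that
#' per-image \code{min} and \code{max} retain their meaning for the initial
#' threshold value.
#'
#' @param path Path to a decodable raster image.
#' @return Numeric matrix in \code{[0, 1]} (a gray image).
#' @export
read_image <- function(path) {
  arr <- .read_raw(path)
  if (length(dim(arr)) == 3L) arr <- .luminance(arr)
  if (nrow(arr) < 1L || ncol(arr) < 1L) stop("degenerate input: zero-sized image")
  rng <- range(arr)
  if (rng[2] > 1 || rng[1] < 0) {
    if (rng[2] > rng[1]) arr <- (arr - rng[1]) / (rng[2] - rng[1]) else arr[] <- 0
  }
  arr
}

# Raw decode: gray -> matrix [row, col]; color -> array [row, col, 3].
.read_raw <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file does not exist: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) return(t(dat))
  dat <- dat[, , seq_len(min(3L, dim(dat)[3])), drop = FALSE]
  if (dim(dat)[3] == 1L) return(t(dat[, , 1]))
  if (dim(dat)[3] < 3L) stop("unsupported channel count: ", dim(dat)[3])
  aperm(dat, c(2, 1, 3))
}

#' Read a tri-level ground-truth mask
#'
#' Ground-truth masks encode nucleus, cytoplasm and background as white
#' (255), gray (128) and black (0). Pixels are snapped to the nearest of the
#' three codes to absorb compression noise; a pixel further than
#' \code{tol} gray levels from every code aborts with a format error, which
#' also rejects masks with more than three well-separated levels.
#'
#' @param path Path to the mask image.
#' @param tol Maximum distance (8-bit gray levels) from a code; default 40.
#' @return Integer matrix with values in \code{\{0, 128, 255\}}.
#' @export
read_trilevel_mask <- function(path, tol = 40) {
  arr <- .read_raw(path)
  if (length(dim(arr)) == 3L) arr <- .luminance(arr)
  v <- round(arr * 255)
  codes <- c(0, 128, 255)
  d <- vapply(codes, function(cd) abs(v - cd), array(0, dim(v)))
  dim(d) <- c(length(v), 3L)
  mind <- do.call(pmin, lapply(1:3, function(j) d[, j]))
  if (any(mind > tol)) {
    bad <- sort(unique(as.vector(v)[mind > tol]))
    stop("not a tri-level mask: values ", paste(head(bad, 8), collapse = ", "),
         " are more than ", tol, " gray levels from every code {0, 128, 255}")
  }
  snapped <- codes[max.col(-d, ties.method = "first")]
  m <- matrix(as.integer(snapped), nrow(v), ncol(v))
  m
}

#' Write a binary or tri-level mask losslessly
#'
#' Binary masks (values 0/1) are written as \code{\{0, 255\}} 8-bit PNG;
#' tri-level masks (values 0/128/255) are written verbatim. Reading the file
#' back reproduces the label grid exactly.
#'
#' @param mask Integer/numeric matrix with values in \code{\{0,1\}} or
#'   \code{\{0,128,255\}}.
#' @param path Output path; the parent directory must exist. Always PNG.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path))) stop("cannot write mask: directory does not exist: ", dirname(path))
  u <- sort(unique(as.vector(mask)))
  if (all(u %in% c(0, 1))) {
    out <- mask * 1.0
  } else if (all(u %in% c(0, 128, 255))) {
    out <- mask / 255
  } else {
    stop("mask values must be {0,1} or {0,128,255}; got: ", paste(head(u, 8), collapse = ", "))
  }
  EBImage::writeImage(.as_ebi(out), path, type = "png")
  invisible(path)
}

#' 8-connected labeling of a binary mask
#'
#' Connected-component labeling with 8-connectivity (diagonal neighbors
#' merge). Labels are positive integers; background is 0.
#'
#' @param mask Binary matrix (0/1).
#' @return Integer matrix of component labels.
#' @export
label_components <- function(mask) {
  lab4 <- .from_ebi(EBImage::bwlabel(.as_ebi(mask != 0)))
  n <- max(lab4)
  if (n <= 1L) return(matrix(as.integer(lab4), nrow(mask), ncol(mask)))
  nr <- nrow(lab4); nc <- ncol(lab4)
  # diagonal adjacencies between distinct 4-connected labels
  a1 <- lab4[-nr, -nc]; b1 <- lab4[-1, -1]    # NW-SE
  a2 <- lab4[-1, -nc];  b2 <- lab4[-nr, -1]   # SW-NE
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  nz <- lab4 > 0
  out[nz] <- relab[lab4[nz]]
  out
}
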