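#' Specification of a synthetic blood-smear fixture
#'
#' Describes one synthetic single-cell image: a dark multi-lobed nucleus, a
#' mid-intensity cytoplasm blob around it, lighter annular red-cell disks
#' (separated from or touching the cell), a bright background, and additive
#' Gaussian noise. The default class means (0.20, 0.55, 0.70, 0.90) place
#' the nucleus--cytoplasm histogram valley near 1/3, the regime the initial
#' value targets on stained smears.
#'
#' @param image_size \code{c(rows, cols)}; default \code{c(120, 120)}
#'   (a 360x363 preset mirrors larger micrographs).
#' @param nucleus_lobes Number of nuclear lobes (>= 1).
#' @param nucleus_mean,cytoplasm_mean,rbc_mean,background_mean Class
#'   intensity means; must increase in this order (background may equal the
#'   red-cell mean).
#' @param noise_sigma Gaussian noise standard deviation; must stay below
#'   half the smallest inter-class gap.
#' @param rbc_count Number of red blood cells.
#' @param touching If \code{TRUE}, at least one red cell touches or
#'   overlaps the cytoplasm rim.
#' @param random_seed Integer seed; identical seeds give bit-identical
#'   fixtures.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(image_size = c(120, 120), nucleus_lobes = 3,
                         nucleus_mean = 0.20, cytoplasm_mean = 0.55,
                         rbc_mean = 0.70, background_mean = 0.90,
                         noise_sigma = 0.03, rbc_count = 5,
                         touching = FALSE, random_seed = 1) {
  means <- c(nucleus_mean, cytoplasm_mean, rbc_mean, background_mean)
  if (any(diff(means) < 0) || nucleus_mean >= cytoplasm_mean ||
      cytoplasm_mean >= rbc_mean || rbc_mean > background_mean) {
    stop("class means must satisfy nucleus < cytoplasm < rbc <= background")
  }
  if (any(means <= 0 | means >= 1)) stop("class means must lie in (0, 1)")
  gaps <- diff(means); gaps <- gaps[gaps > 0]
  if (noise_sigma >= min(gaps) / 2) {
    stop("noise_sigma must be below half the smallest inter-class gap")
  }
  if (nucleus_lobes < 1) stop("nucleus_lobes must be >= 1")
  structure(list(image_size = as.integer(image_size),
                 nucleus_lobes = as.integer(nucleus_lobes),
                 nucleus_mean = nucleus_mean, cytoplasm_mean = cytoplasm_mean,
                 rbc_mean = rbc_mean, background_mean = background_mean,
                 noise_sigma = noise_sigma, rbc_count = as.integer(rbc_count),
                 touching = isTRUE(touching),
                 random_seed = as.integer(random_seed)),
            class = "fixture_spec")
}

# Per-class base hues (purple nucleus, pink cytoplasm, red RBC, near-white
# background), each scaled so its BT.601 luminance equals the class mean
# exactly; the color -> gray path then reproduces the gray fixture.
.class_rgb <- function(mean_val, base) {
  lum <- sum(.LUMA * base)
  rgb <- base * (mean_val / lum)
  if (any(rgb > 1)) rgb <- rgb / max(rgb) * min(1, max(rgb))  # guard; unused for defaults
  rgb
}

.ellipse_mask <- function(nr, nc, cr, cc, a, b, theta) {
  rr <- matrix(seq_len(nr), nr, nc) - cr
  cc_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  u <- cc_ * cos(theta) + rr * sin(theta)
  v <- -cc_ * sin(theta) + rr * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic cell image with exact ground truth
#'
#' Renders the fixture described by \code{spec}: the nucleus is a union of
#' overlapping ellipses near the image center, the cytoplasm a morphological
#' dilation of the nucleus into a containing blob, and red cells are annular
#' disks placed by rejection sampling (never overwriting the cell, so the
#' tri-level ground truth is exact). Gaussian noise is added and the result
#' clipped to \code{[0, 1]}. The grayscale image is the BT.601 luminance of
#' the rendered color image.
#'
#' @param spec A \code{fixture_spec}.
#' @return List with \code{gray} (matrix), \code{mask} (tri-level 0/128/255
#'   matrix), \code{color} (\code{[rows, cols, 3]} array), \code{class}
#'   (a cell-type label derived from the lobe count) and \code{geometry}
#'   (red-cell centers/radii and the realized touching flag).
#' @export
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  # rejection over whole configurations: an unlucky shape draw can leave no
  # room for the requested red cells, so re-draw from a derived sub-seed
  for (attempt in 0:19) {
    sub_seed <- (spec$random_seed + attempt * 1000003) %% .Machine$integer.max
    out <- tryCatch(.render_cell(spec, sub_seed),
                    error = function(e) if (grepl("geometry", conditionMessage(e))) NULL else stop(e))
    if (!is.null(out)) return(out)
  }
  stop("geometry impossible: the canvas cannot hold ", spec$rbc_count, " red blood cells")
}

.render_cell <- function(spec, sub_seed) {
  set.seed(sub_seed)
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  R <- min(nr, nc)
  cen <- c(nr, nc) / 2 + runif(2, -0.03, 0.03) * R

  nucleus <- matrix(FALSE, nr, nc)
  ang0 <- runif(1, 0, 2 * pi)
  for (i in seq_len(spec$nucleus_lobes)) {
    ang <- ang0 + 2 * pi * (i - 1) / spec$nucleus_lobes + runif(1, -0.3, 0.3)
    off <- if (spec$nucleus_lobes == 1) 0 else 0.06 * R * runif(1, 0.8, 1.2)
    lc <- cen + off * c(sin(ang), cos(ang))
    a <- 0.11 * R * runif(1, 0.8, 1.2)
    b <- 0.085 * R * runif(1, 0.8, 1.2)
    nucleus <- nucleus | .ellipse_mask(nr, nc, lc[1], lc[2], a, b, runif(1, 0, pi))
  }
  cyt_r <- round(0.14 * R * runif(1, 0.9, 1.15))
  wbc <- .from_ebi(EBImage::dilate(.as_ebi(nucleus * 1L), .disc(cyt_r))) != 0
  cytoplasm <- wbc & !nucleus

  # distance from background pixels to the nearest cell pixel
  D <- .from_ebi(EBImage::distmap(.as_ebi(1L - wbc * 1L)))
  classes <- matrix("bg", nr, nc)
  classes[cytoplasm] <- "cyto"
  classes[nucleus] <- "nuc"

  centers <- NULL; radii <- c(); touched <- FALSE
  rr_grid <- matrix(seq_len(nr), nr, nc)
  cc_grid <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (j in seq_len(spec$rbc_count)) {
    r_o <- 0.10 * R * runif(1, 0.8, 1.2)
    placed <- FALSE
    for (try in 1:2000) {
      p <- c(runif(1, r_o + 2, nr - r_o - 1), runif(1, r_o + 2, nc - r_o - 1))
      dwbc <- D[round(p[1]), round(p[2])]
      want_touch <- spec$touching && j == 1L
      ok <- if (want_touch) dwbc >= 2 && dwbc <= r_o else dwbc >= r_o + 3
      if (ok && !is.null(centers)) {
        # slight red-cell overlap is allowed (smears crowd them); earlier
        # cells are never overwritten since painting is background-only
        dd <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
        ok <- all(dd >= 0.8 * (radii + r_o))
      }
      if (ok) {
        centers <- rbind(centers, p); radii <- c(radii, r_o)
        if (want_touch) touched <- TRUE
        d2 <- (rr_grid - p[1])^2 + (cc_grid - p[2])^2
        ring <- d2 <= r_o^2 & d2 > (0.55 * r_o)^2 & classes == "bg"
        classes[ring] <- "rbc"
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("geometry impossible: could not place red blood cell ", j)
  }

  means <- c(nuc = spec$nucleus_mean, cyto = spec$cytoplasm_mean,
             rbc = spec$rbc_mean, bg = spec$background_mean)
  bases <- list(nuc = c(0.50, 0.20, 0.90), cyto = c(0.80, 0.55, 0.85),
                rbc = c(1.00, 0.60, 0.65), bg = c(0.95, 0.90, 0.88))
  color <- array(0, c(nr, nc, 3))
  for (cl in names(means)) {
    rgb <- .class_rgb(means[[cl]], bases[[cl]])
    for (ch in 1:3) {
      plane <- color[, , ch]
      plane[classes == cl] <- rgb[ch]
      color[, , ch] <- plane
    }
  }
  if (spec$noise_sigma > 0) {
    noise <- matrix(rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
    for (ch in 1:3) color[, , ch] <- color[, , ch] + noise
  }
  color[color < 0] <- 0; color[color > 1] <- 1
  gray <- .luminance(color)

  mask <- matrix(0L, nr, nc)
  mask[cytoplasm] <- 128L
  mask[nucleus] <- 255L

  cell_class <- c("lymphocyte", "monocyte", "eosinophil")[min(spec$nucleus_lobes, 3)]
  if (spec$nucleus_lobes >= 4) cell_class <- "neutrophil"

  list(gray = gray, mask = mask, color = color, class = cell_class,
       geometry = list(rbc_centers = centers, rbc_radii = radii,
                       touching = touched, cytoplasm_radius = cyt_r),
       spec = spec)
}

#' Generate a reproducible suite of fixtures
#'
#' Draws \code{n_images} fixture specifications (lobes, red-cell counts and
#' per-image child seeds) from \code{seed} and renders each. With
#' \code{outdir} set, the color images and tri-level masks are written as
#' PNG together with a JSON manifest of the specifications; regenerating
#' with the same seed reproduces the manifest byte for byte.
#'
#' @param n_images Number of fixtures (>= 1).
#' @param regime \code{"separated"} or \code{"touching"}.
#' @param seed Suite seed.
#' @param outdir Optional output directory (created if missing).
#' @param image_size Canvas size, default \code{c(120, 120)}.
#' @return Invisibly, the list of rendered fixtures (as from
#'   \code{\link{generate_cell_image}}).
#' @export
generate_suite <- function(n_images, regime = c("separated", "touching"),
                           seed = 42, outdir = NULL, image_size = c(120, 120)) {
  regime <- match.arg(regime)
  if (n_images < 1) stop("n_images must be >= 1")
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n_images)
  lobes <- sample(1:4, n_images, replace = TRUE)
  rbcs <- sample(3:6, n_images, replace = TRUE)
  fixtures <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- fixture_spec(image_size = image_size, nucleus_lobes = lobes[i],
                       rbc_count = rbcs[i], touching = regime == "touching",
                       random_seed = child[i])
    fixtures[[i]] <- generate_cell_image(sp)
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    manifest <- list(seed = seed, regime = regime, n_images = n_images,
                     specs = lapply(fixtures, function(f) unclass(f$spec)),
                     touching_realized = vapply(fixtures, function(f) f$geometry$touching, TRUE))
    for (i in seq_len(n_images)) {
      stem <- sprintf("img_%03d", i)
      EBImage::writeImage(EBImage::Image(aperm(fixtures[[i]]$color, c(2, 1, 3)),
                                         colormode = "Color"),
                          file.path(outdir, paste0(stem, ".png")), type = "png")
      write_mask(fixtures[[i]]$mask, file.path(outdir, paste0(stem, "_mask.png")))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fixtures)
}
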