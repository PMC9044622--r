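#' SLIC superpixels
#'
#' Simple linear iterative clustering: localized k-means over concatenated
#' color and spatial coordinates. Cluster centers start on a regular grid of
#' spacing \code{S = sqrt(N / n_segments)}, are perturbed to the lowest
#' image-gradient position in their 3x3 neighborhood, and are refined for
#' \code{max_iter} iterations, each pixel competing only with centers within
#' a 2S window. The distance is
#' \code{sqrt(d_color^2 + (d_xy / S)^2 * compactness^2)}. A final
#' connectivity pass reassigns stray fragments to the dominant neighboring
#' superpixel.
#'
#' @param image Gray matrix or \code{[rows, cols, 3]} color array in
#'   \code{[0, 1]}.
#' @param n_segments Approximate number of superpixels (default 100).
#' @param compactness Spatial regularization weight (default 10; larger
#'   gives squarer superpixels). Color distances here live in \code{[0, 1]}
#'   per channel, so compactness is interpreted relative to a 0.1 color
#'   scale internally.
#' @param max_iter Refinement iterations (default 10).
#' @return Integer matrix of superpixel labels (1-based).
#' @export
slic_superpixels <- function(image, n_segments = 100, compactness = 10, max_iter = 10) {
  if (n_segments < 4) stop("n_segments must be >= 4")
  if (length(dim(image)) == 2L) {
    arr <- array(image, c(dim(image), 1L))
  } else {
    arr <- image
  }
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; nch <- dim(arr)[3]
  npix <- nr * nc
  S <- max(2, sqrt(npix / n_segments))
  # compactness on the conventional 0..100-ish intensity scale: rescale to [0,1] colors
  m <- compactness / 100
  gray <- if (nch >= 3) .luminance(arr) else arr[, , 1]
  # grid initialization, perturbed to the lowest-gradient 3x3 neighbor
  rs <- round(seq(S / 2, nr - S / 2, by = S)); cs <- round(seq(S / 2, nc - S / 2, by = S))
  rs <- pmin(pmax(rs, 2), nr - 1); cs <- pmin(pmax(cs, 2), nc - 1)
  grad <- matrix(Inf, nr, nc)
  gi <- 2:(nr - 1); gj <- 2:(nc - 1)
  grad[gi, gj] <- (gray[gi + 1, gj] - gray[gi - 1, gj])^2 +
    (gray[gi, gj + 1] - gray[gi, gj - 1])^2
  centers <- do.call(rbind, lapply(rs, function(r) t(vapply(cs, function(cc) {
    win_r <- (r - 1):(r + 1); win_c <- (cc - 1):(cc + 1)
    g <- grad[win_r, win_c]
    k <- arrayInd(which.min(g), dim(g))
    c(win_r[k[1]], win_c[k[2]])
  }, numeric(2)))))
  K <- nrow(centers)
  cen_col <- matrix(0, K, nch)
  for (k in seq_len(K)) cen_col[k, ] <- arr[centers[k, 1], centers[k, 2], ]
  cen_pos <- centers
  label <- matrix(0L, nr, nc)
  for (it in seq_len(max_iter)) {
    dist <- matrix(Inf, nr, nc)
    for (k in seq_len(K)) {
      r0 <- max(1, round(cen_pos[k, 1] - 2 * S)); r1 <- min(nr, round(cen_pos[k, 1] + 2 * S))
      c0 <- max(1, round(cen_pos[k, 2] - 2 * S)); c1 <- min(nc, round(cen_pos[k, 2] + 2 * S))
      rr <- r0:r1; cc <- c0:c1
      dc2 <- 0
      for (ch in seq_len(nch)) {
        dc2 <- dc2 + (arr[rr, cc, ch] - cen_col[k, ch])^2
      }
      ds2 <- outer((rr - cen_pos[k, 1])^2, (cc - cen_pos[k, 2])^2, `+`)
      D <- dc2 + ds2 * (m / S)^2
      win <- dist[rr, cc]
      upd <- D < win
      win[upd] <- D[upd]
      dist[rr, cc] <- win
      lw <- label[rr, cc]
      lw[upd] <- k
      label[rr, cc] <- lw
    }
    # recompute centers
    for (k in seq_len(K)) {
      sel <- which(label == k, arr.ind = TRUE)
      if (!nrow(sel)) next
      cen_pos[k, ] <- colMeans(sel)
      for (ch in seq_len(nch)) cen_col[k, ch] <- mean(arr[, , ch][label == k])
    }
  }
  .slic_enforce_connectivity(label, K)
}

# Reassign non-largest fragments of each superpixel to the most frequent
# neighboring label.
.slic_enforce_connectivity <- function(label, K) {
  nr <- nrow(label); nc <- ncol(label)
  for (k in seq_len(K)) {
    msk <- label == k
    if (!any(msk)) next
    comp <- label_components(msk * 1L)
    ncomp <- max(comp)
    if (ncomp <= 1L) next
    areas <- tabulate(comp[comp > 0L])
    main <- which.max(areas)
    for (frag in setdiff(seq_len(ncomp), main)) {
      sel <- comp == frag
      # neighbor labels via 4-neighborhood shifts
      idx <- which(sel, arr.ind = TRUE)
      nb <- rbind(cbind(idx[, 1] - 1L, idx[, 2]), cbind(idx[, 1] + 1L, idx[, 2]),
                  cbind(idx[, 1], idx[, 2] - 1L), cbind(idx[, 1], idx[, 2] + 1L))
      ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
      nb <- nb[ok, , drop = FALSE]
      labs <- label[nb]
      labs <- labs[labs != k & labs > 0]
      label[sel] <- if (length(labs)) as.integer(names(which.max(table(labs)))) else k
    }
  }
  label
}
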