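# Independent oracles and small fixture builders used across the suite.

# Brute-force neighbor-comparison extrema oracle on a discrete sequence:
# first strict local maximum, then the first strict local minimum after it.
oracle_first_extrema <- function(values) {
  n <- length(values)
  i_max <- NA_integer_
  for (i in 2:(n - 1)) {
    if (values[i] > values[i - 1] && values[i] > values[i + 1]) { i_max <- i; break }
  }
  if (is.na(i_max)) return(NULL)
  for (j in (i_max + 1):(n - 1)) {
    if (j < 2) next
    if (values[j] < values[j - 1] && values[j] < values[j + 1]) {
      return(list(i_max = i_max, i_min = j))
    }
  }
  NULL
}

# Exhaustive between-class-variance Otsu oracle, written with explicit
# per-class sums (independent of the vectorized implementation).
oracle_otsu <- function(image, nbins = 256) {
  v <- as.vector(image)
  idx <- pmin(floor(v * nbins) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  centers <- (seq_len(nbins) - 0.5) / nbins
  total <- sum(counts)
  best <- -Inf; best_k <- NA_integer_
  for (k in 1:(nbins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * centers[(k + 1):nbins]) / n1
    sb <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (sb > best + 1e-15) { best <- sb; best_k <- k }
  }
  best_k / nbins
}

# Closed-form branch oracle for the threshold rule.
oracle_branch <- function(T_nc0, x_c1, Er) {
  d <- abs(T_nc0 - x_c1)
  if (d <= Er) list(branch = "b", eps = (T_nc0 + x_c1) / 2)
  else if (T_nc0 > x_c1) list(branch = "c", eps = (T_nc0 + x_c1 + Er) / 2)
  else list(branch = "d", eps = (T_nc0 + x_c1 - Er) / 2)
}

# A filled disc mask.
disc_mask <- function(nr, nc, cr, cc, r) {
  rr <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  matrix(as.integer((rr - cr)^2 + (cl - cc)^2 <= r^2), nr, nc)
}

# Write an 8-bit gray PNG from a [0,1] matrix, returning the path.
write_gray_png <- function(m, path = tempfile(fileext = ".png")) {
  EBImage::writeImage(EBImage::Image(t(m)), path, type = "png")
  path
}

default_suite_seed <- 42
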