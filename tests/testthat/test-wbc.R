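test_that("threshold family reproduces the endpoint-inclusive worked example", {
  img <- matrix(c(0, 1), 1, 2)
  fam <- generate_wbc_thresholds(img, T_nc0 = 1 / 3, n = 5)
  expect_equal(fam$base, 2 / 3)
  expect_equal(fam$steps, c(0, 1 / 12, 1 / 6, 1 / 4, 1 / 3))
  expect_equal(fam$thresholds, c(2 / 3, 0.75, 5 / 6, 11 / 12, 1), tolerance = 1e-12)

  fam2 <- generate_wbc_thresholds(img, 1 / 3, n = 2)
  expect_equal(fam2$thresholds, c(2 / 3 + 0, 2 / 3 + 1 / 3))

  expect_error(generate_wbc_thresholds(matrix(0.4, 2, 2), 0.3, 5), "constant")
  expect_error(generate_wbc_thresholds(img, 0.3, 1), "n must be")
})

test_that("family invariants hold for n in {2, 5, 10, 50} on varied images", {
  set.seed(21)
  imgs <- list(matrix(runif(400), 20, 20),
               matrix(runif(400, 0.1, 0.9), 20, 20),
               generate_cell_image(fixture_spec(random_seed = 7))$gray)
  for (img in imgs) {
    T0 <- compute_initial_value(img)
    for (n in c(2, 5, 10, 50)) {
      fam <- suppressWarnings(generate_wbc_thresholds(img, T0, n))
      expect_true(all(diff(fam$thresholds_raw) > 0))
      expect_equal(fam$delta_h * (fam$n - 1), fam$a_u - fam$a_l, tolerance = 1e-12)
      expect_equal(fam$steps[1], fam$a_l)
      expect_equal(fam$steps[fam$n], fam$a_u, tolerance = 1e-12)
      expect_equal(fam$thresholds_raw, fam$base + fam$steps, tolerance = 1e-12)
    }
  }
})

test_that("floor images and their average dominate the input pointwise", {
  img <- matrix(c(0.5, 0.9, 0.2, 0.7), 2, 2)
  ti <- threshold_image(img, 0.7)
  expect_equal(ti, matrix(c(0.7, 0.9, 0.7, 0.7), 2, 2))
  expect_true(all(ti >= img))

  fx <- generate_cell_image(fixture_spec(random_seed = 13))
  fam <- suppressWarnings(generate_wbc_thresholds(fx$gray, compute_initial_value(fx$gray)))
  aw <- average_reconstruction(fx$gray, fam)
  expect_true(all(aw >= fx$gray - 1e-12))
  # pixels below every threshold map to the mean of the thresholds
  below <- fx$gray <= min(fam$thresholds)
  expect_equal(unique(round(aw[below], 12)), round(mean(fam$thresholds), 12))
  # pixels above every threshold are untouched
  above <- fx$gray >= max(fam$thresholds)
  expect_equal(aw[above], fx$gray[above])
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(31)
  cases <- list(
    matrix(c(rep(0.2, 100), rep(0.8, 100)), 10, 20),
    matrix(c(rep(0.2, 190), rep(0.8, 10)), 10, 20)
  )
  for (rep in 1:10) {
    n <- sample(c(100, 400), 1)
    mix <- c(rnorm(n, runif(1, 0.1, 0.4), 0.05), rnorm(n, runif(1, 0.6, 0.9), 0.05))
    cases[[length(cases) + 1]] <- matrix(pmin(pmax(mix, 0), 1), 2 * n / 10, 10)
  }
  for (img in cases) {
    t_pkg <- otsu_threshold(img)
    expect_equal(t_pkg, oracle_otsu(img))
    rng <- range(img)
    expect_gt(t_pkg, rng[1]); expect_lt(t_pkg, rng[2])
  }
  # independent library cross-check: empty valley bins create plateau ties,
  # so compare the achieved between-class variance, not the tie chosen
  sigma_b_at <- function(img, t) {
    v <- as.vector(img); p0 <- mean(v <= t)
    if (p0 == 0 || p0 == 1) return(0)
    p0 * (1 - p0) * (mean(v[v <= t]) - mean(v[v > t]))^2
  }
  for (img in cases[3:6]) {
    t_eb <- EBImage::otsu(EBImage::Image(t(img)), range = c(0, 1), levels = 256)
    expect_equal(sigma_b_at(img, otsu_threshold(img)), sigma_b_at(img, t_eb),
                 tolerance = 1e-6)
  }
  expect_error(otsu_threshold(matrix(0.3, 4, 4)), "constant")
})

test_that("nucleus seed is the floor centroid of the largest component", {
  sq <- matrix(0L, 20, 20); sq[1:10, 1:10] <- 1L
  expect_equal(select_seed_from_nucleus(sq), c(4L, 4L))   # 0-based

  # C-shape: centroid falls in the cavity; seed snaps onto the mask
  cshape <- matrix(0L, 30, 30)
  cshape[5:25, 5:10] <- 1L; cshape[5:10, 5:25] <- 1L; cshape[20:25, 5:25] <- 1L
  seed <- select_seed_from_nucleus(cshape)
  expect_equal(cshape[seed[1] + 1, seed[2] + 1], 1L)

  # largest-component rule
  two <- matrix(0L, 30, 30)
  two[1:10, 1:10] <- 1L          # 100 px
  two[25:29, 25:28] <- 1L        # 20 px
  seed2 <- select_seed_from_nucleus(two)
  expect_true(seed2[1] < 10 && seed2[2] < 10)

  expect_error(select_seed_from_nucleus(matrix(0L, 5, 5)), "nucleus segmentation")
})

test_that("seeded extraction keeps exactly the seed component", {
  m <- matrix(0L, 30, 30)
  m[2:10, 2:10] <- 1L
  m[20:28, 20:28] <- 1L
  out <- extract_wbc_by_seed(m, c(5L, 5L))
  expect_equal(sum(out), 81L)
  expect_equal(out[6, 6], 1L)
  expect_equal(out[25, 25], 0L)
  expect_identical(extract_wbc_by_seed(out, c(5L, 5L)), out)
  expect_error(extract_wbc_by_seed(m, c(15L, 15L)), "nearest foreground")
  expect_error(extract_wbc_by_seed(m, c(99L, 0L)), "bounds")
})

test_that("cytoplasm subtraction obeys mask algebra", {
  wbc <- matrix(0L, 20, 20); wbc[5:16, 5:16] <- 1L          # 144 px
  nuc <- matrix(0L, 20, 20); nuc[8:13, 8:13] <- 1L          # 36 px inside
  cyt <- compute_cytoplasm(wbc, nuc)
  expect_equal(sum(cyt), 144L - 36L)
  expect_equal(sum(cyt & nuc), 0L)
  expect_true(all(wbc[cyt == 1L] == 1L))

  expect_equal(sum(compute_cytoplasm(wbc, wbc)), 0L)

  nuc2 <- nuc; nuc2[1:3, 1:3] <- 1L   # partially outside
  expect_warning(cyt2 <- compute_cytoplasm(wbc, nuc2), "clipped")
  expect_equal(sum(cyt2), 144L - 36L)
})

test_that("whole-cell segmentation nests the nucleus and splits the cytoplasm", {
  fx <- generate_cell_image(fixture_spec(random_seed = 42))
  nuc <- segment_nucleus(fx$gray)
  res <- suppressWarnings(segment_wbc(fx$gray, nuc$mask, T_nc0 = nuc$estimate$T_nc0))
  wbc_truth <- matrix(as.integer(fx$mask >= 128), nrow(fx$mask), ncol(fx$mask))
  expect_gte(dice(confusion(res$wbc, wbc_truth)), 0.90)
  # set identities: nucleus inside the cell, cytoplasm = cell minus nucleus
  expect_equal(sum(nuc$mask == 1L & res$wbc == 0L), 0L)
  expect_equal(sum(res$cytoplasm & nuc$mask), 0L)
  expect_identical(matrix(as.integer(res$cytoplasm | (nuc$mask & res$wbc)),
                          nrow(res$wbc), ncol(res$wbc)), res$wbc)
  # the mask is a single connected component
  expect_equal(max(label_components(res$wbc)), 1L)
})
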