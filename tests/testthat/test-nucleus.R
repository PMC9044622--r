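test_that("initial value follows Max(A)/n1 + Min(A)/n2", {
  img <- matrix(c(0, 0.4, 0.7, 1), 2, 2)
  expect_equal(compute_initial_value(img, 3, 3), 1 / 3)

  img2 <- matrix(c(0.1, 0.5, 0.9), 1, 3)
  expect_equal(compute_initial_value(img2, 3, 5), 0.32)

  expect_warning(compute_initial_value(matrix(0.5, 3, 3), 2, 2), "outside")
  expect_error(compute_initial_value(img, 0, 3), "n1 and n2")
})

test_that("the four-branch rule reproduces its closed forms", {
  pair <- function(x_c1) extrema_pair(0.1, x_c1)
  b <- estimate_threshold(0.34, pair(0.30), 0.07)
  expect_equal(b$branch, "b"); expect_equal(b$epsilon_t, 0.32)
  cc <- estimate_threshold(0.45, pair(0.30), 0.07)
  expect_equal(cc$branch, "c"); expect_equal(cc$epsilon_t, 0.41)
  d <- estimate_threshold(0.30, pair(0.45), 0.07)
  expect_equal(d$branch, "d"); expect_equal(d$epsilon_t, 0.34)

  # condition (a) violation signals a retry
  expect_error(estimate_threshold(0.2, extrema_pair(0.3, 0.4), 0.07),
               class = "lminseg_condition_a")
})

test_that("randomized branch triples match the oracle exactly", {
  set.seed(101)
  n <- 1000
  T0 <- runif(n, 0.05, 0.95)
  x1 <- runif(n, 0.05, 0.95)
  Er <- runif(n, 0.01, 0.2)
  # include exact |diff| = Er boundary cases
  x1[1:50] <- T0[1:50] + sample(c(-1, 1), 50, TRUE) * Er[1:50]
  for (i in seq_len(n)) {
    ex <- extrema_pair(min(T0[i], x1[i]) - 0.01, x1[i])
    got <- estimate_threshold(T0[i], ex, Er[i])
    orc <- oracle_branch(T0[i], x1[i], Er[i])
    expect_identical(got$branch, orc$branch)
    expect_identical(got$epsilon_t, orc$eps)
    # interval invariant of the estimate record
    expect_gte(got$epsilon_t, min(T0[i], x1[i]) - Er[i] / 2 - 1e-12)
    expect_lte(got$epsilon_t, max(T0[i], x1[i]) + Er[i] / 2 + 1e-12)
  }
})

test_that("reconstruction floors the dark class and is idempotent and monotone", {
  img <- matrix(c(0.05, 0.2, 0.5, 0.9), 2, 2)
  rec <- reconstruct_nucleus_image(img, 0.32)
  expect_equal(rec[1, 1], 0.05)
  expect_equal(rec[2, 1], 0.05)   # 0.2 -> Min(A)
  expect_equal(rec[1, 2], 0.5)    # unchanged
  expect_equal(reconstruct_nucleus_image(rec, 0.32), rec)

  # monotone: larger threshold floors a superset of pixels
  set.seed(5)
  im <- matrix(runif(400), 20, 20)
  low <- reconstruct_nucleus_image(im, 0.3) == min(im)
  high <- reconstruct_nucleus_image(im, 0.6) == min(im)
  expect_true(all(high[low]))
})

test_that("binarization flags suspicious all-or-nothing masks", {
  img <- matrix(c(0.1, 0.9, 0.3, 0.8), 2, 2)
  expect_equal(binarize_nucleus(img, 0.32), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_warning(binarize_nucleus(img, 0), "empty")
  expect_warning(binarize_nucleus(img, 1), "all-foreground")
})

test_that("postprocess removes specks and fills holes", {
  m <- matrix(0L, 60, 60)
  m[10:35, 10:35] <- 1L                 # ~676 px blob
  m[20:22, 20:22] <- 0L                 # 9 px interior hole
  m[50, 50] <- 1L; m[55, 5] <- 1L; m[5, 55] <- 1L   # specks
  out <- postprocess_mask(m, min_object_area = 50)
  expect_equal(sum(out), 26 * 26)       # hole filled, specks gone
  expect_equal(out[21, 21], 1L)
  expect_equal(out[50, 50], 0L)

  clean <- disc_mask(40, 40, 20, 20, 10)
  expect_equal(postprocess_mask(clean, 50), clean)
})

test_that("nucleus segmentation recovers the dark class on fixtures", {
  fx <- generate_cell_image(fixture_spec(random_seed = 42))
  res <- segment_nucleus(fx$gray)
  truth <- matrix(as.integer(fx$mask == 255), nrow(fx$mask), ncol(fx$mask))
  expect_gte(dice(confusion(res$mask, truth)), 0.95)
  # threshold sits between the class means, near the valley
  expect_gt(res$estimate$epsilon_t, fx$spec$nucleus_mean)
  expect_lt(res$estimate$epsilon_t, fx$spec$cytoplasm_mean)
  expect_true(res$estimate$branch %in% c("b", "c", "d"))

  # constant image: fallback branch
  suppressWarnings({
    res2 <- segment_nucleus(matrix(0.5, 40, 40))
  })
  expect_equal(res2$estimate$branch, "fallback")
  expect_equal(res2$estimate$epsilon_t, res2$estimate$T_nc0)
})

test_that("epsilon_t lands in the valley of two-Gaussian histograms", {
  set.seed(9)
  for (rep in 1:5) {
    m1 <- runif(1, 0.15, 0.25); m2 <- runif(1, 0.5, 0.65)
    v <- c(rnorm(2500, m1, 0.03), rnorm(5500, m2, 0.05))
    img <- matrix(pmin(pmax(v, 0), 1), 80, 100)
    res <- segment_nucleus(img)
    expect_gt(res$estimate$epsilon_t, m1)
    expect_lt(res$estimate$epsilon_t, m2)
  }
})
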