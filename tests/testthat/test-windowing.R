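test_that("level ranges are inclusive runs of integers", {
  r <- level_range(18, 42)
  expect_identical(r$n_levels, 25L)  # {18, 42} holds 25 integer levels
  expect_identical(level_range(5, 5)$n_levels, 1L)
  expect_error(level_range(10, 9), "hi")
  expect_error(level_range(-1, 5), "lo")
})

test_that("histograms tally retained pixels only", {
  m <- matrix(c(1L, 1L, 2L), 1, 3)
  h <- level_histogram(m)
  expect_identical(h, data.frame(value = 1:2, count = c(2L, 1L)))
  h2 <- level_histogram(m, range = level_range(2, 2))
  expect_identical(h2, data.frame(value = 2L, count = 1L))
  # suppressed pixels are excluded entirely, not counted as zeros
  h3 <- level_histogram(m, mask = matrix(c(FALSE, TRUE, TRUE), 1, 3))
  expect_identical(h3$count[h3$value == 1L], 1L)
  # empty retained set: all-zero histogram, not an error
  h4 <- level_histogram(m, mask = matrix(FALSE, 1, 3), range = level_range(1, 3))
  expect_identical(h4$count, c(0L, 0L, 0L))

  ph <- tiny_phantom()
  msk <- ph$truth$tissue
  h5 <- level_histogram(ph$image, msk, level_range(18, 42))
  expect_identical(h5$count,
                   oracle_histogram(pixels(ph$image), msk, 18L, 42L))
  expect_identical(sum(h5$count), sum(msk))
})

test_that("histogram marginalization matches range_mask coverage", {
  ph <- tiny_phantom(size = 48, seed = 12)
  msk <- central_region_mask(ph$image)
  rg <- level_range(18, 42)
  h <- level_histogram(ph$image, msk, rg)
  expect_identical(sum(h$count),
                   sum(combine_masks(list(msk, range_mask(ph$image, rg)))))
})

test_that("distinct_values counts unique retained values", {
  expect_identical(distinct_values(matrix(5L, 1, 3)), 1L)
  expect_identical(distinct_values(matrix(0:3, 1, 4)), 4L)
  ph <- tiny_phantom()
  expect_identical(distinct_values(ph$image, ph$truth$tissue), 25L)
})

test_that("range_mask is inclusive at both ends", {
  m <- matrix(c(17L, 18L, 42L, 43L), 1, 4)
  expect_identical(range_mask(m, c(18, 42)), matrix(c(FALSE, TRUE, TRUE, FALSE), 1, 4))
  expect_identical(range_mask(m, c(0, max(m))), matrix(TRUE, 1, 4))
})

test_that("rescale_unit maps the range affinely onto [0, 1]", {
  m <- matrix(c(18L, 30L, 42L, 17L, 43L), 1, 5)
  r <- rescale_unit(m, level_range(18, 42))
  expect_identical(r[1, 1:3], c(0, 0.5, 1))
  expect_true(all(is.na(r[1, 4:5])))  # out-of-range is suppressed, never clamped
  # adjacent integers differ by exactly 1/(hi - lo)
  g <- rescale_unit(matrix(18:42, 1), level_range(18, 42))
  expect_equal(diff(g[1, ]), rep(1 / 24, 24))
  # strictly monotone: pixel value order is preserved
  expect_true(all(diff(g[1, ]) > 0))
  expect_error(rescale_unit(m, level_range(5, 5)), "degenerate")
})

test_that("relative_gray_step is the adjacent-level contrast 1/max", {
  expect_equal(round(relative_gray_step(1682), 4), 0.0006)
  expect_identical(relative_gray_step(1), 1)
  expect_identical(relative_gray_step(2000), 0.0005)
  expect_error(relative_gray_step(0), "max_value")
})

test_that("masked statistics use retained pixels only, population variance", {
  s <- masked_stats(matrix(c(2L, 4L, 6L, 1000L), 1, 4),
                    matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4))
  expect_identical(s$mean, 4)
  expect_identical(s$n, 3L)
  expect_equal(s$variance, 8 / 3)     # divide by n
  expect_identical(s$variance, s$deviation^2)
  sc <- masked_stats(matrix(7L, 2, 2))
  expect_identical(sc$deviation, 0)
  expect_error(masked_stats(matrix(1L, 2, 2), matrix(FALSE, 2, 2)), "retained")

  ph <- tiny_phantom()
  msk <- combine_masks(list(central_region_mask(ph$image),
                            range_mask(ph$image, c(18, 42))))
  s2 <- masked_stats(ph$image, msk)
  o <- oracle_stats(pixels(ph$image), msk)
  expect_equal(s2$mean, o$mean)
  expect_equal(s2$variance, o$variance)
  expect_identical(s2$n, o$n)
  expect_true(s2$mean >= 18 && s2$mean <= 42)
})

test_that("statistics are mask-consistent however suppression is realized", {
  ph <- tiny_phantom(size = 48, seed = 5)
  m <- pixels(ph$image)
  msk <- combine_masks(list(zero_mask(m), high_value_mask(m, 100)))
  a <- masked_stats(m, msk)
  # same pixels reached by zeroing first and then excluding the zeros
  zeroed <- apply_mask(m, msk)
  b <- masked_stats(zeroed, zero_mask(zeroed) & msk)
  expect_equal(a$mean, b$mean)
  expect_equal(a$variance, b$variance)
})

test_that("neighborhood averaging renormalizes over present stencil members", {
  m <- matrix(1:25, 5, 5)
  # k = 1 is the identity on the retained set
  expect_identical(neighborhood_average(m, 1), m + 0.0)
  # constant image is unchanged for any k
  cst <- matrix(9L, 6, 6)
  for (k in c(2, 5, 7, 9)) {
    av <- neighborhood_average(cst, k)
    expect_true(all(av == 9))
  }
  # k = 7 stencil at interior and border pixels equals the brute-force mean
  full <- matrix(TRUE, 5, 5)
  for (ij in list(c(3, 3), c(1, 1), c(5, 3), c(2, 5))) {
    expect_equal(neighborhood_average(m, 7)[ij[1], ij[2]],
                 oracle_stencil_mean(m, full, ij[1], ij[2], 7))
  }
  # suppressed members are dropped, suppressed pixels stay suppressed
  msk <- matrix(TRUE, 5, 5); msk[3, 4] <- FALSE; msk[2, 2] <- FALSE
  av <- neighborhood_average(m, 7, msk)
  expect_true(is.na(av[3, 4]))
  for (ij in list(c(3, 3), c(2, 3), c(1, 2))) {
    expect_equal(av[ij[1], ij[2]], oracle_stencil_mean(m, msk, ij[1], ij[2], 7))
  }
  expect_error(neighborhood_average(m, 26), "exceeds")
})

test_that("averaging never widens the local value range", {
  ph <- tiny_phantom(size = 48, seed = 9)
  m <- pixels(ph$image)
  msk <- ph$truth$tissue
  av <- neighborhood_average(m, 7, msk)
  expect_true(all(av[msk] >= min(m[msk]) - 1e-12))
  expect_true(all(av[msk] <= max(m[msk]) + 1e-12))
})
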