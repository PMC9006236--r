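test_that("full pipeline reproduces the hand-traced one-dimension fixture", {
  # zstar {0.1, 0.1, 0.6, 0.6}, abundances {1, 3, 2, 6}, alpha = 4:
  # category 1 mean(1,3) = 2, category 3 mean(2,6) = 4 -> wstar {0.5, NA, 1, NA}
  tb <- data.frame(abundance = c(1, 3, 2, 6), temp = c(0.1, 0.1, 0.6, 0.6))
  rng <- tibble::tibble(dimension = "temp", min = 0, max = 1)
  ch <- chromatogram(tb, alpha = 4, m = 1, k = 100, smooth_window = 1,
                     env_range = rng)
  expect_equal(unname(ch$wstar[, "temp"]), c(0.5, NA, 1, NA))
  expect_equal(unname(ch$counts[, "temp"]), c(2L, 0L, 2L, 0L))
})

test_that("equal abundances fill every populated category with exactly 1", {
  tb <- data.frame(abundance = rep(3, 30), env1 = runif(30))
  ch <- chromatogram(tb, alpha = 5, m = 1, k = 5, smooth_window = 1)
  col <- ch$wstar[, 1]
  expect_true(all(col[!is.na(col)] == 1))
})

test_that("all categories below m give an all-missing chromatogram with warning", {
  tb <- data.frame(abundance = c(1, 2), env1 = c(0, 1))
  expect_warning(ch <- chromatogram(tb, alpha = 4, m = 5, k = 100,
                                    smooth_window = 1),
                 "no positive abundance")
  expect_true(all(is.na(ch$wstar)))
})

test_that("with window 1, k 100, m 1 the pipeline equals a group-by mean oracle", {
  set.seed(41)
  for (rep in 1:5) {
    tb <- rand_table(n = sample(30:200, 1), p = sample(1:3, 1))
    alpha <- sample(3:10, 1)
    ch <- chromatogram(tb, alpha = alpha, m = 1, k = 100, smooth_window = 1)
    expect_equal(ch$wstar, groupby_chromatogram(tb, alpha), tolerance = 1e-12)
  }
})

test_that("chromatograms are invariant to sample order and abundance rescaling", {
  set.seed(7)
  tb <- rand_table(80, 2)
  ch <- chromatogram(tb, alpha = 6, m = 2, k = 25)
  perm <- chromatogram(tb[sample(nrow(tb)), ], alpha = 6, m = 2, k = 25)
  expect_equal(ch$wstar, perm$wstar)

  scaled <- tb
  scaled$abundance <- scaled$abundance * 17.3
  chs <- chromatogram(scaled, alpha = 6, m = 2, k = 25)
  expect_equal(ch$wstar, chs$wstar)
})

test_that("raising m only converts categories to missing, never alters survivors", {
  set.seed(11)
  tb <- rand_table(150, 2)
  lo <- chromatogram(tb, alpha = 8, m = 2, k = 30, smooth_window = 1)
  hi <- chromatogram(tb, alpha = 8, m = 10, k = 30, smooth_window = 1)
  surviving <- !is.na(hi$unsmoothed)
  expect_true(all(!is.na(lo$unsmoothed)[surviving]))
  expect_equal(hi$unsmoothed[surviving], lo$unsmoothed[surviving])
})

test_that("non-missing entries lie in [0, 1] and each column attains 1", {
  set.seed(3)
  tb <- rand_table(120, 3)
  ch <- chromatogram(tb, alpha = 10, m = 1, k = 10)
  for (j in 1:3) {
    col <- ch$wstar[, j]
    expect_true(all(col[!is.na(col)] >= 0 & col[!is.na(col)] <= 1))
    expect_equal(max(col, na.rm = TRUE), 1)
  }
})

test_that("rows with missing environmental values are discarded with a message", {
  tb <- data.frame(abundance = c(1, 2, 3), env1 = c(0.1, NA, 0.9),
                   env2 = c(0.2, 0.5, 0.8))
  expect_message(ch <- chromatogram(tb, alpha = 2, m = 1, k = 100,
                                    smooth_window = 1),
                 "1 sample")
  expect_equal(ch$n_samples, 2L)
})

test_that("tidy and glance expose the cells and the summary", {
  tb <- data.frame(abundance = c(1, 3, 2, 6), temp = c(0.1, 0.1, 0.6, 0.6))
  ch <- chromatogram(tb, alpha = 4, m = 1, k = 100, smooth_window = 1,
                     env_range = tibble::tibble(dimension = "temp", min = 0, max = 1))
  td <- tidy(ch)
  expect_equal(nrow(td), 4)
  expect_equal(td$abundance[td$category == 3], 1)
  gl <- glance(ch)
  expect_equal(gl$p, 1L)
  expect_equal(gl$prop_missing, 0.5)
})
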