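test_that("selection fills interior gaps assuming a unimodal niche", {
  ch <- fake_chromatogram(cbind(env1 = c(0, 0.4, 0.1, 0.6, 0)))
  n <- select_and_fill(ch, T = 0.25)
  expect_equal(n$lower, 2L)
  expect_equal(n$upper, 4L)
  expect_equal(n$width, 3L)

  below <- select_and_fill(ch, T = 0.7)
  expect_equal(below$width, 0L)
  expect_true(is.na(below$lower))

  ch0 <- fake_chromatogram(cbind(env1 = c(0, 0.2, 0)))
  n0 <- select_and_fill(ch0, T = 0)
  expect_equal(c(n0$lower, n0$upper, n0$width), c(2L, 2L, 1L))

  # missing categories inside the span are filled unconditionally
  chna <- fake_chromatogram(cbind(env1 = c(0.5, NA, 0.9, 0.1)))
  nna <- select_and_fill(chna, T = 0.25)
  expect_equal(nna$width, 3L)
})

test_that("index D matches hand-computed volume ratios and endpoints", {
  mk <- function(l, u) {
    n <- tibble::tibble(dimension = c("a", "b")[seq_along(l)],
                        lower = as.integer(l), upper = as.integer(u),
                        width = as.integer(u - l + 1))
    attr(n, "alpha") <- 10L
    n
  }
  # beta (2,2), gamma (2,2), theta (1,2): 100 * 2 / (4 + 4 - 2)
  n1 <- mk(c(1, 1), c(2, 2))
  n2 <- mk(c(2, 1), c(3, 2))
  expect_equal(index_d(n1, n2), 100 * 2 / 6)
  expect_equal(index_d(n1, n1), 100)
  # disjoint on one dimension kills the product
  n3 <- mk(c(5, 1), c(6, 2))
  expect_equal(index_d(n1, n3), 0)
  # degenerate (empty) niche yields 0 with a warning
  n4 <- mk(c(NA, 1), c(NA, 2))
  n4$width <- c(0L, 2L)
  expect_warning(d <- index_d(n1, n4), "degenerate")
  expect_equal(d, 0)
  # mismatched dimension sets refuse to compare
  n5 <- mk(1, 2)
  expect_error(index_d(n1, n5), "dimension sets")
})

test_that("index D equals the brute-force lattice Jaccard on random niches", {
  set.seed(101)
  for (i in 1:200) {
    alpha <- sample(3:8, 1)
    p <- sample(1:3, 1)
    n1 <- rand_niche(alpha, p)
    n2 <- rand_niche(alpha, p)
    got <- suppressWarnings(index_d(n1, n2))
    want <- lattice_jaccard(n1$lower, n1$upper, n2$lower, n2$upper)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("D is symmetric, bounded, and invariant to dimension relabeling", {
  set.seed(23)
  for (i in 1:50) {
    p <- sample(2:4, 1)
    n1 <- rand_niche(8, p)
    n2 <- rand_niche(8, p)
    d12 <- suppressWarnings(index_d(n1, n2))
    d21 <- suppressWarnings(index_d(n2, n1))
    expect_equal(d12, d21)
    expect_gte(d12, 0)
    expect_lte(d12, 100)
    perm <- sample(p)
    m1 <- n1[perm, ]
    m2 <- n2[perm, ]
    attr(m1, "alpha") <- attr(m2, "alpha") <- 8L
    expect_equal(suppressWarnings(index_d(m1, m2)), d12)
  }
})

test_that("adding a dimension never increases D", {
  set.seed(77)
  for (i in 1:50) {
    p <- sample(2:4, 1)
    n1 <- rand_niche(8, p, empty_prob = 0)
    n2 <- rand_niche(8, p, empty_prob = 0)
    sub <- sample(p, p - 1)
    d_small <- index_d(n1, n2, dims = sub)
    d_large <- index_d(n1, n2)
    expect_lte(d_large, d_small + 1e-12)
  }
})

test_that("pairwise D is compositional, with 100 on the diagonal", {
  tabs <- generate_pseudo_species(n_samples = 100)
  chs <- chromatograms(tabs[c("sp1", "sp2", "sp4")], alpha = 20, m = 1, k = 5)
  pd <- pairwise_d(chs, T = 0.1)
  m <- d_matrix(pd)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  # off-diagonal entries match element-wise index_d calls
  n1 <- select_and_fill(chs$sp1, 0.1)
  n4 <- select_and_fill(chs$sp4, 0.1)
  expect_equal(m["sp1", "sp4"], index_d(n1, n4))
  # duplicated species give exactly 100
  pd_dup <- pairwise_d(list(a = chs$sp1, b = chs$sp1), T = 0.1)
  expect_equal(pd_dup$d, rep(100, 3))
})

test_that("combination scan finds the most discriminant subsets", {
  # two species, two dims: per-dimension D {33.33, 100}, joint D 33.33
  ch1 <- fake_chromatogram(cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0)))
  ch2 <- fake_chromatogram(cbind(a = c(0, 1, 1, 0), b = c(1, 1, 0, 0)))
  sc <- combination_scan(list(s1 = ch1, s2 = ch2), T = 0.5)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$mean_d[sc$dims == "1"], 100 / 3)
  expect_equal(sc$mean_d[sc$dims == "2"], 100)
  expect_equal(sc$mean_d[sc$dims == "1+2"], 100 * 2 / 6)
  best <- best_combinations(sc)
  expect_equal(best$dims, c("1", "1+2"))
  expect_equal(best$dim_names, c("a", "a+b"))
  expect_true(all(diff(best$mean_d) <= 1e-12))

  # identical species: every subset averages 100
  sc_same <- combination_scan(list(a = ch1, b = ch1), T = 0.5)
  expect_true(all(sc_same$mean_d == 100))
})

test_that("per-size scan minima are non-increasing on random fixtures", {
  set.seed(13)
  for (rep in 1:5) {
    chs <- purrr::map(1:3, function(i) {
      w <- matrix(runif(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
      fake_chromatogram(w)
    })
    names(chs) <- paste0("s", 1:3)
    best <- best_combinations(combination_scan(chs, T = 0.3))
    expect_true(all(diff(best$mean_d) <= 1e-12))
  }
})
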