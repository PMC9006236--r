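# Shared fixtures and independent oracles, built in code at test time.

# random sample table: n samples, p uniform environmental dimensions,
# non-negative lognormal-ish abundances with a share of exact zeros
rand_table <- function(n, p, zero_frac = 0.3) {
  env <- as.data.frame(matrix(runif(n * p), n, p))
  names(env) <- paste0("env", seq_len(p))
  ab <- exp(rnorm(n))
  ab[runif(n) < zero_frac] <- 0
  cbind(data.frame(abundance = ab), env)
}

# brute-force per-category mean oracle (the chromatogram with window = 1,
# k = 100, m = 1 must reduce to this plain group-by mean)
groupby_chromatogram <- function(tb, alpha) {
  dims <- setdiff(names(tb), "abundance")
  w <- matrix(NA_real_, alpha, length(dims), dimnames = list(NULL, dims))
  for (d in dims) {
    z <- (tb[[d]] - min(tb[[d]])) / (max(tb[[d]]) - min(tb[[d]]))
    cat_idx <- pmin(floor(z * alpha) + 1, alpha)
    means <- tapply(tb$abundance, factor(cat_idx, levels = 1:alpha), mean)
    w[, d] <- as.numeric(means)
  }
  sweep(w, 2, apply(w, 2, max, na.rm = TRUE), "/")
}

# brute-force lattice Jaccard: enumerate the explicit category cells of the
# two hyperrectangles and count |A n B| / |A u B|
lattice_jaccard <- function(l1, u1, l2, u2) {
  cells <- function(l, u) {
    if (any(is.na(l)) || any(is.na(u))) return(character(0))
    grids <- Map(seq, l, u)
    do.call(paste, c(expand.grid(grids), sep = ","))
  }
  a <- cells(l1, u1)
  b <- cells(l2, u2)
  un <- length(union(a, b))
  if (un == 0) return(0)
  100 * length(intersect(a, b)) / un
}

# random selected niche on p dimensions, possibly empty on some
rand_niche <- function(alpha, p, empty_prob = 0.15) {
  lower <- upper <- integer(p)
  for (i in seq_len(p)) {
    if (runif(1) < empty_prob) {
      lower[i] <- NA_integer_
      upper[i] <- NA_integer_
    } else {
      lower[i] <- sample.int(alpha, 1)
      upper[i] <- lower[i] + sample.int(alpha - lower[i] + 1L, 1) - 1L
    }
  }
  n <- tibble::tibble(dimension = paste0("env", seq_len(p)),
                      lower = lower, upper = upper,
                      width = ifelse(is.na(lower), 0L, upper - lower + 1L))
  attr(n, "alpha") <- alpha
  n
}

# minimal chromatogram object around a hand-crafted wstar matrix
fake_chromatogram <- function(wstar, alpha = nrow(wstar)) {
  structure(
    list(wstar = wstar, raw = wstar, unsmoothed = wstar,
         counts = matrix(1L, nrow(wstar), ncol(wstar),
                         dimnames = dimnames(wstar)),
         contributors = NULL, env = NULL, abundance = NULL,
         env_range = tibble::tibble(dimension = colnames(wstar), min = 0, max = 1),
         params = list(alpha = as.integer(alpha), m = 1L, k = 100,
                       smooth_window = 1L, n_top_min = 1L),
         species = NULL, n_samples = 0L, n_dropped = 0L),
    class = "chromatogram"
  )
}
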