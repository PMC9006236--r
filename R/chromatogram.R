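#' Build a species chromatogram
#'
#' Projects the p-dimensional niche of a species onto an alpha x p matrix.
#' Each environmental dimension is standardized onto \[0, 1\], divided into
#' `alpha` equidistant categories, and each category is filled with the mean
#' of the top `k` percent abundance values of the samples it contains
#' (provided at least `m` samples are available). Columns are then smoothed
#' with a trailing moving average and rescaled so the best category of each
#' dimension scores 1. Missing categories (fewer than `m` samples, or lost to
#' smoothing) are `NA` and are drawn white.
#'
#' Rows of `data` with a missing value on any environmental dimension are
#' discarded before analysis (a message reports how many).
#'
#' @param data Sample table: a data frame with one non-negative `abundance`
#'   column; every other numeric column (except `lat`, `lon`, `date`, `time`)
#'   is an environmental dimension.
#' @param alpha Number of equidistant categories per gradient (default 50).
#' @param m Minimum samples per category for an abundance estimate
#'   (default 20).
#' @param k Percentage of highest abundance values averaged per category
#'   (default 5).
#' @param smooth_window Trailing moving-average window (default 2; 1 disables
#'   smoothing).
#' @param n_top_min Lower bound on the number of values averaged per category
#'   (default 1).
#' @param env_range Optional shared per-dimension (min, max) tibble from
#'   [shared_env_range()]; required whenever chromatograms of several species
#'   will be compared.
#' @param abundance_col Name of the abundance column.
#' @param species Optional species label stored on the object.
#' @return An object of class `chromatogram`; see [tidy.chromatogram()],
#'   [glance.chromatogram()], [autoplot.chromatogram()].
#' @examples
#' tb <- data.frame(abundance = c(1, 3, 2, 6), temp = c(1, 1, 6, 6))
#' chromatogram(tb, alpha = 4, m = 1, k = 100, smooth_window = 1)
#' @export
chromatogram <- function(data, alpha = 50L, m = 20L, k = 5, smooth_window = 2L,
                         n_top_min = 1L, env_range = NULL,
                         abundance_col = "abundance", species = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (!abundance_col %in% names(data)) {
    stop("no '", abundance_col, "' column in the sample table", call. = FALSE)
  }
  dims <- env_dim_names(data, abundance_col)
  p <- length(dims)

  keep <- stats::complete.cases(data[dims]) & !is.na(data[[abundance_col]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) with missing values discarded")
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no complete samples left", call. = FALSE)
  y <- data[[abundance_col]]
  if (any(y < 0)) stop("abundances must be non-negative", call. = FALSE)

  zstar <- standardize_env(data, env_range = env_range, abundance_col = abundance_col)
  env_range <- attr(zstar, "env_range")
  cats <- assign_categories(zstar, alpha)

  raw <- matrix(NA_real_, nrow = alpha, ncol = p, dimnames = list(NULL, dims))
  counts <- matrix(0L, nrow = alpha, ncol = p, dimnames = list(NULL, dims))
  contributors <- purrr::map(dims, function(d) vector("list", alpha))
  names(contributors) <- dims

  for (j in seq_len(p)) {
    cj <- cats[, j]
    for (i in seq_len(alpha)) {
      members <- which(cj == i)
      counts[i, j] <- length(members)
      if (length(members) < m) next
      vals <- y[members]
      n_top <- min(length(vals), max(n_top_min, ceiling(k / 100 * length(vals))))
      ord <- members[order(vals, decreasing = TRUE)[seq_len(n_top)]]
      contributors[[j]][[i]] <- ord
      raw[i, j] <- mean(vals[order(vals, decreasing = TRUE)[seq_len(n_top)]])
    }
  }

  smoothed <- apply(raw, 2, smooth_column, window = smooth_window)
  dim(smoothed) <- dim(raw)
  dimnames(smoothed) <- dimnames(raw)
  wstar <- standardize_abundance(smoothed)

  structure(
    list(
      wstar = wstar,
      raw = smoothed,
      unsmoothed = raw,
      counts = counts,
      contributors = contributors,
      env = data[dims],
      abundance = y,
      env_range = env_range,
      params = list(alpha = as.integer(alpha), m = as.integer(m), k = k,
                    smooth_window = as.integer(smooth_window),
                    n_top_min = as.integer(n_top_min)),
      species = species,
      n_samples = nrow(data),
      n_dropped = n_dropped
    ),
    class = "chromatogram"
  )
}

#' Build chromatograms for several species with shared standardization
#'
#' Convenience wrapper that pools the environmental ranges of all sample
#' tables (so that category i means the same conditions in every
#' chromatogram) and builds one chromatogram per species.
#'
#' @param tables Named list of sample tables.
#' @inheritParams chromatogram
#' @param ... Further arguments passed to [chromatogram()].
#' @return Named list of `chromatogram` objects.
#' @export
chromatograms <- function(tables, abundance_col = "abundance", ...) {
  stopifnot(is.list(tables), length(tables) >= 1)
  rng <- shared_env_range(tables, abundance_col)
  out <- purrr::imap(tables, function(tb, nm) {
    chromatogram(tb, env_range = rng, abundance_col = abundance_col,
                 species = if (is.character(nm)) nm else NULL, ...)
  })
  out
}

#' @export
print.chromatogram <- function(x, ...) {
  pr <- x$params
  cat("Species chromatogram", if (!is.null(x$species)) paste0("(", x$species, ")"),
      "\n")
  cat("  ", pr$alpha, " categories x ", ncol(x$wstar), " dimension(s): ",
      paste(colnames(x$wstar), collapse = ", "), "\n", sep = "")
  cat("  n = ", x$n_samples, " samples; m = ", pr$m, ", k = ", pr$k,
      "%, smoothing window = ", pr$smooth_window, "\n", sep = "")
  miss <- mean(is.na(x$wstar)) * 100
  cat(sprintf("  %.1f%% missing (white) categories\n", miss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chromatogram into a long tibble
#'
#' One row per (category, dimension) cell with the standardized abundance,
#' the raw (pre-standardization) abundance and the sample count.
#'
#' @param x A `chromatogram`.
#' @param ... Unused.
#' @return A tibble with columns `dimension`, `category`, `abundance`,
#'   `raw_abundance`, `n_samples`.
#' @export
tidy.chromatogram <- function(x, ...) {
  dims <- colnames(x$wstar)
  tidyr::expand_grid(dimension = dims, category = seq_len(nrow(x$wstar))) |>
    dplyr::mutate(
      abundance = purrr::map2_dbl(.data$category, .data$dimension,
                                  ~ x$wstar[.x, .y]),
      raw_abundance = purrr::map2_dbl(.data$category, .data$dimension,
                                      ~ x$raw[.x, .y]),
      n_samples = purrr::map2_int(.data$category, .data$dimension,
                                  ~ x$counts[.x, .y])
    )
}

#' One-row summary of a chromatogram
#'
#' @param x A `chromatogram`.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `p`, `n_samples`, `n_dropped`,
#'   `prop_missing`.
#' @export
glance.chromatogram <- function(x, ...) {
  tibble::tibble(
    alpha = x$params$alpha,
    p = ncol(x$wstar),
    n_samples = x$n_samples,
    n_dropped = x$n_dropped,
    prop_missing = mean(is.na(x$wstar))
  )
}
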