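#' Shared environmental range across several sample tables
#'
#' Computes the per-dimension minimum and maximum over the union of several
#' sample tables. When chromatograms of different species are to be compared,
#' all gradients must be standardized with the same (min, max) pair so that
#' category i means the same environmental conditions in every chromatogram.
#'
#' @param tables A list of sample tables (data frames with one `abundance`
#'   column and numeric environmental columns), or a single data frame.
#' @param abundance_col Name of the abundance column (excluded from ranges).
#' @return A tibble with columns `dimension`, `min`, `max`.
#' @examples
#' a <- data.frame(abundance = 1:2, temp = c(0, 10))
#' b <- data.frame(abundance = 1:2, temp = c(5, 20))
#' shared_env_range(list(a, b))
#' @export
shared_env_range <- function(tables, abundance_col = "abundance") {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  ranges <- purrr::map(tables, function(tb) {
    dims <- env_dim_names(tb, abundance_col)
    tibble::tibble(
      dimension = dims,
      min = purrr::map_dbl(dims, ~ min(tb[[.x]], na.rm = TRUE)),
      max = purrr::map_dbl(dims, ~ max(tb[[.x]], na.rm = TRUE))
    )
  })
  dims0 <- ranges[[1]]$dimension
  for (r in ranges) {
    if (!identical(sort(r$dimension), sort(dims0))) {
      stop("all tables must share the same environmental dimensions", call. = FALSE)
    }
  }
  dplyr::bind_rows(ranges) |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(min = min(.data$min), max = max(.data$max)) |>
    dplyr::arrange(match(.data$dimension, dims0))
}

# environmental column names: everything numeric except abundance/coords
env_dim_names <- function(data, abundance_col = "abundance") {
  reserved <- c(abundance_col, "lat", "lon", "date", "time")
  dims <- setdiff(names(data), reserved)
  dims <- dims[vapply(data[dims], is.numeric, logical(1))]
  if (length(dims) < 1) stop("no environmental dimensions found", call. = FALSE)
  dims
}

#' Standardize environmental values onto [0, 1]
#'
#' Rescales each environmental dimension linearly so that the gradient
#' minimum maps to 0 and the maximum to 1. When several species are compared,
#' pass a shared range (from [shared_env_range()]) so standardization is
#' performed simultaneously for all species.
#'
#' @param data A data frame whose numeric non-abundance columns are
#'   environmental dimensions.
#' @param env_range Optional tibble with columns `dimension`, `min`, `max`
#'   overriding the ranges computed from `data` itself.
#' @param abundance_col Name of the abundance column, if present.
#' @return A tibble of standardized values in \[0, 1\] (one column per
#'   dimension) with the ranges used attached as attribute `"env_range"`.
#' @examples
#' standardize_env(data.frame(abundance = c(1, 1, 1), temp = c(2, 4, 6)))
#' @export
standardize_env <- function(data, env_range = NULL, abundance_col = "abundance") {
  dims <- env_dim_names(data, abundance_col)
  if (is.null(env_range)) {
    env_range <- shared_env_range(list(data), abundance_col)
  }
  stopifnot(all(c("dimension", "min", "max") %in% names(env_range)))
  missing_dims <- setdiff(dims, env_range$dimension)
  if (length(missing_dims) > 0) {
    stop("env_range lacks dimension(s): ", paste(missing_dims, collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::map(dims, function(d) {
    r <- env_range[env_range$dimension == d, ]
    if (r$max <= r$min) {
      stop("constant dimension '", d, "': max equals min, cannot standardize",
           call. = FALSE)
    }
    (data[[d]] - r$min) / (r$max - r$min)
  })
  names(out) <- dims
  out <- tibble::as_tibble(out)
  attr(out, "env_range") <- env_range[match(dims, env_range$dimension), ]
  out
}

#' Assign standardized values to equidistant categories
#'
#' Divides the \[0, 1\] gradient into `alpha` equidistant categories. Bin i
#' covers \[(i-1)/alpha, i/alpha) half-open, with the final bin closed at 1,
#' so every value in \[0, 1\] maps to exactly one category.
#'
#' @param zstar Numeric vector, matrix or data frame of values in \[0, 1\].
#' @param alpha Integer number of categories (>= 2).
#' @return Integer categories in `1:alpha`, same shape as the input.
#' @examples
#' assign_categories(c(0, 0.5, 1), alpha = 50)
#' @export
assign_categories <- function(zstar, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 2, alpha == trunc(alpha))
  vals <- if (is.data.frame(zstar)) as.matrix(zstar) else zstar
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) {
    stop("standardized values outside [0, 1]; standardize with the pooled range first",
         call. = FALSE)
  }
  idx <- pmin(floor(vals * alpha) + 1L, as.integer(alpha))
  storage.mode(idx) <- "integer"
  idx
}

#' Maximal-abundance estimate for one category
#'
#' Mean of the top k percent of the abundance values falling in a category.
#' Averaging only the highest values accounts for samples whose abundance is
#' depressed by unsuitable conditions along *other* niche dimensions:
#' conditions can be suitable on the focal gradient yet hostile elsewhere.
#'
#' @param abundances Non-negative abundance values of the samples in the
#'   category.
#' @param k Percentage (0 < k <= 100) of highest values to average.
#' @param m Minimum number of samples required; fewer yields `NA`.
#' @param n_top_min Lower bound on the number of values averaged (default 1).
#' @return The mean of the top values, or `NA_real_` if fewer than `m`
#'   samples are available.
#' @examples
#' category_abundance(c(1, 2, 3, 4), k = 50, m = 1) # mean of top 2 -> 3.5
#' @export
category_abundance <- function(abundances, k, m, n_top_min = 1L) {
  stopifnot(k > 0, k <= 100, m >= 1, n_top_min >= 1)
  cnt <- length(abundances)
  if (cnt < m) return(NA_real_)
  n_top <- max(n_top_min, ceiling(k / 100 * cnt))
  n_top <- min(n_top, cnt)
  mean(sort(abundances, decreasing = TRUE)[seq_len(n_top)])
}

#' Trailing moving average along a gradient column
#'
#' Simple moving average over `window` consecutive categories, used to damp
#' category-to-category noise in the raw maximal abundances. The first
#' `window - 1` elements are copied unchanged; any window containing a
#' missing category yields a missing value (smoothing can therefore increase
#' the number of white categories).
#'
#' @param column Numeric vector (one chromatogram column), `NA` = missing.
#' @param window Integer window length (>= 1); 1 is the identity.
#' @return Smoothed vector of the same length.
#' @examples
#' smooth_column(c(1, 3, 5, 7), window = 2) # 1 2 4 6
#' @export
smooth_column <- function(column, window = 2L) {
  stopifnot(window >= 1, window == trunc(window))
  n <- length(column)
  if (window == 1 || n == 0) return(column)
  out <- column
  for (i in seq_len(n)) {
    if (i >= window) out[i] <- mean(column[(i - window + 1L):i])
  }
  out
}

#' Standardize chromatogram abundances per dimension
#'
#' Divides each column of the raw maximal-abundance matrix by its column
#' maximum so the best category of every dimension scores exactly 1.
#' Columns that are entirely missing or contain no positive value are left
#' missing with a warning.
#'
#' @param w Numeric matrix (alpha categories x p dimensions), `NA` = missing.
#' @return Matrix of the same shape with non-missing entries in \[0, 1\].
#' @examples
#' standardize_abundance(cbind(a = c(2, 4, NA)))
#' @export
standardize_abundance <- function(w) {
  w <- as.matrix(w)
  out <- w
  degenerate <- character(0)
  for (j in seq_len(ncol(w))) {
    col <- w[, j]
    mx <- suppressWarnings(max(col, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) {
      out[, j] <- NA_real_
      degenerate <- c(degenerate, colnames(w)[j] %||% as.character(j))
    } else {
      out[, j] <- col / mx
    }
  }
  if (length(degenerate) > 0) {
    warning("dimension(s) with no positive abundance left missing: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
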