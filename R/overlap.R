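#' Select niche categories and fill gaps (hyperrectangle assumption)
#'
#' Per dimension, the categories with standardized abundance at or above `T`
#' (strictly above when `T = 0`) define the lowest and highest selected
#' category; all categories in between are included regardless of their
#' value or missingness, assuming a unimodal, continuous niche. The niche on
#' each dimension is therefore a contiguous category interval, and the joint
#' niche a hyperrectangle on the category lattice.
#'
#' @param chrom A [chromatogram()].
#' @param T Standardized abundance threshold in \[0, 1\].
#' @return A tibble with one row per dimension: `dimension`, `lower`,
#'   `upper` (category indices, `NA` when nothing selected) and `width`
#'   (interval length in categories, 0 when empty). The category count
#'   `alpha` is attached as attribute `"alpha"`.
#' @examples
#' tb <- data.frame(abundance = c(1, 3, 2, 6), temp = c(1, 1, 6, 6))
#' ch <- chromatogram(tb, alpha = 4, m = 1, k = 100, smooth_window = 1)
#' select_and_fill(ch, T = 0)
#' @export
select_and_fill <- function(chrom, T = 0.25) {
  stopifnot(inherits(chrom, "chromatogram"), T >= 0, T <= 1)
  dims <- colnames(chrom$wstar)
  rows <- purrr::map(dims, function(d) {
    sel <- selected_categories(chrom$wstar[, d], T)
    if (length(sel) == 0) {
      tibble::tibble(dimension = d, lower = NA_integer_, upper = NA_integer_,
                     width = 0L)
    } else {
      tibble::tibble(dimension = d, lower = min(sel), upper = max(sel),
                     width = max(sel) - min(sel) + 1L)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- chrom$params$alpha
  class(out) <- c("selected_niche", class(out))
  out
}

#' Niche-overlap index D between two selected niches
#'
#' Symmetric hyperrectangle overlap: with per-dimension interval lengths
#' beta_i and gamma_i for the two species and theta_i the length of their
#' interval intersection, the niche volumes are V1 = prod(beta_i),
#' V2 = prod(gamma_i) and V12 = prod(theta_i), and
#' D = 100 * V12 / (V1 + V2 - V12), the percentage of the union volume that
#' the two species share. D = 100 iff the filled intervals are identical on
#' every dimension considered; D = 0 when they are disjoint on any one.
#'
#' @param niche1,niche2 Niches from [select_and_fill()], built with the same
#'   `alpha` and dimension set (shared standardization).
#' @param dims Optional subset of dimension names or indices (default: all).
#' @return D in percent. A species with an empty niche on some considered
#'   dimension has volume 0 and yields D = 0 with a warning.
#' @examples
#' n1 <- tibble::tibble(dimension = c("a", "b"), lower = c(1L, 1L),
#'                      upper = c(2L, 2L), width = c(2L, 2L))
#' n2 <- tibble::tibble(dimension = c("a", "b"), lower = c(2L, 1L),
#'                      upper = c(3L, 2L), width = c(2L, 2L))
#' index_d(n1, n2) # 100 * 2 / (4 + 4 - 2)
#' @export
index_d <- function(niche1, niche2, dims = NULL) {
  check_comparable(niche1, niche2)
  use <- resolve_subset(niche1$dimension, dims)
  d_from_intervals(
    niche1$lower[use], niche1$upper[use],
    niche2$lower[use], niche2$upper[use],
    warn = TRUE
  )
}

# core formula for D on category intervals; NA lower/upper = empty interval
d_from_intervals <- function(l1, u1, l2, u2, warn = FALSE) {
  b <- interval_width(l1, u1)
  g <- interval_width(l2, u2)
  v1 <- prod(b)
  v2 <- prod(g)
  if (v1 == 0 || v2 == 0) {
    if (warn) warning("degenerate niche (empty on some dimension): D set to 0",
                      call. = FALSE)
    return(0)
  }
  lo <- pmax(l1, l2)
  hi <- pmin(u1, u2)
  theta <- pmax(0, hi - lo + 1)
  v12 <- prod(theta)
  if (v12 == 0) return(0)
  100 * v12 / (v1 + v2 - v12)
}

interval_width <- function(l, u) {
  w <- u - l + 1L
  w[is.na(w)] <- 0L
  w
}

check_comparable <- function(n1, n2) {
  stopifnot(is.data.frame(n1), is.data.frame(n2))
  if (!identical(n1$dimension, n2$dimension)) {
    stop("niches have different dimension sets; rebuild with shared standardization",
         call. = FALSE)
  }
  a1 <- attr(n1, "alpha")
  a2 <- attr(n2, "alpha")
  if (!is.null(a1) && !is.null(a2) && a1 != a2) {
    stop("niches built with different numbers of categories (alpha)", call. = FALSE)
  }
  invisible(TRUE)
}

resolve_subset <- function(all_dims, dims) {
  if (is.null(dims)) return(seq_along(all_dims))
  if (is.character(dims)) {
    use <- match(dims, all_dims)
    if (anyNA(use)) stop("unknown dimension(s): ",
                         paste(dims[is.na(use)], collapse = ", "), call. = FALSE)
  } else {
    use <- as.integer(dims)
    if (any(use < 1 | use > length(all_dims))) {
      stop("dimension index out of range", call. = FALSE)
    }
  }
  if (length(use) == 0) stop("dimension subset must be non-empty", call. = FALSE)
  use
}

#' Pairwise niche overlap for a set of species
#'
#' Computes index D for every pair of chromatograms (which must share
#' standardization: same alpha, same dimensions, same pooled environmental
#' ranges).
#'
#' @param chroms Named list of [chromatogram()] objects.
#' @param T Standardized abundance threshold (default 0.25).
#' @param dims Optional dimension subset.
#' @return A tibble with one row per unordered pair (including self-pairs,
#'   for which D = 100 by construction): `species1`, `species2`, `d`.
#' @seealso [d_matrix()] for the symmetric matrix form.
#' @export
pairwise_d <- function(chroms, T = 0.25, dims = NULL) {
  stopifnot(is.list(chroms), length(chroms) >= 2)
  nms <- names(chroms) %||% paste0("sp", seq_along(chroms))
  if (is.null(names(chroms))) names(chroms) <- nms
  ranges <- purrr::map(chroms, "env_range")
  if (!all(purrr::map_lgl(ranges[-1], ~ isTRUE(all.equal(.x, ranges[[1]]))))) {
    warning("chromatograms were standardized with different environmental ranges; ",
            "categories are not comparable across species", call. = FALSE)
  }
  niches <- purrr::map(chroms, select_and_fill, T = T)
  pairs <- tidyr::expand_grid(i = seq_along(chroms), j = seq_along(chroms)) |>
    dplyr::filter(.data$i <= .data$j)
  pairs |>
    dplyr::mutate(
      species1 = nms[.data$i],
      species2 = nms[.data$j],
      d = purrr::map2_dbl(.data$i, .data$j, function(a, b) {
        if (a == b) return(100)
        index_d(niches[[a]], niches[[b]], dims = dims)
      })
    ) |>
    dplyr::select("species1", "species2", "d")
}

#' Symmetric D matrix from a pairwise overlap table
#'
#' @param pairs Tibble from [pairwise_d()].
#' @return A symmetric numeric matrix with 100 on the diagonal.
#' @export
d_matrix <- function(pairs) {
  nms <- unique(c(pairs$species1, pairs$species2))
  m <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$species1[r], pairs$species2[r]] <- pairs$d[r]
    m[pairs$species2[r], pairs$species1[r]] <- pairs$d[r]
  }
  diag(m) <- 100
  m
}

#' Scan all dimension subsets for the most discriminant combinations
#'
#' Computes, for every non-empty subset of environmental dimensions, the mean
#' pairwise index D over all species pairs, and flags per subset size the
#' subset minimizing that mean — the combination of variables that best
#' separates the species' niches. Adding a dimension can only shrink the
#' intersection-to-union ratio, so the per-size minima are non-increasing in
#' subset size.
#'
#' @param chroms Named list of [chromatogram()] objects (>= 2 species) with
#'   shared standardization.
#' @param T Standardized abundance threshold (default 0.25).
#' @param include_diagonal Include the self-overlap 100s in the mean
#'   (default `FALSE`: mean over the off-diagonal upper triangle only).
#' @return A tibble with one row per subset: `n_dims`, `dims` (dimension
#'   indices pasted with "+"), `dim_names`, `mean_d`, `is_min` (`TRUE` for
#'   the minimizing subset of its size; ties broken lexicographically by
#'   dimension index).
#' @export
combination_scan <- function(chroms, T = 0.25, include_diagonal = FALSE) {
  stopifnot(is.list(chroms), length(chroms) >= 2)
  niches <- purrr::map(chroms, select_and_fill, T = T)
  purrr::walk(niches[-1], check_comparable, n1 = niches[[1]])
  dims <- niches[[1]]$dimension
  p <- length(dims)
  if (p > 20) {
    stop("p = ", p, " dimensions would require ", 2^p - 1, " subsets; ",
         "pre-select at most 20 dimensions", call. = FALSE)
  }
  n_sp <- length(niches)
  pair_idx <- utils::combn(n_sp, 2)

  lowers <- purrr::map(niches, "lower")
  uppers <- purrr::map(niches, "upper")

  subset_rows <- purrr::map(seq_len(p), function(s) {
    combos <- utils::combn(p, s)
    purrr::map(seq_len(ncol(combos)), function(ci) {
      use <- combos[, ci]
      ds <- vapply(seq_len(ncol(pair_idx)), function(pi) {
        a <- pair_idx[1, pi]
        b <- pair_idx[2, pi]
        d_from_intervals(lowers[[a]][use], uppers[[a]][use],
                         lowers[[b]][use], uppers[[b]][use])
      }, numeric(1))
      if (include_diagonal) ds <- c(ds, rep(100, n_sp))
      name_label <- paste(dims[use], collapse = "+")
      tibble::tibble(
        n_dims = s,
        dims = paste(use, collapse = "+"),
        dim_names = name_label,
        mean_d = mean(ds)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(subset_rows))
  # lexicographic tie-break: rows are generated in lexicographic combn order,
  # so the first minimum per size is the winner
  out |>
    dplyr::group_by(.data$n_dims) |>
    dplyr::mutate(is_min = seq_along(.data$mean_d) == which.min(.data$mean_d)) |>
    dplyr::ungroup()
}

#' Best combination per subset size
#'
#' Filters a [combination_scan()] table down to the minimizing subset of each
#' size, mirroring the usual "most discriminant combinations" table layout.
#'
#' @param scan Tibble from [combination_scan()].
#' @return Tibble with one row per subset size.
#' @export
best_combinations <- function(scan) {
  dplyr::filter(scan, .data$is_min) |>
    dplyr::arrange(.data$n_dims)
}
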