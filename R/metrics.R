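#' Niche optimum along one dimension
#'
#' The optimum is the environmental value at which the species' abundance is
#' maximal. The category(ies) where the standardized chromatogram column
#' attains its maximum are located, and the optimum is the mean *raw*
#' environmental value of the samples whose abundances were averaged in
#' those categories (the top-k% contributors recorded before smoothing).
#' Ties across categories pool the contributors of all tied categories.
#'
#' @param chrom A [chromatogram()].
#' @param dim Dimension name or index.
#' @return The optimum, in raw environmental units.
#' @export
niche_optimum <- function(chrom, dim) {
  stopifnot(inherits(chrom, "chromatogram"))
  j <- resolve_dim(chrom, dim)
  col <- chrom$wstar[, j]
  if (all(is.na(col))) {
    stop("dimension '", colnames(chrom$wstar)[j],
         "' has no non-missing category", call. = FALSE)
  }
  mx <- max(col, na.rm = TRUE)
  best <- which(!is.na(col) & col == mx)
  # NA-propagating smoothing guarantees a non-missing smoothed cell has a
  # non-missing pre-smoothing cell, hence recorded contributors
  idx <- unlist(chrom$contributors[[j]][best])
  if (length(idx) == 0) {
    stop("no contributing samples recorded for the maximal category",
         call. = FALSE)
  }
  mean(chrom$env[[j]][idx])
}

#' Niche breadth along one dimension
#'
#' Percentage of a dimension's categories spanned by abundances at or above
#' threshold `T` (strictly above when `T = 0`, so that observed nil
#' abundance never counts as presence). With `span = "inclusive"` (default)
#' the numerator is the inclusive category count `Umax - Umin + 1`, which
#' yields exactly 100% for a full-span niche; `span = "printed"` uses the
#' difference `Umax - Umin`. The denominator is the number of categories
#' with a non-missing estimate. Breadth is capped at 100%.
#'
#' @param chrom A [chromatogram()].
#' @param dim Dimension name or index.
#' @param T Standardized abundance threshold in \[0, 1\] (default 0.25).
#' @param span `"inclusive"` or `"printed"` (see Details).
#' @return Breadth in percent (0-100). 0 when no category is selected.
#' @export
niche_breadth <- function(chrom, dim, T = 0.25, span = c("inclusive", "printed")) {
  stopifnot(inherits(chrom, "chromatogram"), T >= 0, T <= 1)
  span <- match.arg(span)
  j <- resolve_dim(chrom, dim)
  col <- chrom$wstar[, j]
  u_star <- sum(!is.na(col))
  if (u_star == 0) {
    stop("dimension '", colnames(chrom$wstar)[j],
         "' has no non-missing category", call. = FALSE)
  }
  sel <- selected_categories(col, T)
  if (length(sel) == 0) return(0)
  num <- if (span == "inclusive") diff(range(sel)) + 1 else diff(range(sel))
  min(100, num / u_star * 100)
}

# categories meeting the threshold; strict > when T = 0
selected_categories <- function(col, T) {
  if (T == 0) which(!is.na(col) & col > 0) else which(!is.na(col) & col >= T)
}

#' Average niche breadth over all dimensions
#'
#' @param breadths Numeric vector of per-dimension breadths (percent).
#' @return Their arithmetic mean.
#' @examples
#' mean_breadth(c(100, 0))
#' @export
mean_breadth <- function(breadths) {
  stopifnot(length(breadths) >= 1)
  mean(breadths)
}

#' Per-dimension niche summary
#'
#' Niche optimum (raw units) and breadth (percent) for every dimension of a
#' chromatogram. The average breadth over dimensions is attached as attribute
#' `"mean_breadth"` and can be recomputed with [mean_breadth()].
#'
#' @inheritParams niche_breadth
#' @return A tibble with columns `dimension`, `optimum`, `breadth`,
#'   `threshold`.
#' @export
niche_summary <- function(chrom, T = 0.25, span = c("inclusive", "printed")) {
  stopifnot(inherits(chrom, "chromatogram"))
  span <- match.arg(span)
  dims <- colnames(chrom$wstar)
  out <- tibble::tibble(
    dimension = dims,
    optimum = purrr::map_dbl(dims, ~ niche_optimum(chrom, .x)),
    breadth = purrr::map_dbl(dims, ~ niche_breadth(chrom, .x, T = T, span = span)),
    threshold = T
  )
  attr(out, "mean_breadth") <- mean_breadth(out$breadth)
  out
}

resolve_dim <- function(chrom, dim) {
  dims <- colnames(chrom$wstar)
  if (is.character(dim)) {
    j <- match(dim, dims)
    if (is.na(j)) stop("unknown dimension '", dim, "'", call. = FALSE)
  } else {
    j <- as.integer(dim)
    if (j < 1 || j > length(dims)) stop("dimension index out of range", call. = FALSE)
  }
  j
}
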