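#' Beta response function along an environmental gradient
#'
#' Classic unimodal skewed abundance response: the abundance rises from 0 at
#' `p_min`, peaks at exactly `c` at the optimum `p_opt`, and falls back to 0
#' at `p_max`; outside \[p_min, p_max\] the abundance is 0.
#'
#' A(p) = c * ((p_max - p)/(p_max - p_opt)) *
#'            ((p - p_min)/(p_opt - p_min))^((p_opt - p_min)/(p_max - p_opt))
#'
#' @param p Environmental values (vectorized).
#' @param c Maximal abundance (> 0).
#' @param p_min,p_opt,p_max Lower limit, optimum and upper limit of the
#'   response, with `p_min < p_opt < p_max`.
#' @return Abundances, same length as `p`.
#' @examples
#' beta_response(5, c = 1, p_min = 0, p_opt = 10, p_max = 20) # 0.75
#' @export
beta_response <- function(p, c, p_min, p_opt, p_max) {
  if (!(is.finite(c) && c > 0)) stop("c must be > 0", call. = FALSE)
  if (!(p_min < p_opt && p_opt < p_max)) {
    stop("need p_min < p_opt < p_max", call. = FALSE)
  }
  inside <- p > p_min & p < p_max
  a <- numeric(length(p))
  q <- (p_opt - p_min) / (p_max - p_opt)
  pi_ <- p[inside]
  a[inside] <- c * ((p_max - pi_) / (p_max - p_opt)) *
    ((pi_ - p_min) / (p_opt - p_min))^q
  a
}

#' Specification of one pseudo-species
#'
#' A pseudo-species has one beta response per environmental dimension; its
#' abundance in a sample is the sum of the per-dimension responses (additive
#' aggregation).
#'
#' @param p_min,p_opt,p_max Numeric vectors (one entry per dimension) with
#'   `p_min < p_opt < p_max` elementwise.
#' @param c Maximal abundance per dimension (recycled, default 1).
#' @param dim_names Optional dimension names.
#' @return A tibble with columns `dimension`, `c`, `p_min`, `p_opt`, `p_max`.
#' @export
pseudo_species_spec <- function(p_min, p_opt, p_max, c = 1,
                                dim_names = NULL) {
  n <- length(p_opt)
  stopifnot(length(p_min) == n, length(p_max) == n)
  if (!all(p_min < p_opt & p_opt < p_max)) {
    stop("need p_min < p_opt < p_max on every dimension", call. = FALSE)
  }
  c <- rep_len(c, n)
  if (any(c <= 0)) stop("c must be > 0", call. = FALSE)
  tibble::tibble(
    dimension = dim_names %||% paste0("env", seq_len(n)),
    c = c, p_min = p_min, p_opt = p_opt, p_max = p_max
  )
}

#' Default gradients for the pseudo-species experiment
#'
#' Three hypothetical environmental dimensions: `env1` running from 0 to 25,
#' `env2` from 0 to 40, and `env3` a *decreasing* gradient from 1 to 0
#' (orientation is irrelevant after standardization).
#'
#' @return A tibble with columns `dimension`, `from`, `to`.
#' @export
default_gradients <- function() {
  tibble::tibble(
    dimension = c("env1", "env2", "env3"),
    from = c(0, 0, 1),
    to = c(25, 40, 0)
  )
}

#' Default family of seven pseudo-species
#'
#' Seven documented specifications spanning the default gradients, chosen so
#' the family exercises the overlap analysis. Because per-dimension
#' abundances are *summed*, a pseudo-species is present wherever any one of
#' its responses is positive; supports are therefore aligned in quantile
#' position across the three gradients so that the intended niche relations
#' hold for the whole species: species 1 (low specialist, quantiles 0-0.4 on
#' every gradient) and species 2 (high specialist, quantiles 0.6-1) are
#' fully disjoint — their supports on dimension 1 are 0-10 vs 15-25; species
#' 5's support contains species 4's on every dimension with the same optima
#' and exactly doubled amplitude (p_max - p_min); species 3 is a broad
#' generalist; 6 and 7 are intermediate.
#'
#' @return A named list of seven [pseudo_species_spec()] tibbles.
#' @export
default_pseudo_species <- function() {
  d <- function(...) pseudo_species_spec(..., dim_names = default_gradients()$dimension)
  list(
    sp1 = d(p_min = c(0, 0, 0.60), p_opt = c(5, 8, 0.80), p_max = c(10, 16, 1.00)),
    sp2 = d(p_min = c(15, 24, 0.00), p_opt = c(20, 32, 0.20), p_max = c(25, 40, 0.40)),
    sp3 = d(p_min = c(0, 0, 0.00), p_opt = c(12.5, 20, 0.50), p_max = c(25, 40, 1.00)),
    sp4 = d(p_min = c(5, 8, 0.40), p_opt = c(10, 16, 0.60), p_max = c(15, 24, 0.80)),
    sp5 = d(p_min = c(0, 0, 0.20), p_opt = c(10, 16, 0.60), p_max = c(20, 32, 1.00)),
    sp6 = d(p_min = c(10, 16, 0.20), p_opt = c(15, 24, 0.40), p_max = c(20, 32, 0.60)),
    sp7 = d(p_min = c(2, 4, 0.50), p_opt = c(6, 10, 0.80), p_max = c(12, 18, 0.95))
  )
}

#' Generate pseudo-species sample tables
#'
#' Builds one sample table per specification: `n_samples` samples are placed
#' along each gradient (an even grid by default, or uniform random with a
#' seed), the beta response of each dimension is evaluated, and the
#' per-dimension abundances are summed (additive model). With
#' `duplicate = TRUE` every table is copied exactly, which is the standard
#' check that a method reports 100% overlap for two identical niches.
#'
#' @param specs List of [pseudo_species_spec()] tibbles (default:
#'   [default_pseudo_species()]).
#' @param n_samples Samples per species (default 100).
#' @param gradients Tibble with columns `dimension`, `from`, `to` (default:
#'   [default_gradients()]); `from > to` gives a decreasing gradient.
#' @param duplicate If `TRUE`, append an exact copy of every species
#'   (`sp<i>_dup`).
#' @param sampling `"grid"` (evenly spaced, deterministic) or `"random"`
#'   (uniform over each gradient).
#' @param seed Integer seed used when `sampling = "random"`.
#' @return A named list of sample tables (tibbles with `abundance` plus one
#'   column per dimension).
#' @examples
#' tabs <- generate_pseudo_species(n_samples = 50)
#' names(tabs)
#' @export
generate_pseudo_species <- function(specs = default_pseudo_species(),
                                    n_samples = 100L,
                                    gradients = default_gradients(),
                                    duplicate = FALSE,
                                    sampling = c("grid", "random"),
                                    seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(n_samples >= 1)
  if (sampling == "random" && !is.null(seed)) set.seed(seed)
  dims <- gradients$dimension

  env <- purrr::map(seq_len(nrow(gradients)), function(j) {
    if (sampling == "grid") {
      seq(gradients$from[j], gradients$to[j], length.out = n_samples)
    } else {
      stats::runif(n_samples, min(gradients$from[j], gradients$to[j]),
                   max(gradients$from[j], gradients$to[j]))
    }
  })
  names(env) <- dims
  env <- tibble::as_tibble(env)

  tabs <- purrr::map(specs, function(sp) {
    stopifnot(all(sp$dimension %in% dims))
    per_dim <- purrr::map(seq_len(nrow(sp)), function(r) {
      beta_response(env[[sp$dimension[r]]], c = sp$c[r], p_min = sp$p_min[r],
                    p_opt = sp$p_opt[r], p_max = sp$p_max[r])
    })
    dplyr::bind_cols(
      tibble::tibble(abundance = Reduce(`+`, per_dim)),
      env
    )
  })
  if (is.null(names(tabs))) names(tabs) <- paste0("sp", seq_along(tabs))
  if (duplicate) {
    dups <- tabs
    names(dups) <- paste0(names(tabs), "_dup")
    tabs <- c(tabs, dups)
  }
  tabs
}

#' Symmetrize an asymmetric range-box overlap
#'
#' Converts an asymmetric overlap report (volume of each niche plus the
#' portion of niche 1 covered by niche 2) into the symmetric percentage
#' D = 100 * (vol1 * port21) / (vol1 + vol2 - vol1 * port21), comparable to
#' [index_d()].
#'
#' @param vol1,vol2 Niche volumes (>= 0).
#' @param port21 Average portion of niche 1 covered by niche 2, in \[0, 1\].
#' @return Symmetric overlap in percent.
#' @examples
#' symmetrize_dynrb(2, 4, 0.5) # 20
#' @export
symmetrize_dynrb <- function(vol1, vol2, port21) {
  stopifnot(vol1 >= 0, vol2 >= 0, port21 >= 0, port21 <= 1)
  denom <- vol1 + vol2 - vol1 * port21
  if (any(denom <= 0)) stop("non-positive denominator: volumes too small",
                            call. = FALSE)
  100 * vol1 * port21 / denom
}
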