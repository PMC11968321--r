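## Pure decision functions implementing the disclosure rules. Each returns a
## filter_decision and holds no state; the node and the aggregate statistics
## call these at pre- and post-execution checkpoints.

# Boundary tolerance for fractional thresholds (ratio * N). Comparisons within
# this distance of the boundary are resolved in favour of blocking (fail safe).
.boundary_eps <- 1e-12

filter_decision <- function(allowed, rule = "", detail = "") {
  structure(list(allowed = allowed, rule = rule, detail = detail),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(if (x$allowed) "<filter: allowed>" else
        sprintf("<filter: blocked by %s (%s)>", x$rule, x$detail), "\n")
  invisible(x)
}

#' Contingency-table cell-count filter
#'
#' Blocks a table if any *non-empty* cell holds fewer than
#' `s$tab_threshold` observations. Empty (zero) cells never trigger the rule:
#' a zero count reveals only absence, whereas a small positive count points
#' at identifiable individuals. Tables of up to three dimensions are in
#' scope.
#'
#' @param counts Array (1 to 3 dimensional) of non-negative integer counts.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @examples
#' check_table(matrix(c(3, 5, 7, 2), 2), default_settings())  # blocked
#' check_table(matrix(c(0, 5, 7, 9), 2), default_settings())  # allowed
#' @export
check_table <- function(counts, s) {
  k <- if (is.null(dim(counts))) 1L else length(dim(counts))
  if (k > 3L) return(filter_decision(FALSE, "table_dims", "more than 3 dimensions"))
  cnt <- as.vector(counts)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    stop_sdc("BAD_ARGUMENT")
  }
  small <- cnt > 0 & cnt < s$tab_threshold
  if (any(small)) {
    filter_decision(FALSE, "nfilter.tab",
                    sprintf("%d non-empty cell(s) below %d", sum(small),
                            s$tab_threshold))
  } else filter_decision(TRUE)
}

#' Subset-size filter
#'
#' Blocks creation of a derived subset with fewer than `s$subset_threshold`
#' rows (empty subsets included).
#'
#' @param n Number of rows in the candidate subset.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_subset_size <- function(n, s) {
  if (!is_count(n)) stop_sdc("BAD_ARGUMENT")
  if (n < s$subset_threshold) {
    filter_decision(FALSE, "nfilter.subset", sprintf("subset of %d rows", n))
  } else filter_decision(TRUE)
}

#' Model-dimension filter
#'
#' Blocks a regression with more than `s$glm_ratio * N` unknown parameters on
#' a dataset of sample size `N`. Applied per site: a federated model must
#' pass at every site against that site's own `N`. The boundary is resolved
#' toward blocking within a small numerical tolerance.
#'
#' @param p Number of model parameters (including any intercept).
#' @param N Site sample size.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_glm_dimension <- function(p, N, s) {
  if (!is_pos_count(p) || !is_pos_count(N)) stop_sdc("BAD_ARGUMENT")
  if (p > s$glm_ratio * N - .boundary_eps) {
    filter_decision(FALSE, "nfilter.glm",
                    sprintf("p=%d exceeds %.4g * N=%d", p, s$glm_ratio, N))
  } else filter_decision(TRUE)
}

#' Category-levels filter
#'
#' Blocks the return of a categorical variable's unique levels when there are
#' more than `s$levels_density * N` of them (the variable is nearly an
#' identifier) or more than `s$levels_max` in absolute terms. Either bound
#' alone triggers.
#'
#' @param n_levels Number of unique levels.
#' @param N Length of the categorical vector.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_levels <- function(n_levels, N, s) {
  if (!is_count(n_levels) || !is_pos_count(N)) stop_sdc("BAD_ARGUMENT")
  if (n_levels > s$levels_density * N - .boundary_eps) {
    return(filter_decision(FALSE, "nfilter.levels.density",
                           sprintf("%d levels over %.4g * N=%d", n_levels,
                                   s$levels_density, N)))
  }
  if (n_levels > s$levels_max) {
    return(filter_decision(FALSE, "nfilter.levels.max",
                           sprintf("%d levels over max %d", n_levels,
                                   s$levels_max)))
  }
  filter_decision(TRUE)
}

#' k-nearest-neighbour size filter
#'
#' Blocks centroid obfuscation with a neighbourhood smaller than
#' `s$knn_min` (too small a neighbourhood barely displaces a point); a
#' neighbourhood larger than the number of points is infeasible.
#'
#' @param k Requested neighbourhood size (the point itself plus `k - 1`
#'   neighbours).
#' @param n Number of points available.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_knn <- function(k, n, s) {
  if (!is_pos_count(k) || !is_pos_count(n)) stop_sdc("BAD_ARGUMENT")
  if (k < s$knn_min) {
    filter_decision(FALSE, "nfilter.kNN", sprintf("k=%d below %d", k, s$knn_min))
  } else if (k > n) {
    filter_decision(FALSE, "nfilter.kNN",
                    sprintf("k=%d infeasible for n=%d points", k, n))
  } else filter_decision(TRUE)
}

#' Noise-variance filter
#'
#' Blocks Gaussian-noise obfuscation whose noise variance is less than
#' `s$noise_min_fraction` of the variable's own variance (too little noise
#' leaves values effectively un-obfuscated).
#'
#' @param f Requested noise variance as a fraction of the data variance.
#' @param s Disclosure settings.
#' @return A `filter_decision`.
#' @export
check_noise_fraction <- function(f, s) {
  if (!is_scalar(f, is.numeric) || f <= 0) stop_sdc("BAD_ARGUMENT")
  if (f < s$noise_min_fraction - .boundary_eps) {
    filter_decision(FALSE, "nfilter.noise",
                    sprintf("fraction %.4g below %.4g", f, s$noise_min_fraction))
  } else filter_decision(TRUE)
}
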