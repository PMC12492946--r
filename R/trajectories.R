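# internal: accept an rnam_fit or a 3x3 matrix as the genetic covariance
as_genetic_K <- function(K) {
  if (inherits(K, "rnam_fit")) K <- K$K
  if (!is.matrix(K) || nrow(K) != 3 || ncol(K) != 3) {
    stop("K must be a 3x3 genetic covariance over (intercept, slope, trait2)",
         call. = FALSE)
  }
  check_psd(K, "K")
  K
}

new_trajectory <- function(p_grid, values, quantity) {
  if (any(diff(p_grid) <= 0)) {
    stop("p_grid must be strictly increasing", call. = FALSE)
  }
  structure(tibble::tibble(p = p_grid, value = values, quantity = quantity),
            class = c("rn_trajectory", class(tibble::tibble())))
}

#' Total additive genetic variance of DFI along the gradient
#'
#' `Var(a1)(p) = var_a10 + p^2 var_a11 + 2 p cov_a10_a11`, the variance of
#' the total breeding value `a1 = a10 + p a11` at each grid point.
#'
#' @param K 3x3 genetic covariance over (intercept, slope, trait2), or an
#'   `rnam_fit`.
#' @param p_grid Strictly increasing gradient values in `[0, 1]`.
#' @return A trajectory tibble (`p`, `value`, `quantity`).
#' @export
#' @examples
#' total_genetic_variance(trait_K("AGE"), p_grid = c(0, 0.24, 1))
total_genetic_variance <- function(K, p_grid = seq(0, 1, length.out = 101)) {
  K <- as_genetic_K(K)
  v <- K[1, 1] + p_grid^2 * K[2, 2] + 2 * p_grid * K[1, 2]
  new_trajectory(p_grid, v, "total_genetic_variance")
}

#' Genetic correlation of DFI with the companion trait along the gradient
#'
#' `r(a1, a2)(p) = (cov_a10_a2 + p cov_a11_a2) /
#'   sqrt(Var(a1)(p) var_a2)`; at `p = 0` this is the intercept--trait
#' correlation `r(a10, a2)`.
#'
#' @inheritParams total_genetic_variance
#' @return A trajectory tibble.
#' @export
correlation_dfi_trait <- function(K, p_grid = seq(0, 1, length.out = 101)) {
  K <- as_genetic_K(K)
  va1 <- K[1, 1] + p_grid^2 * K[2, 2] + 2 * p_grid * K[1, 2]
  if (any(va1 <= 0) || K[3, 3] <= 0) {
    stop("zero variance along the grid; correlation undefined", call. = FALSE)
  }
  r <- (K[1, 3] + p_grid * K[2, 3]) / sqrt(va1 * K[3, 3])
  new_trajectory(p_grid, r, "correlation_dfi_trait")
}

#' Genetic correlation of the DFI slope with the companion trait
#'
#' The scalar `r(a11, a2) = cov_a11_a2 / sqrt(var_a11 var_a2)`: the
#' association between environmental sensitivity and the trait.
#'
#' @inheritParams total_genetic_variance
#' @return A single correlation.
#' @export
#' @examples
#' correlation_slope_trait(trait_K("AGE"))
correlation_slope_trait <- function(K) {
  K <- as_genetic_K(K)
  if (K[2, 2] <= 0 || K[3, 3] <= 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  K[2, 3] / sqrt(K[2, 2] * K[3, 3])
}

#' Genetic correlation of total DFI breeding value with its slope
#'
#' `r(a1, a11)(p) = (cov_a10_a11 + p var_a11) /
#'   sqrt(Var(a1)(p) var_a11)`. It crosses zero exactly at the
#' insensitivity point `p* = -cov_a10_a11 / var_a11`.
#'
#' @inheritParams total_genetic_variance
#' @return A trajectory tibble.
#' @export
correlation_total_slope <- function(K, p_grid = seq(0, 1, length.out = 101)) {
  K <- as_genetic_K(K)
  va1 <- K[1, 1] + p_grid^2 * K[2, 2] + 2 * p_grid * K[1, 2]
  if (any(va1 <= 0) || K[2, 2] <= 0) {
    stop("zero variance along the grid; correlation undefined", call. = FALSE)
  }
  r <- (K[1, 2] + p_grid * K[2, 2]) / sqrt(va1 * K[2, 2])
  new_trajectory(p_grid, r, "correlation_total_slope")
}

#' Environmental insensitivity point
#'
#' The gradient value `p* = -cov_a10_a11 / var_a11` at which intercept and
#' slope of DFI are genetically uncorrelated and the total genetic variance
#' is minimal; selection at `p*` is not expected to change environmental
#' sensitivity. Returned unclipped, with attribute `in_range` flagging
#' whether it falls inside `[0, 1]`.
#'
#' @inheritParams total_genetic_variance
#' @return A scalar with attribute `in_range`.
#' @export
#' @examples
#' insensitivity_point(trait_K("AGE"))
insensitivity_point <- function(K) {
  K <- as_genetic_K(K)
  if (K[2, 2] <= 0) stop("zero slope variance; p* undefined", call. = FALSE)
  p <- -K[1, 2] / K[2, 2]
  attr(p, "in_range") <- p >= 0 && p <= 1
  p
}

#' Gradient summary of one fitted trait pair
#'
#' Bundles every gradient-dependent quantity: the three trajectories, the
#' slope--trait correlation, the insensitivity point and the minimum total
#' genetic variance.
#'
#' @inheritParams total_genetic_variance
#' @return A list with `trajectories` (one long tibble), `r_slope_trait`,
#'   `p_star`, `min_genetic_variance`.
#' @export
gradient_summary <- function(K, p_grid = seq(0, 1, length.out = 101)) {
  K <- as_genetic_K(K)
  traj <- dplyr::bind_rows(
    total_genetic_variance(K, p_grid),
    correlation_dfi_trait(K, p_grid),
    correlation_total_slope(K, p_grid))
  ps <- as.numeric(insensitivity_point(K))
  list(trajectories = traj,
       r_slope_trait = correlation_slope_trait(K),
       p_star = ps,
       min_genetic_variance = K[1, 1] + ps^2 * K[2, 2] + 2 * ps * K[1, 2])
}
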