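#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a mixture fit
#'
#' @param x A `cv_mixture` object.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `mean`, `sd`.
#' @export
tidy.cv_mixture <- function(x, ...) {
  tibble::tibble(component = c("low_cv", "high_cv"),
                 weight = x$weights, mean = x$means, sd = x$sds)
}

#' @rdname tidy.cv_mixture
#' @export
glance.cv_mixture <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = length(x$values),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a REML fit
#'
#' Long table of every estimated (co)variance component.
#'
#' @param x An `rnam_fit` object.
#' @param ... Unused.
#' @return Tibble with `component`, `structure` (genetic / permanent /
#'   residual) and `estimate`.
#' @export
tidy.rnam_fit <- function(x, ...) {
  lab <- function(M, prefix) {
    nm <- rownames(M)
    idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
    tibble::tibble(
      component = ifelse(idx[, 1] == idx[, 2],
                         paste0("var_", prefix, nm[idx[, 1]]),
                         paste0("cov_", prefix, nm[idx[, 2]], "_",
                                prefix, nm[idx[, 1]])),
      structure = if (prefix == "a_") "genetic" else "permanent",
      estimate = M[idx])
  }
  dplyr::bind_rows(
    lab(x$K, "a_"), lab(x$T, "pe_"),
    tibble::tibble(component = c("var_e1", "var_e2"),
                   structure = "residual", estimate = unname(x$Q)))
}

#' @rdname tidy.rnam_fit
#' @export
glance.rnam_fit <- function(x, ...) {
  tibble::tibble(model = x$model, trait = x$trait, loglik = x$loglik,
                 minus2loglik = x$minus2loglik,
                 n_dfi = unname(x$data_signature["n1"]),
                 n_trait = unname(x$data_signature["n2"]),
                 n_iter = x$n_iter, converged = x$converged)
}

#' @rdname tidy.rnam_fit
#' @param data Unused (present for the generic).
#' @export
augment.rnam_fit <- function(x, data = NULL, ...) {
  g <- tidyr::pivot_wider(x$solutions$genetic, names_from = "effect",
                          values_from = "value")
  p <- tidyr::pivot_wider(x$solutions$permanent, names_from = "effect",
                          values_from = "value")
  dplyr::left_join(g, p, by = "animal_id")
}

#' Tidy a REML ratio test
#'
#' @param x A `remlrt` object.
#' @param ... Unused.
#' @return One-row tibble: `m2ll_am`, `m2ll_rnam`, `chi2`, `p_value`.
#' @export
tidy.remlrt <- function(x, ...) {
  tibble::tibble(m2ll_am = x$m2ll_am, m2ll_rnam = x$m2ll_rnam,
                 chi2 = x$chi2, p_value = x$p_value)
}
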