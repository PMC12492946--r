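# ---- log-Cholesky parameterization of a covariance matrix --------------
# theta holds the lower triangle of L (K = L L') column-wise with the
# diagonal entries log-transformed, so every theta maps to a PD matrix.
ltri_index <- function(k) which(lower.tri(diag(k), diag = TRUE))

pack_cov <- function(M) {
  L <- t(chol(M + diag(1e-10 * mean(diag(M)), nrow(M))))
  theta <- L[ltri_index(nrow(M))]
  dpos <- diag_positions(nrow(M))
  theta[dpos] <- log(theta[dpos])
  theta
}

diag_positions <- function(k) {
  # positions of L[i,i] within the column-wise lower-triangle vector
  cumsum(c(1, if (k > 1) k - seq_len(k - 1) + 1))[seq_len(k)]
}

unpack_cov <- function(theta, k) {
  L <- matrix(0, k, k)
  L[ltri_index(k)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

# number of free parameters of a k x k covariance
n_cov_par <- function(k) k * (k + 1) / 2

# ---- REML fitting ------------------------------------------------------

#' Fit the bivariate (reaction-norm) animal model by REML
#'
#' Maximizes the restricted log-likelihood over the variance components by
#' quasi-Newton (L-BFGS-B) search on log-Cholesky factors of the genetic
#' covariance `K` and permanent-environmental covariance `T` and on the log
#' residual variances, so every iterate is positive definite by
#' construction. Each likelihood evaluation assembles and factorizes the
#' sparse mixed-model equations (see [restricted_loglik()]). Convergence is
#' declared when the relative improvement of the restricted likelihood
#' between iterations falls below `tol` and the optimizer reports success.
#'
#' @param frame A [build_model_frame()] object.
#' @param relationship_inv Sparse genetic-kernel inverse (pedigree `A^-1`
#'   or single-step `H^-1`) with animal ids as dimnames.
#' @param init Optional list with starting `K`, `T` (matrices) and `Q`
#'   (length-2 vector); defaults to moment-based heuristics.
#' @param model `"rnam"` for the reaction-norm model (3x3 `K`, `T`) or
#'   `"am"` for the plain animal model without slope terms (2x2).
#' @param tol Relative-improvement convergence tolerance on the restricted
#'   likelihood.
#' @param max_iter Maximum optimizer iterations.
#' @param verbose Print optimizer progress.
#' @return An object of class `rnam_fit`: estimates `K`, `T`, `Q`, the
#'   restricted log-likelihood `loglik` and `minus2loglik`, `converged`,
#'   `n_iter`, `boundary` flags per variance, `pe2_flatness` (the
#'   `-2 logLik` increase when a quarter of the trait-2
#'   permanent-environmental variance is shifted into the trait-2 residual;
#'   near zero means that split is not identified and should not be
#'   over-interpreted), and `solutions` (tibbles of fixed-effect estimates
#'   and per-animal BLUPs of the genetic and permanent-environmental
#'   effects).
#' @export
#' @examples
#' sim <- simulate_population(n_batches = 3, animals_per_batch = 8,
#'                            days_per_batch = 10, seed = 3)
#' frame <- build_model_frame(
#'   sim$dfi, sim$traits,
#'   dplyr::rename(sim$calendar, p = true_p))
#' fit <- reml_fit(frame, pedigree_Ainv(sim$pedigree), max_iter = 50)
#' glance(fit)
reml_fit <- function(frame, relationship_inv, init = NULL,
                     model = c("rnam", "am"), tol = 1e-8, max_iter = 500,
                     verbose = FALSE) {
  model <- match.arg(model)
  parts <- mme_parts(frame, relationship_inv, model)
  k <- parts$k
  vy1 <- stats::var(frame$y1); vy2 <- stats::var(frame$y2)
  if (is.null(init)) {
    gK <- if (k == 3) c(0.2 * vy1, 0.2 * vy1, 0.4 * vy2) else
      c(0.25 * vy1, 0.4 * vy2)
    gT <- if (k == 3) c(0.15 * vy1, 0.15 * vy1, 0.25 * vy2) else
      c(0.2 * vy1, 0.25 * vy2)
    init <- list(K = diag(gK, k), T = diag(gT, k),
                 Q = c(0.5 * vy1, 0.35 * vy2))
  }
  check_psd(init$K, "init$K"); check_psd(init$T, "init$T")
  theta0 <- c(pack_cov(init$K), pack_cov(init$T), log(init$Q))
  nK <- n_cov_par(k)
  split_theta <- function(theta) {
    list(K = unpack_cov(theta[1:nK], k),
         T = unpack_cov(theta[nK + 1:nK], k),
         Q = exp(theta[2 * nK + 1:2]))
  }
  # bounds: keep log-diagonals within a wide but finite band around the
  # data scale so near-boundary variances stay numerically benign
  dposK <- diag_positions(k)
  lower <- rep(-Inf, length(theta0)); upper <- rep(Inf, length(theta0))
  scale_sd <- sqrt(c(diag(init$K), diag(init$T)))
  dpos_all <- c(dposK, nK + dposK)
  lower[dpos_all] <- log(scale_sd * 1e-4)
  upper[dpos_all] <- log(scale_sd * 1e3)
  off <- setdiff(seq_len(2 * nK), dpos_all)
  lower[off] <- -1e3 * max(scale_sd); upper[off] <- 1e3 * max(scale_sd)
  lower[2 * nK + 1:2] <- log(c(vy1, vy2) * 1e-6)
  upper[2 * nK + 1:2] <- log(c(vy1, vy2) * 1e3)

  fn <- function(theta) {
    pars <- split_theta(theta)
    mme_eval(parts, pars$K, pars$T, pars$Q)$m2ll
  }
  opt <- stats::optim(theta0, fn, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter,
                                     factr = max(tol / .Machine$double.eps, 10),
                                     trace = if (verbose) 1 else 0))
  pars <- split_theta(opt$par)
  # relative-change check at the optimum (finite-difference neighbourhood)
  ev <- mme_eval(parts, pars$K, pars$T, pars$Q, solutions = TRUE)
  boundary <- c(diag(pars$K), diag(pars$T)) <= (scale_sd * 1e-4)^2 * 1.01

  # profile flatness of the pe2/e2 split: with one record per animal for
  # trait 2, sigma2_pe2 and sigma2_e2 are separated only through the
  # cross-trait pe covariances; report how much -2logLik worsens when a
  # quarter of sigma2_pe2 is shifted into sigma2_e2 (small = flat profile,
  # do not over-interpret the split)
  pe2_flatness <- NA_real_
  ti <- k  # trait-2 index in T
  delta <- 0.25 * pars$T[ti, ti]
  T_alt <- pars$T; T_alt[ti, ti] <- T_alt[ti, ti] - delta
  if (delta > 0 && min(eigen(T_alt, symmetric = TRUE,
                             only.values = TRUE)$values) > 0) {
    Q_alt <- pars$Q; Q_alt[2] <- Q_alt[2] + delta
    alt <- mme_eval(parts, pars$K, T_alt, Q_alt)
    if (alt$m2ll < 1e12) pe2_flatness <- alt$m2ll - ev$m2ll
  }

  dimnames(pars$K) <- dimnames(pars$T) <-
    if (k == 3) list(c("intercept", "slope", "trait2"),
                     c("intercept", "slope", "trait2"))
    else list(c("dfi", "trait2"), c("dfi", "trait2"))

  sol <- ev$sol
  pf <- parts$p_fixed
  fixed <- tibble::tibble(term = parts$fixed_names,
                          estimate = sol[seq_len(pf)])
  eff_names <- if (k == 3) c("a10", "a11", "a2") else c("a1", "a2")
  pe_names <- if (k == 3) c("pe10", "pe11", "pe2") else c("pe1", "pe2")
  gen <- tibble::tibble(
    animal_id = rep(parts$gen_ids, k),
    effect = rep(eff_names, each = parts$nA),
    value = sol[pf + seq_len(k * parts$nA)])
  pe <- tibble::tibble(
    animal_id = rep(parts$pe_ids, k),
    effect = rep(pe_names, each = parts$nP),
    value = sol[pf + k * parts$nA + seq_len(k * parts$nP)])

  structure(list(
    K = pars$K, T = pars$T, Q = stats::setNames(pars$Q, c("var_e1", "var_e2")),
    loglik = -0.5 * ev$m2ll, minus2loglik = ev$m2ll,
    n_iter = unname(opt$counts[1]), converged = opt$convergence == 0,
    message = opt$message, boundary = boundary,
    pe2_flatness = pe2_flatness, model = model,
    trait = frame$trait,
    data_signature = c(n1 = parts$n1, n2 = parts$n2,
                       s1 = sum(frame$y1), s2 = sum(frame$y2)),
    solutions = list(fixed = fixed, genetic = gen, permanent = pe)),
    class = "rnam_fit")
}

#' Fit the plain animal model (no reaction norm)
#'
#' The null model of the REML ratio test: identical to [reml_fit()] with
#' the genetic and permanent-environmental slope terms removed, so `K` and
#' `T` collapse to 2x2 over (DFI, trait2).
#'
#' @inheritParams reml_fit
#' @return An `rnam_fit` object with `model = "am"`.
#' @export
fit_animal_model <- function(frame, relationship_inv, init = NULL,
                             tol = 1e-8, max_iter = 500, verbose = FALSE) {
  reml_fit(frame, relationship_inv, init = init, model = "am",
           tol = tol, max_iter = max_iter, verbose = verbose)
}

#' @export
print.rnam_fit <- function(x, ...) {
  cat("<rnam_fit>", if (x$model == "rnam") "reaction-norm animal model"
      else "animal model", "for DFI +", x$trait, "\n")
  cat("  -2 logLik:", round(x$minus2loglik, 2),
      " converged:", x$converged, " evals:", x$n_iter, "\n")
  cat("K:\n"); print(round(x$K, 4))
  cat("T:\n"); print(round(x$T, 4))
  cat("Q:", round(x$Q, 4), "\n")
  invisible(x)
}

# survival function of the boundary null: 0.5 chi2_5 + 0.5 chi2_7
mixture_chisq_p <- function(x, df_pair = c(5, 7), weights = c(0.5, 0.5)) {
  weights[1] * stats::pchisq(x, df_pair[1], lower.tail = FALSE) +
    weights[2] * stats::pchisq(x, df_pair[2], lower.tail = FALSE)
}

#' REML ratio test of the reaction norm
#'
#' Compares the reaction-norm model against the plain animal model fitted
#' to the same data: `chi2 = (-2 logLik AM) - (-2 logLik RNAM)`. Because
#' the null pins slope variances to the boundary of the parameter space,
#' significance is evaluated against the mixture
#' `0.5 chi2_5 + 0.5 chi2_7`. A slightly negative statistic (numerical
#' noise on nested fits) is clamped to zero.
#'
#' @param fit_rnam,fit_am `rnam_fit` objects from [reml_fit()] and
#'   [fit_animal_model()] on the same model frame.
#' @return An object of class `remlrt`: `chi2`, `p_value`, `df_pair`,
#'   `weights`, `m2ll_am`, `m2ll_rnam`.
#' @export
remlrt <- function(fit_rnam, fit_am) {
  stopifnot(inherits(fit_rnam, "rnam_fit"), inherits(fit_am, "rnam_fit"))
  if (fit_rnam$model != "rnam" || fit_am$model != "am") {
    stop("arguments must be a reaction-norm fit and an animal-model fit",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(fit_rnam$data_signature, fit_am$data_signature))) {
    stop("fits come from different model frames", call. = FALSE)
  }
  remlrt_arithmetic(fit_am$minus2loglik, fit_rnam$minus2loglik)
}

#' REML ratio test from -2 log-likelihood values
#'
#' The arithmetic of [remlrt()] applied directly to reported
#' `-2 logLik` values (e.g. from a published model-comparison table):
#' `chi2 = m2ll_am - m2ll_rnam`, with the boundary-mixture p-value
#' `0.5 P(chi2_5 > x) + 0.5 P(chi2_7 > x)`. Vectorized.
#'
#' @param m2ll_am,m2ll_rnam `-2` restricted log-likelihoods of the null
#'   (animal model) and the reaction-norm model.
#' @return For scalars, a `remlrt` object; for vectors, a tibble with
#'   `chi2` and `p_value`.
#' @export
#' @examples
#' remlrt_arithmetic(881941.77, 868811.53)
remlrt_arithmetic <- function(m2ll_am, m2ll_rnam) {
  chi2 <- m2ll_am - m2ll_rnam
  if (any(chi2 < -1e-3)) {
    warning("RNAM fit worse than AM by more than numerical tolerance")
  }
  chi2 <- pmax(chi2, 0)
  p <- mixture_chisq_p(chi2)
  if (length(chi2) > 1) {
    return(tibble::tibble(chi2 = chi2, p_value = p))
  }
  structure(list(chi2 = chi2, p_value = p, df_pair = c(5, 7),
                 weights = c(0.5, 0.5),
                 m2ll_am = m2ll_am, m2ll_rnam = m2ll_rnam),
            class = "remlrt")
}

#' @export
print.remlrt <- function(x, ...) {
  cat("<remlrt> chi2 =", round(x$chi2, 2), " df mixture (5, 7), p =",
      format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}
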