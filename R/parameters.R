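#' Default true parameters for the synthetic population
#'
#' Bundles every quantity the generator needs: the 3x3 additive-genetic
#' covariance `K` and permanent-environmental covariance `T` over
#' (intercept, slope, trait2), the diagonal residual variances `Q`
#' (feed intake, trait2), trait means, the two-component mixture of the
#' day-level log coefficient of variation (CV) of daily feed intake (DFI),
#' and the prevalence of challenge ("high CV") days.
#'
#' Defaults reproduce the DFI--AGE analysis of a Piétrain sire line shipped
#' in [reference_components()]: genetic intercept/slope variances 0.036 and
#' 0.087 with covariance -0.021, trait2 (age at 100 kg) variance 34.773, and
#' residual variances 0.175 and 12.420. Mean DFI is 2.36 kg/day and mean AGE
#' 135.1 days. Mixture defaults (means -1.828 and -1.128 on the log-CV
#' scale, both sds 0.15, prevalence 0.3) are calibrated so that (i) the two
#' components are separated by about 4.7 pooled standard deviations, giving a
#' clearly bimodal day-level CV distribution, (ii) implied CVs stay within
#' the empirically observed 0.10--1.31 range, and (iii) the
#' prevalence-weighted mean day-level residual variance equals `sigma2_e1`,
#' so the residual variance remains the REML estimand under the
#' heterogeneous-day generator (see the methods vignette).
#'
#' @param trait Name of the companion single-record trait. Only used as a
#'   label; covariances always follow the DFI--AGE defaults unless
#'   overridden.
#' @param K,T 3x3 symmetric positive-semidefinite covariance matrices over
#'   (intercept, slope, trait2) for additive-genetic and
#'   permanent-environmental effects.
#' @param Q Length-2 vector of residual variances `(sigma2_e1, sigma2_e2)`.
#' @param mu Length-2 vector of trait means `(DFI kg/day, trait2 units)`.
#' @param mixture_means,mixture_sds,mixture_weights Two-component Gaussian
#'   mixture of the day-level log CV; components are stored with means
#'   ascending and weights must sum to 1. `mixture_weights` doubles as
#'   (1 - prevalence, prevalence) of challenge days.
#' @param challenge_prevalence Probability that a batch-day is a challenge
#'   ("high CV") day.
#' @return An object of class `rn_parameters` (a named list).
#' @export
#' @examples
#' pars <- default_parameters()
#' pars$K
default_parameters <- function(trait = "AGE",
                               K = NULL, T = NULL, Q = NULL, mu = NULL,
                               mixture_means = c(-1.828, -1.128),
                               mixture_sds = c(0.15, 0.15),
                               mixture_weights = NULL,
                               challenge_prevalence = 0.3) {
  if (is.null(K)) {
    K <- matrix(c(0.036, -0.021, -0.918,
                  -0.021, 0.087, 0.254,
                  -0.918, 0.254, 34.773), 3, 3)
  }
  if (is.null(T)) {
    T <- matrix(c(0.030, -0.004, -0.836,
                  -0.004, 0.122, -0.776,
                  -0.836, -0.776, 30.422), 3, 3)
  }
  if (is.null(Q)) Q <- c(0.175, 12.420)
  if (is.null(mu)) mu <- c(2.36, 135.10)
  if (is.null(mixture_weights)) {
    mixture_weights <- c(1 - challenge_prevalence, challenge_prevalence)
  }
  dimnames(K) <- dimnames(T) <- list(c("intercept", "slope", "trait2"),
                                     c("intercept", "slope", "trait2"))
  stopifnot(length(Q) == 2, all(Q > 0), length(mu) == 2,
            length(mixture_means) == 2, length(mixture_sds) == 2,
            all(mixture_sds > 0),
            abs(sum(mixture_weights) - 1) < 1e-8,
            challenge_prevalence >= 0, challenge_prevalence <= 1)
  if (mixture_means[1] > mixture_means[2]) {
    mixture_means <- rev(mixture_means)
    mixture_sds <- rev(mixture_sds)
    mixture_weights <- rev(mixture_weights)
  }
  check_psd(K, "K")
  check_psd(T, "T")
  structure(list(
    trait = trait, K = K, T = T, Q = Q, mu = mu,
    mixture = tibble::tibble(
      component = c("low_cv", "high_cv"),
      weight = mixture_weights,
      mean = mixture_means,
      sd = mixture_sds),
    challenge_prevalence = challenge_prevalence
  ), class = "rn_parameters")
}

#' @export
print.rn_parameters <- function(x, ...) {
  cat("<rn_parameters> trait2 =", x$trait, "\n")
  cat("K (genetic):\n"); print(round(x$K, 4))
  cat("T (permanent environmental):\n"); print(round(x$T, 4))
  cat("Q (residual):", x$Q, "   means:", x$mu, "\n")
  cat("log-CV mixture: means", x$mixture$mean, " sds", x$mixture$sd,
      " prevalence", x$challenge_prevalence, "\n")
  invisible(x)
}

# stop unless a symmetric matrix is PSD (tiny negative eigenvalues tolerated)
check_psd <- function(M, name, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-7)) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(name, " is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reference reaction-norm estimates for a Piétrain sire line
#'
#' A built-in table of published-scale REML estimates from bivariate
#' reaction-norm analyses of daily feed intake (DFI) paired with eight
#' production traits (AGE, BFT, LMT, FCR, LMP, PH24, DLP, BHW) in a Piétrain
#' male line: the six genetic (co)variances over (intercept, slope, trait2),
#' the six permanent-environmental (co)variances, the two residual variances,
#' the reported intercept--trait and slope--trait genetic correlations, and
#' the -2 restricted log-likelihoods of the reaction-norm and plain animal
#' models used by the REML ratio test. Used by examples, consistency checks
#' and [trait_K()].
#'
#' @return A tibble with one row per companion trait.
#' @export
#' @examples
#' reference_components()
reference_components <- function() {
  tibble::tribble(
    ~trait, ~var_a10, ~var_a11, ~var_a2, ~cov_a10_a11, ~cov_a10_a2, ~cov_a11_a2,
    ~var_pe10, ~var_pe11, ~var_pe2, ~cov_pe10_pe11, ~cov_pe10_pe2, ~cov_pe11_pe2,
    ~var_e1, ~var_e2, ~r_a10_a2, ~r_a11_a2, ~m2ll_am, ~m2ll_rnam,
    "AGE", 0.036, 0.087, 34.773, -0.021, -0.918, 0.254,
      0.030, 0.122, 30.422, -0.004, -0.836, -0.776,
      0.175, 12.420, -0.817, 0.146, 881941.77, 868811.53,
    "BFT", 0.037, 0.089, 0.483, -0.013, 0.063, 0.007,
      0.024, 0.125, 0.127, -0.016, 0.009, 0.003,
      0.175, 0.381, 0.470, 0.035, 559758.28, 546479.09,
    "LMT", 0.033, 0.093, 10.389, -0.018, 0.048, -0.282,
      0.026, 0.123, 5.662, -0.014, -0.027, 0.206,
      0.175, 7.708, 0.081, -0.286, 796114.77, 782843.03,
    "FCR", 0.043, 0.088, 0.018, -0.013, 0.025, 0.002,
      0.023, 0.122, 0.004, -0.015, 0.009, 0.002,
      0.175, 0.009, 0.901, 0.052, 356623.06, 343434.96,
    "LMP", 0.034, 0.089, 1.329, -0.016, -0.068, -0.024,
      0.025, 0.124, 0.945, -0.014, -0.064, 0.081,
      0.175, 1.878, -0.318, -0.069, 524503.18, 511215.86,
    "PH24", 0.033, 0.089, 0.006, -0.017, 0.003, -0.003,
      0.026, 0.125, 0.006, -0.014, 0.001, 0.003,
      0.175, 0.012, 0.177, -0.130, 346118.14, 332845.72,
    "DLP", 0.033, 0.089, 1.143, -0.017, -0.042, 0.019,
      0.026, 0.125, 1.846, -0.014, -0.012, 0.002,
      0.175, 0.0003, -0.214, 0.059, 455067.78, 441798.60,
    "BHW", 0.034, 0.089, 0.040, -0.017, -0.012, 0.009,
      0.026, 0.124, 0.017, -0.014, 0.006, -0.007,
      0.175, 0.097, -0.315, 0.149, 384808.03, 371538.62
  )
}

#' Genetic covariance block for one reference trait pair
#'
#' Extracts the 3x3 genetic (co)variance matrix over
#' (intercept, slope, trait2) for one DFI--trait pair from
#' [reference_components()], in the form the trajectory functions expect.
#'
#' @param trait One of "AGE", "BFT", "LMT", "FCR", "LMP", "PH24", "DLP", "BHW".
#' @return A 3x3 symmetric matrix with dimnames
#'   `(intercept, slope, trait2)`.
#' @export
#' @examples
#' trait_K("AGE")
trait_K <- function(trait) {
  ref <- reference_components()
  row <- ref[ref$trait == trait, ]
  if (nrow(row) != 1) {
    stop("unknown trait '", trait, "'; see reference_components()$trait",
         call. = FALSE)
  }
  K <- matrix(c(row$var_a10, row$cov_a10_a11, row$cov_a10_a2,
                row$cov_a10_a11, row$var_a11, row$cov_a11_a2,
                row$cov_a10_a2, row$cov_a11_a2, row$var_a2), 3, 3)
  dimnames(K) <- list(c("intercept", "slope", "trait2"),
                      c("intercept", "slope", "trait2"))
  K
}

#' Default fixed effects per trait
#'
#' The fixed-effect sets used in the national evaluation context this
#' package emulates: DFI is adjusted for pen, batch and farm; single-record
#' traits for sex, batch and farm, with weight at test, carcass weight,
#' slaughter date and sample weight added for the traits that need them.
#' The synthetic generator only simulates `sex`, `pen` and `batch` (one
#' farm), so [build_model_frame()] silently keeps the intersection of this
#' list with the columns present in the data.
#'
#' @param trait Companion trait name (see [reference_components()]).
#' @return A list with elements `dfi` and `trait`, each a character vector
#'   of effect names.
#' @export
default_fixed_effects <- function(trait = "AGE") {
  tab <- list(
    AGE  = c("sex", "batch", "farm"),
    BFT  = c("sex", "batch", "farm", "weight_control"),
    LMT  = c("sex", "batch", "farm", "weight_control"),
    FCR  = c("pen", "batch", "farm", "weight_control"),
    LMP  = c("sex", "batch", "farm", "carcass_weight"),
    PH24 = c("sex", "batch", "farm", "carcass_weight", "slaughter_date"),
    DLP  = c("sex", "batch", "farm", "weight_control", "slaughter_date",
             "sample_weight"),
    BHW  = c("sex", "batch", "farm", "weight_control")
  )
  if (!trait %in% names(tab)) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  list(dfi = c("pen", "batch", "farm"), trait = tab[[trait]])
}
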