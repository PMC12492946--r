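#' Day-level coefficient of variation of daily feed intake
#'
#' Computes, within each batch-day, the coefficient of variation of daily
#' feed intake across the animals of the batch (sample standard deviation
#' with the n-1 denominator divided by the day mean) and its natural log.
#' Days with fewer than `min_animals` records, a non-positive mean, or zero
#' dispersion (log CV undefined) are excluded; the exclusion tally is
#' attached as the `"excluded"` attribute and reported as a message.
#'
#' @param records Tibble of DFI records with `animal_id`, `batch_id`,
#'   `day_index`, `dfi`.
#' @param min_animals Minimum animals per batch-day (>= 2).
#' @return A tibble `batch_id`, `day_index`, `n_animals`, `cv`, `log_cv`.
#' @export
#' @examples
#' recs <- tibble::tibble(animal_id = 1:2, batch_id = 1, day_index = 1,
#'                        dfi = c(1, 3))
#' daily_log_cv(recs, min_animals = 2)
daily_log_cv <- function(records, min_animals = 5) {
  if (min_animals < 2) stop("min_animals must be >= 2", call. = FALSE)
  day <- dplyr::summarise(
    dplyr::group_by(records, .data$batch_id, .data$day_index),
    n_animals = dplyr::n(),
    mean_dfi = mean(.data$dfi),
    sd_dfi = stats::sd(.data$dfi),
    .groups = "drop")
  reason <- dplyr::case_when(
    day$n_animals < min_animals ~ "too_few_animals",
    day$mean_dfi <= 0 ~ "nonpositive_mean",
    day$sd_dfi <= 0 ~ "zero_dispersion",
    TRUE ~ "kept")
  excluded <- table(reason[reason != "kept"])
  keep <- day[reason == "kept", ]
  if (nrow(keep) == 0) {
    stop("all batch-days excluded; nothing to analyse", call. = FALSE)
  }
  if (length(excluded)) {
    message("daily_log_cv: excluded ", sum(excluded), " batch-day(s) [",
            paste(names(excluded), excluded, sep = "=", collapse = ", "), "]")
  }
  out <- tibble::tibble(
    batch_id = keep$batch_id, day_index = keep$day_index,
    n_animals = keep$n_animals,
    cv = keep$sd_dfi / keep$mean_dfi,
    log_cv = log(keep$sd_dfi / keep$mean_dfi))
  attr(out, "excluded") <- excluded
  out
}

# internal: log-likelihood of a 2-component normal mixture
mixture_loglik <- function(x, w, m, s) {
  sum(log(w[1] * stats::dnorm(x, m[1], s[1]) +
            w[2] * stats::dnorm(x, m[2], s[2])))
}

# internal: one EM run from a given start; returns NULL on collapse
em_run <- function(x, w, m, s, tol, max_iter, sd_floor) {
  n <- length(x)
  ll <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, m[1], s[1])
    d2 <- w[2] * stats::dnorm(x, m[2], s[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    r2 <- d2 / tot
    ll_new <- sum(log(tot))
    converged <- is.finite(ll) && (ll_new - ll) < tol
    ll <- ll_new
    trace <- c(trace, ll)
    if (converged) break
    n2 <- sum(r2); n1 <- n - n2
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    m <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    s <- sqrt(c(sum((1 - r2) * (x - m[1])^2) / n1,
                sum(r2 * (x - m[2])^2) / n2))
    if (any(s < sd_floor)) return(NULL)
    w <- c(n1, n2) / n
  }
  list(w = w, m = m, s = s, loglik = ll, trace = trace, n_iter = it,
       converged = it < max_iter, resp2 = r2)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Univariate two-component normal mixture fitted by
#' Expectation--Maximization with multiple restarts (the best restricted
#' log-likelihood is kept). The first start splits the data at the median;
#' further starts split at random quantiles with perturbed component means.
#' Components are stored with means ascending, so component 2 is always the
#' higher-mean ("high CV") component. A floor on the component standard
#' deviations guards against variance collapse; a start that collapses is
#' discarded and the fit errors only if every start collapses.
#'
#' @param values Numeric observations (>= 10), typically day-level log CVs.
#' @param tol EM stops when the log-likelihood improves by less than `tol`.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Number of restarts.
#' @param seed Optional integer seed for the random restarts.
#' @param sd_floor Lower bound on component standard deviations.
#' @return An object of class `cv_mixture`: `weights`, `means`, `sds`,
#'   `responsibilities` (n x 2, rows sum to 1), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `values`.
#' @export
fit_gaussian_mixture <- function(values, tol = 1e-8, max_iter = 1000,
                                 n_starts = 10, seed = NULL,
                                 sd_floor = 1e-4) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    q <- if (k == 1) 0.5 else stats::runif(1, 0.2, 0.8)
    cut <- stats::quantile(x, q)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(lo) < 2 || length(hi) < 2) next
    m <- c(mean(lo), mean(hi))
    s <- pmax(c(stats::sd(lo), stats::sd(hi)), 10 * sd_floor)
    if (k > 1) m <- m + stats::rnorm(2, 0, stats::sd(x) / 4)
    run <- em_run(x, c(q, 1 - q), m, s, tol, max_iter, sd_floor)
    if (!is.null(run) && (is.null(best) || run$loglik > best$loglik)) {
      best <- run
    }
  }
  if (is.null(best)) {
    stop("degenerate fit: every EM start collapsed", call. = FALSE)
  }
  if (best$m[1] > best$m[2]) {  # enforce ascending means
    best$m <- rev(best$m); best$s <- rev(best$s); best$w <- rev(best$w)
    best$resp2 <- 1 - best$resp2
  }
  structure(list(
    weights = best$w, means = best$m, sds = best$s,
    responsibilities = cbind(low_cv = 1 - best$resp2, high_cv = best$resp2),
    loglik = best$loglik, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged, values = x),
    class = "cv_mixture")
}

#' @export
print.cv_mixture <- function(x, ...) {
  cat("<cv_mixture> 2-component Gaussian mixture, n =", length(x$values),
      "\n  weights:", round(x$weights, 3),
      "\n  means:  ", round(x$means, 3),
      "\n  sds:    ", round(x$sds, 3),
      "\n  loglik:", round(x$loglik, 3), " iters:", x$n_iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Posterior challenge probability per batch-day
#'
#' The environmental descriptor: for each retained batch-day, the posterior
#' probability that its log CV belongs to the higher-mean ("high CV")
#' mixture component,
#' `p = w2 phi(x; m2, s2) / (w1 phi(x; m1, s1) + w2 phi(x; m2, s2))`.
#'
#' @param fit A converged [fit_gaussian_mixture()] object.
#' @param day_cv Output of [daily_log_cv()].
#' @return A tibble `batch_id`, `day_index`, `log_cv`, `p` with `p` in
#'   `[0, 1]`.
#' @export
posterior_challenge_probability <- function(fit, day_cv) {
  stopifnot(inherits(fit, "cv_mixture"))
  if (!isTRUE(fit$converged)) {
    stop("mixture fit did not converge", call. = FALSE)
  }
  x <- day_cv$log_cv
  d1 <- fit$weights[1] * stats::dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(x, fit$means[2], fit$sds[2])
  p <- ifelse(d1 + d2 > 0, d2 / (d1 + d2),
              as.numeric(x > mean(fit$means)))
  tibble::tibble(batch_id = day_cv$batch_id, day_index = day_cv$day_index,
                 log_cv = x, p = pmin(pmax(p, 0), 1))
}

#' Parametric bootstrap test for the presence of two mixture components
#'
#' Likelihood-ratio statistic `2 * (loglik(2-component EM) - loglik(single
#' Gaussian MLE))`, with its null distribution obtained by refitting both
#' models on `n_bootstrap` datasets simulated from the single-Gaussian MLE.
#' The p-value is `(1 + #{boot >= observed}) / (n_bootstrap + 1)`.
#'
#' @param values Numeric observations.
#' @param n_bootstrap Number of bootstrap replicates (>= 99).
#' @param seed Integer seed.
#' @param n_starts,tol,max_iter EM settings per fit, applied identically to
#'   the observed data and every bootstrap replicate (lighter than the
#'   [fit_gaussian_mixture()] defaults to keep the bootstrap affordable).
#' @return A list with `statistic`, `p_value`, `n_bootstrap`,
#'   `boot_statistics`.
#' @export
bootstrap_component_test <- function(values, n_bootstrap = 199, seed = 1,
                                     n_starts = 4, tol = 1e-6,
                                     max_iter = 300) {
  if (n_bootstrap < 99) stop("n_bootstrap must be >= 99", call. = FALSE)
  x <- values[is.finite(values)]
  n <- length(x)
  lrt_stat <- function(z, sd_seed) {
    mu <- mean(z); sig <- sqrt(mean((z - mu)^2))  # single-Gaussian MLE
    ll1 <- sum(stats::dnorm(z, mu, sig, log = TRUE))
    fit2 <- fit_gaussian_mixture(z, tol = tol, max_iter = max_iter,
                                 n_starts = n_starts, seed = sd_seed)
    max(0, 2 * (fit2$loglik - ll1))
  }
  set.seed(seed)
  observed <- lrt_stat(x, sd_seed = seed)
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  boot <- numeric(n_bootstrap)
  set.seed(seed + 1L)
  for (b in seq_len(n_bootstrap)) {
    stat <- NULL
    for (try in 1:5) {  # redraw on EM failure, bounded retries
      z <- stats::rnorm(n, mu, sig)
      stat <- tryCatch(lrt_stat(z, sd_seed = NULL), error = function(e) NULL)
      if (!is.null(stat)) break
    }
    if (is.null(stat)) {
      stop("EM failed repeatedly inside the bootstrap", call. = FALSE)
    }
    boot[b] <- stat
  }
  list(statistic = observed,
       p_value = (1 + sum(boot >= observed)) / (n_bootstrap + 1),
       n_bootstrap = n_bootstrap, boot_statistics = boot)
}

#' Estimate the environmental descriptor from raw feed-intake records
#'
#' One-call wrapper: [daily_log_cv()], then [fit_gaussian_mixture()] pooled
#' over all batches, then [posterior_challenge_probability()].
#'
#' @inheritParams daily_log_cv
#' @inheritParams fit_gaussian_mixture
#' @return A list with `day_cv`, `fit` (`cv_mixture`) and `descriptor`
#'   (tibble with the per-day challenge probability `p`).
#' @export
#' @examples
#' sim <- simulate_population(n_batches = 3, animals_per_batch = 10,
#'                            days_per_batch = 20, seed = 2)
#' est <- estimate_descriptor(sim$dfi, seed = 2)
#' head(est$descriptor)
estimate_descriptor <- function(records, min_animals = 5, n_starts = 10,
                                seed = NULL) {
  day_cv <- daily_log_cv(records, min_animals = min_animals)
  fit <- fit_gaussian_mixture(day_cv$log_cv, n_starts = n_starts, seed = seed)
  list(day_cv = day_cv, fit = fit,
       descriptor = posterior_challenge_probability(fit, day_cv))
}
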