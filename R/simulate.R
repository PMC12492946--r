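#' Simulate the challenge calendar of a batch structure
#'
#' Each batch-day independently is a challenge ("high CV") day with
#' probability `challenge_prevalence`. The day then receives a target log
#' coefficient of variation (CV) of daily feed intake drawn from the
#' corresponding mixture component, and `true_p`, the Bayes posterior
#' probability that the day belongs to the higher-mean component given its
#' target log CV under the generating mixture. `true_p` is the ground truth
#' against which the estimated environmental descriptor is judged.
#'
#' @param n_batches,days_per_batch Calendar dimensions.
#' @param params An [default_parameters()] object (mixture must have two
#'   components with distinct means).
#' @param seed Integer seed.
#' @return A tibble with `batch_id`, `day_index`, `challenge_state` (0/1),
#'   `target_log_cv` and `true_p`.
#' @export
simulate_environment <- function(n_batches, days_per_batch,
                                 params = default_parameters(), seed = 1) {
  mix <- params$mixture
  if (nrow(mix) != 2 || abs(diff(mix$mean)) < 1e-12) {
    stop("mixture must have exactly two components with distinct means",
         call. = FALSE)
  }
  set.seed(seed)
  n <- n_batches * days_per_batch
  state <- stats::rbinom(n, 1L, params$challenge_prevalence)
  target <- stats::rnorm(n, mix$mean[state + 1L], mix$sd[state + 1L])
  dens <- cbind(mix$weight[1] * stats::dnorm(target, mix$mean[1], mix$sd[1]),
                mix$weight[2] * stats::dnorm(target, mix$mean[2], mix$sd[2]))
  tibble::tibble(
    batch_id = rep(seq_len(n_batches), each = days_per_batch),
    day_index = rep(seq_len(days_per_batch), n_batches),
    challenge_state = state,
    target_log_cv = target,
    true_p = dens[, 2] / rowSums(dens))
}

#' Assign animals to batches and pens
#'
#' Splits the given animals evenly over `n_batches` contiguous batches and,
#' within each batch, over pens of about `pen_size` animals.
#'
#' @param animal_ids Vector of animal ids to assign.
#' @param n_batches Number of batches.
#' @param pen_size Target pen size (animals per feeder).
#' @return A tibble with `animal_id`, `batch_id`, `pen`.
#' @export
assign_batches <- function(animal_ids, n_batches, pen_size = 13) {
  n <- length(animal_ids)
  batch <- rep(seq_len(n_batches), length.out = n)
  batch <- sort(batch)
  out <- tibble::tibble(animal_id = animal_ids, batch_id = batch)
  out <- dplyr::group_by(out, .data$batch_id)
  out <- dplyr::mutate(out, pen = paste0(
    .data$batch_id, "_", (dplyr::row_number() - 1L) %/% pen_size + 1L))
  dplyr::ungroup(out)
}

# internal: symmetric square root for sampling from a PSD covariance
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# internal: between-animal variance of a DFI record at covariate p,
# excluding the day-level residual (genetic + permanent env + pen)
reaction_norm_variance <- function(params, p, pen_sd) {
  K <- params$K; T <- params$T
  K[1, 1] + p^2 * K[2, 2] + 2 * p * K[1, 2] +
    T[1, 1] + p^2 * T[2, 2] + 2 * p * T[1, 2] + pen_sd^2
}

#' Simulate daily feed intake and single-record trait phenotypes
#'
#' Draws joint breeding values `(a10, a11, a2)` with covariance `K %x% A`
#' (pedigree relationship as the genetic kernel), permanent-environmental
#' triples i.i.d. with covariance `T`, and builds, for every animal and
#' every recorded day of its batch,
#' `DFI = mu1 + batch + pen + a10 + p * a11 + pe10 + p * pe11 + e1`,
#' where `p` is the day's true challenge probability from the calendar; the
#' companion trait is `mu2 + sex + batch + a2 + pe2 + e2`, once per animal.
#'
#' With `heterogeneous_residual = TRUE` (default) the day-level residual
#' variance is scaled so the expected between-animal variance of the day
#' matches the day's target CV from the calendar, which makes the day-level
#' log CV of the generated records follow the generating mixture (the
#' signature the environmental descriptor estimates). The mixture defaults
#' are calibrated so the prevalence-weighted mean day residual variance
#' equals `sigma2_e1`, keeping the residual variance the REML estimand.
#' With `heterogeneous_residual = FALSE` the residual is homoscedastic
#' `N(0, sigma2_e1)` exactly.
#'
#' @param pedigree Pedigree tibble; breeding values are drawn for all its
#'   animals.
#' @param calendar Output of [simulate_environment()].
#' @param params [default_parameters()] object.
#' @param assignment Tibble `animal_id`, `batch_id` (and optionally `pen`)
#'   giving the phenotyped animals; every `batch_id` must be in the
#'   calendar.
#' @param seed Integer seed.
#' @param heterogeneous_residual Realize day-level CV targets (see above).
#' @param batch_sd,pen_sd,sex_effect,batch_sd_trait Magnitudes of the
#'   simulated fixed effects: batch and pen effects on DFI (kg/day), the
#'   male-minus-female contrast and batch effects on the companion trait
#'   (trait units).
#' @return A list of class `rn_simulation` with elements `dfi` (tibble:
#'   `animal_id`, `batch_id`, `pen`, `day_index`, `dfi`), `traits` (tibble:
#'   `animal_id`, `trait`, `value`, `sex`, `batch_id`, `pen`), `pedigree`,
#'   `calendar`, `assignment`, `true_values` (breeding values and permanent
#'   environmental effects per animal) and `params`.
#' @export
simulate_phenotypes <- function(pedigree, calendar, params, assignment,
                                seed = 1, heterogeneous_residual = TRUE,
                                batch_sd = 0.10, pen_sd = 0.05,
                                sex_effect = 0.5, batch_sd_trait = NULL) {
  check_psd(params$K, "K"); check_psd(params$T, "T")
  if (!all(assignment$batch_id %in% calendar$batch_id)) {
    stop("every assigned batch must appear in the calendar", call. = FALSE)
  }
  if (!all(assignment$animal_id %in% pedigree$animal_id)) {
    stop("every assigned animal must appear in the pedigree", call. = FALSE)
  }
  if (anyDuplicated(assignment$animal_id)) {
    stop("animals must belong to exactly one batch", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(batch_sd_trait)) batch_sd_trait <- 0.1 * sqrt(params$K[3, 3])
  if (!"pen" %in% names(assignment)) {
    assignment$pen <- paste0(assignment$batch_id, "_1")
  }

  # joint breeding values over the whole pedigree: vec ~ N(0, K %x% A)
  A <- pedigree_A(pedigree)
  n <- nrow(A)
  LA <- t(chol(A + diag(1e-10, n)))
  avals <- LA %*% matrix(stats::rnorm(n * 3), n, 3) %*% t(psd_sqrt(params$K))
  colnames(avals) <- c("a10", "a11", "a2")

  idx <- match(assignment$animal_id, pedigree$animal_id)
  nP <- nrow(assignment)
  pe <- matrix(stats::rnorm(nP * 3), nP, 3) %*% t(psd_sqrt(params$T))
  colnames(pe) <- c("pe10", "pe11", "pe2")

  batches <- sort(unique(calendar$batch_id))
  beff_dfi <- stats::setNames(stats::rnorm(length(batches), 0, batch_sd),
                              batches)
  beff_tr <- stats::setNames(stats::rnorm(length(batches), 0, batch_sd_trait),
                             batches)
  pens <- sort(unique(assignment$pen))
  peff <- stats::setNames(stats::rnorm(length(pens), 0, pen_sd), pens)
  sex <- sample(c("M", "F"), nP, replace = TRUE)

  # one DFI record per assigned animal per calendar day of its batch
  recs <- dplyr::inner_join(assignment, calendar, by = "batch_id",
                            relationship = "many-to-many")
  ai <- match(recs$animal_id, assignment$animal_id)
  p <- recs$true_p
  mu_day <- params$mu[1] + beff_dfi[as.character(recs$batch_id)]
  genetic <- avals[idx[ai], "a10"] + p * avals[idx[ai], "a11"]
  permenv <- pe[ai, "pe10"] + p * pe[ai, "pe11"]
  if (heterogeneous_residual) {
    v_target <- (exp(recs$target_log_cv) * mu_day)^2
    v_re <- reaction_norm_variance(params, p, pen_sd)
    sd_day <- sqrt(pmax(v_target - v_re, 1e-3))
  } else {
    sd_day <- sqrt(params$Q[1])
  }
  dfi <- mu_day + peff[recs$pen] + genetic + permenv +
    stats::rnorm(nrow(recs), 0, sd_day)
  dfi_tbl <- tibble::tibble(
    animal_id = recs$animal_id, batch_id = recs$batch_id, pen = recs$pen,
    day_index = recs$day_index, dfi = as.numeric(dfi))

  trait_val <- params$mu[2] + ifelse(sex == "M", sex_effect / 2,
                                     -sex_effect / 2) +
    beff_tr[as.character(assignment$batch_id)] +
    avals[idx, "a2"] + pe[, "pe2"] +
    stats::rnorm(nP, 0, sqrt(params$Q[2]))
  traits <- tibble::tibble(
    animal_id = assignment$animal_id, trait = params$trait,
    value = as.numeric(trait_val), sex = sex,
    batch_id = assignment$batch_id, pen = assignment$pen)

  true_values <- tibble::tibble(
    animal_id = pedigree$animal_id,
    a10 = avals[, 1], a11 = avals[, 2], a2 = avals[, 3])
  true_values <- dplyr::left_join(
    true_values,
    tibble::tibble(animal_id = assignment$animal_id,
                   pe10 = pe[, 1], pe11 = pe[, 2], pe2 = pe[, 3]),
    by = "animal_id")

  structure(list(dfi = dfi_tbl, traits = traits, pedigree = pedigree,
                 calendar = calendar, assignment = assignment,
                 true_values = true_values, params = params),
            class = "rn_simulation")
}

#' @export
print.rn_simulation <- function(x, ...) {
  cat("<rn_simulation>", nrow(x$dfi), "DFI records on",
      nrow(x$assignment), "animals in",
      length(unique(x$assignment$batch_id)), "batches;",
      nrow(x$traits), params_trait_label(x$params), "records\n")
  invisible(x)
}

params_trait_label <- function(params) params$trait

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [assign_batches()] (phenotyping the final generation),
#' [simulate_environment()] and [simulate_phenotypes()].
#'
#' @param n_batches,animals_per_batch,days_per_batch Study dimensions.
#' @param n_founders Founder count of the two-generation pedigree backbone;
#'   defaults to half the number of phenotyped animals.
#' @param params [default_parameters()] object.
#' @param seed Integer seed controlling every stage.
#' @param ... Passed to [simulate_phenotypes()].
#' @return An `rn_simulation` list; see [simulate_phenotypes()].
#' @export
#' @examples
#' sim <- simulate_population(n_batches = 2, animals_per_batch = 8,
#'                            days_per_batch = 5, seed = 1)
#' sim$dfi
simulate_population <- function(n_batches, animals_per_batch, days_per_batch,
                                n_founders = NULL,
                                params = default_parameters(), seed = 1, ...) {
  n_pheno <- n_batches * animals_per_batch
  if (is.null(n_founders)) n_founders <- max(4, ceiling(n_pheno / 2))
  # enough matings so the final generation covers the phenotyped animals
  off <- ceiling(n_pheno / max(1, floor(n_founders / 2)))
  ped <- simulate_pedigree(n_founders, n_generations = 1,
                           offspring_per_mating = max(2, off), seed = seed)
  last <- ped$animal_id[ped$generation == max(ped$generation)]
  pheno <- sort(sample(last, n_pheno))
  assignment <- assign_batches(pheno, n_batches)
  calendar <- simulate_environment(n_batches, days_per_batch, params,
                                   seed = seed + 1L)
  simulate_phenotypes(ped, calendar, params, assignment,
                      seed = seed + 2L, ...)
}

#' Derive production traits from test-station measurements
#'
#' Applies the standard French evaluation formulas: average daily gain
#' `ADG = (W_final - W_initial) / (age_final - age_initial)`; age at 100 kg
#' `AGE = age_initial + (100 - W_final) / ADG`; ultrasound backfat and loin
#' muscle thickness adjusted to 100 kg live weight via their regression
#' slopes on weight; and lean meat percentage
#' `LMP = 60.12 - 0.487 G3 - 0.133 G4 + 0.111 M3 + 0.036 M4` from the four
#' carcass fat/muscle depth measurements (mm).
#'
#' All arguments are vectorized; the result is exactly linear in each
#' measurement input.
#'
#' @param age_initial,age_final Ages (days) at start and end of test.
#' @param W_initial,W_final Live weights (kg) at start and end of test.
#' @param BFT_test,LMT_test Ultrasound backfat / loin muscle depth (mm) at
#'   test weight.
#' @param beta_BFT,beta_LMT Regression slopes of backfat / loin depth on
#'   live weight (mm/kg).
#' @param G3,G4,M3,M4 Carcass fat (G) and muscle (M) depth measurements (mm).
#' @return A tibble with columns `ADG`, `AGE`, `BFT`, `LMT`, `LMP`.
#' @export
#' @examples
#' derive_production_traits(70, 30, 100, 140, BFT_test = 8, LMT_test = 70)
derive_production_traits <- function(age_initial, W_initial, W_final,
                                     age_final, BFT_test = NA, LMT_test = NA,
                                     beta_BFT = 0.06, beta_LMT = 0.45,
                                     G3 = NA, G4 = NA, M3 = NA, M4 = NA) {
  if (any(age_final <= age_initial)) {
    stop("age_final must exceed age_initial", call. = FALSE)
  }
  if (any(W_final <= W_initial)) {
    stop("W_final must exceed W_initial", call. = FALSE)
  }
  ADG <- (W_final - W_initial) / (age_final - age_initial)
  if (any(ADG == 0)) stop("zero ADG: AGE undefined", call. = FALSE)
  AGE <- age_initial + (100 - W_final) / ADG
  BFT <- BFT_test + beta_BFT * (100 - W_final)
  LMT <- LMT_test + beta_LMT * (100 - W_final)
  LMP <- 60.12 - 0.487 * G3 - 0.133 * G4 + 0.111 * M3 + 0.036 * M4
  tibble::tibble(ADG = ADG, AGE = AGE, BFT = BFT, LMT = LMT, LMP = LMP)
}
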