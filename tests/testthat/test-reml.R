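# a very small study for dense-oracle comparisons (8 phenotyped animals)
tiny_sim <- function(seed = 51) {
  simulate_population(n_batches = 2, animals_per_batch = 4,
                      days_per_batch = 5, seed = seed)
}

test_that("model frame shapes and incidence structure are as specified", {
  sim <- small_sim()
  frame <- small_frame(sim)
  expect_equal(length(frame$y1), frame$n1)
  expect_equal(length(frame$y2), nrow(sim$traits))
  expect_true(all(frame$p >= 0 & frame$p <= 1))

  Ainv <- pedigree_Ainv(sim$pedigree)
  parts <- rnresilience:::mme_parts(frame, Ainv, "rnam")
  # slope columns equal intercept columns scaled by the record's p
  nA <- parts$nA; p1 <- parts$p1; p2 <- parts$p2
  Z10 <- as.matrix(parts$M1[, p1 + p2 + seq_len(nA)])
  Z11 <- as.matrix(parts$M1[, p1 + p2 + nA + seq_len(nA)])
  expect_equal(Z11, Z10 * frame$p, tolerance = 1e-12)
  expect_equal(nrow(parts$M1), frame$n1)
  expect_equal(nrow(parts$M2), frame$n2)

  # descriptor with p = 0 everywhere zeroes the slope block
  desc0 <- dplyr::mutate(dplyr::rename(sim$calendar, p = true_p), p = 0)
  frame0 <- suppressMessages(build_model_frame(sim$dfi, sim$traits, desc0))
  parts0 <- rnresilience:::mme_parts(frame0, Ainv, "rnam")
  expect_equal(Matrix::norm(parts0$M1[, p1 + p2 + nA + seq_len(nA)], "F"), 0)

  expect_error(build_model_frame(sim$dfi, sim$traits[0, ],
                                 dplyr::rename(sim$calendar, p = true_p)),
               "zero records")
  expect_error(
    suppressMessages(build_model_frame(
      sim$dfi, sim$traits, dplyr::rename(sim$calendar, p = true_p),
      fixed_config = list(dfi = "nonsense", trait = "sex"))),
    "unknown fixed effect")
})

test_that("hand-built toy incidence matrices match the assembled design", {
  dfi <- tibble::tibble(animal_id = c("a", "b", "c", "a"),
                        batch_id = 1, day_index = c(1, 1, 2, 2),
                        dfi = c(2.1, 2.4, 2.2, 2.5))
  traits <- tibble::tibble(animal_id = c("a", "b", "c"), trait = "AGE",
                           value = c(130, 140, 135))
  desc <- tibble::tibble(batch_id = 1, day_index = c(1, 2), p = c(0.2, 0.9))
  frame <- suppressMessages(build_model_frame(
    dfi, traits, desc, fixed_config = list(dfi = "batch", trait = "batch")))
  Ainv <- Matrix::Diagonal(3)
  dimnames(Ainv) <- list(c("a", "b", "c"), c("a", "b", "c"))
  parts <- rnresilience:::mme_parts(frame, Ainv, "rnam")
  # single batch: both designs collapse to an intercept column
  expect_equal(parts$p1, 1); expect_equal(parts$p2, 1)
  M1 <- as.matrix(parts$M1)
  p <- c(0.2, 0.2, 0.9, 0.9)
  hand <- cbind(1, 0,
                diag(3)[c(1, 2, 3, 1), ], diag(3)[c(1, 2, 3, 1), ] * p,
                matrix(0, 4, 3),
                diag(3)[c(1, 2, 3, 1), ], diag(3)[c(1, 2, 3, 1), ] * p,
                matrix(0, 4, 3))
  expect_equal(unname(M1), unname(hand), tolerance = 1e-12)
})

test_that("MME restricted likelihood equals the dense-matrix oracle", {
  sim <- tiny_sim()
  frame <- small_frame(sim)
  Ainv <- pedigree_Ainv(sim$pedigree)
  A <- pedigree_A(sim$pedigree)
  pars <- default_parameters()

  ll <- restricted_loglik(frame, pars$K, pars$T, pars$Q, Ainv)
  m2_dense <- dense_reml_m2ll(frame, pars$K, pars$T, pars$Q, A)
  expect_equal(-2 * ll, m2_dense, tolerance = 1e-6)

  # a second parameter point, and the animal-model route
  K2 <- diag(c(0.05, 0.1, 20)); T2 <- diag(c(0.02, 0.05, 10))
  ll2 <- restricted_loglik(frame, K2, T2, c(0.2, 10), Ainv)
  expect_equal(-2 * ll2, dense_reml_m2ll(frame, K2, T2, c(0.2, 10), A),
               tolerance = 1e-6)
  Kam <- pars$K[c(1, 3), c(1, 3)]; Tam <- pars$T[c(1, 3), c(1, 3)]
  llam <- restricted_loglik(frame, Kam, Tam, pars$Q, Ainv, model = "am")
  expect_equal(-2 * llam, dense_reml_m2ll(frame, Kam, Tam, pars$Q, A, "am"),
               tolerance = 1e-6)
})

test_that("likelihood obeys scaling and duplication identities", {
  sim <- tiny_sim(52)
  frame <- small_frame(sim)
  Ainv <- pedigree_Ainv(sim$pedigree)
  pars <- default_parameters()

  # consistent rescaling shifts the likelihood by the Jacobian term
  cc <- 3.7
  frame_s <- frame
  frame_s$y1 <- frame$y1 * cc; frame_s$y2 <- frame$y2 * cc
  ll <- restricted_loglik(frame, pars$K, pars$T, pars$Q, Ainv)
  ll_s <- restricted_loglik(frame_s, cc^2 * pars$K, cc^2 * pars$T,
                            cc^2 * pars$Q, Ainv)
  N <- frame$n1 + frame$n2
  p_fix <- ncol(frame$X1) + ncol(frame$X2)
  expect_equal(ll_s, ll - 0.5 * (N - p_fix) * log(cc^2), tolerance = 1e-8)

  # an independent copy of the data doubles likelihood differences
  sim$dfi$animal_id <- as.character(sim$dfi$animal_id)
  sim$traits$animal_id <- as.character(sim$traits$animal_id)
  sim2 <- sim
  sim2$dfi$animal_id <- paste0("dup_", sim2$dfi$animal_id)
  sim2$dfi$batch_id <- sim2$dfi$batch_id + 100
  sim2$dfi$pen <- paste0("dup_", sim2$dfi$pen)
  sim2$traits$animal_id <- paste0("dup_", sim2$traits$animal_id)
  sim2$traits$batch_id <- sim2$traits$batch_id + 100
  sim2$traits$sex <- paste0("dup_", sim2$traits$sex)  # no shared effects
  cal2 <- dplyr::mutate(sim$calendar, batch_id = batch_id + 100)
  dfi_both <- dplyr::bind_rows(sim$dfi, sim2$dfi)
  traits_both <- dplyr::bind_rows(sim$traits, sim2$traits)
  desc_both <- dplyr::bind_rows(dplyr::rename(sim$calendar, p = true_p),
                                dplyr::rename(cal2, p = true_p))
  frame2 <- suppressMessages(build_model_frame(dfi_both, traits_both,
                                               desc_both))
  Ainv2 <- Matrix::bdiag(Ainv, Ainv)
  dimnames(Ainv2) <- list(c(rownames(Ainv), paste0("dup_", rownames(Ainv))),
                          c(rownames(Ainv), paste0("dup_", rownames(Ainv))))
  thA <- list(K = pars$K, T = pars$T, Q = pars$Q)
  thB <- list(K = 1.5 * pars$K, T = 0.8 * pars$T, Q = c(0.3, 9))
  d1 <- restricted_loglik(frame, thA$K, thA$T, thA$Q, Ainv) -
    restricted_loglik(frame, thB$K, thB$T, thB$Q, Ainv)
  d2 <- restricted_loglik(frame2, thA$K, thA$T, thA$Q, Ainv2) -
    restricted_loglik(frame2, thB$K, thB$T, thB$Q, Ainv2)
  expect_equal(d2, 2 * d1, tolerance = 1e-6)
})

test_that("REML fitting converges, nests the animal model, and exposes tidiers", {
  sim <- small_sim()
  frame <- small_frame(sim)
  Ainv <- pedigree_Ainv(sim$pedigree)
  fit <- reml_fit(frame, Ainv, max_iter = 300)
  am <- fit_animal_model(frame, Ainv, max_iter = 300)
  expect_true(fit$converged)
  expect_true(am$converged)
  # nested models: the reaction norm fits at least as well
  expect_gte(am$minus2loglik - fit$minus2loglik, -0.1)
  # PSD estimates at convergence
  expect_silent(chol(fit$K + diag(1e-12, 3)))
  expect_silent(chol(fit$T + diag(1e-12, 3)))
  expect_true(all(fit$Q > 0))

  lrt <- remlrt(fit, am)
  expect_gte(lrt$chi2, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)

  td <- tidy(fit)
  expect_equal(nrow(td), 6 + 6 + 2)
  gl <- glance(fit)
  expect_equal(gl$model, "rnam")
  aug <- augment(fit)
  expect_true(all(c("a10", "a11", "a2") %in% names(aug)))
  sol_g <- fit$solutions$genetic
  expect_equal(nrow(sol_g), 3 * nrow(sim$pedigree))
})

test_that("with p identically zero the slope is inert and models agree", {
  sim <- tiny_sim(53)
  desc0 <- dplyr::mutate(dplyr::rename(sim$calendar, p = true_p), p = 0)
  frame0 <- suppressMessages(build_model_frame(sim$dfi, sim$traits, desc0))
  Ainv <- pedigree_Ainv(sim$pedigree)
  fit <- reml_fit(frame0, Ainv, max_iter = 200)
  am <- fit_animal_model(frame0, Ainv, max_iter = 200)
  # likelihoods coincide (slope terms cannot improve the fit)
  expect_equal(fit$minus2loglik, am$minus2loglik, tolerance = 0.5)
  # intercept genetic variances agree (absolute tolerance)
  expect_lt(abs(fit$K[1, 1] - am$K[1, 1]), 0.1 * am$K[1, 1] + 0.01)
})

test_that("REML ratio test arithmetic and boundary mixture are correct", {
  eq <- remlrt_arithmetic(1234.5, 1234.5)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)

  # quadrature oracle for the mixture survival function at chi2 = 20
  quad <- 0.5 * integrate(function(x) dchisq(x, 5), 20, Inf)$value +
    0.5 * integrate(function(x) dchisq(x, 7), 20, Inf)$value
  r20 <- remlrt_arithmetic(1020, 1000)
  expect_equal(r20$p_value, quad, tolerance = 1e-6)

  sim <- tiny_sim(54)
  frame <- small_frame(sim)
  Ainv <- pedigree_Ainv(sim$pedigree)
  fit <- reml_fit(frame, Ainv, max_iter = 60)
  am2 <- fit_animal_model(frame, Ainv, max_iter = 60)
  am2$data_signature["s1"] <- am2$data_signature["s1"] + 1
  expect_error(remlrt(fit, am2), "different model frames")
  expect_error(remlrt(am2, am2), "reaction-norm fit")
})
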