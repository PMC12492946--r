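# Shared fixtures and independent oracles used across test files.

# a small fully simulated study (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(n_batches = 3, animals_per_batch = 6,
                                    days_per_batch = 8, seed = 42)
    }
    cache
  }
})

# model frame of the small study using the true challenge probability
small_frame <- function(sim = small_sim()) {
  suppressMessages(build_model_frame(
    sim$dfi, sim$traits, dplyr::rename(sim$calendar, p = true_p)))
}

# Independent dense-matrix REML oracle: builds V = Z (K x A) Z' +
# W (T x I) W' + R explicitly from the raw frame pieces and evaluates
# -2 l_R = log|V| + log|X'V^-1 X| + y'Py + (N - p) log(2 pi).
dense_reml_m2ll <- function(frame, K, T, Q, A, model = "rnam") {
  gid <- rownames(A); nA <- length(gid); nP <- length(frame$pe_ids)
  n1 <- frame$n1; n2 <- frame$n2
  Z10 <- matrix(0, n1, nA)
  Z10[cbind(seq_len(n1), match(frame$dfi_animal, gid))] <- 1
  Z2 <- matrix(0, n2, nA)
  Z2[cbind(seq_len(n2), match(frame$trait_animal, gid))] <- 1
  W10 <- matrix(0, n1, nP)
  W10[cbind(seq_len(n1), match(frame$dfi_animal, frame$pe_ids))] <- 1
  W2 <- matrix(0, n2, nP)
  W2[cbind(seq_len(n2), match(frame$trait_animal, frame$pe_ids))] <- 1
  if (model == "rnam") {
    Z <- rbind(cbind(Z10, Z10 * frame$p, matrix(0, n1, nA)),
               cbind(matrix(0, n2, 2 * nA), Z2))
    W <- rbind(cbind(W10, W10 * frame$p, matrix(0, n1, nP)),
               cbind(matrix(0, n2, 2 * nP), W2))
  } else {
    Z <- rbind(cbind(Z10, matrix(0, n1, nA)),
               cbind(matrix(0, n2, nA), Z2))
    W <- rbind(cbind(W10, matrix(0, n1, nP)),
               cbind(matrix(0, n2, nP), W2))
  }
  X <- rbind(cbind(frame$X1, matrix(0, n1, ncol(frame$X2))),
             cbind(matrix(0, n2, ncol(frame$X1)), frame$X2))
  R <- diag(c(rep(Q[1], n1), rep(Q[2], n2)))
  V <- Z %*% kronecker(K, A) %*% t(Z) +
    W %*% kronecker(T, diag(nP)) %*% t(W) + R
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  y <- c(frame$y1, frame$y2)
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XtVX)$modulus +
               t(y) %*% P %*% y + (n1 + n2 - ncol(X)) * log(2 * pi))
}

# Gene-dropping oracle for additive relationships: drops `n_loci` unlinked
# loci with unique founder allele labels and estimates A_ij = 2 * kinship.
gene_drop_A <- function(pedigree, n_loci = 5000, seed = 99) {
  set.seed(seed)
  ped <- pedigree
  ped$sire_id[!is.na(ped$sire_id) & ped$sire_id == 0] <- NA
  ped$dam_id[!is.na(ped$dam_id) & ped$dam_id == 0] <- NA
  id <- ped$animal_id
  s <- match(ped$sire_id, id); d <- match(ped$dam_id, id)
  n <- length(id)
  L1 <- matrix(0L, n, n_loci); L2 <- matrix(0L, n, n_loci)
  for (i in seq_len(n)) {
    L1[i, ] <- if (!is.na(s[i])) {
      ifelse(runif(n_loci) < 0.5, L1[s[i], ], L2[s[i], ])
    } else rep.int(2L * i - 1L, n_loci)
    L2[i, ] <- if (!is.na(d[i])) {
      ifelse(runif(n_loci) < 0.5, L1[d[i], ], L2[d[i], ])
    } else rep.int(2L * i, n_loci)
  }
  kin <- function(i, j) {
    mean((L1[i, ] == L1[j, ]) + (L1[i, ] == L2[j, ]) +
           (L2[i, ] == L1[j, ]) + (L2[i, ] == L2[j, ])) / 2
  }
  list(kinship2 = kin, ids = id)
}
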