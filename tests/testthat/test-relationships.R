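test_that("SNP quality control applies its rules in order", {
  # 10 animals x 4 SNPs: col1 fails call rate (8/10), col2 fails MAF,
  # col3 fails HWE with counts (50,0,50) scaled down, col4 passes
  set.seed(41)
  good <- rbinom(10, 2, 0.5)
  g <- cbind(snpA = c(NA, NA, good[3:10]),
             snpB = c(1, rep(0, 9)),          # MAF 0.05... make it 0.04-ish
             snpC = rep(c(0, 2), 5),          # no heterozygotes at p = 0.5
             snpD = good)
  g[1, "snpB"] <- 0                            # MAF 0 -> below 0.05
  rownames(g) <- paste0("a", 1:10)
  qc <- snp_qc(g)
  expect_equal(qc$report$n_removed_callrate, 1)
  expect_equal(qc$report$n_removed_maf, 1)
  expect_gte(qc$report$n_removed_hwe, 1)
  expect_equal(qc$report$n_snps_out,
               qc$report$n_snps_in - qc$report$n_removed_callrate -
                 qc$report$n_removed_maf - qc$report$n_removed_hwe)
  expect_false("snpC" %in% colnames(qc$genotypes))

  # hand-computed HWE chi-square for counts (50, 0, 50)
  obs <- c(50, 0, 50); m <- 100; p <- 0.5
  expd <- m * c(0.25, 0.5, 0.25)
  chi2 <- sum((obs - expd)^2 / expd)
  expect_equal(chi2, 100)
  expect_lt(pchisq(chi2, 1, lower.tail = FALSE), 1e-20)

  expect_error(snp_qc(matrix(c(0, 0, 0, 0), 2, 2)), "removed")
})

test_that("pedigree relationships reproduce textbook values", {
  # parent-offspring: A = 0.5
  ped <- tibble::tibble(animal_id = 1:3, sire_id = c(NA, NA, 1),
                        dam_id = c(NA, NA, 2))
  A <- pedigree_A(ped)
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "3"], 1)

  # offspring of full-sib mating: F = 0.25, diagonal 1.25
  ped2 <- tibble::tibble(animal_id = 1:5,
                         sire_id = c(NA, NA, 1, 1, 3),
                         dam_id = c(NA, NA, 2, 2, 4))
  A2 <- pedigree_A(ped2)
  expect_equal(A2["5", "5"], 1.25)

  # sparse inverse equals the dense inverse
  ped3 <- simulate_pedigree(20, 3, 2, seed = 4)
  A3 <- pedigree_A(ped3)
  Ainv <- pedigree_Ainv(ped3)
  expect_lt(max(abs(as.matrix(Ainv) - solve(A3))), 1e-8)
  # PSD on generator pedigrees: Cholesky succeeds
  expect_silent(chol(A3))

  expect_error(pedigree_A(tibble::tibble(animal_id = 1:2, sire_id = c(2, NA),
                                         dam_id = c(NA, NA))),
               "precede")
})

test_that("pedigree relationships match the gene-dropping oracle", {
  ped <- simulate_pedigree(30, 3, 2, seed = 13)
  A <- pedigree_A(ped)
  gd <- gene_drop_A(ped, n_loci = 4000, seed = 14)
  set.seed(15)
  pick <- cbind(sample(nrow(A), 40, replace = TRUE),
                sample(nrow(A), 40, replace = TRUE))
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    expect_lt(abs(A[i, j] - gd$kinship2(i, j)), 0.06)
  }
})

test_that("VanRaden G matches hand computation and its invariances", {
  g <- rbind(a = c(0, 2), b = c(2, 0))
  colnames(g) <- c("s1", "s2")
  G <- genomic_G(g, blend_alpha = 1, tune = FALSE)
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  # identical genotype rows give identical diagonal and off-diagonal entries
  set.seed(16)
  gg <- matrix(rbinom(60, 2, 0.4), nrow = 3)
  gg[2, ] <- gg[1, ]
  rownames(gg) <- c("x", "y", "z")
  gg <- gg[, apply(gg, 2, stats::var) > 0]
  G2 <- genomic_G(gg, blend_alpha = 1, tune = FALSE)
  expect_equal(G2["x", "x"], G2["y", "y"])
  expect_equal(G2["x", "x"], G2["x", "y"])

  # gene-dropped genotypes approximate pedigree relationships closely
  ped <- simulate_pedigree(50, 2, 3, seed = 17)
  gm <- simulate_genotypes(ped, 5000, seed = 18)
  gm <- gm[, apply(gm, 2, stats::var) > 0]  # drop drift-fixed SNPs
  A22 <- pedigree_A(ped)
  G3 <- genomic_G(gm, blend_alpha = 1, A22 = A22, tune = TRUE)
  lo <- lower.tri(A22)
  expect_lt(mean(abs(G3[lo] - A22[lo])), 0.05)

  mono <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("m1", "m2")))
  expect_error(genomic_G(mono), "monomorphic")
})

test_that("single-step H inverse obeys its limiting cases and dense oracle", {
  ped <- simulate_pedigree(6, 2, 2, seed = 19)
  A <- pedigree_A(ped)
  Ainv <- pedigree_Ainv(ped)

  # no genotyped animals: H^-1 = A^-1
  H0 <- h_inverse(A, G = NULL, genotyped_index = integer(0))
  expect_lt(max(abs(as.matrix(H0) - solve(A))), 1e-8)

  # all animals genotyped: H^-1 = G^-1
  gm <- simulate_genotypes(ped, 800, seed = 20)
  gm <- gm[, apply(gm, 2, stats::var) > 0]
  Gall <- genomic_G(gm, blend_alpha = 0.95, A22 = A)
  Hall <- h_inverse(A, Gall, genotyped_index = seq_len(nrow(A)))
  expect_lt(max(abs(as.matrix(Hall) - solve(Gall))), 1e-6)

  # mixed case: matches the dense conditional-expectation construction
  gi <- match(ped$animal_id[ped$generation == 2], ped$animal_id)
  ng <- setdiff(seq_len(nrow(A)), gi)
  gm22 <- gm[gi, , drop = FALSE]
  gm22 <- gm22[, apply(gm22, 2, stats::var) > 0]
  G22 <- genomic_G(gm22, blend_alpha = 0.95, A22 = A[gi, gi])
  Hinv <- h_inverse(A, G22, genotyped_index = gi, Ainv = Ainv)
  A12 <- A[ng, gi]; A22 <- A[gi, gi]; A22i <- solve(A22)
  H11 <- A[ng, ng] + A12 %*% A22i %*% (G22 - A22) %*% A22i %*% t(A12)
  H12 <- A12 %*% A22i %*% G22
  H <- matrix(0, nrow(A), nrow(A))
  H[ng, ng] <- H11; H[ng, gi] <- H12; H[gi, ng] <- t(H12); H[gi, gi] <- G22
  expect_lt(max(abs(as.matrix(Hinv) - solve(H))), 1e-6)
  # symmetry
  expect_lt(max(abs(as.matrix(Hinv) - t(as.matrix(Hinv)))),
            1e-10 * max(abs(as.matrix(Hinv))))
})
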