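#' SNP quality control
#'
#' Removes SNPs failing, in this order: call rate below `call_rate_min`;
#' minor allele frequency below `maf_min`; a 1-df chi-square goodness-of-fit
#' test of Hardy--Weinberg proportions at `P < hwe_alpha`. Each SNP is
#' attributed to the first rule it fails.
#'
#' @param genotypes Integer matrix of 0/1/2 calls (NA = missing), animals in
#'   rows.
#' @param call_rate_min,maf_min,hwe_alpha Thresholds.
#' @return A list with `genotypes` (the retained panel) and `report`, a
#'   one-row tibble tallying `n_snps_in`, removals per rule, `n_snps_out`,
#'   `n_animals_out`.
#' @export
snp_qc <- function(genotypes, call_rate_min = 0.90, maf_min = 0.05,
                   hwe_alpha = 0.05) {
  if (nrow(genotypes) < 1 || ncol(genotypes) < 1) {
    stop("need at least one animal and one SNP", call. = FALSE)
  }
  n <- nrow(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  call_rate <- n_obs / n
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    obs <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
    m <- sum(obs)
    q <- (obs[2] + 2 * obs[3]) / (2 * m)
    expd <- m * c((1 - q)^2, 2 * q * (1 - q), q^2)
    if (any(expd == 0)) return(1)
    chi2 <- sum((obs - expd)^2 / expd)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  fail_cr <- call_rate < call_rate_min
  fail_maf <- !fail_cr & maf < maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_alpha
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep)) stop("all SNPs removed by quality control", call. = FALSE)
  report <- tibble::tibble(
    n_snps_in = ncol(genotypes),
    n_removed_callrate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_snps_out = sum(keep),
    n_animals_out = n)
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G0 = Z Z' / (2 sum p_k (1 - p_k))` with `Z = M - 2p`, using observed
#' allele frequencies; missing calls are imputed to the per-SNP mean.
#' Optionally `G0` is rescaled (`tune = TRUE`) so its mean diagonal and mean
#' off-diagonal match those of the pedigree submatrix `A22`, then blended as
#' `G = blend_alpha G0 + (1 - blend_alpha) A22` to guarantee invertibility.
#'
#' @param genotypes QC'd 0/1/2 matrix, animals in rows.
#' @param blend_alpha Weight of the genomic component (set 1 for no blend).
#' @param A22 Pedigree relationship submatrix of the genotyped animals;
#'   required when tuning or blending.
#' @param tune Rescale `G0` to the scale of `A22`.
#' @return A dense symmetric matrix with rownames = animal ids.
#' @export
genomic_G <- function(genotypes, blend_alpha = 0.95, A22 = NULL,
                      tune = !is.null(A22)) {
  M <- genotypes
  p <- colMeans(M, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("monomorphic or all-missing SNP present; run snp_qc first",
         call. = FALSE)
  }
  for (j in which(colSums(is.na(M)) > 0)) {
    M[is.na(M[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(M, 2, 2 * p)
  G0 <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  if ((tune || blend_alpha < 1) && is.null(A22)) {
    stop("A22 is required for tuning/blending", call. = FALSE)
  }
  if (tune) {
    # match mean diagonal and mean off-diagonal to A22: G* = a + b G0
    n <- nrow(G0)
    dG <- mean(diag(G0)); oG <- (sum(G0) - sum(diag(G0))) / (n * (n - 1))
    dA <- mean(diag(A22)); oA <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
    b <- (dA - oA) / (dG - oG)
    a <- dA - b * dG
    G0 <- a + b * G0
  }
  G <- if (blend_alpha < 1) blend_alpha * G0 + (1 - blend_alpha) * A22 else G0
  dimnames(G) <- dimnames(genotypes)[c(1, 1)]
  G
}

#' Inverse of the single-step combined relationship matrix
#'
#' `H^-1 = A^-1 + [[0, 0], [0, G^-1 - A22^-1]]` on the genotyped block
#' (`tau = omega = 1`). With no genotyped animals this is `A^-1`; with all
#' animals genotyped it reduces to `G^-1`.
#'
#' @param A Pedigree numerator relationship matrix (dense, with dimnames),
#'   or its sparse inverse via `Ainv`.
#' @param G Genomic relationship matrix over the genotyped animals.
#' @param genotyped_index Integer or character index of the genotyped
#'   animals within `A`.
#' @param Ainv Optional pre-computed sparse `A^-1` (e.g.
#'   [pedigree_Ainv()]); avoids a dense inversion of `A`.
#' @return A sparse symmetric matrix with the dimnames of `A`.
#' @export
h_inverse <- function(A, G, genotyped_index, Ainv = NULL) {
  if (is.null(Ainv)) {
    Ainv <- Matrix::forceSymmetric(Matrix::Matrix(chol2inv(chol(A))))
    dimnames(Ainv) <- dimnames(A)
  }
  if (length(genotyped_index) == 0) return(Ainv)
  gi <- if (is.character(genotyped_index)) {
    match(genotyped_index, rownames(A))
  } else genotyped_index
  A22 <- A[gi, gi, drop = FALSE]
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) {
    stop("G is singular; blend it with A22 (see genomic_G)", call. = FALSE)
  })
  A22inv <- chol2inv(chol(A22))
  Hinv <- as(Ainv, "CsparseMatrix")
  Hinv[gi, gi] <- Hinv[gi, gi] + (Ginv - A22inv)
  Matrix::forceSymmetric(Hinv)
}

#' Build the full relationship set for an analysis
#'
#' Convenience wrapper producing the pedigree inverse (and, when genotypes
#' are supplied, the QC'd panel, blended genomic matrix and single-step
#' `H^-1`).
#'
#' @param pedigree Pedigree tibble.
#' @param genotypes Optional 0/1/2 matrix on a subset of the pedigree.
#' @param ... Passed to [snp_qc()].
#' @return A list with `kernel_inv` (the matrix to use as the genetic-kernel
#'   inverse in REML), and when genotypes are given, `G`, `qc_report`,
#'   `genotyped_ids`.
#' @export
relationship_set <- function(pedigree, genotypes = NULL, ...) {
  Ainv <- pedigree_Ainv(pedigree)
  if (is.null(genotypes)) return(list(kernel_inv = Ainv))
  qc <- snp_qc(genotypes, ...)
  A <- pedigree_A(pedigree)
  ids <- rownames(qc$genotypes)
  G <- genomic_G(qc$genotypes, A22 = A[ids, ids])
  Hinv <- h_inverse(A, G, genotyped_index = ids, Ainv = Ainv)
  list(kernel_inv = Hinv, G = G, qc_report = qc$report, genotyped_ids = ids)
}
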