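#' Simulate SNP genotypes by gene dropping through a pedigree
#'
#' Founder gametes are drawn from Hardy--Weinberg proportions at per-SNP
#' allele frequencies sampled uniformly in `[maf_low, maf_high]`;
#' descendants inherit one allele per parent per SNP independently
#' (unlinked Mendelian transmission). Missing calls are then inserted
#' completely at random at `missing_rate`.
#'
#' @param pedigree Pedigree tibble (parents before offspring).
#' @param n_snps Number of unlinked SNPs.
#' @param maf_low,maf_high Bounds for founder minor-allele frequencies,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param missing_rate Probability a call is set to `NA`.
#' @param seed Integer seed.
#' @return An integer matrix of 0/1/2 counts (NA = missing) with rownames =
#'   animal ids and colnames = SNP ids.
#' @export
simulate_genotypes <- function(pedigree, n_snps, maf_low = 0.1,
                               maf_high = 0.5, missing_rate = 0, seed = 1) {
  if (nrow(pedigree) == 0) stop("empty pedigree", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  px <- pedigree_index(normalize_pedigree(pedigree))
  n <- px$n
  freq <- stats::runif(n_snps, maf_low, maf_high)
  # two gamete matrices, allele counts in {0,1}
  H1 <- matrix(0L, n, n_snps)
  H2 <- matrix(0L, n, n_snps)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    H1[i, ] <- if (s > 0L) {
      ifelse(stats::runif(n_snps) < 0.5, H1[s, ], H2[s, ])
    } else as.integer(stats::runif(n_snps) < freq)
    H2[i, ] <- if (d > 0L) {
      ifelse(stats::runif(n_snps) < 0.5, H1[d, ], H2[d, ])
    } else as.integer(stats::runif(n_snps) < freq)
  }
  M <- H1 + H2
  if (missing_rate > 0) {
    M[stats::runif(length(M)) < missing_rate] <- NA_integer_
  }
  dimnames(M) <- list(px$id, paste0("snp", seq_len(n_snps)))
  M
}
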