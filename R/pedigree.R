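#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation is
#' produced by pairing every female of the previous generation with a
#' randomly chosen male of that generation (so selfing is impossible), each
#' mating leaving `offspring_per_mating` offspring of random sex. Animals
#' are stored parents-before-offspring.
#'
#' @param n_founders Number of founders (>= 2; both sexes guaranteed).
#' @param n_generations Number of generations bred after the founders
#'   (0 gives founders only).
#' @param offspring_per_mating Litter size per mating.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A tibble with columns `animal_id`, `sire_id`, `dam_id`
#'   (`NA` = unknown), `sex` ("M"/"F") and `generation`.
#' @export
#' @examples
#' simulate_pedigree(n_founders = 6, n_generations = 2, seed = 1)
simulate_pedigree <- function(n_founders, n_generations = 1,
                              offspring_per_mating = 2, seed = 1) {
  if (!is.numeric(n_founders) || n_founders < 2) {
    stop("n_founders must be >= 2", call. = FALSE)
  }
  if (!is.numeric(n_generations) || n_generations < 0) {
    stop("n_generations must be >= 0", call. = FALSE)
  }
  if (offspring_per_mating < 1) {
    stop("offspring_per_mating must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  n_founders <- as.integer(n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)[sample.int(n_founders)]
  ped <- tibble::tibble(
    animal_id = seq_len(n_founders),
    sire_id = NA_integer_, dam_id = NA_integer_,
    sex = sex, generation = 0L)
  g <- 0L
  while (g < n_generations) {
    g <- g + 1L
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal_id[prev$sex == "M"]
    females <- prev$animal_id[prev$sex == "F"]
    if (length(males) == 0 || length(females) == 0) {
      stop("generation ", g - 1L, " has a single sex; cannot mate",
           call. = FALSE)
    }
    sires <- sample(males, length(females), replace = TRUE)
    n_off <- length(females) * offspring_per_mating
    off <- tibble::tibble(
      animal_id = max(ped$animal_id) + seq_len(n_off),
      sire_id = rep(sires, each = offspring_per_mating),
      dam_id = rep(females, each = offspring_per_mating),
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g)
    ped <- dplyr::bind_rows(ped, off)
  }
  ped
}

# internal: validate ordering and map parent ids to row indices (0 = unknown)
pedigree_index <- function(pedigree) {
  id <- pedigree$animal_id
  if (anyDuplicated(id)) stop("duplicated animal ids", call. = FALSE)
  s <- match(pedigree$sire_id, id)
  d <- match(pedigree$dam_id, id)
  s[is.na(pedigree$sire_id)] <- 0L
  d[is.na(pedigree$dam_id)] <- 0L
  if (any(is.na(s)) || any(is.na(d))) {
    stop("every named parent must appear as an animal", call. = FALSE)
  }
  n <- length(id)
  if (any(s >= seq_len(n)) || any(d >= seq_len(n))) {
    stop("parents must precede offspring (pedigree not sorted or cyclic)",
         call. = FALSE)
  }
  list(sire = s, dam = d, id = id, n = n)
}

#' Pedigree numerator relationship matrix
#'
#' Tabular-method recursion with inbreeding: `A[i,i] = 1 + 0.5 A[s,d]` and
#' `A[i,j] = 0.5 (A[j,s] + A[j,d])`, unknown parents contributing zero.
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id` (`NA` or 0 =
#'   unknown), parents stored before offspring.
#' @return A dense symmetric matrix with dimnames = animal ids.
#' @export
pedigree_A <- function(pedigree) {
  pedigree <- normalize_pedigree(pedigree)
  px <- pedigree_index(pedigree)
  n <- px$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[j, s]
      if (d > 0L) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(px$id, px$id)
  A
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: per-animal Mendelian sampling
#' variances use the parental inbreeding coefficients (obtained from the
#' tabular-method diagonal), so `pedigree_Ainv(ped)` equals
#' `solve(pedigree_A(ped))`.
#'
#' @inheritParams pedigree_A
#' @return A sparse symmetric `Matrix::dgCMatrix` with dimnames = animal ids.
#' @export
pedigree_Ainv <- function(pedigree) {
  pedigree <- normalize_pedigree(pedigree)
  px <- pedigree_index(pedigree)
  Fcoef <- diag(pedigree_A(pedigree)) - 1
  n <- px$n
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (i in seq_len(n)) {
    s <- px$sire[i]; d <- px$dam[i]
    Fs <- if (s > 0L) Fcoef[s] else 0
    Fd <- if (d > 0L) Fcoef[d] else 0
    dv <- 1 - (s > 0L) * 0.25 * (1 + Fs) - (d > 0L) * 0.25 * (1 + Fd)
    m <- 1 / dv
    add(i, i, m)
    for (par in c(s, d)[c(s, d) > 0L]) {
      add(i, par, -m / 2); add(par, i, -m / 2)
    }
    if (s > 0L && d > 0L) {
      add(s, s, m / 4); add(d, d, m / 4)
      add(s, d, m / 4); add(d, s, m / 4)
    } else if (s > 0L) add(s, s, m / 4) else if (d > 0L) add(d, d, m / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(px$id, px$id))
  Matrix::forceSymmetric(Ainv)
}

# internal: accept 0 or NA as unknown parent; coerce ids to integer-like
normalize_pedigree <- function(pedigree) {
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(pedigree)))
  pedigree$sire_id[!is.na(pedigree$sire_id) & pedigree$sire_id == 0] <- NA
  pedigree$dam_id[!is.na(pedigree$dam_id) & pedigree$dam_id == 0] <- NA
  pedigree
}
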