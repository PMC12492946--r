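# Recognized fixed-effect names and the data column each maps to.
# "weight_control", "carcass_weight", "sample_weight" enter as continuous
# covariates when numeric; everything else is a factor.
fixed_effect_columns <- c(
  sex = "sex", pen = "pen", batch = "batch_id", farm = "farm",
  weight_control = "weight_control", carcass_weight = "carcass_weight",
  slaughter_date = "slaughter_date", sample_weight = "sample_weight")
continuous_effects <- c("weight_control", "carcass_weight", "sample_weight")

# internal: full-rank fixed-effect design with reference-level coding
fixed_design <- function(data, effects, label) {
  unknown <- setdiff(effects, names(fixed_effect_columns))
  if (length(unknown)) {
    stop("unknown fixed effect name(s) for ", label, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- fixed_effect_columns[effects]
  present <- cols[cols %in% names(data)]
  dropped <- setdiff(cols, present)
  if (length(dropped)) {
    message("build_model_frame: effect column(s) absent from ", label,
            " data, skipped: ", paste(dropped, collapse = ", "))
  }
  df <- as.data.frame(data[, present, drop = FALSE])
  for (nm in names(df)) {
    if (!names(present)[match(nm, present)] %in% continuous_effects ||
        !is.numeric(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
      if (nlevels(df[[nm]]) < 2) df[[nm]] <- NULL  # constant: absorbed
    }
  }
  X <- if (ncol(df) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = df)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

#' Assemble the bivariate reaction-norm model frame
#'
#' Joins the environmental descriptor onto the daily feed intake records,
#' builds full-rank fixed-effect designs for both traits (reference-level
#' coding; requested effects whose columns are absent from the data are
#' skipped with a message, unrecognized names are an error) and collects
#' the response vectors, the per-record challenge probability `p`, and the
#' animal index maps the sparse mixed-model equations need. Records whose
#' batch-day has no descriptor value are dropped with a reported count.
#'
#' @param dfi DFI records: `animal_id`, `batch_id`, `day_index`, `dfi`,
#'   plus any fixed-effect columns (e.g. `pen`).
#' @param traits Single-record trait data: `animal_id`, `value`, plus
#'   fixed-effect columns (e.g. `sex`, `batch_id`).
#' @param descriptor Tibble `batch_id`, `day_index`, `p` from
#'   [posterior_challenge_probability()] (or a calendar's `true_p` renamed).
#' @param fixed_config List with character vectors `dfi` and `trait` naming
#'   the fixed effects per trait; defaults to [default_fixed_effects()] for
#'   the trait in `traits`.
#' @return An object of class `model_frame`.
#' @export
build_model_frame <- function(dfi, traits, descriptor, fixed_config = NULL) {
  if (nrow(traits) == 0) stop("trait with zero records", call. = FALSE)
  if (nrow(dfi) == 0) stop("no DFI records", call. = FALSE)
  trait_name <- if ("trait" %in% names(traits)) traits$trait[1] else "trait2"
  if (is.null(fixed_config)) {
    fixed_config <- tryCatch(default_fixed_effects(trait_name),
                             error = function(e) list(dfi = "batch",
                                                      trait = "batch"))
  }
  d <- dplyr::inner_join(dfi, descriptor[, c("batch_id", "day_index", "p")],
                         by = c("batch_id", "day_index"))
  n_drop <- nrow(dfi) - nrow(d)
  if (n_drop > 0) {
    message("build_model_frame: dropped ", n_drop,
            " DFI record(s) without a descriptor value")
  }
  if (nrow(d) == 0) stop("no DFI records with a descriptor", call. = FALSE)
  if (any(d$p < 0 | d$p > 1)) stop("p must be in [0, 1]", call. = FALSE)

  X1 <- fixed_design(d, fixed_config$dfi, "DFI")
  X2 <- fixed_design(traits, fixed_config$trait, trait_name)
  dfi_animal <- as.character(d$animal_id)
  trait_animal <- as.character(traits$animal_id)
  pe_ids <- sort(unique(c(dfi_animal, trait_animal)))
  structure(list(
    y1 = d$dfi, y2 = traits$value, X1 = X1, X2 = X2, p = d$p,
    dfi_animal = dfi_animal, trait_animal = trait_animal, pe_ids = pe_ids,
    n1 = nrow(d), n2 = nrow(traits), trait = trait_name,
    n_dropped = n_drop), class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat("<model_frame> DFI records:", x$n1, " (", ncol(x$X1), "fixed cols ),",
      x$trait, "records:", x$n2, " (", ncol(x$X2), "fixed cols ),",
      length(x$pe_ids), "animals with records\n")
  invisible(x)
}

# internal: sparse joint design matrix and block bookkeeping.
# Column order: [X1 | X2 | genetic effect blocks | pe effect blocks];
# genetic blocks span all kernel animals, pe blocks the recorded animals.
# model = "rnam": effects (intercept, slope, trait2); "am": (dfi, trait2).
mme_parts <- function(frame, relationship_inv, model = c("rnam", "am")) {
  model <- match.arg(model)
  gen_ids <- rownames(relationship_inv)
  if (is.null(gen_ids)) stop("relationship_inv needs dimnames", call. = FALSE)
  miss <- setdiff(c(frame$dfi_animal, frame$trait_animal), gen_ids)
  if (length(miss)) {
    stop("animals missing from the relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  nA <- length(gen_ids); nP <- length(frame$pe_ids)
  n1 <- frame$n1; n2 <- frame$n2
  p1 <- ncol(frame$X1); p2 <- ncol(frame$X2)
  g1 <- match(frame$dfi_animal, gen_ids)
  g2 <- match(frame$trait_animal, gen_ids)
  e1 <- match(frame$dfi_animal, frame$pe_ids)
  e2 <- match(frame$trait_animal, frame$pe_ids)
  ind <- function(n, j, ncol, x = rep(1, n)) {
    Matrix::sparseMatrix(i = seq_len(n), j = j, x = x, dims = c(n, ncol))
  }
  X1s <- Matrix::Matrix(frame$X1, sparse = TRUE)
  X2s <- Matrix::Matrix(frame$X2, sparse = TRUE)
  Z0 <- function(n, ncol) Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0),
                                               dims = c(n, ncol))
  if (model == "rnam") {
    M1 <- cbind(X1s, Z0(n1, p2),
                ind(n1, g1, nA), ind(n1, g1, nA, frame$p), Z0(n1, nA),
                ind(n1, e1, nP), ind(n1, e1, nP, frame$p), Z0(n1, nP))
    M2 <- cbind(Z0(n2, p1), X2s,
                Z0(n2, nA), Z0(n2, nA), ind(n2, g2, nA),
                Z0(n2, nP), Z0(n2, nP), ind(n2, e2, nP))
    k <- 3L
  } else {
    M1 <- cbind(X1s, Z0(n1, p2), ind(n1, g1, nA), Z0(n1, nA),
                ind(n1, e1, nP), Z0(n1, nP))
    M2 <- cbind(Z0(n2, p1), X2s, Z0(n2, nA), ind(n2, g2, nA),
                Z0(n2, nP), ind(n2, e2, nP))
    k <- 2L
  }
  Hinv <- Matrix::forceSymmetric(methods::as(relationship_inv,
                                             "CsparseMatrix"))
  chH <- Matrix::Cholesky(Hinv, LDL = TRUE, perm = TRUE)
  logdetH <- -as.numeric(Matrix::determinant(chH, logarithm = TRUE,
                                             sqrt = FALSE)$modulus)
  list(
    M1 = M1, M2 = M2,
    CtC1 = Matrix::crossprod(M1), CtC2 = Matrix::crossprod(M2),
    r1 = Matrix::crossprod(M1, frame$y1),
    r2 = Matrix::crossprod(M2, frame$y2),
    yy1 = sum(frame$y1^2), yy2 = sum(frame$y2^2),
    Hinv = Hinv, logdetH = logdetH, Ipe = Matrix::Diagonal(nP),
    k = k, nA = nA, nP = nP, n1 = n1, n2 = n2, p_fixed = p1 + p2,
    p1 = p1, p2 = p2, gen_ids = gen_ids, pe_ids = frame$pe_ids,
    fixed_names = c(paste0("dfi:", colnames(frame$X1)),
                    paste0(frame$trait, ":", colnames(frame$X2))),
    model = model)
}

# internal: -2 * restricted log-likelihood (with Gaussian constant) and,
# optionally, the MME solutions, for given variance components.
mme_eval <- function(parts, K, T, Q, solutions = FALSE) {
  k <- parts$k
  stopifnot(nrow(K) == k, nrow(T) == k, length(Q) == 2, all(Q > 0))
  cK <- tryCatch(chol(K), error = function(e) NULL)
  cT <- tryCatch(chol(T), error = function(e) NULL)
  if (is.null(cK) || is.null(cT)) return(list(m2ll = 1e12))
  Kinv <- chol2inv(cK); Tinv <- chol2inv(cT)
  ldK <- 2 * sum(log(diag(cK))); ldT <- 2 * sum(log(diag(cT)))
  Ginv <- Matrix::bdiag(
    Matrix::Diagonal(parts$p_fixed, x = 0),
    kronecker(Kinv, parts$Hinv),
    kronecker(Tinv, parts$Ipe))
  C <- parts$CtC1 / Q[1] + parts$CtC2 / Q[2] + Ginv
  rhs <- parts$r1 / Q[1] + parts$r2 / Q[2]
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = TRUE, perm = TRUE),
    error = function(e) NULL)
  if (is.null(ch)) return(list(m2ll = 1e12))
  logdetC <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                            sqrt = FALSE)$modulus)
  sol <- Matrix::solve(ch, rhs, system = "A")
  yPy <- parts$yy1 / Q[1] + parts$yy2 / Q[2] - sum(sol * rhs)
  logdetG <- parts$nA * ldK + k * parts$logdetH + parts$nP * ldT
  N <- parts$n1 + parts$n2
  m2ll <- parts$n1 * log(Q[1]) + parts$n2 * log(Q[2]) + logdetG +
    logdetC + yPy + (N - parts$p_fixed) * log(2 * pi)
  out <- list(m2ll = as.numeric(m2ll))
  if (solutions) out$sol <- as.numeric(sol)
  out
}

#' Restricted log-likelihood of the bivariate reaction-norm model
#'
#' Evaluates the REML log-likelihood of the Gaussian mixed model with
#' marginal covariance `V = Z (K %x% H) Z' + W (T %x% I) W' + R` (residuals
#' diagonal by trait from `Q`) at given variance components, through sparse
#' mixed-model-equation identities rather than the dense `V`:
#' `-2 l_R = log|R| + log|G| + log|C| + y' P y + (N - p) log(2 pi)`.
#'
#' @param frame A [build_model_frame()] object.
#' @param K,T Genetic and permanent-environmental covariance matrices
#'   (3x3 for the reaction-norm model, 2x2 for the plain animal model).
#' @param Q Length-2 vector of residual variances (DFI, trait2).
#' @param relationship_inv Sparse inverse of the genetic kernel (pedigree
#'   `A^-1` or single-step `H^-1`) with animal ids as dimnames.
#' @param model `"rnam"` (reaction norm) or `"am"` (plain animal model).
#' @return The restricted log-likelihood (a scalar; includes the Gaussian
#'   constant).
#' @export
restricted_loglik <- function(frame, K, T, Q, relationship_inv,
                              model = c("rnam", "am")) {
  check_psd(K, "K"); check_psd(T, "T")
  if (any(Q <= 0)) stop("Q must be positive", call. = FALSE)
  parts <- mme_parts(frame, relationship_inv, match.arg(model))
  ev <- mme_eval(parts, K, T, Q)
  if (ev$m2ll >= 1e12) stop("likelihood evaluation failed (non-PD system)",
                            call. = FALSE)
  -0.5 * ev$m2ll
}
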