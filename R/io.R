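# internal: CSV writer that renders doubles with 17 significant digits so
# a read-back is bit-identical (needed for faithful pipeline resumption)
write_csv_exact <- function(df, path) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a simulation to plain-text files
#'
#' Writes the feed-intake and trait records as tidy CSV, the pedigree as a
#' 3-column CSV (animal, sire, dam; 0 = unknown), the calendar as CSV, the
#' generating parameters as YAML and a JSON manifest recording the files.
#'
#' @param sim An `rn_simulation` from [simulate_phenotypes()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_simulation <- function(sim, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- sim$pedigree[, c("animal_id", "sire_id", "dam_id")]
  ped$sire_id[is.na(ped$sire_id)] <- 0
  ped$dam_id[is.na(ped$dam_id)] <- 0
  files <- list(
    dfi = "dfi_records.csv", traits = "trait_records.csv",
    pedigree = "pedigree.csv", calendar = "calendar.csv",
    params = "parameters.yaml")
  write_csv_exact(sim$dfi, file.path(dir, files$dfi))
  write_csv_exact(sim$traits, file.path(dir, files$traits))
  readr::write_csv(ped, file.path(dir, files$pedigree))
  write_csv_exact(sim$calendar, file.path(dir, files$calendar))
  write_parameters_yaml(sim$params, file.path(dir, files$params))
  manifest <- list(seed = seed, files = files,
                   n_dfi = nrow(sim$dfi), n_traits = nrow(sim$traits),
                   n_pedigree = nrow(sim$pedigree))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_simulation
#' @param path File path.
#' @export
read_dfi_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize / read generator parameters as YAML
#'
#' @param params An [default_parameters()] object.
#' @param path File path.
#' @return `read_parameters_yaml()` returns an `rn_parameters` object.
#' @export
write_parameters_yaml <- function(params, path) {
  yaml::write_yaml(list(
    trait = params$trait,
    K = as.list(as.data.frame(params$K)),
    T = as.list(as.data.frame(params$T)),
    Q = params$Q, mu = params$mu,
    mixture = list(weight = params$mixture$weight,
                   mean = params$mixture$mean, sd = params$mixture$sd),
    challenge_prevalence = params$challenge_prevalence), path)
  invisible(path)
}

#' @rdname write_parameters_yaml
#' @export
read_parameters_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  default_parameters(
    trait = y$trait,
    K = matrix(unlist(y$K), 3, 3), T = matrix(unlist(y$T), 3, 3),
    Q = unlist(y$Q), mu = unlist(y$mu),
    mixture_means = unlist(y$mixture$mean),
    mixture_sds = unlist(y$mixture$sd),
    mixture_weights = unlist(y$mixture$weight),
    challenge_prevalence = y$challenge_prevalence)
}

#' Write / read genotypes as a TSV matrix
#'
#' Animals in rows (first column `animal_id`), SNPs in columns, calls in
#' `{0, 1, 2, NA}`.
#'
#' @param genotypes 0/1/2 matrix with dimnames.
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(animal_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  M <- as.matrix(df[, -1])
  storage.mode(M) <- "integer"
  rownames(M) <- as.character(df$animal_id)
  M
}

#' Write a symmetric matrix in coordinate format
#'
#' Upper triangle as `i, j, value` rows plus a companion id-map file
#' (`<path>.ids`) listing the row labels.
#'
#' @param M Matrix (dense or sparse) with dimnames.
#' @param path File path.
#' @export
write_matrix_coords <- function(M, path) {
  Ms <- methods::as(methods::as(Matrix::Matrix(M), "generalMatrix"),
                    "TsparseMatrix")
  keep <- Ms@i <= Ms@j
  readr::write_csv(tibble::tibble(i = Ms@i[keep] + 1L, j = Ms@j[keep] + 1L,
                                  value = Ms@x[keep]), path)
  readr::write_lines(rownames(M), paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_matrix_coords
#' @export
read_matrix_coords <- function(path) {
  co <- readr::read_csv(path, show_col_types = FALSE)
  ids <- readr::read_lines(paste0(path, ".ids"))
  n <- length(ids)
  M <- Matrix::sparseMatrix(i = co$i, j = co$j, x = co$value, dims = c(n, n),
                            symmetric = TRUE, dimnames = list(ids, ids))
  M
}
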